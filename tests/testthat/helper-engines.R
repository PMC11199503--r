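# Naive per-cell reference engine: every cell is one row, events drawn cell
# by cell. Independent of the clone-indexed implementation; used as a
# distributional oracle on tiny instances (NS scenario: visible antigenicity
# is the full cumulative antigenicity, so no genealogy bookkeeping needed).
naive_simulate <- function(config, steps, n0 = 1L) {
  b <- config$division_prob
  b0 <- config$basal_survival
  s <- config$selection_s
  c1 <- config$cell_threshold
  A <- rep(0, n0)
  for (t in seq_len(steps)) {
    n <- length(A)
    if (n == 0L) break
    newA <- numeric(0)
    for (i in seq_len(n)) {
      a <- A[i]
      if (a > c1) {                       # immune attack on immunogenic cells
        if (stats::runif(1) < min(1, -s * a)) next
      }
      if (stats::runif(1) < b) {
        for (d in 1:2) {
          m <- stats::rpois(1, config$mutation_rate / 2)
          add <- 0
          if (m > 0) {
            anti <- stats::runif(m) < config$antigenic_fraction
            if (any(anti)) {
              add <- sum(stats::rexp(sum(anti),
                                     1 / config$antigenicity_mean))
            }
          }
          newA <- c(newA, a + add)
        }
      } else {
        dq <- min(1, max(0, 1 - (1 + (if (a > c1) s else 0) * a) * b0))
        if (stats::runif(1) >= dq) newA <- c(newA, a)
      }
    }
    A <- newA
    if (length(A) >= config$max_population) break
  }
  length(A)
}

# Hand-built simulation result: founder clone 1 (no mutations), clone 2 adds
# mutation A (50 cells + 30 in its child), clone 3 = child of 2 adds B
# (30 cells), clone 4 adds C (20 cells). T = 100.
toy_result <- function() {
  structure(list(
    clones = data.frame(
      clone_id = c(2L, 3L, 4L), cell_count = c(50L, 30L, 20L),
      cumulative_antigenicity = c(0.3, 0.3, 0),
      escaped = FALSE, driver_count = 0L
    ),
    genealogy = c(0L, 1L, 2L, 1L),
    mutations = data.frame(
      mutation_id = 1:3, origin_clone = c(2L, 3L, 4L),
      antigenicity = c(0.3, 0, 0), is_antigenic = c(TRUE, FALSE, FALSE),
      is_driver = FALSE, birth_step = c(1L, 2L, 2L)
    ),
    snapshots = list(),
    outcome = "censored", outcome_time = 2L,
    config = sim_config("NS", rng_seed = 1)
  ), class = "nfds_result")
}

# Log-rank oracle: observed-minus-expected and hypergeometric variance
# accumulated over the pooled risk table, independent of survival::survdiff.
logrank_by_hand <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a == 1], time_b[event_b == 1])))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t & event_a == 1)
    d2 <- sum(time_b == t & event_b == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}
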