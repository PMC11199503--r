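#' Initialize a tumor state
#'
#' Creates the founding population: a single antigenically neutral cell (the
#' founder carries no neoantigens, so that a highly immunogenic founder cannot
#' abort the lineage immediately).
#'
#' @param config An [sim_config()] object.
#' @return An object of class `nfds_state`.
#' @export
new_tumor <- function(config) {
  validate_config(config)
  cap <- 4096L
  parent_full <- integer(cap)
  asum_full <- numeric(cap)
  state <- list(
    time = 0L,
    clone_id = 1L,
    clone_A = 0,
    clone_escaped = FALSE,
    clone_driver = 0L,
    clone_count = 1L,
    next_clone_id = 2L,
    next_mutation_id = 1L,
    parent_full = parent_full,   # parent id of every clone ever created
    asum_full = asum_full,       # antigenicity originating in each clone
    mut_chunks = list(),
    traj = list(c(0, 1, 0, 0)),
    icb_active = FALSE,
    icb_started_at = NA_integer_,
    post_icb_taken = FALSE,
    snapshots = list()
  )
  class(state) <- "nfds_state"
  state
}

#' Total cells of a tumor state
#' @param state An `nfds_state`.
#' @return Integer population size.
#' @export
total_cells <- function(state) sum(state$clone_count)

# Visible (immune-presented) antigenicity of each active clone.
#
# Under NS every neoantigen a lineage carries is presented, so the visible
# antigenicity is the full cumulative antigenicity. Under NFDS the immune
# response depends on the clonality of each neoantigen: an antigen is
# presented effectively only while its cancer-cell fraction exceeds the
# tumor threshold c2. All mutations that originated in the same clone share
# one carrier set (that clone's subtree), so per-antigen frequencies reduce
# to per-origin-clone frequencies and the visible antigenicity of a cell is
# the path sum, over its ancestry, of the antigenicity that originated in
# frequent clones.
visible_antigenicity <- function(state, config) {
  if (!(config$scenario %in% c("NFDS", "NFDS_IE"))) {
    return(state$clone_A)
  }
  n <- state$next_clone_id - 1L
  parent <- state$parent_full[seq_len(n)]
  carriers <- .subtree_carriers(parent, state$clone_id,
                                as.numeric(state$clone_count))
  total <- sum(state$clone_count)
  g <- state$asum_full[seq_len(n)]
  g[carriers <= config$tumor_threshold * total] <- 0
  .path_sums(parent, g)[state$clone_id]
}

#' Advance a tumor state by one synchronous generation
#'
#' One step of the default event scheme. The ambient selection coefficient is
#' fixed from the pre-step state via [effective_selection()]. Selected
#' immunogenic cells survive immune attack with probability
#' `1 + s * a_vis` (clamped), where `a_vis` is the visible antigenicity
#' (the full cumulative antigenicity under NS; under NFDS only neoantigens
#' whose cancer-cell fraction exceeds `c2` are presented). Surviving cells
#' divide with probability `b` (two daughters, each drawing new mutations
#' and testing for immune escape and driver events) or otherwise die with
#' the [death_prob()] of their visible antigenicity (the basal `1 - b0` for
#' non-immunogenic and escaped cells). Escaped cells are exempt from
#' selection until immune-checkpoint blockade revokes the exemption.
#'
#' @param state An `nfds_state` (non-extinct).
#' @param config The [sim_config()] used for the run.
#' @return The advanced `nfds_state` (time increased by one).
#' @export
advance_step <- function(state, config) {
  if (total_cells(state) == 0L) stop("population is extinct", call. = FALSE)
  b <- config$division_prob
  b0 <- config$basal_survival
  c1 <- config$cell_threshold
  p <- config$antigenic_fraction
  amean <- config$antigenicity_mean
  attn <- config$driver_attenuation
  t_now <- state$time

  # ICB latch: a step starting at or after icb_time (or after the population
  # milestone has been hit) applies therapy.
  if (!state$icb_active) {
    hit_time <- !is.na(config$icb_time) && t_now >= config$icb_time
    hit_pop <- !is.na(config$icb_population_fraction) &&
      total_cells(state) >=
        config$icb_population_fraction * config$max_population
    if (hit_time || hit_pop) {
      state$icb_active <- TRUE
      state$icb_started_at <- t_now
      state$snapshots[[length(state$snapshots) + 1L]] <- list(
        label = "pre_icb", time = t_now,
        clone_id = state$clone_id, clone_count = state$clone_count
      )
    }
  }
  pe <- if (state$icb_active) 0 else config$escape_prob

  cnt <- state$clone_count
  a_vis <- effective_antigenicity(visible_antigenicity(state, config),
                                  state$clone_driver, attn)
  immu <- a_vis > c1
  T_tot <- sum(cnt)
  T_ac <- sum(cnt[immu])
  s_amb <- effective_selection(T_ac, T_tot, config$tumor_threshold,
                               config$selection_s, config$scenario)
  exempt <- state$clone_escaped & !state$icb_active
  selected <- immu & !exempt
  s_cell <- ifelse(selected, s_amb, 0)

  if (config$event_scheme == "division_first") {
    k <- attack_prob(a_vis, s_cell)
    nkill <- stats::rbinom(length(cnt), cnt, k)
    alive <- cnt - nkill
    ndiv <- stats::rbinom(length(cnt), alive, b)
    dq <- death_prob(a_vis, s_cell, b0)
    ndie <- stats::rbinom(length(cnt), alive - ndiv, dq)
  } else {
    # competing-rates alternative: division and the Eq.-2 death probability
    # compete directly; renormalized when b + d exceeds one.
    d <- death_prob(a_vis, s_cell, b0)
    z <- pmax(1, b + d)
    ndiv <- stats::rbinom(length(cnt), cnt, b / z)
    ndie <- stats::rbinom(length(cnt), cnt - ndiv,
                          pmin(1, d / z / pmax(1e-12, 1 - b / z)))
    alive <- cnt
  }
  stay <- alive - ndiv - ndie

  n_daughters <- 2L * sum(ndiv)
  if (n_daughters > 0L) {
    pidx <- rep(seq_along(cnt), 2L * ndiv)
    if (config$mutation_dosing == "split") {
      m <- stats::rpois(n_daughters, config$mutation_rate / 2)
    } else {
      m <- integer(n_daughters)
      odd <- seq(1L, n_daughters, by = 2L)
      m[odd] <- stats::rpois(length(odd), config$mutation_rate)
    }
    esc_new <- if (pe > 0) stats::runif(n_daughters) < pe
               else logical(n_daughters)
    drv_new <- if (config$driver_prob > 0) {
      stats::runif(n_daughters) < config$driver_prob
    } else logical(n_daughters)

    unchanged <- m == 0L & !esc_new & !drv_new
    stay <- stay + tabulate(pidx[unchanged], nbins = length(cnt))
    newi <- which(!unchanged)
    nn <- length(newi)
    if (nn > 0L) {
      mi <- m[newi]
      pn <- pidx[newi]
      total_m <- sum(mi)
      grp <- rep.int(seq_len(nn), mi)
      is_anti <- stats::runif(total_m) < p
      a_vals <- numeric(total_m)
      a_vals[is_anti] <- stats::rexp(sum(is_anti), rate = 1 / amean)
      dA <- numeric(nn)
      if (total_m > 0L) {
        ss <- rowsum(a_vals, grp)
        dA[as.integer(rownames(ss))] <- ss[, 1L]
      }
      has_drv <- drv_new[newi]
      n_drv <- sum(has_drv)
      drv_anti <- logical(0)
      drv_vals <- numeric(0)
      if (n_drv > 0L) {
        # a driver event is itself a mutation and may be antigenic
        drv_anti <- stats::runif(n_drv) < p
        drv_vals <- numeric(n_drv)
        drv_vals[drv_anti] <- stats::rexp(sum(drv_anti), rate = 1 / amean)
        dA[has_drv] <- dA[has_drv] + drv_vals
      }

      ids_new <- seq.int(state$next_clone_id, length.out = nn)
      last_id <- state$next_clone_id + nn - 1L
      if (last_id > length(state$parent_full)) {
        new_cap <- max(2L * length(state$parent_full), last_id)
        state$parent_full <- c(state$parent_full,
                               integer(new_cap - length(state$parent_full)))
        state$asum_full <- c(state$asum_full,
                             numeric(new_cap - length(state$asum_full)))
      }
      state$parent_full[ids_new] <- state$clone_id[pn]
      state$asum_full[ids_new] <- dA
      n_mut_rows <- total_m + n_drv
      if (n_mut_rows > 0L) {
        chunk <- list(
          origin = c(rep.int(ids_new, mi), ids_new[has_drv]),
          antigenicity = c(a_vals, drv_vals),
          is_antigenic = c(is_anti, drv_anti),
          is_driver = c(logical(total_m), rep.int(TRUE, n_drv)),
          birth_step = rep.int(t_now + 1L, n_mut_rows)
        )
        state$mut_chunks[[length(state$mut_chunks) + 1L]] <- chunk
        state$next_mutation_id <- state$next_mutation_id + n_mut_rows
      }
      state$clone_id <- c(state$clone_id, ids_new)
      state$clone_A <- c(state$clone_A, state$clone_A[pn] + dA)
      state$clone_escaped <- c(state$clone_escaped,
                               state$clone_escaped[pn] | esc_new[newi])
      state$clone_driver <- c(state$clone_driver,
                              state$clone_driver[pn] + as.integer(has_drv))
      state$next_clone_id <- state$next_clone_id + nn
      cnt <- c(stay, rep.int(1L, nn))
    } else {
      cnt <- stay
    }
  } else {
    cnt <- stay
  }

  keep <- cnt > 0L
  state$clone_id <- state$clone_id[keep]
  state$clone_A <- state$clone_A[keep]
  state$clone_escaped <- state$clone_escaped[keep]
  state$clone_driver <- state$clone_driver[keep]
  state$clone_count <- cnt[keep]
  state$time <- t_now + 1L

  if (length(state$clone_id) > 0L) {
    a_vis2 <- effective_antigenicity(visible_antigenicity(state, config),
                                     state$clone_driver, attn)
    t_ac2 <- sum(state$clone_count[a_vis2 > c1])
  } else {
    t_ac2 <- 0
  }
  state$traj[[length(state$traj) + 1L]] <- c(
    state$time, sum(state$clone_count), t_ac2,
    sum(state$clone_count[state$clone_escaped])
  )
  # on-therapy snapshot a fixed number of steps after ICB activation
  if (state$icb_active && !state$post_icb_taken &&
      state$time - state$icb_started_at >= config$icb_observe_delta &&
      length(state$clone_id) > 0L) {
    state$post_icb_taken <- TRUE
    state$snapshots[[length(state$snapshots) + 1L]] <- list(
      label = "post_icb", time = state$time,
      clone_id = state$clone_id, clone_count = state$clone_count
    )
  }
  state
}

#' Simulate one tumor
#'
#' Runs the branching process from a single neutral founder until extinction,
#' the population ceiling, or the step horizon. All randomness is drawn from
#' R's RNG, seeded with `config$rng_seed` when set.
#'
#' @param config An [sim_config()] object.
#' @param snapshot_times Optional numeric vector of times at which to record
#'   clone snapshots (usable later by [true_ccf_table()]). A snapshot labelled
#'   `"pre_icb"` is always recorded when ICB activates.
#' @param record_mutations Keep the per-mutation registry (needed for CCF
#'   tables). Disable for pure population-dynamics runs to save memory.
#' @return An object of class `nfds_result` with elements `trajectory`
#'   (data frame: `time`, `total_cells`, `immunogenic_cells`,
#'   `escaped_cells`), `outcome` (`"reached_ceiling"`, `"extinct"`, or
#'   `"censored"`), `outcome_time`, `max_population_attained`, `clones`
#'   (final live clones), `genealogy` (parent index of every clone ever
#'   created), `mutations`, `snapshots`, `config`, and `seed`.
#' @examples
#' cfg <- sim_config(scenario = "NFDS", max_population = 500,
#'                   max_time = 200, rng_seed = 42)
#' res <- simulate_tumor(cfg)
#' res$outcome
#' @export
simulate_tumor <- function(config, snapshot_times = numeric(),
                           record_mutations = TRUE) {
  validate_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  state <- new_tumor(config)
  outcome <- "censored"
  outcome_time <- config$max_time
  max_attained <- 1L
  repeat {
    if (state$time >= config$max_time) break
    state <- advance_step(state, config)
    if (!record_mutations) state$mut_chunks <- list()
    T_tot <- total_cells(state)
    max_attained <- max(max_attained, T_tot)
    if (state$time %in% snapshot_times && T_tot > 0L) {
      state$snapshots[[length(state$snapshots) + 1L]] <- list(
        label = sprintf("t%d", state$time), time = state$time,
        clone_id = state$clone_id, clone_count = state$clone_count
      )
    }
    if (T_tot == 0L) {
      outcome <- "extinct"
      outcome_time <- state$time
      break
    }
    if (T_tot >= config$max_population) {
      outcome <- "reached_ceiling"
      outcome_time <- state$time
      break
    }
  }
  if (state$icb_active && !state$post_icb_taken &&
      length(state$clone_id) > 0L) {
    state$snapshots[[length(state$snapshots) + 1L]] <- list(
      label = "post_icb", time = state$time,
      clone_id = state$clone_id, clone_count = state$clone_count
    )
  }
  traj <- do.call(rbind, state$traj)
  trajectory <- data.frame(
    time = traj[, 1], total_cells = traj[, 2],
    immunogenic_cells = traj[, 3], escaped_cells = traj[, 4]
  )
  mutations <- NULL
  if (record_mutations) {
    if (length(state$mut_chunks) > 0L) {
      mutations <- data.frame(
        mutation_id = seq_len(state$next_mutation_id - 1L),
        origin_clone = unlist(lapply(state$mut_chunks, `[[`, "origin")),
        antigenicity = unlist(lapply(state$mut_chunks, `[[`, "antigenicity")),
        is_antigenic = unlist(lapply(state$mut_chunks, `[[`, "is_antigenic")),
        is_driver = unlist(lapply(state$mut_chunks, `[[`, "is_driver")),
        birth_step = unlist(lapply(state$mut_chunks, `[[`, "birth_step"))
      )
    } else {
      mutations <- data.frame(
        mutation_id = integer(), origin_clone = integer(),
        antigenicity = numeric(), is_antigenic = logical(),
        is_driver = logical(), birth_step = integer()
      )
    }
  }
  res <- list(
    trajectory = trajectory,
    outcome = outcome,
    outcome_time = outcome_time,
    max_population_attained = max_attained,
    clones = data.frame(
      clone_id = state$clone_id, cell_count = state$clone_count,
      cumulative_antigenicity = state$clone_A,
      escaped = state$clone_escaped, driver_count = state$clone_driver
    ),
    genealogy = state$parent_full[seq_len(state$next_clone_id - 1L)],
    mutations = mutations,
    snapshots = state$snapshots,
    config = config,
    seed = config$rng_seed
  )
  class(res) <- "nfds_result"
  res
}

#' @export
print.nfds_result <- function(x, ...) {
  cat("<nfds_result>", x$config$scenario, "tumor:", x$outcome, "at t =",
      x$outcome_time, "\n  final cells:", sum(x$clones$cell_count),
      "; max attained:", x$max_population_attained,
      "; clones ever:", length(x$genealogy), "\n")
  invisible(x)
}

#' Fitted exponential growth rate of a trajectory
#'
#' Least-squares slope of `log(total_cells)` against time, the growth rate
#' `r` of the exponential model `T = T0 * exp(r t)`. Time points with zero
#' population are excluded.
#'
#' @param x An `nfds_result`, a trajectory data frame with columns `time`
#'   and `total_cells`, or a numeric vector of population sizes (time then
#'   taken as `0, 1, ...`).
#' @return The growth rate per step.
#' @examples
#' growth_rate_fit(data.frame(time = 0:10, total_cells = 100 * 1.2^(0:10)))
#' @export
growth_rate_fit <- function(x) {
  if (inherits(x, "nfds_result")) x <- x$trajectory
  if (is.numeric(x) && is.null(dim(x))) {
    x <- data.frame(time = seq_along(x) - 1, total_cells = x)
  }
  stopifnot(all(c("time", "total_cells") %in% names(x)))
  x <- x[x$total_cells > 0, , drop = FALSE]
  if (nrow(x) < 2L) {
    stop("need at least two time points with positive population",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(total_cells) ~ time, data = x))[2L])
}

#' Simulate replicate tumors with establishment conditioning
#'
#' Runs replicate simulations with child seeds derived deterministically
#' from `seed`. A replicate that goes extinct before ever reaching
#' `establish_cells` cells is counted as a failed initiation and re-drawn with
#' the next child seed (a lone founder dies with probability ~0.6 at the
#' default parameters regardless of scenario, so unconditioned replicate sets
#' would mostly consist of empty tumors). Extinctions after establishment are
#' kept: they are biological outcomes, not initiation failures.
#'
#' @param config Base [sim_config()]; its `rng_seed` is ignored.
#' @param n Number of established replicates to return.
#' @param seed Root seed for the replicate set.
#' @param establish_cells Establishment size (default 100 cells).
#' @param max_attempts Cap on total attempts (default `50 * n`).
#' @param summarize Optional function applied to each established
#'   `nfds_result`; when supplied, only its (small) return value is retained.
#'   Full-scale results carry multi-million-row mutation registries, so
#'   reducing on the fly keeps replicate sets within memory.
#' @param ... Passed to [simulate_tumor()] (e.g. `record_mutations`,
#'   `snapshot_times`).
#' @return A list with `results` (list of `nfds_result` or of `summarize`
#'   values), `seeds`, `failed_initiations`, and `attempts`.
#' @export
run_replicates <- function(config, n, seed, establish_cells = 100,
                           max_attempts = 50 * n, summarize = NULL, ...) {
  validate_config(config)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, max_attempts)
  results <- vector("list", n)
  seeds <- integer(n)
  got <- 0L
  attempt <- 0L
  failed <- 0L
  while (got < n && attempt < max_attempts) {
    attempt <- attempt + 1L
    cfg <- config
    cfg$rng_seed <- child_seeds[attempt]
    res <- simulate_tumor(cfg, ...)
    if (res$max_population_attained >= establish_cells) {
      got <- got + 1L
      results[[got]] <- if (is.null(summarize)) res else summarize(res)
      seeds[got] <- cfg$rng_seed
    } else {
      failed <- failed + 1L
    }
  }
  if (got < n) {
    stop(sprintf("only %d of %d replicates established after %d attempts",
                 got, n, attempt), call. = FALSE)
  }
  list(results = results, seeds = seeds, failed_initiations = failed,
       attempts = attempt)
}
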