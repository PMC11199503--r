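neutral_config <- function(...) {
  sim_config("NS", antigenic_fraction = 0, driver_prob = 0,
             max_population = 1e9, max_time = 10, ...)
}

test_that("a non-dividing tumor goes extinct", {
  cfg <- sim_config("NS", division_prob = 0, max_time = 200, rng_seed = 1)
  res <- simulate_tumor(cfg)
  expect_equal(res$outcome, "extinct")
  expect_true(res$outcome_time < 200)
})

test_that("a neutral population multiplies by 1 + b - (1-b)(1-b0) per step", {
  # division-first generations: expected factor 1.2 at b = 0.5, b0 = 0.4
  cfg <- neutral_config()
  set.seed(42)
  totals <- replicate(200, {
    state <- new_tumor(cfg)
    state$clone_count <- 100L
    for (t in 1:10) state <- advance_step(state, cfg)
    total_cells(state)
  })
  expected <- 100 * 1.2^10
  # per-founder offspring variance 0.76; variance after t steps scales as
  # sigma^2 m^(t-1) (m^t - 1) / (m - 1)
  var1 <- 0.76 * 1.2^9 * (1.2^10 - 1) / 0.2
  se <- sqrt(100 * var1 / 200)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("time advances even when no events can occur", {
  cfg <- sim_config("NS", division_prob = 0, basal_survival = 1,
                    antigenic_fraction = 0, driver_prob = 0)
  state <- new_tumor(cfg)
  s2 <- advance_step(state, cfg)
  expect_equal(s2$time, 1L)
  expect_equal(total_cells(s2), 1L)
  expect_equal(s2$clone_A, state$clone_A)
})

test_that("escaped clones are exempt until checkpoint blockade", {
  base <- list(scenario = "NS", escape_prob = 0, driver_prob = 0,
               antigenic_fraction = 0, max_population = 1e9)
  mk_state <- function(cfg) {
    st <- new_tumor(cfg)
    st$clone_A <- 5
    st$clone_escaped <- TRUE
    st$clone_count <- 1000L
    st
  }
  cfg_no <- do.call(sim_config, base)
  set.seed(1)
  st <- advance_step(mk_state(cfg_no), cfg_no)
  # pre-ICB: death probability exactly 1 - b0; expected growth factor 1.2
  expect_gt(total_cells(st), 1200 - 5 * sqrt(1000 * 0.76))
  expect_lt(total_cells(st), 1200 + 5 * sqrt(1000 * 0.76))

  # after ICB the ambient attack applies: kill probability min(1, -s*A) = 1
  cfg_icb <- do.call(sim_config, c(base, list(icb_time = 0)))
  st2 <- advance_step(mk_state(cfg_icb), cfg_icb)
  expect_equal(total_cells(st2), 0L)
  expect_equal(vapply(st2$snapshots, `[[`, "", "label")[1], "pre_icb")
})

test_that("escape and driver status are heritable and never lost", {
  cfg <- sim_config("NS_IE", escape_prob = 0, driver_prob = 0,
                    max_population = 1e4, max_time = 15, rng_seed = 9)
  st <- new_tumor(cfg)
  st$clone_escaped <- TRUE
  st$clone_driver <- 1L
  st$clone_count <- 50L
  set.seed(9)
  for (t in 1:15) st <- advance_step(st, cfg)
  expect_true(all(st$clone_escaped))
  expect_true(all(st$clone_driver >= 1L))
})

test_that("trajectories satisfy the population bookkeeping invariants", {
  cfg <- sim_config("NFDS", max_population = 3000, max_time = 300,
                    rng_seed = 5)
  res <- simulate_tumor(cfg)
  tr <- res$trajectory
  expect_true(all(diff(tr$time) == 1))
  expect_true(all(tr$immunogenic_cells <= tr$total_cells))
  expect_true(all(tr$escaped_cells <= tr$total_cells))
  expect_equal(utils::tail(tr$total_cells, 1), sum(res$clones$cell_count))
  if (res$outcome == "reached_ceiling") {
    expect_gte(utils::tail(tr$total_cells, 1), 3000)
    expect_equal(res$outcome_time, utils::tail(tr$time, 1))
  }
  # cumulative antigenicity caches are consistent with the mutation registry
  carried <- tapply(res$mutations$antigenicity, res$mutations$origin_clone,
                    sum)
  own <- carried[as.character(res$clones$clone_id)]
  own[is.na(own)] <- 0
  expect_true(all(res$clones$cumulative_antigenicity + 1e-9 >= own))
})

test_that("identical seeds reproduce identical simulations", {
  cfg <- sim_config("NFDS_IE", max_population = 2000, max_time = 200,
                    rng_seed = 77)
  a <- simulate_tumor(cfg)
  b <- simulate_tumor(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$outcome, b$outcome)
})

test_that("growth-rate fitting recovers exact exponential series", {
  expect_equal(growth_rate_fit(data.frame(time = c(0, 10),
                                          total_cells = c(1, exp(10)))), 1)
  expect_equal(growth_rate_fit(rep(100, 20)), 0)
  expect_equal(growth_rate_fit(100 * 1.2^(0:20)), log(1.2))
  # zero-population points are excluded, not fitted
  tr <- data.frame(time = 0:3, total_cells = c(1, exp(1), exp(2), 0))
  expect_equal(growth_rate_fit(tr), 1)
  expect_error(growth_rate_fit(data.frame(time = 0, total_cells = 5)),
               "two time points")
})

test_that("replicate runner conditions on establishment and reports it", {
  cfg <- sim_config("NS", antigenic_fraction = 0, driver_prob = 0,
                    max_population = 150, max_time = 100)
  rr <- run_replicates(cfg, n = 5, seed = 3, establish_cells = 100,
                       record_mutations = FALSE)
  expect_length(rr$results, 5)
  expect_true(all(vapply(rr$results, `[[`, 0,
                         "max_population_attained") >= 100))
  expect_gte(rr$failed_initiations, 1)  # founder drift loses ~60% of starts
  rr2 <- run_replicates(cfg, n = 5, seed = 3, establish_cells = 100,
                        record_mutations = FALSE)
  expect_identical(rr$seeds, rr2$seeds)
  expect_identical(lapply(rr$results, `[[`, "trajectory"),
                   lapply(rr2$results, `[[`, "trajectory"))
})
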