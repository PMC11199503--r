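test_that("true CCFs are carrier fractions over the clone genealogy", {
  res <- toy_result()
  tab <- true_ccf_table(res, min_ccf = 0)
  expect_equal(tab$true_ccf[tab$mutation_id == 1], 0.8)  # 50 + 30 carriers
  expect_equal(tab$true_ccf[tab$mutation_id == 2], 0.3)
  expect_equal(tab$true_ccf[tab$mutation_id == 3], 0.2)
  expect_equal(tab$true_vaf, tab$true_ccf / 2)
})

test_that("the retention threshold drops low-frequency mutations", {
  res <- toy_result()
  # 3 carriers of 100 -> CCF 0.03 <= 0.04 is dropped; a clonal mutation stays
  res$clones$cell_count <- c(77L, 3L, 20L)
  tab <- true_ccf_table(res, min_ccf = 0.04)
  expect_false(2 %in% tab$mutation_id)          # CCF 0.03
  expect_true(1 %in% tab$mutation_id)           # CCF 0.80
  full <- true_ccf_table(res, min_ccf = 0)
  expect_equal(nrow(full), 3)
})

test_that("extinct states are rejected", {
  res <- toy_result()
  res$clones <- res$clones[0, ]
  expect_error(true_ccf_table(res), "extinct")
})

test_that("read sampling is binomial with purity-diluted success", {
  tab <- data.frame(mutation_id = 1:2, is_antigenic = TRUE,
                    antigenicity = 0.1, true_ccf = c(0, 1))
  set.seed(1)
  obs <- observe_reads(tab, depth = 100, purity = 1)
  expect_false(1 %in% obs$mutation_id)  # CCF 0 can never be observed

  set.seed(2)
  n <- 1e4
  tab <- data.frame(mutation_id = seq_len(n), is_antigenic = FALSE,
                    antigenicity = 0, true_ccf = 1)
  obs <- observe_reads(tab, depth = 100, purity = 1)
  # Binomial(100, 0.5): mean alt reads 50 within 3 standard errors
  expect_lt(abs(mean(obs$alt_reads) - 50), 3 * 5 / sqrt(n))

  # purity scales the expected VAF: E[vaf] = purity * ccf / 2 = 0.1
  set.seed(3)
  tab$true_ccf <- 0.4
  obs <- observe_reads(tab, depth = 200, purity = 0.5)
  kept <- nrow(obs)
  # reconstruct the pre-filter mean: filtered rows all had zero alt reads
  pre_filter_mean <- sum(obs$observed_vaf) / n
  expect_lt(abs(pre_filter_mean - 0.1), 3 * sqrt(0.1 * 0.9 / 200) / sqrt(n))
  expect_true(all(obs$alt_reads >= 1))
  expect_true(all(obs$observed_ccf <= 1))
})

test_that("deep sequencing at full purity recovers the true CCF", {
  tab <- data.frame(mutation_id = 1:50, is_antigenic = FALSE,
                    antigenicity = 0,
                    true_ccf = seq(0.05, 1, length.out = 50))
  set.seed(4)
  obs <- observe_reads(tab, depth = 1e5, purity = 1)
  expect_equal(nrow(obs), 50)
  expect_true(all(abs(obs$observed_ccf - obs$true_ccf) < 0.01))
})

test_that("lowering depth or purity never helps detection", {
  tab <- data.frame(mutation_id = 1:2000, is_antigenic = FALSE,
                    antigenicity = 0, true_ccf = 0.06)
  surv <- function(depth, purity, seed) {
    set.seed(seed)
    nrow(observe_reads(tab, depth = depth, purity = purity))
  }
  expect_gte(surv(100, 1, 5), surv(30, 1, 5))
  expect_gte(surv(100, 1, 6), surv(100, 0.3, 6))
})

test_that("invalid sequencing parameters are rejected", {
  tab <- data.frame(true_ccf = 0.5)
  expect_error(observe_reads(tab, purity = 0), "purity")
  expect_error(observe_reads(tab, purity = 1.5), "purity")
  expect_error(observe_reads(tab, depth = 0), "depth")
})
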