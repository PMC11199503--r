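test_that("average CCF filters, restricts and returns missing when empty", {
  tab <- data.frame(true_ccf = c(0.2, 0.4, 0.6),
                    is_antigenic = c(TRUE, FALSE, TRUE))
  expect_equal(average_ccf(tab, ccf_threshold = 0.1), 0.4)
  expect_true(is.na(average_ccf(tab, ccf_threshold = 0.7)))
  tab5 <- data.frame(true_ccf = c(0.1, 0.2, 0.3, 0.4, 0.5),
                     is_antigenic = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(average_ccf(tab5, antigenic_only = TRUE),
               mean(c(0.1, 0.2, 0.5)))
})

test_that("antigenic load counts by threshold and clonality", {
  empty <- data.frame(true_ccf = numeric(), is_antigenic = logical())
  expect_equal(antigenic_load(empty), 0L)
  tab <- data.frame(true_ccf = c(1.0, 0.5, 0.3, 0.02, 0.009),
                    is_antigenic = TRUE)
  expect_equal(antigenic_load(tab, 0.01, subclonal_only = TRUE), 3)
  expect_equal(antigenic_load(tab, 0.04, subclonal_only = TRUE), 2)
  expect_equal(antigenic_load(tab, 0.01), 4)
  # patient tables carry an explicit clonality call
  ptab <- data.frame(ccf = c(0.9, 0.5), is_antigenic = TRUE,
                     clonality = c("clonal", "subclonal"))
  expect_equal(antigenic_load(ptab, 0.01, subclonal_only = TRUE), 1)
})

test_that("Shannon diversity over clone abundances", {
  expect_equal(shannon_diversity(10), 0)
  expect_equal(shannon_diversity(rep(3, 4)), log(4))
  q <- c(0.5, 0.3, 0.2)
  expect_equal(shannon_diversity(c(50, 30, 20)), -sum(q * log(q)))
  expect_equal(shannon_diversity(c(50, 30, 20, 0)), -sum(q * log(q)))
  expect_error(shannon_diversity(c(0, 0)), "zero")
  expect_error(shannon_diversity(c(-1, 2)), "non-negative")
})

test_that("Spearman correlation matches exact rank computation", {
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  expect_equal(spearman_correlation(1:5, 1:5)$rho, 1)
  # d^2 = 4 over n = 5: rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_correlation(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_correlation(1:3, 1:4), "mismatch")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("an exact 1/f spectrum fits the neutral power law perfectly", {
  inv <- seq(1 / 0.4, 1 / 0.1, length.out = 40)  # uniform in 1/f
  f <- 1 / inv
  fit <- neutrality_r2(f, window = c(0.1, 0.4))
  expect_lt(abs(fit$r_squared - 1), 1e-9)
  expect_gt(fit$slope, 0)
  expect_equal(fit$n_mutations, 40)
})

test_that("degenerate frequency spectra are flagged, not fitted", {
  expect_true(is.na(neutrality_r2(c(0.2, 0.2, 0.2))$r_squared))
  expect_true(is.na(neutrality_r2(c(0.2, 0.3))$r_squared))
  expect_true(is.na(neutrality_r2(numeric())$r_squared))
})

test_that("a two-subclone spectrum gives the hand-computed R-squared", {
  # frequencies {0.4, 0.4, 0.2, 0.2}: points (2.5, 1), (2.5, 2), (5, 3),
  # (5, 4); R^2 = Sxy^2 / (Sxx Syy) = 25 / 31.25 = 0.8
  fit <- neutrality_r2(c(0.4, 0.4, 0.2, 0.2), window = c(0.1, 0.45))
  expect_equal(fit$r_squared, 0.8)
  expect_lt(fit$r_squared, 1)
})

test_that("the neutrality fit ignores row order and clonal mutations", {
  set.seed(8)
  f <- runif(60, 0.12, 0.38)
  base <- neutrality_r2(f)$r_squared
  expect_equal(neutrality_r2(sample(f))$r_squared, base)
  with_clonal <- c(f, rep(1, 25), runif(10, 0.6, 0.9))
  expect_equal(neutrality_r2(with_clonal)$r_squared, base)
})

test_that("group comparisons dispatch to the right nonparametric test", {
  x <- c(1, 3, 5, 7, 9)
  y <- c(2, 4, 6, 8, 10)
  # rank-sum statistic: number of (x, y) pairs with x > y = 10
  expect_equal(compare_groups(x, y)$statistic, 10)
  same <- compare_groups(1:20, 1:20)
  expect_gt(same$p_value, 0.9)
  apart <- compare_groups(1:20, 101:120)
  expect_lt(apart$p_value, 1e-4)
  three <- compare_groups(rnorm(10), rnorm(10), rnorm(10))
  expect_equal(three$test, "kruskal")
  expect_error(compare_groups(numeric(), 1:3), "non-empty")
})
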