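test_that("multiplicity inference picks the nearest expected VAF", {
  expect_equal(infer_multiplicity(0.5, 1, 2), 1L)
  expect_equal(infer_multiplicity(1.0, 1, 2), 2L)
  expect_equal(infer_multiplicity(0.25, 0.5, 2), 1L)
  # equidistant between m = 1 (0.5) and m = 2 (1.0): tie breaks low
  expect_equal(infer_multiplicity(0.75, 1, 2), 1L)
  expect_equal(infer_multiplicity(0.9, 1, 4), 4L)
  expect_true(is.na(infer_multiplicity(0.5, 1, 0)))
  expect_error(infer_multiplicity(0.5, 0, 2), "purity")
  expect_error(infer_multiplicity(0, 1, 2), "f must")
})

test_that("CCF point estimates evaluate the purity/copy-number correction", {
  expect_equal(ccf_point(0.5, 1, 1, 2), 1)
  expect_equal(ccf_point(0.25, 1, 0.5, 2), 1)    # 0.25/0.5 * (1 + 1)
  expect_equal(ccf_point(0.125, 1, 0.5, 2), 0.5)
  expect_equal(ccf_point(0.9, 1, 1, 2), 1.1)     # capped at 1.1
  expect_error(ccf_point(0.5, 0, 1, 2), "multiplicity")
  expect_error(ccf_point(0.5, 1, 0, 2), "purity")
})

test_that("the fully clonal VAF is a fixed point of the CCF formula", {
  for (n_t in 1:4) for (m in seq_len(n_t)) for (rho in c(0.3, 0.5, 0.8, 1)) {
    f <- m * rho / (rho * n_t + 2 * (1 - rho))
    expect_equal(ccf_point(f, m, rho, n_t), 1,
                 info = sprintf("m=%d rho=%g n_t=%d", m, rho, n_t))
  }
})

test_that("CCF is non-increasing in purity at fixed reads", {
  rhos <- seq(0.2, 1, by = 0.1)
  for (n_t in c(2, 3)) {
    vals <- ccf_point(0.2, 1, rhos, n_t)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("confidence intervals bracket the point estimate", {
  ci <- ccf_interval(50, 100, 1, 1, 2)
  pt <- ccf_point(0.5, 1, 1, 2)
  expect_lte(ci$lo, pt)
  expect_gte(ci$hi, pt)
  # saturated VAF maps to the maximal CCF for the locus
  top <- ccf_interval(100, 100, 1, 1, 2)
  expect_equal(top$hi, ccf_point(1, 1, 1, 2))
  cp <- ccf_interval(50, 100, 1, 1, 2, method = "clopper-pearson")
  expect_lte(cp$lo, pt)
  expect_gte(cp$hi, pt)
})

test_that("the Wilson interval keeps near-nominal coverage at depth 100", {
  set.seed(21)
  p <- 0.5
  alt <- stats::rbinom(2000, 100, p)
  covered <- vapply(alt, function(a) {
    ci <- ccf_interval(a, 100, 1, 1, 2)
    ci$vaf_lo <= p && p <= ci$vaf_hi
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("clonality is called from the upper CI bound", {
  expect_equal(classify_clonality(0.93), "subclonal")
  expect_equal(classify_clonality(1.0), "clonal")
  expect_equal(classify_clonality(1.4), "clonal")
  expect_equal(classify_clonality(list(lo = 0.2, hi = 0.8)), "subclonal")
})

test_that("perturbing one read moves the point estimate continuously", {
  base <- vapply(40:60, function(a) {
    est <- estimate_ccf(data.frame(
      sample_id = "s", alt_reads = a, depth = 100, total_cn = 2,
      purity = 0.8, is_neoantigen = TRUE, multiplicity = 1
    ))
    est$ccf
  }, numeric(1))
  expect_true(all(abs(diff(base)) < 0.05))
})

test_that("the per-record estimator flags unusable records", {
  maf <- data.frame(
    sample_id = "s1",
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    alt_reads = c(50, 0, 30, 10), depth = 100,
    total_cn = c(2, 2, 0, 2), purity = 0.8,
    is_neoantigen = c(TRUE, TRUE, FALSE, FALSE)
  )
  est <- estimate_ccf(maf)
  expect_false(any(is.na(est$ccf[c(1, 4)])))
  expect_true(is.na(est$ccf[2]))   # zero alt reads never reach estimation
  expect_true(is.na(est$ccf[3]))   # homozygous deletion
  expect_error(estimate_ccf(maf[, -1]), "missing columns")
  expect_error(estimate_ccf(transform(maf, alt_reads = 200)), "exceeds")
})

test_that("sample summaries count subclonal neoantigens as specified", {
  rec <- data.frame(
    sample_id = "s1",
    is_neoantigen = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    ccf = c(0.2, 0.3, 0.5, 1, 1, 0.4),
    clonality = c("subclonal", "subclonal", "subclonal", "clonal",
                  "clonal", "subclonal")
  )
  ss <- sample_summary(rec)
  expect_equal(ss$avg_ccf_neoantigen, mean(c(0.2, 0.3, 0.5, 1, 1)))
  expect_equal(ss$avg_ccf_subclonal_neoantigen, mean(c(0.2, 0.3, 0.5)))
  expect_equal(ss$subclonal_neoantigen_count, 3L)
  expect_equal(ss$subclonal_count, 4L)

  solo <- data.frame(sample_id = "s2", is_neoantigen = TRUE, ccf = 1,
                     clonality = "clonal")
  ss2 <- sample_summary(solo)
  expect_equal(ss2$avg_ccf_neoantigen, 1)
  expect_equal(ss2$subclonal_neoantigen_count, 0L)

  none <- data.frame(sample_id = "s3", is_neoantigen = FALSE, ccf = 0.5,
                     clonality = "subclonal")
  expect_true(is.na(sample_summary(none)$avg_ccf_neoantigen))
})

test_that("MAF round-trips through the tab-separated reader/writer", {
  fx <- make_fixture_cohort(n_samples = 4, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_maf(fx$maf, path)
  back <- read_maf(path)
  expect_equal(back, fx$maf)
})
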