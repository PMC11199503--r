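#' Infer mutation multiplicity from VAF, purity and copy number
#'
#' Picks the integer number of mutated allele copies `m` in `[1, N_T]` whose
#' expected VAF, `m * rho / (rho * N_T + 2 * (1 - rho))`, is closest to the
#' observed VAF; ties break toward the smaller `m`.
#'
#' @param f Observed variant-allele frequency in (0, 1]; vectorized.
#' @param purity Tumor purity `rho` in (0, 1].
#' @param n_t Tumor total copy number at the locus (integer >= 1); vectorized.
#' @return Integer multiplicities (`NA` where `n_t` is 0, flagged upstream).
#' @examples
#' infer_multiplicity(0.5, 1, 2)   # 1: heterozygous diploid
#' infer_multiplicity(1.0, 1, 2)   # 2
#' @export
infer_multiplicity <- function(f, purity, n_t) {
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]",
                                          call. = FALSE)
  if (any(f <= 0 | f > 1)) stop("f must be in (0, 1]", call. = FALSE)
  n <- max(length(f), length(n_t), length(purity))
  f <- rep_len(f, n); n_t <- rep_len(n_t, n); purity <- rep_len(purity, n)
  vapply(seq_len(n), function(i) {
    if (is.na(n_t[i]) || n_t[i] < 1) return(NA_integer_)
    m <- seq_len(n_t[i])
    expected <- m * purity[i] / (purity[i] * n_t[i] + 2 * (1 - purity[i]))
    m[which.min(abs(f[i] - expected))]  # which.min takes the first: lower m
  }, integer(1))
}

#' Cancer-cell-fraction point estimate
#'
#' `CCF = f / (m * rho) * (rho * N_T + 2 * (1 - rho))`. Noise can push the
#' raw value above 1; estimates are retained up to `cap` (default 1.1) for
#' confidence-interval classification and reported capped at 1 by
#' [estimate_ccf()].
#'
#' @inheritParams infer_multiplicity
#' @param m Mutation multiplicity (integer >= 1).
#' @param cap Upper cap applied to the raw estimate.
#' @return CCF estimates.
#' @examples
#' ccf_point(0.5, 1, 1, 2)     # 1.0: clonal heterozygous diploid
#' ccf_point(0.125, 1, 0.5, 2) # 0.5
#' @export
ccf_point <- function(f, m, purity, n_t, cap = 1.1) {
  if (any(purity <= 0)) stop("purity must be positive", call. = FALSE)
  if (any(m < 1)) stop("multiplicity must be at least 1", call. = FALSE)
  pmin(f / (m * purity) * (purity * n_t + 2 * (1 - purity)), cap)
}

#' Confidence interval for a CCF estimate
#'
#' Binomial confidence interval on the VAF (Wilson score by default,
#' Clopper-Pearson optionally), with both endpoints mapped through
#' [ccf_point()]. The Wilson interval is used for its coverage stability at
#' low alt-read counts; the original cohort analyses used an external tool
#' whose interval construction is not public, so this is the package's own
#' (labelled) substitute.
#'
#' @param alt_reads,depth Alt-supporting reads and total depth.
#' @param m,purity,n_t As in [ccf_point()].
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @param cap Cap applied to the transformed endpoints.
#' @return A list with `lo`, `hi` (CCF scale) and `vaf_lo`, `vaf_hi`.
#' @export
ccf_interval <- function(alt_reads, depth, m, purity, n_t, level = 0.95,
                         method = c("wilson", "clopper-pearson"), cap = 1.1) {
  method <- match.arg(method)
  stopifnot(alt_reads >= 0, depth >= 1, alt_reads <= depth)
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    phat <- alt_reads / depth
    denom <- 1 + z^2 / depth
    center <- (phat + z^2 / (2 * depth)) / denom
    half <- z * sqrt(phat * (1 - phat) / depth + z^2 / (4 * depth^2)) / denom
    vlo <- max(0, center - half)
    vhi <- min(1, center + half)
  } else {
    alpha <- 1 - level
    vlo <- if (alt_reads == 0) 0 else
      stats::qbeta(alpha / 2, alt_reads, depth - alt_reads + 1)
    vhi <- if (alt_reads == depth) 1 else
      stats::qbeta(1 - alpha / 2, alt_reads + 1, depth - alt_reads)
  }
  list(
    lo = ccf_point(vlo, m, purity, n_t, cap = cap),
    hi = ccf_point(vhi, m, purity, n_t, cap = cap),
    vaf_lo = vlo, vaf_hi = vhi
  )
}

#' Clonal/subclonal call from a CCF confidence interval
#'
#' A mutation is subclonal when the upper bound of its CCF confidence
#' interval is below 1; otherwise clonal.
#'
#' @param hi Upper CI bound(s) on the CCF scale (or a list from
#'   [ccf_interval()]).
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(hi) {
  if (is.list(hi)) hi <- hi$hi
  ifelse(hi < 1, "subclonal", "clonal")
}

#' Per-record CCF estimation for a MAF-like mutation table
#'
#' Runs the full patient-side estimator over a tab-separated-style mutation
#' table: multiplicity inference (unless a `multiplicity` column is
#' supplied), the purity- and copy-number-corrected CCF point estimate, the
#' binomial confidence interval, and the clonality call.
#'
#' @param maf Data frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `alt_reads`, `depth`, `total_cn`, `purity`, `is_neoantigen`
#'   (and optionally `multiplicity`).
#' @param level Confidence level for the interval.
#' @param method Interval method, see [ccf_interval()].
#' @return The input with added columns `vaf`, `multiplicity`, `ccf`
#'   (capped at 1), `ccf_lo`, `ccf_hi`, `clonality`. Records with
#'   `total_cn = 0` (homozygous deletion) or zero alt reads are flagged via
#'   `NA` estimates.
#' @export
estimate_ccf <- function(maf, level = 0.95, method = "wilson") {
  required <- c("sample_id", "alt_reads", "depth", "total_cn", "purity",
                "is_neoantigen")
  missing_cols <- setdiff(required, names(maf))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(maf$alt_reads > maf$depth)) {
    stop("alt_reads exceeds depth", call. = FALSE)
  }
  n <- nrow(maf)
  out <- maf
  out$vaf <- maf$alt_reads / maf$depth
  ok <- out$vaf > 0 & !is.na(maf$total_cn) & maf$total_cn >= 1
  if (!"multiplicity" %in% names(out)) out$multiplicity <- NA_integer_
  need_m <- ok & is.na(out$multiplicity)
  if (any(need_m)) {
    out$multiplicity[need_m] <- infer_multiplicity(
      out$vaf[need_m], maf$purity[need_m], maf$total_cn[need_m]
    )
  }
  out$ccf <- out$ccf_lo <- out$ccf_hi <- NA_real_
  out$clonality <- NA_character_
  for (i in which(ok)) {
    raw <- ccf_point(out$vaf[i], out$multiplicity[i], maf$purity[i],
                     maf$total_cn[i])
    ci <- ccf_interval(maf$alt_reads[i], maf$depth[i], out$multiplicity[i],
                       maf$purity[i], maf$total_cn[i], level = level,
                       method = method)
    out$ccf[i] <- min(raw, 1)
    out$ccf_lo[i] <- min(ci$lo, 1)
    out$ccf_hi[i] <- ci$hi
    out$clonality[i] <- classify_clonality(ci$hi)
  }
  out
}

#' Per-sample clonality summaries
#'
#' Reduces per-record CCF estimates to the sample-level quantities used to
#' look for the frequency-dependent-selection signature: the average CCF of
#' neoantigens (all, and subclonal-only), the subclonal neoantigen count,
#' the total subclonal count, and the neutrality R-squared over subclonal
#' CCFs.
#'
#' @param records Output of [estimate_ccf()].
#' @param window Neutrality fit window passed to [neutrality_r2()].
#' @return One row per sample: `sample_id`, `n_mutations`,
#'   `avg_ccf_neoantigen`, `avg_ccf_subclonal_neoantigen`,
#'   `subclonal_neoantigen_count`, `subclonal_count`, `r_squared`.
#'   Samples without neoantigen records carry `NA` averages.
#' @export
sample_summary <- function(records, window = c(0.1, 0.4)) {
  stopifnot(nrow(records) >= 1L)
  res <- lapply(split(records, records$sample_id), function(d) {
    neo <- d$is_neoantigen & !is.na(d$ccf)
    sub <- !is.na(d$clonality) & d$clonality == "subclonal"
    data.frame(
      sample_id = d$sample_id[1L],
      n_mutations = nrow(d),
      avg_ccf_neoantigen = if (any(neo)) mean(d$ccf[neo]) else NA_real_,
      avg_ccf_subclonal_neoantigen =
        if (any(neo & sub)) mean(d$ccf[neo & sub]) else NA_real_,
      subclonal_neoantigen_count = sum(neo & sub),
      subclonal_count = sum(sub),
      r_squared = neutrality_r2(d$ccf[sub & !is.na(d$ccf)],
                                window = window)$r_squared
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cohort-level NFDS-signature analysis
#'
#' Computes per-sample summaries, the Spearman correlation between the
#' average neoantigen CCF and the subclonal neoantigen burden (the
#' frequency-dependent-selection signature: negative under NFDS), and an
#' optional stratification of samples by neutrality R-squared.
#'
#' @param records Output of [estimate_ccf()] for a cohort.
#' @param r2_cutoff Cutoff for the high/low R-squared stratification
#'   (default 0.7).
#' @param window Neutrality fit window.
#' @return List with `samples` (the summary table), `correlation`
#'   (Spearman rho and p), and `r2_strata` (sample counts by stratum).
#' @export
cohort_analysis <- function(records, r2_cutoff = 0.7,
                            window = c(0.1, 0.4)) {
  samples <- sample_summary(records, window = window)
  ok <- !is.na(samples$avg_ccf_neoantigen)
  correlation <- if (sum(ok) >= 3L) {
    spearman_correlation(samples$avg_ccf_neoantigen[ok],
                         samples$subclonal_neoantigen_count[ok])
  } else {
    list(rho = NA_real_, p_value = NA_real_)
  }
  strata <- ifelse(is.na(samples$r_squared), NA_character_,
                   ifelse(samples$r_squared >= r2_cutoff, "high", "low"))
  list(
    samples = samples,
    correlation = correlation,
    r2_strata = table(factor(strata, levels = c("high", "low")))
  )
}

#' Read / write MAF-like mutation tables
#'
#' Tab-separated tables with a header; positions are 1-based inclusive
#' (MAF convention).
#'
#' @param path File path.
#' @return `read_maf()` returns a data frame.
#' @export
read_maf <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_maf
#' @param x Data frame to write.
#' @export
write_maf <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
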