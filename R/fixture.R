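#' Synthetic patient cohort with known clonality structure
#'
#' Generates a MAF-like mutation table for a cohort of synthetic samples with
#' a built-in association between the average neoantigen CCF and the
#' subclonal neoantigen burden. Each sample draws a latent intensity
#' `u ~ Uniform(0, 1)`: its subclonal neoantigen count grows with `u` while
#' its clonal neoantigen count shrinks (for `correlation_sign = -1`,
#' the frequency-dependent-selection signature) or the reverse (`+1`).
#' Reads are drawn from the same binomial model as [observe_reads()], at
#' diploid copy number, so the table round-trips through [estimate_ccf()].
#'
#' @param n_samples Number of samples.
#' @param correlation_sign `-1` (negative association, NFDS-like) or `+1`.
#' @param depth Sequencing depth.
#' @param purity Tumor purity applied to every sample.
#' @param subclonal_range Range of subclonal neoantigen counts across the
#'   cohort (low at `u = 0`, high at `u = 1`).
#' @param clonal_share_range Range of the clonal share of the neoantigen
#'   burden; the share moves from high to low across the latent axis for
#'   `correlation_sign = -1` and from low to high for `+1`, which is what
#'   drives the average-CCF trend.
#' @param subclonal_ccf_range True CCFs of subclonal mutations are drawn
#'   uniformly from this range.
#' @param passenger_per_sample Additional non-antigenic subclonal passengers
#'   per sample.
#' @param seed RNG seed.
#' @return List with `maf` (the mutation table: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `alt_reads`, `depth`, `total_cn`, `purity`,
#'   `is_neoantigen`) and `truth` (per-sample true average neoantigen CCF
#'   and subclonal counts).
#' @export
make_fixture_cohort <- function(n_samples = 40, correlation_sign = -1,
                                depth = 100, purity = 0.8,
                                subclonal_range = c(5, 60),
                                clonal_share_range = c(0.1, 0.6),
                                subclonal_ccf_range = c(0.15, 0.6),
                                passenger_per_sample = 10,
                                seed = NULL) {
  stopifnot(correlation_sign %in% c(-1, 1))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  truth <- list()
  for (i in seq_len(n_samples)) {
    u <- (i - 0.5) / n_samples            # even coverage of the latent axis
    share <- if (correlation_sign < 0) {
      clonal_share_range[2] - u * diff(clonal_share_range)
    } else {
      clonal_share_range[1] + u * diff(clonal_share_range)
    }
    n_sub <- round(subclonal_range[1] + u * diff(subclonal_range))
    n_clo <- max(1, round(share / (1 - share) * n_sub))
    ccf <- c(rep(1, n_clo),
             stats::runif(n_sub, subclonal_ccf_range[1],
                          subclonal_ccf_range[2]))
    is_neo <- rep(TRUE, n_clo + n_sub)
    if (passenger_per_sample > 0) {
      ccf <- c(ccf, stats::runif(passenger_per_sample,
                                 subclonal_ccf_range[1],
                                 subclonal_ccf_range[2]))
      is_neo <- c(is_neo, rep(FALSE, passenger_per_sample))
    }
    nmut <- length(ccf)
    alt <- stats::rbinom(nmut, depth, purity * ccf / 2)
    keep <- alt > 0
    if (!any(keep)) next
    sid <- sprintf("S%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid,
      chrom = sample(paste0("chr", 1:22), sum(keep), replace = TRUE),
      pos = sample.int(1e8, sum(keep)),
      ref = sample(bases, sum(keep), replace = TRUE),
      alt = sample(bases, sum(keep), replace = TRUE),
      alt_reads = alt[keep],
      depth = depth,
      total_cn = 2L,
      purity = purity,
      is_neoantigen = is_neo[keep]
    )
    truth[[length(truth) + 1L]] <- data.frame(
      sample_id = sid,
      true_avg_ccf_neo = mean(ccf[is_neo]),
      true_subclonal_neo = n_sub,
      true_clonal_neo = n_clo
    )
  }
  list(maf = do.call(rbind, rows), truth = do.call(rbind, truth))
}
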