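#' Average cancer-cell fraction
#'
#' Arithmetic mean CCF over mutations above a threshold, optionally
#' restricted to antigenic mutations. An empty filtered set yields `NA`
#' (never zero), so replicate-level summaries are not biased downward.
#'
#' @param table A mutation table with a CCF column.
#' @param antigenic_only Restrict to rows with `is_antigenic`.
#' @param ccf_threshold Keep rows with CCF strictly above this value.
#' @param ccf_col Which CCF column to use (default `"true_ccf"`, falling
#'   back to `"observed_ccf"` or `"ccf"` when absent).
#' @return Mean CCF, or `NA_real_` for an empty set.
#' @export
average_ccf <- function(table, antigenic_only = FALSE, ccf_threshold = 0,
                        ccf_col = NULL) {
  ccf <- pick_ccf(table, ccf_col)
  keep <- ccf > ccf_threshold
  if (antigenic_only) keep <- keep & table$is_antigenic
  if (!any(keep)) return(NA_real_)
  mean(ccf[keep])
}

pick_ccf <- function(table, ccf_col = NULL) {
  if (is.null(ccf_col)) {
    ccf_col <- intersect(c("true_ccf", "observed_ccf", "ccf"), names(table))[1]
    if (is.na(ccf_col)) stop("no CCF column found", call. = FALSE)
  }
  table[[ccf_col]]
}

#' Antigenic mutation load
#'
#' Number of antigenic mutations with CCF above a threshold, optionally
#' counting subclonal mutations only (CCF < 1, or an explicit `clonality`
#' column with value `"subclonal"` for patient-derived tables).
#'
#' @inheritParams average_ccf
#' @param subclonal_only Count subclonal mutations only.
#' @return Integer count.
#' @export
antigenic_load <- function(table, ccf_threshold = 0.01,
                           subclonal_only = FALSE, ccf_col = NULL) {
  if (nrow(table) == 0L) return(0L)
  ccf <- pick_ccf(table, ccf_col)
  keep <- table$is_antigenic & ccf > ccf_threshold
  if (subclonal_only) {
    if ("clonality" %in% names(table)) {
      keep <- keep & table$clonality == "subclonal"
    } else {
      keep <- keep & ccf < 1
    }
  }
  sum(keep)
}

#' Shannon diversity index
#'
#' `-sum(q_i log q_i)` over normalized abundances, natural logarithm;
#' zero-abundance classes are excluded.
#'
#' @param abundances Non-negative abundances (e.g. clone cell counts or
#'   CCF-normalized weights), at least one positive.
#' @return The Shannon index (0 for a single class).
#' @examples
#' shannon_diversity(c(50, 30, 20))
#' @export
shannon_diversity <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative",
                                call. = FALSE)
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0L) stop("all abundances are zero", call. = FALSE)
  q <- abundances / sum(abundances)
  -sum(q * log(q))
}

#' Spearman rank correlation with p-value
#'
#' Tie-corrected Spearman correlation via [stats::cor.test()].
#'
#' @param x,y Paired numeric vectors, length at least 3.
#' @return List with `rho` and `p_value` (two-sided).
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Power-law neutrality fit (1/f cumulative frequency)
#'
#' Under neutral growth the number of subclonal mutations with frequency at
#' least `f` grows linearly in `1/f`. For each mutation frequency inside the
#' fit window the cumulative count `M(f)` (mutations with frequency `>= f`)
#' is regressed on `1/f`; the coefficient of determination measures how
#' closely the frequency spectrum follows the neutral expectation
#' (R-squared near 1: effectively neutral).
#'
#' @param x A mutation table (a CCF column is selected as in
#'   [average_ccf()]) or a numeric vector of frequencies.
#' @param window Subclonal frequency window `(low, high)` used for the fit;
#'   default `c(0.1, 0.4)`.
#' @param ccf_col Optional explicit CCF column name.
#' @return An object of class `neutrality_fit`: list with `r_squared`,
#'   `slope`, `intercept`, `window`, `n_mutations`. When fewer than 3
#'   mutations fall in the window (or the frequencies are degenerate) the
#'   fit is flagged: `r_squared` is `NA`.
#' @examples
#' f <- 1 / seq(1 / 0.24, 1 / 0.1, length.out = 30) # exact 1/f spectrum
#' neutrality_r2(f)$r_squared
#' @export
neutrality_r2 <- function(x, window = c(0.1, 0.4), ccf_col = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2], window[2] < 1)
  f <- if (is.numeric(x) && is.null(dim(x))) x else pick_ccf(x, ccf_col)
  f <- f[f >= window[1] & f <= window[2]]
  n <- length(f)
  fit <- list(r_squared = NA_real_, slope = NA_real_,
              intercept = NA_real_, window = window, n_mutations = n)
  class(fit) <- "neutrality_fit"
  if (n < 3L) return(fit)
  if (length(unique(f)) < 2L) return(fit)  # zero variance in 1/f
  # cumulative mutation count M as frequency sweeps downward: the k-th
  # mutation in descending-frequency order contributes the point
  # (1/f_(k), k)
  f_desc <- sort(f, decreasing = TRUE)
  inv <- 1 / f_desc
  M <- seq_along(f_desc)
  lmfit <- stats::lm(M ~ inv)
  # summary.lm warns on numerically perfect fits; R-squared is still valid
  fit$r_squared <- suppressWarnings(summary(lmfit)$r.squared)
  fit$slope <- unname(stats::coef(lmfit)[2L])
  fit$intercept <- unname(stats::coef(lmfit)[1L])
  fit
}

#' @export
print.neutrality_fit <- function(x, ...) {
  if (is.na(x$r_squared)) {
    cat("<neutrality_fit> undefined (", x$n_mutations,
        " mutations in window [", x$window[1], ", ", x$window[2], "])\n",
        sep = "")
  } else {
    cat(sprintf(
      "<neutrality_fit> R^2 = %.4f (slope %.2f, %d mutations in [%g, %g])\n",
      x$r_squared, x$slope, x$n_mutations, x$window[1], x$window[2]))
  }
  invisible(x)
}

#' Compare two (or more) groups nonparametrically
#'
#' Wilcoxon rank-sum for two groups, Kruskal-Wallis for more.
#'
#' @param ... Two or more numeric vectors, or a single list of them.
#' @param test `"wilcoxon"` or `"kruskal"`; default picks by group count.
#' @param alternative Passed to [stats::wilcox.test()] for the two-group
#'   case (`"two.sided"`, `"greater"`: first group larger, `"less"`).
#' @return List with `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(..., test = NULL, alternative = "two.sided") {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) == 0L)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  if (is.null(test)) {
    test <- if (length(groups) == 2L) "wilcoxon" else "kruskal"
  }
  if (test == "wilcoxon") {
    stopifnot(length(groups) == 2L)
    ht <- suppressWarnings(stats::wilcox.test(groups[[1L]], groups[[2L]],
                                              alternative = alternative))
  } else {
    ht <- stats::kruskal.test(groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}
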