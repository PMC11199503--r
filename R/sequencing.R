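#' True cancer-cell-fraction table of a simulated tumor
#'
#' Computes, for every recorded mutation, the fraction of tumor cells whose
#' clone carries it (its true CCF), by accumulating clone cell counts over the
#' clone genealogy. Mutations at or below `min_ccf` are dropped, matching the
#' detection floor applied before virtual sequencing.
#'
#' @param result An `nfds_result` simulated with `record_mutations = TRUE`.
#' @param min_ccf Retention threshold: rows with `true_ccf <= min_ccf` are
#'   dropped (default 0.04).
#' @param snapshot `NULL` for the final state, or the label/index of a
#'   snapshot recorded during the run (e.g. `"pre_icb"`).
#' @return A data frame: `mutation_id`, `antigenicity`, `is_antigenic`,
#'   `is_driver`, `birth_step`, `true_ccf`, `true_vaf` (`= true_ccf / 2`,
#'   diploid heterozygous convention).
#' @export
true_ccf_table <- function(result, min_ccf = 0.04, snapshot = NULL) {
  stopifnot(inherits(result, "nfds_result"))
  if (is.null(result$mutations)) {
    stop("run simulate_tumor() with record_mutations = TRUE", call. = FALSE)
  }
  if (is.null(snapshot)) {
    ids <- result$clones$clone_id
    counts <- result$clones$cell_count
  } else {
    snap <- find_snapshot(result, snapshot)
    ids <- snap$clone_id
    counts <- snap$clone_count
  }
  total <- sum(counts)
  if (total == 0L) stop("tumor state is extinct", call. = FALSE)
  parent <- result$genealogy
  carriers <- .subtree_carriers(parent, ids, as.numeric(counts))
  mut <- result$mutations
  ccf <- carriers[mut$origin_clone] / total
  keep <- ccf > min_ccf
  out <- mut[keep, c("mutation_id", "antigenicity", "is_antigenic",
                     "is_driver", "birth_step")]
  out$true_ccf <- pmin(ccf[keep], 1)
  out$true_vaf <- out$true_ccf / 2
  rownames(out) <- NULL
  out
}

find_snapshot <- function(result, snapshot) {
  snaps <- result$snapshots
  if (length(snaps) == 0L) stop("result has no snapshots", call. = FALSE)
  if (is.numeric(snapshot)) return(snaps[[snapshot]])
  labels <- vapply(snaps, `[[`, "", "label")
  hit <- which(labels == snapshot)
  if (length(hit) == 0L) {
    stop("no snapshot labelled '", snapshot, "'", call. = FALSE)
  }
  snaps[[hit[1L]]]
}

#' Virtual sequencing of a CCF table
#'
#' Adds binomial read noise to true mutation frequencies. The expected
#' variant-allele frequency of a diploid heterozygous mutation observed at
#' tumor purity `rho` is `rho * CCF / 2`; the observed alt-read count is
#' `Binomial(depth, rho * CCF / 2)`. Rows drawn with zero alt reads are
#' removed (an unobserved variant is never reported by a caller), and the
#' observed CCF is `2 * observed_vaf / rho`, capped at 1.
#'
#' @param table A CCF table from [true_ccf_table()] (needs `true_ccf`).
#' @param depth Mean sequencing depth (default 100).
#' @param purity Tumor purity in (0, 1].
#' @param depth_model `"fixed"` (every site at `depth`) or `"poisson"`
#'   (per-site depths Poisson(`depth`), floored at 1).
#' @return The table with added columns `depth`, `alt_reads`,
#'   `observed_vaf`, `observed_ccf`, `purity`, zero-read rows removed.
#' @examples
#' tab <- data.frame(mutation_id = 1, is_antigenic = TRUE,
#'                   antigenicity = 0.3, true_ccf = 0.5)
#' set.seed(1)
#' observe_reads(tab, depth = 100, purity = 1)
#' @export
observe_reads <- function(table, depth = 100, purity = 1,
                          depth_model = c("fixed", "poisson")) {
  depth_model <- match.arg(depth_model)
  stopifnot("true_ccf" %in% names(table))
  if (purity <= 0 || purity > 1) {
    stop("purity must be in (0, 1]", call. = FALSE)
  }
  if (depth < 1) stop("depth must be at least 1", call. = FALSE)
  n <- nrow(table)
  N <- if (depth_model == "fixed") rep.int(as.integer(depth), n)
       else pmax(1L, stats::rpois(n, depth))
  pr <- purity * table$true_ccf / 2
  alt <- stats::rbinom(n, N, pr)
  out <- table
  out$depth <- N
  out$alt_reads <- alt
  out$observed_vaf <- ifelse(N > 0, alt / N, 0)
  out$observed_ccf <- pmin(2 * out$observed_vaf / purity, 1)
  out$purity <- purity
  out <- out[out$alt_reads > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
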