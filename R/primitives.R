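#' Is a cell immunogenic?
#'
#' A cell is immunogenic when its effective cumulative antigenicity strictly
#' exceeds the cell immunogenicity threshold `c1`.
#'
#' @param a Cumulative (effective) antigenicity, non-negative; vectorized.
#' @param c1 Cell immunogenicity threshold, positive.
#' @return Logical vector, `TRUE` where `a > c1`.
#' @examples
#' cell_is_immunogenic(c(0, 0.5, 0.6), c1 = 0.5)
#' @export
cell_is_immunogenic <- function(a, c1 = 0.5) {
  if (any(a < 0)) stop("antigenicity must be non-negative", call. = FALSE)
  if (c1 <= 0) stop("c1 must be positive", call. = FALSE)
  a > c1
}

#' Ambient selection coefficient under a scenario
#'
#' Under negative selection (NS) the coefficient `s` applies whenever any
#' immunogenic cell exists. Under negative frequency-dependent selection
#' (NFDS) it applies only while the immunogenic fraction of the tumor exceeds
#' the tumor threshold `c2`; otherwise selection is off (`0`).
#'
#' @param immunogenic_cells Number of immunogenic cells.
#' @param total_cells Total number of cells (positive).
#' @param c2 Tumor immunogenicity threshold.
#' @param s Selection coefficient (non-positive).
#' @param scenario One of `"NS"`, `"NFDS"`, `"NS_IE"`, `"NFDS_IE"`.
#' @return The effective ambient coefficient, `s` or `0`.
#' @examples
#' effective_selection(60, 100, c2 = 0.5, s = -0.8, scenario = "NFDS") # -0.8
#' effective_selection(40, 100, c2 = 0.5, s = -0.8, scenario = "NFDS") #  0
#' @export
effective_selection <- function(immunogenic_cells, total_cells, c2, s,
                                scenario) {
  if (total_cells < 1) stop("population is extinct", call. = FALSE)
  if (immunogenic_cells < 0 || immunogenic_cells > total_cells) {
    stop("immunogenic_cells must lie in [0, total_cells]", call. = FALSE)
  }
  if (scenario %in% c("NFDS", "NFDS_IE")) {
    if (immunogenic_cells / total_cells > c2) s else 0
  } else {
    s
  }
}

#' Per-step death probability of a non-dividing cell
#'
#' The death probability of a quiescent cell is the complement of its
#' survival, the basal survival `b0` reduced by the cell's effective
#' antigenicity under the effective selection coefficient:
#' `1 - (1 + s_eff * a_eff) * b0`, clamped to `[0, 1]`. With `s_eff = 0`
#' (no selection, or an escaped cell) this is the basal death `1 - b0`.
#'
#' In the default event scheme this compound decomposes into immune attack
#' (survival factor `1 + s_eff * a_eff`) followed by basal death `1 - b0`;
#' see the methods vignette.
#'
#' @param a_eff Effective cumulative antigenicity (non-negative; vectorized).
#' @param s_eff Effective selection coefficient (non-positive).
#' @param b0 Basal survival probability.
#' @return Death probability in `[0, 1]`.
#' @examples
#' death_prob(0.5, -0.8, 0.4) # 0.76
#' death_prob(1.0,  0.0, 0.4) # 0.6, selection off
#' @export
death_prob <- function(a_eff, s_eff, b0) {
  if (any(a_eff < 0)) stop("a_eff must be non-negative", call. = FALSE)
  if (any(s_eff > 0)) stop("s_eff must be non-positive", call. = FALSE)
  if (b0 < 0 || b0 > 1) stop("b0 must be in [0, 1]", call. = FALSE)
  pmin(pmax(1 - (1 + s_eff * a_eff) * b0, 0), 1)
}

# Immune-attack kill probability: the selection component of death_prob().
# A selected immunogenic cell survives the attack with probability
# 1 + s_eff * a_eff (clamped), so that (attack) + (survive attack) *
# (basal death) reproduces death_prob() for a quiescent cell.
attack_prob <- function(a_eff, s_eff) {
  pmin(pmax(-s_eff * a_eff, 0), 1)
}

#' Driver-attenuated effective antigenicity
#'
#' Driver-carrying lineages present their neoantigens poorly; their cumulative
#' antigenicity is attenuated by a single multiplicative factor, regardless of
#' how many driver events the lineage has accumulated.
#'
#' @param a Raw cumulative antigenicity (vectorized).
#' @param driver_count Number of driver events carried (vectorized).
#' @param attenuation Attenuation factor, default 0.2.
#' @return Effective antigenicity: `a` where `driver_count == 0`, else
#'   `attenuation * a`.
#' @examples
#' effective_antigenicity(1, 0)            # 1.0
#' effective_antigenicity(1, 1)            # 0.2
#' effective_antigenicity(1, 3)            # 0.2: attenuation saturates
#' @export
effective_antigenicity <- function(a, driver_count, attenuation = 0.2) {
  ifelse(driver_count > 0, attenuation * a, a)
}

#' Draw the new mutations of daughter cells
#'
#' Each daughter receives `Poisson(mu_per_daughter)` new mutations. A mutation
#' is antigenic with probability `p` and then carries an antigenicity drawn
#' from an exponential distribution with the given mean; passengers carry
#' antigenicity exactly 0.
#'
#' @param n_daughters Number of daughters to draw for.
#' @param mu_per_daughter Poisson mean per daughter.
#' @param p Antigenic fraction.
#' @param antigenicity_mean Mean of the exponential antigenicity distribution.
#' @return A data frame with one row per mutation: `daughter` (index),
#'   `antigenicity`, `is_antigenic`.
#' @examples
#' set.seed(1)
#' draw_daughter_mutations(2, 2.5, 0.1, 0.2)
#' @export
draw_daughter_mutations <- function(n_daughters, mu_per_daughter, p,
                                    antigenicity_mean) {
  stopifnot(n_daughters >= 0, mu_per_daughter >= 0, p >= 0, p <= 1)
  m <- stats::rpois(n_daughters, mu_per_daughter)
  total <- sum(m)
  daughter <- rep.int(seq_len(n_daughters), m)
  is_antigenic <- stats::runif(total) < p
  antigenicity <- numeric(total)
  antigenicity[is_antigenic] <- stats::rexp(sum(is_antigenic),
                                            rate = 1 / antigenicity_mean)
  data.frame(daughter = daughter, antigenicity = antigenicity,
             is_antigenic = is_antigenic)
}
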