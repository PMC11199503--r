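#' Simulation configuration
#'
#' Builds and validates the parameter set for one branching-process tumor
#' simulation. Defaults are the study conditions used throughout the package:
#' division probability `b = 0.5`, basal survival `b0 = 0.4`, genome-wide
#' mutation rate `mu = 5` per cell division, antigenic fraction `p = 0.1`,
#' exponentially distributed antigenicity with mean 0.2, selection coefficient
#' `s = -0.8`, and immunogenicity thresholds `c1 = c2 = 0.5`.
#'
#' @param scenario Immune-selection scenario: `"NS"` (negative selection,
#'   active whenever any immunogenic cell exists), `"NFDS"` (negative
#'   frequency-dependent selection, active only while the immunogenic cell
#'   fraction exceeds `tumor_threshold`), or the same two with heritable
#'   subclonal immune escape (`"NS_IE"`, `"NFDS_IE"`).
#' @param division_prob Per-step division probability `b`.
#' @param basal_survival Basal survival probability `b0` of a non-dividing
#'   cell in the absence of immune attack.
#' @param mutation_rate Expected new mutations per cell division (genome-wide
#'   Poisson mean `mu`); under the default `"split"` dosing each daughter
#'   draws Poisson(`mu/2`).
#' @param antigenic_fraction Probability `p` that a new mutation is antigenic.
#' @param antigenicity_mean Mean of the exponential antigenicity distribution.
#' @param selection_s Selection coefficient `s`, non-positive, in `[-2, 0]`.
#' @param cell_threshold Cell immunogenicity threshold `c1`: a cell is
#'   immunogenic when its (driver-attenuated) cumulative antigenicity
#'   strictly exceeds `c1`.
#' @param tumor_threshold Tumor immunogenicity threshold `c2` for NFDS.
#' @param escape_prob Per-daughter, per-division probability of acquiring
#'   heritable immune escape. Defaults to `1e-4` for the `_IE` scenarios and
#'   0 otherwise.
#' @param driver_prob Per-daughter, per-division probability of a driver
#'   event (0 disables drivers).
#' @param driver_attenuation Multiplicative attenuation of cumulative
#'   antigenicity in driver-carrying cells (applied once, regardless of how
#'   many drivers a lineage holds).
#' @param max_population Population ceiling; reaching it ends the run with
#'   outcome `"reached_ceiling"`.
#' @param max_time Step horizon; runs still alive at `max_time` are censored.
#' @param icb_time Optional step at which immune-checkpoint blockade is
#'   applied: from then on escaped clones are subject to ambient selection
#'   again and no new escape is acquired.
#' @param icb_population_fraction Optional alternative trigger: ICB is applied
#'   the first time the population reaches this fraction of
#'   `max_population`. Useful when comparing runs whose growth timing varies.
#' @param icb_observe_delta Steps after ICB activation at which the
#'   on-therapy (`"post_icb"`) snapshot is recorded (default 25); if the run
#'   ends earlier the final state is used.
#' @param event_scheme `"division_first"` (default; see the methods vignette)
#'   or `"competing"`, a rates-style alternative in which division and death
#'   compete directly (subcritical at the default parameters; provided for
#'   exploration only).
#' @param mutation_dosing `"split"` (each daughter draws Poisson(`mu/2`)) or
#'   `"single_daughter"` (one daughter draws Poisson(`mu`)).
#' @param rng_seed Integer seed consumed by [simulate_tumor()].
#'
#' @return An object of class `nfds_config` (a validated named list).
#' @examples
#' cfg <- sim_config(scenario = "NFDS", max_population = 1000, rng_seed = 1)
#' cfg$selection_s
#' @export
sim_config <- function(scenario = c("NS", "NFDS", "NS_IE", "NFDS_IE"),
                       division_prob = 0.5,
                       basal_survival = 0.4,
                       mutation_rate = 5,
                       antigenic_fraction = 0.1,
                       antigenicity_mean = 0.2,
                       selection_s = -0.8,
                       cell_threshold = 0.5,
                       tumor_threshold = 0.5,
                       escape_prob = NULL,
                       driver_prob = 1e-6,
                       driver_attenuation = 0.2,
                       max_population = 1e5,
                       max_time = 1000,
                       icb_time = NA_real_,
                       icb_population_fraction = NA_real_,
                       icb_observe_delta = 25,
                       event_scheme = c("division_first", "competing"),
                       mutation_dosing = c("split", "single_daughter"),
                       rng_seed = NULL) {
  scenario <- match.arg(scenario)
  event_scheme <- match.arg(event_scheme)
  mutation_dosing <- match.arg(mutation_dosing)
  if (is.null(escape_prob)) {
    escape_prob <- if (grepl("_IE$", scenario)) 1e-4 else 0
  }
  cfg <- list(
    scenario = scenario,
    division_prob = division_prob,
    basal_survival = basal_survival,
    mutation_rate = mutation_rate,
    antigenic_fraction = antigenic_fraction,
    antigenicity_mean = antigenicity_mean,
    selection_s = selection_s,
    cell_threshold = cell_threshold,
    tumor_threshold = tumor_threshold,
    escape_prob = escape_prob,
    driver_prob = driver_prob,
    driver_attenuation = driver_attenuation,
    max_population = max_population,
    max_time = max_time,
    icb_time = icb_time,
    icb_population_fraction = icb_population_fraction,
    icb_observe_delta = icb_observe_delta,
    event_scheme = event_scheme,
    mutation_dosing = mutation_dosing,
    rng_seed = rng_seed
  )
  class(cfg) <- "nfds_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "nfds_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$division_prob) && cfg$division_prob >= 0 &&
        cfg$division_prob <= 1, "division_prob must be in [0, 1]")
  chk(cfg$basal_survival >= 0 && cfg$basal_survival <= 1,
      "basal_survival must be in [0, 1]")
  chk(cfg$mutation_rate >= 0, "mutation_rate must be non-negative")
  chk(cfg$antigenic_fraction >= 0 && cfg$antigenic_fraction <= 1,
      "antigenic_fraction must be in [0, 1]")
  chk(cfg$antigenicity_mean > 0, "antigenicity_mean must be positive")
  chk(cfg$selection_s >= -2 && cfg$selection_s <= 0,
      "selection_s must lie in [-2, 0]")
  chk(cfg$cell_threshold > 0, "cell_threshold must be positive")
  chk(cfg$tumor_threshold >= 0 && cfg$tumor_threshold <= 1,
      "tumor_threshold must be in [0, 1]")
  chk(cfg$escape_prob >= 0 && cfg$escape_prob <= 1,
      "escape_prob must be in [0, 1]")
  chk(cfg$driver_prob >= 0 && cfg$driver_prob <= 1,
      "driver_prob must be in [0, 1]")
  chk(cfg$driver_attenuation >= 0 && cfg$driver_attenuation <= 1,
      "driver_attenuation must be in [0, 1]")
  chk(cfg$max_population >= 1, "max_population must be at least 1")
  chk(cfg$max_time >= 1, "max_time must be at least 1")
  if (!is.na(cfg$icb_population_fraction)) {
    chk(cfg$icb_population_fraction > 0 && cfg$icb_population_fraction <= 1,
        "icb_population_fraction must be in (0, 1]")
  }
  invisible(cfg)
}

#' @export
print.nfds_config <- function(x, ...) {
  cat("<nfds_config> scenario:", x$scenario,
      sprintf("(b=%g, b0=%g, mu=%g, p=%g, s=%g, c1=%g, c2=%g, pe=%g)\n",
              x$division_prob, x$basal_survival, x$mutation_rate,
              x$antigenic_fraction, x$selection_s, x$cell_threshold,
              x$tumor_threshold, x$escape_prob))
  cat("  ceiling:", format(x$max_population, big.mark = ","),
      "cells; horizon:", x$max_time, "steps")
  if (!is.na(x$icb_time)) cat("; ICB at t =", x$icb_time)
  if (!is.na(x$icb_population_fraction)) {
    cat("; ICB at ", x$icb_population_fraction * 100, "% of ceiling", sep = "")
  }
  cat("\n")
  invisible(x)
}
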