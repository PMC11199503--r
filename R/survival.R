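#' Virtual patients from replicate simulations
#'
#' Reduces simulation outcomes to survival records. A virtual patient is
#' deceased when the tumor reaches the population ceiling; runs stopped by
#' the step horizon are right-censored, and extinct tumors (cures) are
#' censored at their extinction time and flagged.
#'
#' @param results List of `nfds_result` objects (e.g.
#'   `run_replicates(...)$results`).
#' @param group Optional group label recycled across patients.
#' @param treated Optional logical flag recycled across patients.
#' @return Data frame: `patient_id`, `event_time`, `event` (1 = ceiling
#'   reached), `outcome`, `group`, `treated`.
#' @export
virtual_patients <- function(results, group = NA_character_, treated = NA) {
  stopifnot(length(results) > 0L)
  data.frame(
    patient_id = seq_along(results),
    event_time = vapply(results, `[[`, 0, "outcome_time"),
    event = as.integer(vapply(results, `[[`, "", "outcome") ==
                         "reached_ceiling"),
    outcome = vapply(results, `[[`, "", "outcome"),
    group = group,
    treated = treated
  )
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with right censoring, via [survival::survfit()].
#'
#' @param patients Data frame with `event_time` and `event` columns (1 =
#'   event, 0 = censored), e.g. from [virtual_patients()].
#' @return Data frame step function: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with the fitted `survfit` object attached as
#'   attribute `"fit"`.
#' @examples
#' km_curve(data.frame(event_time = c(5, 8, 8, 10),
#'                     event = c(1, 1, 1, 0)))
#' @export
km_curve <- function(patients) {
  stopifnot(nrow(patients) >= 1L,
            all(c("event_time", "event") %in% names(patients)))
  fit <- survival::survfit(
    survival::Surv(event_time, event) ~ 1, data = patients
  )
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  attr(out, "fit") <- fit
  out
}

#' Log-rank test between two survival groups
#'
#' One-degree-of-freedom log-rank chi-square via [survival::survdiff()].
#'
#' @param group_a,group_b Data frames with `event_time` and `event`.
#' @return List with `statistic` (chi-square) and `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1L, nrow(group_b) >= 1L)
  dat <- rbind(
    data.frame(event_time = group_a$event_time, event = group_a$event,
               g = "a"),
    data.frame(event_time = group_b$event_time, event = group_b$event,
               g = "b")
  )
  sd <- survival::survdiff(survival::Surv(event_time, event) ~ g, data = dat)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), p_value = p)
}
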