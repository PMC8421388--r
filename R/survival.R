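#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate over the distinct event times of each group;
#' censored times reduce the at-risk count only. Thin wrapper over
#' `survival::survfit`, returned as a tidy table.
#'
#' @param records data.frame with columns `time_h` (or `time`), `event`
#'   (logical/0-1) and optionally `group`.
#' @return data.frame: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`. Rows are the distinct observed times per group.
#' @export
km_estimator <- function(records) {
  records <- normalize_survival(records)
  if (any(records$time < 0)) stop("negative survival times")
  fit <- if (nlevels(records$group) > 1L)
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  else
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(records$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, n_censor = sm$n.censor,
             survival = sm$surv)
}

#' Cumulative risk-of-death curves
#'
#' Two standard summaries of the same survival experience: the cumulative
#' incidence `1 - S(t)` and the Nelson-Aalen cumulative hazard
#' `sum(d_i / n_i)` over event times up to t. Both are reported because
#' "cumulative risk-of-death" is used loosely in the literature; group
#' contrasts should come from the Cox model either way.
#'
#' @param records survival records as for [km_estimator()].
#' @return data.frame: `group`, `time`, `series` (`"cumulative_incidence"` or
#'   `"cumulative_hazard"`), `value`.
#' @export
cumulative_risk <- function(records) {
  records <- normalize_survival(records)
  fit <- if (nlevels(records$group) > 1L)
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  else
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(records$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  na <- if (!is.null(sm$cumhaz)) sm$cumhaz else -log(sm$surv)
  rbind(
    data.frame(group = grp, time = sm$time, series = "cumulative_incidence",
               value = 1 - sm$surv),
    data.frame(group = grp, time = sm$time, series = "cumulative_hazard",
               value = na))
}

#' Cox proportional-hazards fit of group effects
#'
#' Fits `Surv(time, event) ~ group` by partial likelihood with the Efron tie
#' correction (imaging at discrete 12-24 h intervals produces heavy ties, for
#' which Efron is less biased than Breslow), via `survival::coxph`. Reports,
#' per non-reference group, the log-hazard coefficient, hazard ratio, Wald
#' standard error, 95 percent CI `exp(beta +/- 1.96 se)` and Wald p-value.
#'
#' @param records survival records as for [km_estimator()]; needs >= 2 groups
#'   and at least one event.
#' @param reference_group group used as baseline (default: first level).
#' @param robust_wells optional column name for well-cluster robust standard
#'   errors (off by default; the per-neuron analysis ignores within-well
#'   clustering).
#' @return data.frame of class `cox_result`: `group`, `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `n`, `n_event`.
#' @export
cox_fit <- function(records, reference_group = NULL, robust_wells = NULL) {
  records <- normalize_survival(records)
  if (nlevels(records$group) < 2L)
    stop("Cox fit needs at least two groups")
  if (!is.null(reference_group)) {
    if (!reference_group %in% levels(records$group))
      stop("unknown reference group: ", reference_group)
    records$group <- stats::relevel(records$group, ref = reference_group)
  }
  ev <- tapply(records$event, records$group, sum)
  if (sum(records$event) == 0L)
    stop("no events in the data; Cox model is unidentifiable")
  if (any(ev == 0))
    warning("group(s) with no events: ",
            paste(names(ev)[ev == 0], collapse = ", "),
            " (estimates may be unstable)")
  fml <- survival::Surv(time, event) ~ group
  fit <- if (is.null(robust_wells))
    survival::coxph(fml, data = records, ties = "efron")
  else
    survival::coxph(survival::Surv(time, event) ~ group +
                      survival::cluster(cluster_id),
                    data = transform(records,
                                     cluster_id = records[[robust_wells]]),
                    ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- beta / se
  out <- data.frame(
    group = sub("^group", "", names(beta)),
    beta = as.numeric(beta), se = as.numeric(se),
    hr = exp(as.numeric(beta)),
    ci_low = exp(as.numeric(beta - 1.96 * se)),
    ci_high = exp(as.numeric(beta + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(z)),
    n = nrow(records), n_event = sum(records$event))
  class(out) <- c("cox_result", "data.frame")
  rownames(out) <- NULL
  out
}

# Harmonize survival input: accept `time` or `time_h`, coerce event to
# logical, group to factor (single pseudo-group when absent).
normalize_survival <- function(records) {
  if (!"time" %in% names(records)) {
    if ("time_h" %in% names(records)) records$time <- records$time_h
    else stop("records need a `time` or `time_h` column")
  }
  if (!"event" %in% names(records)) stop("records need an `event` column")
  records$event <- as.logical(records$event)
  if (!"group" %in% names(records)) records$group <- "all"
  if (!is.factor(records$group)) records$group <- factor(records$group)
  records$group <- droplevels(records$group)
  records
}
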