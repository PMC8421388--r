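#' Log-linear decay regression and half-life
#'
#' Ordinary least squares of log2 intensity against time over a post-death
#' window. Using log base 2 makes the slope directly `-1/t_half` (hours), so
#' the half-life is recovered exactly on noise-free exponentials. Non-positive
#' intensities in the window are dropped with a warning; at least 3 samples
#' must remain.
#'
#' @param trace a [fluorescence_trace()].
#' @param window optional `c(t_min, t_max)` restricting the fit (hours).
#' @return an object of class `decay_fit`: `slope` (log2 units/h),
#'   `half_life` (hours; `Inf` for a flat trace), `intercept`, `r_squared`,
#'   `n`.
#' @export
fit_log_decay <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  t <- trace$times; v <- trace$values
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; v <- v[sel]
  }
  pos <- v > 0
  if (any(!pos)) {
    warning(sum(!pos), " non-positive sample(s) dropped from log-decay fit")
    t <- t[pos]; v <- v[pos]
  }
  if (length(v) < 3L) stop("fewer than 3 positive samples in the decay window")
  fit <- stats::lm(log2(v) ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < 1e-12) slope <- 0   # numerically constant trace
  half <- if (slope == 0) Inf else -1 / slope
  # R2 computed directly: summary.lm warns on numerically perfect fits
  ly <- log2(v)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(slope = slope, half_life = half,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(v)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> slope %.4g log2/h, t1/2 = %.4g h, R2 = %.4f (n=%d)\n",
              x$slope, x$half_life, x$r_squared, x$n))
  invisible(x)
}

#' Plateau-then-one-phase-association fit of a signal rise
#'
#' Least-squares fit of the piecewise model
#' `F(t) = F0` for `t < t0`;
#' `F(t) = F0 + (plateau - F0) * (1 - exp(-(t - t0)/tau))` for `t >= t0`,
#' the standard description of a delayed saturating rise (e.g. GEDI signal
#' onset at death). For each candidate onset `t0`, `F0` and `plateau` are
#' profiled out linearly and `tau` is found by one-dimensional optimization;
#' the onset grid is the observed timepoints, refined continuously around the
#' best gridpoint. This multi-start scheme avoids the local minima of a joint
#' four-parameter descent.
#'
#' @param trace a [fluorescence_trace()] spanning pre- and post-onset samples.
#' @param t0_grid candidate onset times; default all interior observed times.
#' @return an object of class `rise_fit`: `f0`, `plateau`, `t0`, `tau`,
#'   `peak` (max observed value), `sse`, and `flat` (TRUE when the rise
#'   amplitude is negligible and `tau` is unidentifiable).
#' @export
fit_rise <- function(trace, t0_grid = NULL) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  t <- trace$times; y <- trace$values
  if (length(t) < 4L) stop("need at least 4 samples to fit a rise")
  if (is.null(t0_grid)) t0_grid <- t[t > min(t) & t < max(t)]
  if (length(t0_grid) == 0L) stop("no interior candidate onset times")
  span <- diff(range(t))
  dt <- min(diff(t))
  log_tau_rng <- log(c(dt / 20, span * 20))

  sse_of <- function(t0, log_tau) {
    tau <- exp(log_tau)
    b <- ifelse(t >= t0, 1 - exp(-(t - t0) / tau), 0)
    f <- stats::lm.fit(cbind(1, b), y)
    sum(f$residuals^2)
  }
  best_tau_for <- function(t0) {
    o <- stats::optimize(function(lt) sse_of(t0, lt),
                         interval = log_tau_rng, tol = 1e-10)
    c(sse = o$objective, log_tau = o$minimum)
  }
  grid_fits <- vapply(t0_grid, best_tau_for, numeric(2))
  k <- which.min(grid_fits["sse", ])
  # refine t0 continuously between the neighbouring gridpoints
  lo <- if (k > 1) t0_grid[k - 1] else max(min(t), t0_grid[k] - dt)
  hi <- if (k < length(t0_grid)) t0_grid[k + 1] else min(max(t), t0_grid[k] + dt)
  o2 <- stats::optimize(function(t0) best_tau_for(t0)["sse"],
                        interval = c(lo, hi), tol = 1e-9)
  cand <- matrix(unname(c(
    t0_grid[k], grid_fits["sse", k], grid_fits["log_tau", k],
    o2$minimum, o2$objective, best_tau_for(o2$minimum)["log_tau"])),
    nrow = 2, byrow = TRUE,
    dimnames = list(NULL, c("t0", "sse", "log_tau")))
  bestrow <- cand[which.min(cand[, "sse"]), ]
  t0 <- unname(bestrow["t0"]); tau <- exp(unname(bestrow["log_tau"]))
  b <- ifelse(t >= t0, 1 - exp(-(t - t0) / tau), 0)
  cf <- stats::lm.fit(cbind(1, b), y)$coefficients
  f0 <- unname(cf[1]); amp <- unname(cf[2])
  if (is.na(amp)) amp <- 0
  scale <- max(abs(y), 1e-12)
  flat <- abs(amp) < 1e-6 * scale ||
    tau <= exp(log_tau_rng[1]) * 1.0001 || tau >= exp(log_tau_rng[2]) * 0.9999
  structure(list(f0 = f0, plateau = f0 + amp, t0 = t0, tau = tau,
                 peak = max(y), sse = unname(bestrow["sse"]), flat = flat),
            class = "rise_fit")
}

#' @export
print.rise_fit <- function(x, ...) {
  cat(sprintf(
    "<rise_fit> F0 %.4g -> plateau %.4g, onset t0 = %.4g, tau = %.4g%s\n",
    x$f0, x$plateau, x$t0, x$tau,
    if (x$flat) " (flat; tau unidentifiable)" else ""))
  invisible(x)
}

#' Two-sample comparison via a standard test
#'
#' Convenience wrapper delegating to the standard routines (no re-derivation):
#' Mann-Whitney U (`stats::wilcox.test`, default, as used for comparing decay
#' slopes between reporters) or Welch's t-test.
#'
#' @param values_a,values_b numeric samples, non-empty.
#' @param test `"mann-whitney"` or `"t"`.
#' @return list: `test`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_group_statistic <- function(values_a, values_b,
                                    test = c("mann-whitney", "t")) {
  test <- match.arg(test)
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be non-empty")
  if (length(values_a) < 2L || length(values_b) < 2L)
    warning("sample of size 1: the comparison has essentially no power")
  res <- switch(test,
    "mann-whitney" = suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = NULL)),
    "t" = stats::t.test(values_a, values_b))
  list(test = test, statistic = unname(res$statistic),
       p_value = res$p.value, n_a = length(values_a), n_b = length(values_b))
}
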