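#' Simulate a two-arm (or multi-arm) survival cohort under proportional hazards
#'
#' Event times are exponential with rate `baseline_rate * hazard_ratio^g`
#' where g indexes the non-reference groups, with administrative censoring at
#' `censor_time`. This is the generating law assumed when checking that the
#' Cox fitter recovers a known hazard ratio.
#'
#' @param n_per_group integer vector of group sizes; names become group
#'   labels (defaults `group1`, `group2`, ...). The first group is the
#'   reference (hazard ratio 1).
#' @param baseline_rate events per hour for the reference group; > 0.
#' @param hazard_ratio hazard ratio(s) of the non-reference group(s) relative
#'   to the reference; length `length(n_per_group) - 1`, all > 0.
#' @param censor_time administrative censoring time, hours.
#' @param seed integer RNG seed (local to this call).
#' @return data.frame with columns `id`, `group` (factor, reference first),
#'   `time_h`, `event` (logical).
#' @export
generate_survival_cohort <- function(n_per_group, baseline_rate, hazard_ratio,
                                     censor_time, seed = 1L) {
  labels <- names(n_per_group)
  n_per_group <- as.integer(n_per_group)
  stopifnot(length(n_per_group) >= 2L, all(n_per_group >= 1L))
  if (baseline_rate <= 0) stop("`baseline_rate` must be > 0")
  if (length(hazard_ratio) != length(n_per_group) - 1L)
    stop("need one hazard ratio per non-reference group")
  if (any(hazard_ratio <= 0)) stop("hazard ratios must be > 0")
  if (censor_time < 0) stop("`censor_time` must be >= 0")
  if (is.null(labels)) labels <- paste0("group", seq_along(n_per_group))
  rates <- baseline_rate * c(1, hazard_ratio)

  out <- local_seed(seed, {
    rows <- lapply(seq_along(n_per_group), function(g) {
      t_event <- stats::rexp(n_per_group[g], rate = rates[g])
      data.frame(group = labels[g],
                 time_h = pmin(t_event, censor_time),
                 event = t_event <= censor_time)
    })
    do.call(rbind, rows)
  })
  out$id <- seq_len(nrow(out))
  out$group <- factor(out$group, levels = labels)
  out[c("id", "group", "time_h", "event")]
}

#' Simulate an exponentially decaying fluorescence trace
#'
#' `value(t) = initial * 2^(-t / half_life) + noise`, the model assumed for
#' post-death decay of reporter fluorescence. At `noise_sd = 0` the trace is
#' exactly log-linear and the half-life is recoverable to machine precision by
#' [fit_log_decay()].
#'
#' @param initial intensity at t = 0; > 0.
#' @param half_life decay half-life, hours; > 0.
#' @param times sampling times, hours, strictly increasing.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer RNG seed used when `noise_sd > 0`.
#' @return a [fluorescence_trace()] with baseline window at the first sample.
#' @export
generate_decay_trace <- function(initial, half_life, times, noise_sd = 0,
                                 seed = 1L) {
  if (!is.finite(initial) || initial <= 0) stop("`initial` must be > 0")
  if (!is.finite(half_life) || half_life <= 0) stop("`half_life` must be > 0")
  v <- initial * 2^(-times / half_life)
  if (noise_sd > 0)
    v <- v + local_seed(seed, stats::rnorm(length(times), sd = noise_sd))
  fluorescence_trace(times, v, baseline_window = 1L)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulation helpers do not perturb outer streams.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
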