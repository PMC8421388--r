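#' Define a calcium-sensor equilibrium model
#'
#' A sensor is described by its equilibrium Hill parameters: the dissociation
#' constant `kd` (molar Ca2+ at half occupancy), the Hill coefficient
#' `hill_n`, and the relative fluorescence at zero (`f_min`) and saturating
#' (`f_max`) Ca2+. Activity indicators (GECIs, e.g. GCaMP6f) have kd in the
#' physiological cytosolic range; death indicators (GEDIs, e.g. RGEDI, GC150)
#' have kd shifted towards organellar/extracellular Ca2+ so they only respond
#' when the membrane loses integrity.
#'
#' Parameter values are user-supplied configuration, not built-in constants:
#' see [read_sensor_registry()] and the example registry shipped under
#' `inst/extdata/sensors_example.yaml`.
#'
#' @param name label for the sensor.
#' @param kd dissociation constant, molar; must be > 0.
#' @param hill_n Hill coefficient, dimensionless; must be > 0.
#' @param f_min,f_max relative fluorescence at zero / saturating Ca2+,
#'   arbitrary units; `f_max >= f_min >= 0`.
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function(name, kd, hill_n, f_min = 0, f_max = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("`kd` must be a single positive number (molar)")
  if (!is.numeric(hill_n) || length(hill_n) != 1L || !is.finite(hill_n) || hill_n <= 0)
    stop("`hill_n` must be a single positive number")
  if (!is.finite(f_min) || !is.finite(f_max) || f_min < 0 || f_max < f_min)
    stop("need f_max >= f_min >= 0")
  structure(list(name = name, kd = kd, hill_n = hill_n,
                 f_min = f_min, f_max = f_max),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> %s: Kd = %.3g M, n = %.3g, F range [%.3g, %.3g]\n",
              x$name, x$kd, x$hill_n, x$f_min, x$f_max))
  invisible(x)
}

#' Equilibrium Hill-model fluorescence
#'
#' Relative fluorescence of a sensor at a given free Ca2+ concentration:
#' `f_min + (f_max - f_min) * ca^n / (kd^n + ca^n)`. Continuous and
#' non-decreasing in `ca`; equals the midpoint of `f_min` and `f_max` at
#' `ca = kd` for any Hill coefficient.
#'
#' @param sensor a [sensor_spec()].
#' @param ca free Ca2+ concentration(s), molar; must be >= 0.
#' @return relative fluorescence, same length as `ca`.
#' @export
hill_fluorescence <- function(sensor, ca) {
  stopifnot(inherits(sensor, "sensor_spec"))
  if (length(ca) == 0L) return(numeric(0))
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("Ca2+ concentrations must be finite and non-negative")
  # work on the log scale to avoid overflow of ca^n at saturating levels
  occ <- ifelse(ca == 0, 0,
                1 / (1 + exp(sensor$hill_n * (log(sensor$kd) - log(ca)))))
  sensor$f_min + (sensor$f_max - sensor$f_min) * occ
}

#' Evaluate a sensor's dose-response curve on a concentration grid
#'
#' @param sensor a [sensor_spec()].
#' @param ca_grid Ca2+ concentrations, molar, all >= 0.
#' @param normalize if `TRUE`, rescale the curve to `[0, 1]` by its own
#'   minimum and maximum (constant curves are returned as zeros).
#' @return numeric vector of relative fluorescence, one value per grid point.
#' @export
response_curve <- function(sensor, ca_grid, normalize = FALSE) {
  f <- hill_fluorescence(sensor, ca_grid)
  if (normalize && length(f)) {
    rng <- range(f)
    f <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else rep(0, length(f))
  }
  f
}

#' Construct a fluorescence trace
#'
#' A single-cell intensity time course with an explicit baseline window used
#' to define F0 for fold-change computations. By default the baseline is every
#' sample strictly before `stim_index` (the first stimulus/treatment marker),
#' or the first sample when no marker is given.
#'
#' @param times timestamps, strictly increasing (units declared by the caller,
#'   seconds or hours).
#' @param values intensities, same length as `times`, arbitrary units.
#' @param baseline_window integer indices defining F0; defaults as described.
#' @param stim_index optional index of the first stimulus sample.
#' @return an object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, values, baseline_window = NULL,
                               stim_index = NULL) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) == 0L)
    stop("`times` and `values` must be non-empty and of equal length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (is.null(baseline_window)) {
    baseline_window <- if (!is.null(stim_index)) {
      if (stim_index < 2L) stop("`stim_index` leaves no baseline samples")
      seq_len(stim_index - 1L)
    } else 1L
  }
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L || any(baseline_window < 1L) ||
      any(baseline_window > length(times)))
    stop("`baseline_window` must be a non-empty index range within the trace")
  structure(list(times = times, values = values,
                 baseline_window = baseline_window),
            class = "fluorescence_trace")
}

#' Fold change in fluorescence relative to baseline
#'
#' Computes (F(t) - F0)/F0 for every timepoint, where F0 is the mean intensity
#' over the trace's baseline window. Intended for background-subtracted
#' traces; F0 must be positive.
#'
#' @param trace a [fluorescence_trace()].
#' @return numeric vector of dimensionless fold changes.
#' @export
delta_f_over_f <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  f0 <- mean(trace$values[trace$baseline_window])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline fluorescence F0 must be positive; check background subtraction")
  (trace$values - f0) / f0
}

#' Ratio of peak stimulation response to peak death response
#'
#' The specificity statistic for a death sensor: the maximum fold change under
#' physiological stimulation divided by the maximum fold change during
#' toxin-induced death, per cell. Values near 0 indicate a death-specific
#' sensor; values near 1 an activity sensor. The ratio is reported unclamped
#' (it can be negative when the stimulation window dips below baseline).
#'
#' @param stim_trace,death_trace [fluorescence_trace()] objects from the same
#'   cell under stimulation and lethal treatment.
#' @return dimensionless ratio.
#' @export
stim_death_ratio <- function(stim_trace, death_trace) {
  peak_stim  <- max(delta_f_over_f(stim_trace))
  peak_death <- max(delta_f_over_f(death_trace))
  if (peak_death <= 0)
    stop("maximum death response is not positive; ratio undefined")
  peak_stim / peak_death
}

#' Read a sensor registry from a YAML config
#'
#' The registry is a named list of entries with fields `kd`, `hill_n` and
#' optionally `f_min`, `f_max`. Literature Kd/Hill values are deliberately not
#' hard-coded in the package; users supply them here.
#'
#' @param path path to a YAML file.
#' @return named list of [sensor_spec()] objects.
#' @export
read_sensor_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sensors)) stop("registry must have a top-level `sensors` map")
  out <- lapply(names(cfg$sensors), function(nm) {
    s <- cfg$sensors[[nm]]
    sensor_spec(nm, kd = s$kd, hill_n = s$hill_n,
                f_min = if (is.null(s$f_min)) 0 else s$f_min,
                f_max = if (is.null(s$f_max)) 1 else s$f_max)
  })
  names(out) <- names(cfg$sensors)
  out
}

#' Read / write a fluorescence trace as CSV
#'
#' CSV schema: columns `time`, `value`. The baseline window is not stored in
#' the file; supply it on read.
#'
#' @param path file path.
#' @param trace a [fluorescence_trace()] (for writing).
#' @param ... passed to [fluorescence_trace()] on read (e.g.
#'   `baseline_window`).
#' @return the trace (invisibly for the writer).
#' @export
read_trace_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    stop("trace CSV must have columns `time` and `value`")
  fluorescence_trace(d$time, d$value, ...)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  utils::write.csv(data.frame(time = trace$times, value = trace$values),
                   path, row.names = FALSE)
  invisible(trace)
}
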