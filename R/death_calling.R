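#' GEDI ratio of a segmented object
#'
#' Background-subtracted mean GEDI-channel intensity over the soma mask
#' divided by the mean morphology-channel intensity. The pseudo-ratiometric
#' readout: low in live neurons, jumping irreversibly when the membrane loses
#' Ca2+ integrity at death.
#'
#' @param mean_gedi,mean_morph per-object mean intensities (vectorized).
#' @return dimensionless ratio(s).
#' @export
compute_gedi_ratio <- function(mean_gedi, mean_morph) {
  if (any(mean_morph <= 0))
    stop("morphology mean intensity must be positive; ratio undefined")
  mean_gedi / mean_morph
}

#' Add GEDI ratios to a feature table, dropping undefined objects
#'
#' Objects whose morphology mean is not positive cannot carry a ratio; they
#' are removed and reported in the drop log rather than silently kept.
#'
#' @param features data.frame with `mean_gedi` and `mean_morph` columns.
#' @return list with `features` (input plus `gedi_ratio` column) and
#'   `dropped` (the removed rows with a `reason` column).
#' @export
add_gedi_ratio <- function(features) {
  bad <- features$mean_morph <= 0
  dropped <- features[bad, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "nonpositive_morphology_mean"
  kept <- features[!bad, , drop = FALSE]
  kept$gedi_ratio <- if (nrow(kept))
    compute_gedi_ratio(kept$mean_gedi, kept$mean_morph) else numeric(0)
  list(features = kept, dropped = dropped)
}

#' Calibrate the GEDI death threshold from live and dead reference ratios
#'
#' The threshold sits one quarter of the way from the live-population mean to
#' the dead-population mean:
#' `threshold = mean(live) + weight * (mean(dead) - mean(live))` with
#' `weight = 0.25` by default. Thresholds are recalibrated per experiment:
#' population means shift with expression level, so a threshold is not reused
#' across plates.
#'
#' @param live_ratios GEDI ratios of a known-live calibration population
#'   (typically all objects at the pre-treatment timepoint).
#' @param dead_ratios GEDI ratios of a known-dead population (typically
#'   objects in lethally treated positive-control wells).
#' @param weight interpolation weight, default 0.25.
#' @return an object of class `threshold_model`: `mean_live`, `mean_dead`,
#'   `threshold`, `weight`, `reliable` (FALSE, with a warning, when the dead
#'   mean falls below the live mean).
#' @export
calibrate_threshold <- function(live_ratios, dead_ratios, weight = 0.25) {
  if (length(live_ratios) == 0L || length(dead_ratios) == 0L)
    stop("both calibration populations must be non-empty")
  m_live <- mean(live_ratios); m_dead <- mean(dead_ratios)
  reliable <- m_dead >= m_live
  if (!reliable)
    warning("dead-population mean is below live-population mean; ",
            "threshold flagged unreliable")
  structure(list(mean_live = m_live, mean_dead = m_dead,
                 threshold = (m_dead - m_live) * weight + m_live,
                 weight = weight, reliable = reliable),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> live mean %.4g, dead mean %.4g -> threshold %.4g%s\n",
    x$mean_live, x$mean_dead, x$threshold,
    if (x$reliable) "" else " (UNRELIABLE)"))
  invisible(x)
}

#' Classify GEDI ratios as live or dead
#'
#' Dead if and only if the ratio strictly exceeds the threshold (a ratio
#' exactly at the threshold is live).
#'
#' @param ratio GEDI ratio(s).
#' @param model a [calibrate_threshold()] model or a bare threshold.
#' @return character vector, `"live"` or `"dead"`.
#' @export
classify_ratio <- function(ratio, model) {
  thr <- if (inherits(model, "threshold_model")) model$threshold else model
  ifelse(ratio > thr, "dead", "live")
}

#' Assign a time of death (or censoring) to one track
#'
#' Death is the earliest of (a) the first timepoint at which the GEDI ratio
#' strictly exceeds the threshold and (b) the timepoint at which the track is
#' lost (the first missing timepoint — that is when the loss is observed). A
#' track with neither is censored at the last imaging time.
#'
#' @param times observation timepoints, hours, ascending.
#' @param ratios GEDI ratios aligned to `times` (artifact-flagged timepoints
#'   already excluded per policy).
#' @param model threshold model or scalar threshold.
#' @param lost_at first missing timepoint, or `NA` if never lost.
#' @param last_time final imaging time of the experiment.
#' @return list: `time_h`, `event` (logical), `cause` (`"ratio_crossing"`,
#'   `"track_loss"` or `"censored"`).
#' @export
assign_death_time <- function(times, ratios, model, lost_at = NA,
                              last_time = max(times)) {
  if (length(times) == 0L) stop("empty track")
  thr <- if (inherits(model, "threshold_model")) model$threshold else model
  ord <- order(times)
  times <- times[ord]; ratios <- ratios[ord]
  cross <- times[ratios > thr][1]    # NA when never crossing
  cand <- c(ratio_crossing = cross, track_loss = as.numeric(lost_at))
  if (all(is.na(cand)))
    return(list(time_h = last_time, event = FALSE, cause = "censored"))
  k <- which.min(cand)
  list(time_h = as.numeric(cand[k]), event = TRUE, cause = names(cand)[k])
}

#' Death calls for every track in a processed well set
#'
#' Applies [assign_death_time()] per track. Tracks carrying reversal-artifact
#' flags are excluded by default (routed to the drop log) because reversals
#' indicate segmentation or tracking errors rather than resurrection.
#'
#' @param records data.frame with `track_id`, `timepoint_h`, `gedi_ratio`.
#' @param tracks track summary from [link_tracks()] (`track_id`, `lost_at`).
#' @param model threshold model or scalar threshold.
#' @param last_time final imaging time.
#' @param exclude_flagged exclude reversal-flagged tracks (default TRUE).
#' @return list with `calls` (data.frame: `track_id`, `time_h`, `event`,
#'   `cause`) and `dropped` (data.frame: `track_id`, `reason`).
#' @export
assign_death_calls <- function(records, tracks, model,
                               last_time = max(records$timepoint_h),
                               exclude_flagged = TRUE) {
  flags <- flag_track_reversals(records, model)
  drop_ids <- if (exclude_flagged) unique(flags$track_id) else integer(0)
  calls <- lapply(split(records, records$track_id), function(r) {
    id <- r$track_id[1]
    if (id %in% drop_ids) return(NULL)
    res <- assign_death_time(
      r$timepoint_h, r$gedi_ratio, model,
      lost_at = tracks$lost_at[match(id, tracks$track_id)],
      last_time = last_time)
    data.frame(track_id = id, time_h = res$time_h, event = res$event,
               cause = res$cause)
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls))
    calls <- data.frame(track_id = integer(0), time_h = numeric(0),
                        event = logical(0), cause = character(0))
  rownames(calls) <- NULL
  dropped <- data.frame(track_id = drop_ids,
                        reason = rep("reversal_artifact", length(drop_ids)))
  list(calls = calls, dropped = dropped)
}

#' Concordance between threshold-based and manually curated death calls
#'
#' Cross-tabulates the two call sets over a shared set of tracks and counts
#' the "human error" category: tracks curated live but above threshold that
#' are unambiguously dead at the next imaged timepoint (loss or fragmentation
#' of fluorescence), i.e. cases where the curator, not the threshold, erred.
#'
#' @param calls_by_threshold,calls_by_curation data.frames with `track_id`
#'   and `call` (`"live"`/`"dead"`), covering the same tracks.
#' @param dead_next optional data.frame `track_id`, `dead_next` (logical):
#'   whether the object was dead at the subsequent timepoint.
#' @return list with `table` (2x2 contingency: threshold x curation) and
#'   `human_errors` (count).
#' @export
curation_concordance <- function(calls_by_threshold, calls_by_curation,
                                 dead_next = NULL) {
  a <- calls_by_threshold; b <- calls_by_curation
  if (!setequal(a$track_id, b$track_id))
    stop("the two call sets must cover the same tracks")
  b <- b[match(a$track_id, b$track_id), , drop = FALSE]
  lv <- c("live", "dead")
  tab <- table(threshold = factor(a$call, lv),
               curation = factor(b$call, lv))
  he <- 0L
  if (!is.null(dead_next) && nrow(a)) {
    dn <- dead_next$dead_next[match(a$track_id, dead_next$track_id)]
    he <- sum(a$call == "dead" & b$call == "live" & dn %in% TRUE)
  }
  list(table = tab, human_errors = he)
}

#' Serialize / read a threshold model as a JSON sidecar
#'
#' @param model a [calibrate_threshold()] model.
#' @param path file path.
#' @return the model (invisibly for the writer).
#' @export
write_threshold_json <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_threshold_json
#' @export
read_threshold_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("mean_live", "mean_dead", "threshold", "weight", "reliable")],
            class = "threshold_model")
}
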