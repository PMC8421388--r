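#' Simulate a plate to disk, with a reproducibility manifest
#'
#' Orchestration stage 1: renders the configured plate via [generate_plate()]
#' and records the seed and full configuration in `run_manifest.json` so a
#' rerun with the same config and seed reproduces the outputs byte for byte.
#'
#' @param config a [plate_config()].
#' @param output_dir plate output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return list with `dir`, `truth`, `manifest`.
#' @export
run_simulate <- function(config, output_dir, overwrite = FALSE) {
  res <- generate_plate(config, output_dir, overwrite = overwrite)
  manifest <- list(stage = "simulate", seed = config$seed,
                   config = unclass_deep(config),
                   n_images = length(list.files(output_dir,
                                                pattern = "\\.tif$")))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = output_dir, truth = res$truth,
                 manifest = manifest))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Process a plate: images to features, tracks and death calls
#'
#' Orchestration stage 2, in the canonical order: per-tile median background
#' subtraction, montage stitching, cross-timepoint alignment (shifts
#' estimated on the morphology channel and applied to both), soma
#' segmentation with the minimum-size filter, per-object feature extraction,
#' proximity tracking, GEDI-ratio computation, threshold calibration
#' (Eq.-style live/dead interpolation unless `threshold_override` is given),
#' reversal-artifact flagging and per-track death calling. Every dropped
#' object or track is logged with a reason code.
#'
#' Calibration populations default to: live = all objects at the first
#' timepoint of non-lethal wells; dead = all objects of lethal
#' (positive-control) wells. Lethal wells are excluded from the returned
#' survival records.
#'
#' @param plate_dir plate directory written by [run_simulate()] (or any
#'   directory following the same naming scheme and manifest).
#' @param output_dir where to write `features.csv`, `tracks.csv`,
#'   `gedi_records.csv`, `death_calls.csv`, `threshold.json`, `drops.csv`;
#'   `NULL` to skip writing.
#' @param min_size,sigma segmentation parameters (see [segment()]).
#' @param max_link_dist tracking gate, px; default 2x the median soma
#'   diameter estimated from the segmented objects.
#' @param max_shift registration cap, px.
#' @param threshold_override fixed GEDI threshold replacing calibration.
#' @param gap_tolerance see [link_tracks()].
#' @return list: `features`, `tracks` (observations + summary), `records`
#'   (per-track GEDI ratios), `threshold` (model or override), `calls`
#'   (death calls with well/group), `drops` (log), `paths`.
#' @export
run_process <- function(plate_dir, output_dir = NULL,
                        min_size = 100L, sigma = 2,
                        max_link_dist = NULL, max_shift = 20L,
                        threshold_override = NULL, gap_tolerance = 0L) {
  plate <- read_plate(plate_dir)
  manifest <- plate$manifest
  tg <- manifest$tile_grid
  tps <- manifest$timepoints
  wells <- vapply(manifest$wells, `[[`, character(1), "well")
  lethal <- vapply(manifest$wells, function(w) isTRUE(w$lethal), logical(1))
  groups <- vapply(manifest$wells, `[[`, character(1), "group")

  drops <- list()
  feats <- list()
  for (w in wells) {
    # stitch per timepoint/channel (tiles are background-subtracted first)
    stitched <- list()
    for (ti in seq_along(tps)) {
      for (ch in manifest$channels) {
        tiles <- Filter(function(f)
          f$well == w && f$timepoint == tps[ti] && f$channel == ch,
          plate$frames)
        if (!length(tiles))
          stop("missing channel ", ch, " for well ", w,
               " at timepoint ", tps[ti])
        tiles <- lapply(tiles, subtract_background)
        stitched[[paste(ti, ch)]] <-
          stitch_montage(tiles, tg$rows, tg$cols, tg$overlap)
      }
    }
    # registration on the morphology channel
    morph_series <- lapply(seq_along(tps),
                           function(ti) stitched[[paste(ti, "morphology")]])
    shifts <- align_timepoints(morph_series, max_shift = max_shift)
    for (ti in seq_along(tps)) {
      for (ch in manifest$channels) {
        key <- paste(ti, ch)
        stitched[[key]] <- apply_shift(stitched[[key]],
                                       -shifts[ti, "dx"], -shifts[ti, "dy"])
      }
    }
    # segmentation + features per timepoint
    for (ti in seq_along(tps)) {
      seg <- segment(stitched[[paste(ti, "morphology")]],
                     min_size = min_size, sigma = sigma)
      chs <- lapply(manifest$channels,
                    function(ch) stitched[[paste(ti, ch)]])
      names(chs) <- manifest$channels
      f <- extract_features(seg, chs, well = w, timepoint = tps[ti])
      feats[[paste(w, ti)]] <- f
    }
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  attr(features, "registered") <- TRUE

  # GEDI ratios; undefined objects dropped with a reason
  rat <- add_gedi_ratio(features)
  features <- rat$features
  if (nrow(rat$dropped))
    drops[["ratio"]] <- data.frame(
      stage = "gedi_ratio", well = rat$dropped$well,
      timepoint_h = rat$dropped$timepoint_h,
      id = as.character(rat$dropped$object_label),
      reason = rat$dropped$reason)

  # tracking per well
  obs <- list(); trks <- list(); offset <- 0L
  for (w in wells) {
    fw <- features[features$well == w, , drop = FALSE]
    if (!nrow(fw)) next
    mld <- max_link_dist
    if (is.null(mld)) {
      soma_diam <- 2 * sqrt(stats::median(fw$area_px) / pi)
      mld <- 2 * soma_diam
    }
    lt <- link_tracks(fw, max_link_dist = mld,
                      gap_tolerance = gap_tolerance)
    lt$observations$track_id <- lt$observations$track_id + offset
    lt$tracks$track_id <- lt$tracks$track_id + offset
    offset <- offset + max(0L, nrow(lt$tracks))
    obs[[w]] <- lt$observations; trks[[w]] <- lt$tracks
  }
  observations <- do.call(rbind, obs); tracks <- do.call(rbind, trks)
  rownames(observations) <- rownames(tracks) <- NULL

  # per-track GEDI records
  records <- merge(observations,
                   features[c("well", "timepoint_h", "object_label",
                              "gedi_ratio")],
                   by = c("well", "timepoint_h", "object_label"))
  records <- records[order(records$track_id, records$timepoint_h), ]

  # threshold calibration
  if (is.null(threshold_override)) {
    live <- records$gedi_ratio[records$timepoint_h == tps[1] &
                               !(records$well %in% wells[lethal])]
    dead <- records$gedi_ratio[records$well %in% wells[lethal]]
    if (!length(dead))
      stop("no lethal (positive-control) wells in the plate; supply ",
           "`threshold_override` or calibration labels")
    model <- calibrate_threshold(live, dead)
  } else {
    model <- threshold_override
  }

  # death calls (lethal wells excluded from survival records)
  surv_records <- records[!(records$well %in% wells[lethal]), , drop = FALSE]
  dc <- assign_death_calls(surv_records, tracks, model,
                           last_time = max(tps))
  if (nrow(dc$dropped))
    drops[["reversal"]] <- data.frame(
      stage = "death_call", well = NA_character_, timepoint_h = NA_real_,
      id = as.character(dc$dropped$track_id), reason = dc$dropped$reason)
  calls <- dc$calls
  wmap <- tracks$well[match(calls$track_id, tracks$track_id)]
  calls$well <- wmap
  calls$group <- groups[match(wmap, wells)]
  # tracks first seen after t0 are new objects (debris, late detections) --
  # keep them; their survival time starts at first observation.

  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(stage = character(0), well = character(0),
               timepoint_h = numeric(0), id = character(0),
               reason = character(0))
  rownames(drops) <- NULL

  paths <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      features = file.path(output_dir, "features.csv"),
      tracks = file.path(output_dir, "tracks.csv"),
      records = file.path(output_dir, "gedi_records.csv"),
      calls = file.path(output_dir, "death_calls.csv"),
      drops = file.path(output_dir, "drops.csv"),
      threshold = file.path(output_dir, "threshold.json"))
    utils::write.csv(features, paths$features, row.names = FALSE)
    utils::write.csv(tracks, paths$tracks, row.names = FALSE)
    utils::write.csv(records, paths$records, row.names = FALSE)
    utils::write.csv(calls, paths$calls, row.names = FALSE)
    utils::write.csv(drops, paths$drops, row.names = FALSE)
    if (inherits(model, "threshold_model"))
      write_threshold_json(model, paths$threshold)
  }
  list(features = features, tracks = tracks, observations = observations,
       records = records, threshold = model, calls = calls, drops = drops,
       paths = paths)
}

#' Survival summaries from death calls
#'
#' Orchestration stage 3: Kaplan-Meier curves per group, cumulative
#' risk-of-death curves (cumulative incidence and Nelson-Aalen hazard), and a
#' Cox proportional-hazards table against the reference group. With a single
#' group the Cox stage is skipped with a notice.
#'
#' @param calls death-call table with `time_h`, `event` and a `group` column
#'   (e.g. from [run_process()]), or a path to such a CSV.
#' @param reference_group baseline group for the Cox model.
#' @param output_dir optional; writes `km.csv`, `crd.csv`, `cox.csv`,
#'   `survival_report.txt`.
#' @return list: `km`, `crd`, `cox` (NULL when skipped), `report` (character).
#' @export
run_survival <- function(calls, reference_group = NULL, output_dir = NULL) {
  if (is.character(calls)) calls <- utils::read.csv(calls)
  if (!"group" %in% names(calls))
    stop("death calls need a `group` column for survival analysis")
  km <- km_estimator(calls)
  crd <- cumulative_risk(calls)
  n_groups <- length(unique(calls$group))
  cox <- NULL
  notice <- NULL
  if (n_groups >= 2L && sum(calls$event) > 0) {
    cox <- cox_fit(calls, reference_group = reference_group)
  } else {
    notice <- if (n_groups < 2L)
      "single group: Cox model skipped" else
      "no events: Cox model skipped"
  }
  report <- c(
    sprintf("Survival analysis: %d subjects, %d groups, %d events",
            nrow(calls), n_groups, sum(calls$event)),
    if (!is.null(notice)) notice,
    if (!is.null(cox)) apply(cox, 1, function(r) sprintf(
      "group %s vs %s: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g",
      r[["group"]],
      if (is.null(reference_group)) "reference" else reference_group,
      as.numeric(r[["hr"]]), as.numeric(r[["ci_low"]]),
      as.numeric(r[["ci_high"]]), as.numeric(r[["p"]]))))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(km, file.path(output_dir, "km.csv"), row.names = FALSE)
    utils::write.csv(crd, file.path(output_dir, "crd.csv"), row.names = FALSE)
    if (!is.null(cox))
      utils::write.csv(cox, file.path(output_dir, "cox.csv"),
                       row.names = FALSE)
    writeLines(report, file.path(output_dir, "survival_report.txt"))
  }
  list(km = km, crd = crd, cox = cox, report = report)
}
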