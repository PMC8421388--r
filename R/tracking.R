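#' Link segmented objects across timepoints into single-neuron tracks
#'
#' Proximity tracking: at each timepoint, open tracks are matched to current
#' objects by iterated mutual-nearest-centroid pairing within `max_link_dist`
#' pixels (repeatedly linking the globally closest remaining pair, breaking
#' distance ties by the lower object label). Unmatched current objects start
#' new tracks; an open track with no match is marked lost at that timepoint
#' and, unless `gap_tolerance` allows one missed frame, never reopens.
#'
#' Works on registered coordinates (apply [align_timepoints()] shifts first);
#' if the table carries no registration metadata the function proceeds with a
#' warning when `warn_unregistered` is set.
#'
#' @param objects data.frame of segmented objects for one well, with columns
#'   `timepoint_h`, `object_label`, `centroid_x`, `centroid_y` and optionally
#'   `well`.
#' @param max_link_dist maximum centroid displacement (px) for a link. The
#'   recommended default is twice the median soma diameter of the dataset.
#' @param gap_tolerance 0 (default: a missed detection closes the track) or 1
#'   (a track survives one missing timepoint).
#' @param warn_unregistered emit a warning when shift metadata (attribute
#'   `"registered"`) is absent.
#' @return list with `observations` (data.frame: `track_id`, `well`,
#'   `timepoint_h`, `object_label`, `x`, `y`) and `tracks` (data.frame:
#'   `track_id`, `well`, `first_t`, `last_t`, `lost_at` — `NA` when the track
#'   is observed at the final timepoint).
#' @export
link_tracks <- function(objects, max_link_dist, gap_tolerance = 0L,
                        warn_unregistered = FALSE) {
  stopifnot(max_link_dist > 0, gap_tolerance %in% c(0L, 1L))
  need <- c("timepoint_h", "object_label", "centroid_x", "centroid_y")
  if (!all(need %in% names(objects)))
    stop("`objects` must have columns: ", paste(need, collapse = ", "))
  if (warn_unregistered && is.null(attr(objects, "registered")))
    warning("no registration metadata on object table; proceeding unregistered")
  well <- if ("well" %in% names(objects) && nrow(objects))
    objects$well[1] else NA_character_
  tps <- sort(unique(objects$timepoint_h))
  obs <- list()
  # open tracks: id, x, y, misses (consecutive missed timepoints)
  open <- data.frame(track_id = integer(0), x = numeric(0), y = numeric(0),
                     misses = integer(0))
  lost <- data.frame(track_id = integer(0), lost_at = numeric(0))
  first_seen <- last_seen <- numeric(0)
  next_id <- 1L
  for (t in tps) {
    cur <- objects[objects$timepoint_h == t, , drop = FALSE]
    cur <- cur[order(cur$object_label), , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(cur))
    if (nrow(open) && nrow(cur)) {
      d <- outer(open$x, cur$centroid_x, "-")^2 +
           outer(open$y, cur$centroid_y, "-")^2
      d <- sqrt(d)
      free_tr <- rep(TRUE, nrow(open)); free_ob <- rep(TRUE, nrow(cur))
      repeat {
        dd <- d
        dd[!free_tr, ] <- Inf; dd[, !free_ob] <- Inf
        m <- min(dd)
        if (!is.finite(m) || m > max_link_dist) break
        hit <- which(dd == m, arr.ind = TRUE)
        # ties: lowest current-object label, then lowest track id
        hit <- hit[order(cur$object_label[hit[, 2]],
                         open$track_id[hit[, 1]]), , drop = FALSE]
        i <- hit[1, 1]; j <- hit[1, 2]
        assigned[j] <- i
        free_tr[i] <- FALSE; free_ob[j] <- FALSE
      }
    }
    new_open <- open
    matched_tr <- stats::na.omit(assigned)
    # record observations for matched pairs and refreshed positions
    for (j in seq_len(nrow(cur))) {
      i <- assigned[j]
      if (is.na(i)) {
        id <- next_id; next_id <- next_id + 1L
        first_seen[as.character(id)] <- t
        new_open <- rbind(new_open,
                          data.frame(track_id = id, x = cur$centroid_x[j],
                                     y = cur$centroid_y[j], misses = 0L))
      } else {
        id <- open$track_id[i]
        k <- which(new_open$track_id == id)
        new_open$x[k] <- cur$centroid_x[j]
        new_open$y[k] <- cur$centroid_y[j]
        new_open$misses[k] <- 0L
      }
      last_seen[as.character(id)] <- t
      obs[[length(obs) + 1L]] <- data.frame(
        track_id = id, well = well, timepoint_h = t,
        object_label = cur$object_label[j],
        x = cur$centroid_x[j], y = cur$centroid_y[j])
    }
    # tracks with no match this timepoint
    if (nrow(open)) {
      unmatched <- setdiff(seq_len(nrow(open)), matched_tr)
      for (i in unmatched) {
        id <- open$track_id[i]
        k <- which(new_open$track_id == id)
        new_open$misses[k] <- new_open$misses[k] + 1L
        if (new_open$misses[k] > gap_tolerance) {
          first_missed <- tps[match(t, tps) - (new_open$misses[k] - 1L)]
          lost <- rbind(lost, data.frame(track_id = id, lost_at = first_missed))
          new_open <- new_open[new_open$track_id != id, , drop = FALSE]
        }
      }
    }
    open <- new_open
  }
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(track_id = integer(0), well = character(0),
               timepoint_h = numeric(0), object_label = integer(0),
               x = numeric(0), y = numeric(0))
  ids <- sort(unique(observations$track_id))
  tracks <- data.frame(
    track_id = ids, well = rep(well, length(ids)),
    first_t = as.numeric(first_seen[as.character(ids)]),
    last_t = as.numeric(last_seen[as.character(ids)]),
    lost_at = lost$lost_at[match(ids, lost$track_id)])
  list(observations = observations, tracks = tracks)
}

#' Flag ratio-reversal artifacts in a track
#'
#' A timepoint whose GEDI ratio exceeds the death threshold while some later
#' timepoint falls back below it is flagged `"reversal"`. Such patterns were
#' traced to segmentation/tracking artifacts (not resurrection), so flagged
#' tracks are routed to review or excluded from survival analysis rather than
#' silently re-classified.
#'
#' @param ratios GEDI ratios, time-ordered.
#' @param times matching timepoints (hours).
#' @param threshold death threshold (scalar or [calibrate_threshold()] model).
#' @return data.frame with columns `timepoint_h`, `reason` (zero rows when the
#'   track is clean).
#' @export
flag_reversal_artifacts <- function(ratios, times, threshold) {
  if (inherits(threshold, "threshold_model")) threshold <- threshold$threshold
  stopifnot(length(ratios) == length(times))
  if (length(ratios) == 0L)
    return(data.frame(timepoint_h = numeric(0), reason = character(0)))
  above <- ratios > threshold
  later_below <- rev(cummax(rev(!above))) == 1  # any later tp below threshold
  # shift: "later" must be strictly after
  later_below <- c(later_below[-1], FALSE)
  flag <- above & later_below
  data.frame(timepoint_h = times[flag],
             reason = rep("reversal", sum(flag)))
}

#' Flag reversal artifacts for every track in a record table
#'
#' @param records data.frame with `track_id`, `timepoint_h`, `gedi_ratio`.
#' @param threshold scalar threshold or a [calibrate_threshold()] model.
#' @return data.frame `track_id`, `timepoint_h`, `reason`.
#' @export
flag_track_reversals <- function(records, threshold) {
  out <- lapply(split(records, records$track_id), function(r) {
    r <- r[order(r$timepoint_h), ]
    f <- flag_reversal_artifacts(r$gedi_ratio, r$timepoint_h, threshold)
    if (nrow(f)) cbind(track_id = r$track_id[1], f) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), timepoint_h = numeric(0),
                      reason = character(0))
  rownames(out) <- NULL
  out
}
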