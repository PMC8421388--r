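#' Match pipeline tracks to ground-truth neurons
#'
#' Each track is matched to the nearest ground-truth neuron present at the
#' track's first observed timepoint, within `max_dist` pixels; a greedy
#' nearest-first one-to-one assignment per well. Used to score death calls
#' against the generator's programmed fates.
#'
#' @param observations track observations from [link_tracks()] (columns
#'   `track_id`, `well`, `timepoint_h`, `x`, `y`).
#' @param truth ground-truth table from [generate_well()]/[generate_plate()].
#' @param max_dist maximum centroid-to-truth distance for a match, px.
#' @return data.frame `track_id`, `neuron_id` (NA for unmatched tracks).
#' @export
match_tracks_to_truth <- function(observations, truth, max_dist = 10) {
  first_obs <- do.call(rbind, lapply(split(observations,
                                           observations$track_id), function(o)
    o[which.min(o$timepoint_h), , drop = FALSE]))
  out <- list()
  for (w in unique(first_obs$well)) {
    fo <- first_obs[first_obs$well == w, , drop = FALSE]
    res <- data.frame(track_id = fo$track_id,
                      neuron_id = NA_character_)
    for (t in unique(fo$timepoint_h)) {
      ft <- which(fo$timepoint_h == t)
      tt <- truth[truth$well == w & truth$t == t, , drop = FALSE]
      if (!nrow(tt)) next
      d <- sqrt(outer(fo$x[ft], tt$x, "-")^2 + outer(fo$y[ft], tt$y, "-")^2)
      taken <- rep(FALSE, nrow(tt))
      repeat {
        dd <- d
        dd[!is.na(res$neuron_id[ft]), ] <- Inf
        dd[, taken] <- Inf
        m <- min(dd)
        if (!is.finite(m) || m > max_dist) break
        hit <- which(dd == m, arr.ind = TRUE)[1, , drop = TRUE]
        res$neuron_id[ft[hit[1]]] <- tt$neuron_id[hit[2]]
        taken[hit[2]] <- TRUE
      }
    }
    out[[w]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Confusion summary of death calls against ground truth
#'
#' A neuron's true label is "dead" when its programmed death time falls within
#' the imaging window. Sensitivity is the fraction of truly dead neurons
#' called dead; specificity the fraction of truly surviving neurons called
#' live (censored).
#'
#' @param calls death calls (`track_id`, `event`) from
#'   [assign_death_calls()].
#' @param matches track-to-truth matches from [match_tracks_to_truth()].
#' @param neurons per-neuron truth (from [generate_well()] `$neurons`, or the
#'   unique neuron rows of a truth table) with `neuron_id` and `censored`.
#' @return list: `table` (2x2 call x truth), `sensitivity`, `specificity`,
#'   `n_matched`, `n_unmatched`.
#' @export
death_call_confusion <- function(calls, matches, neurons) {
  m <- merge(calls, matches, by = "track_id")
  m <- m[!is.na(m$neuron_id), , drop = FALSE]
  truth_dead <- !neurons$censored[match(m$neuron_id, neurons$neuron_id)]
  call_dead <- as.logical(m$event)
  tab <- table(call = factor(ifelse(call_dead, "dead", "live"),
                             c("dead", "live")),
               truth = factor(ifelse(truth_dead, "dead", "live"),
                              c("dead", "live")))
  sens <- if (sum(truth_dead)) sum(call_dead & truth_dead) / sum(truth_dead)
          else NA_real_
  spec <- if (sum(!truth_dead)) sum(!call_dead & !truth_dead) / sum(!truth_dead)
          else NA_real_
  list(table = tab, sensitivity = sens, specificity = spec,
       n_matched = nrow(m), n_unmatched = sum(is.na(matches$neuron_id)))
}
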