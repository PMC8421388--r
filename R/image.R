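#' Construct a single-channel frame
#'
#' A frame is one channel at one timepoint of one well (and one montage tile).
#' Pixels are a numeric matrix indexed `[row, col]`; coordinates elsewhere in
#' the package are 0-based with x increasing to the right (columns) and y
#' downwards (rows).
#'
#' @param pixels numeric matrix of non-negative finite intensities.
#' @param well well label.
#' @param timepoint acquisition time, hours.
#' @param channel one of `"gedi"`, `"morphology"`, `"aux"`.
#' @param tile integer `(row, col)` of the montage tile, 0-based.
#' @return an object of class `frame_image`.
#' @export
frame_image <- function(pixels, well = NA_character_, timepoint = NA_real_,
                        channel = c("morphology", "gedi", "aux"),
                        tile = c(0L, 0L)) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop("empty image")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  structure(list(pixels = pixels, well = well, timepoint = timepoint,
                 channel = channel, tile = as.integer(tile)),
            class = "frame_image")
}

# Accept either a frame_image or a bare matrix in image operations.
px <- function(image) {
  if (inherits(image, "frame_image")) image$pixels else as.matrix(image)
}

with_px <- function(image, pixels) {
  if (inherits(image, "frame_image")) { image$pixels <- pixels; image }
  else pixels
}

#' Median background subtraction
#'
#' Subtracts the median intensity of the image from every pixel and clamps
#' negatives to zero. The median-zero property makes GEDI ratios comparable
#' across datasets; on an image whose median is already 0 the operation is
#' idempotent.
#'
#' @param image a [frame_image()] or numeric matrix.
#' @return same type as the input, background-subtracted.
#' @export
subtract_background <- function(image) {
  p <- px(image)
  with_px(image, pmax(p - stats::median(p), 0))
}

#' Stitch a grid of tiles into one montage
#'
#' Tiles of size h x w on an `rows` x `cols` grid with `overlap` pixels shared
#' between adjacent tiles produce a montage of size
#' `(rows*h - (rows-1)*overlap) x (cols*w - (cols-1)*overlap)`. Pixels covered
#' by several tiles are averaged.
#'
#' @param tiles list of [frame_image()]s (or matrices, ordered row-major) with
#'   `tile` metadata giving the 0-based grid position.
#' @param rows,cols grid dimensions.
#' @param overlap overlap between adjacent tiles, pixels.
#' @return a [frame_image()] (metadata from the first tile) or matrix.
#' @export
stitch_montage <- function(tiles, rows, cols, overlap = 0) {
  stopifnot(rows >= 1, cols >= 1, overlap >= 0)
  mats <- lapply(tiles, px)
  pos <- lapply(tiles, function(t)
    if (inherits(t, "frame_image")) t$tile else NULL)
  if (any(vapply(pos, is.null, logical(1)))) {
    if (length(tiles) != rows * cols)
      stop("bare-matrix tiles must be a complete row-major grid")
    pos <- lapply(seq_along(tiles) - 1L,
                  function(i) c(i %/% cols, i %% cols))
  }
  key <- vapply(pos, function(p) paste(p, collapse = ","), character(1))
  need <- as.vector(outer(0:(rows - 1), 0:(cols - 1),
                          function(r, c) paste(r, c, sep = ",")))
  missing <- setdiff(need, key)
  if (length(missing))
    stop("missing tile(s) at grid position(s): ", paste(missing, collapse = "; "))
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  if (overlap >= h || overlap >= w) stop("overlap must be smaller than the tile")
  H <- rows * h - (rows - 1) * overlap
  W <- cols * w - (cols - 1) * overlap
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (i in seq_along(mats)) {
    if (!identical(dim(mats[[i]]), c(h, w))) stop("tiles differ in shape")
    r0 <- pos[[i]][1] * (h - overlap); c0 <- pos[[i]][2] * (w - overlap)
    ri <- (r0 + 1):(r0 + h); ci <- (c0 + 1):(c0 + w)
    acc[ri, ci] <- acc[ri, ci] + mats[[i]]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  out <- acc / cnt
  first <- tiles[[1]]
  if (inherits(first, "frame_image")) {
    first$pixels <- out; first$tile <- c(0L, 0L); first
  } else out
}

#' Estimate per-frame translation of a time series
#'
#' Registers every frame of one well/channel series to the first frame by
#' maximum circular cross-correlation (computed by FFT), returning integer
#' `(dx, dy)` shifts such that frame k approximately equals frame 0 translated
#' by `(dx, dy)` (x rightwards/columns, y downwards/rows). Shifts larger than
#' `max_shift` are clamped with a warning; featureless (zero-variance) frames
#' get a zero shift with a warning. Whole-image translation only: the drift
#' model is stage jitter, not rotation or scaling.
#'
#' @param series list of [frame_image()]s or matrices, same shape, length >= 2.
#' @param max_shift cap on |dx| and |dy| in pixels.
#' @return integer matrix with columns `dx`, `dy`, one row per frame (first
#'   row is 0, 0).
#' @export
align_timepoints <- function(series, max_shift = 50L) {
  stopifnot(length(series) >= 2L)
  mats <- lapply(series, px)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all frames must have the same shape")
  ref <- mats[[1]] - mean(mats[[1]])
  Fref <- stats::fft(ref)
  shifts <- matrix(0L, nrow = length(mats), ncol = 2,
                   dimnames = list(NULL, c("dx", "dy")))
  for (k in 2:length(mats)) {
    cur <- mats[[k]]
    if (stats::sd(cur) == 0 || stats::sd(ref) == 0) {
      warning("featureless frame at position ", k, "; using zero shift")
      next
    }
    cc <- Re(stats::fft(stats::fft(cur - mean(cur)) * Conj(Fref),
                        inverse = TRUE))
    idx <- arrayInd(which.max(cc), d)
    dy <- idx[1] - 1L; dx <- idx[2] - 1L
    if (dy > d[1] %/% 2) dy <- dy - d[1]
    if (dx > d[2] %/% 2) dx <- dx - d[2]
    if (abs(dx) > max_shift || abs(dy) > max_shift) {
      warning("estimated shift (", dx, ", ", dy, ") at position ", k,
              " exceeds max_shift = ", max_shift, "; clamped")
      dx <- max(-max_shift, min(max_shift, dx))
      dy <- max(-max_shift, min(max_shift, dy))
    }
    shifts[k, ] <- c(dx, dy)
  }
  shifts
}

#' Translate an image by an integer shift
#'
#' Moves content by `(dx, dy)` (x rightwards, y downwards), filling exposed
#' borders with zero. Applying the negated shifts from [align_timepoints()]
#' registers a series onto its first frame.
#'
#' @param image a [frame_image()] or matrix.
#' @param dx,dy integer shift in pixels.
#' @return shifted image, same type as input.
#' @export
apply_shift <- function(image, dx, dy) {
  p <- px(image)
  h <- nrow(p); w <- ncol(p)
  out <- matrix(0, h, w)
  sr <- max(1, 1 - dy):min(h, h - dy)   # source rows
  sc <- max(1, 1 - dx):min(w, w - dx)
  if (length(sr) && length(sc))
    out[sr + dy, sc + dx] <- p[sr, sc]
  with_px(image, out)
}

#' Segment bright somata from a background-subtracted morphology image
#'
#' Pipeline: Gaussian smoothing (sigma `sigma`) -> global threshold at the
#' larger of Otsu's value and the `floor_quantile` intensity quantile ->
#' 4-connected component labelling -> removal of components smaller than
#' `min_size` pixels. Components larger than `soma_cap` pixels are restricted
#' to their pixels above the `soma_quantile` intensity quantile and relabelled,
#' biasing masks to the bright soma core rather than neurites. The operator is
#' deliberately pluggable; the defaults target sparse bright somata on a dark
#' background.
#'
#' @param image background-subtracted morphology-channel [frame_image()] or
#'   matrix.
#' @param min_size minimum object area in pixels (default 100).
#' @param sigma Gaussian smoothing scale in pixels; 0 disables smoothing.
#' @param floor_quantile quantile of the smoothed image used as a lower bound
#'   on the threshold.
#' @param noise_floor_k robust noise guard: the threshold is never below
#'   `median + k * mad` of the smoothed image, so frames containing no
#'   objects (where Otsu splits the noise distribution itself) yield no
#'   spurious components. Set to 0 to disable.
#' @param soma_cap area (px) above which a component is restricted to its
#'   bright core.
#' @param soma_quantile intensity quantile defining the bright core.
#' @return a `segmentation`: list with `labels` (integer matrix, 0 =
#'   background) and `objects` (data.frame: `label`, `area_px`, `centroid_x`,
#'   `centroid_y`, 0-based pixel coordinates).
#' @export
segment <- function(image, min_size = 100L, sigma = 2,
                    floor_quantile = 0.5, noise_floor_k = 5,
                    soma_cap = 1000L, soma_quantile = 0.75) {
  p <- px(image)
  sm <- if (sigma > 0) as.matrix(EBImage::gblur(p, sigma = sigma)) else p
  mx <- max(sm)
  empty <- function() structure(
    list(labels = matrix(0L, nrow(p), ncol(p)),
         objects = data.frame(label = integer(0), area_px = integer(0),
                              centroid_x = numeric(0), centroid_y = numeric(0))),
    class = "segmentation")
  if (mx <= 0) return(empty())
  thr_otsu <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  thr <- max(thr_otsu, stats::quantile(sm, floor_quantile),
             stats::median(sm) + noise_floor_k * stats::mad(sm))
  bw <- sm > thr
  if (!any(bw)) return(empty())
  lab <- relabel_sized(bwlabel4(bw), min_size)
  # soma restriction for oversized components
  if (is.finite(soma_cap) && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    big <- which(areas > soma_cap)
    if (length(big)) {
      for (b in big) {
        sel <- lab == b
        core <- stats::quantile(sm[sel], soma_quantile)
        lab[sel & sm <= core] <- 0L
      }
      lab <- relabel_sized(bwlabel4(lab > 0), min_size)
    }
  }
  if (max(lab) == 0L) return(empty())
  idx <- which(lab > 0)
  ij <- arrayInd(idx, dim(lab))
  l <- lab[idx]
  objects <- data.frame(
    label = sort(unique(l)),
    area_px = as.integer(tabulate(l)[sort(unique(l))]),
    centroid_x = as.numeric(tapply(ij[, 2] - 1, l, mean)),
    centroid_y = as.numeric(tapply(ij[, 1] - 1, l, mean)))
  structure(list(labels = lab, objects = objects), class = "segmentation")
}

# 4-connected labelling via EBImage, returned as a plain integer matrix.
bwlabel4 <- function(bw) {
  lab <- EBImage::bwlabel(bw * 1)
  matrix(as.integer(round(lab)), nrow(bw), ncol(bw))
}

# Drop components smaller than min_size and renumber 1..K in raster order of
# first occurrence (matching EBImage's numbering convention).
relabel_sized <- function(lab, min_size) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= min_size)
  map <- integer(max(lab))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Extract per-object intensity features across channels
#'
#' Mean and peak intensity within each segmented mask, per channel, computed
#' on background-subtracted images. One row per object, using the fixed
#' feature schema shared by the pipeline CSVs.
#'
#' @param seg a segmentation from [segment()].
#' @param channels named list of background-subtracted [frame_image()]s or
#'   matrices (same shape as the segmented image); must contain at least
#'   `gedi` and `morphology` for the standard schema, but any names work.
#' @param well,timepoint metadata recorded in the output (defaults taken from
#'   the first `frame_image` in `channels` if available).
#' @return data.frame: `well`, `timepoint_h`, `object_label`, `area_px`,
#'   `centroid_x`, `centroid_y`, then `mean_<ch>` and `peak_<ch>` per channel
#'   (with `morphology` abbreviated `morph`).
#' @export
extract_features <- function(seg, channels, well = NULL, timepoint = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be a named list")
  meta <- Filter(function(x) inherits(x, "frame_image"), channels)
  if (is.null(well)) well <- if (length(meta)) meta[[1]]$well else NA_character_
  if (is.null(timepoint))
    timepoint <- if (length(meta)) meta[[1]]$timepoint else NA_real_
  objs <- seg$objects
  out <- data.frame(well = rep(well, nrow(objs)),
                    timepoint_h = rep(timepoint, nrow(objs)),
                    object_label = objs$label,
                    area_px = objs$area_px,
                    centroid_x = objs$centroid_x,
                    centroid_y = objs$centroid_y)
  lab <- seg$labels
  for (ch in names(channels)) {
    p <- px(channels[[ch]])
    if (!identical(dim(p), dim(lab)))
      stop("channel `", ch, "` image missing or of wrong shape")
    short <- if (ch == "morphology") "morph" else ch
    if (nrow(objs)) {
      v <- p[lab > 0]; l <- lab[lab > 0]
      out[[paste0("mean_", short)]] <-
        as.numeric(tapply(v, l, mean)[as.character(objs$label)])
      out[[paste0("peak_", short)]] <-
        as.numeric(tapply(v, l, max)[as.character(objs$label)])
    } else {
      out[[paste0("mean_", short)]] <- numeric(0)
      out[[paste0("peak_", short)]] <- numeric(0)
    }
  }
  out
}

#' Binarized signal area over time, normalized to the first timepoint
#'
#' For whole-organism reporter imaging (e.g. motor-axon area per fish): each
#' frame is background-subtracted, exclusion-masked, binarized at a threshold
#' fixed on the first timepoint (Otsu by default, reused for all frames so
#' area trends are not confounded by per-frame thresholds), and the foreground
#' pixel count is divided by the count at t0.
#'
#' @param series list of [frame_image()]s or matrices (one per timepoint).
#' @param exclusion_mask optional logical/0-1 matrix; `TRUE`/1 pixels are
#'   zeroed before thresholding (manual anatomical masking).
#' @param binarize_threshold optional fixed threshold; default Otsu on the
#'   processed t0 frame.
#' @return numeric vector of normalized areas, one per timepoint (1.0 at t0).
#' @export
quantify_masked_area <- function(series, exclusion_mask = NULL,
                                 binarize_threshold = NULL) {
  stopifnot(length(series) >= 1L)
  proc <- lapply(series, function(f) {
    p <- px(subtract_background(f))
    if (!is.null(exclusion_mask)) {
      if (!identical(dim(exclusion_mask), dim(p)))
        stop("exclusion mask shape mismatch")
      p[exclusion_mask > 0] <- 0
    }
    p
  })
  if (is.null(binarize_threshold)) {
    mx <- max(proc[[1]])
    if (mx <= 0) stop("no signal at the first timepoint; cannot normalize")
    binarize_threshold <-
      EBImage::otsu(EBImage::Image(proc[[1]] / mx), range = c(0, 1)) * mx
  }
  counts <- vapply(proc, function(p) sum(p > binarize_threshold), numeric(1))
  if (counts[1] == 0)
    stop("zero foreground area at the first timepoint; cannot normalize")
  counts / counts[1]
}

#' GEDI ratio over a region of interest
#'
#' Mean background-subtracted GEDI intensity over the ROI divided by the mean
#' background-subtracted morphology intensity, for preparations where single
#' cells cannot be resolved (e.g. per hemi-segment in vivo).
#'
#' @param gedi_image,morph_image [frame_image()]s or matrices, same shape.
#' @param roi_mask logical/0-1 matrix selecting the ROI; must be non-empty.
#' @return dimensionless ratio.
#' @export
roi_ratio <- function(gedi_image, morph_image, roi_mask) {
  g <- px(subtract_background(gedi_image))
  m <- px(subtract_background(morph_image))
  if (!identical(dim(g), dim(m)) || !identical(dim(g), dim(roi_mask)))
    stop("images and ROI mask must share one shape")
  sel <- roi_mask > 0
  if (!any(sel)) stop("ROI mask is empty")
  denom <- mean(m[sel])
  if (denom <= 0) stop("morphology signal in ROI is not positive; ratio undefined")
  mean(g[sel]) / denom
}
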