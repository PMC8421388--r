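#' Describe one well of a synthetic plate
#'
#' @param well well label (e.g. `"A1"`).
#' @param group biological group label used in survival analysis.
#' @param n_neurons number of neurons seeded in the well.
#' @param rate exponential death hazard, events per hour (0 = no deaths).
#' @param lethal if `TRUE` the well is a positive-control (lethally treated)
#'   well: every neuron is dead from the first timepoint. Lethal wells are the
#'   default dead-calibration population and are excluded from survival
#'   records.
#' @return a `well_spec` list.
#' @export
well_spec <- function(well, group, n_neurons, rate = 0, lethal = FALSE) {
  stopifnot(is.character(well), is.character(group),
            n_neurons >= 0, rate >= 0)
  structure(list(well = well, group = group,
                 n_neurons = as.integer(n_neurons),
                 rate = rate, lethal = isTRUE(lethal)),
            class = "well_spec")
}

#' Configure a synthetic two-channel time-lapse plate
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' sparse Gaussian somata with thin neurite strokes on a noisy background,
#' whose GEDI:morphology intensity ratio sits in a low live band until a
#' programmed death time, jumps irreversibly to a high dead band, then decays
#' exponentially in both channels (equal half-lives by default, the measured
#' behaviour of the red/green reporter pair) until the debris drops below the
#' disappearance floor (peak below `2 * noise_sd`) and the object vanishes.
#' Death times are exponential draws from per-well hazards (Weibull optional
#' via `weibull_shape`); a global integer stage jitter is applied per
#' timepoint.
#'
#' @param wells list of [well_spec()]s.
#' @param timepoints acquisition times in hours, strictly increasing
#'   (default 0-96 h at 24 h intervals, the plate-survival cadence).
#' @param image_shape `c(height, width)` pixels of the full well image.
#' @param tile_grid list `rows`, `cols`, `overlap` (px) for montage tiling.
#' @param psf_sigma soma Gaussian scale, px.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @param background_level constant background intensity.
#' @param background_gradient peak-to-peak amplitude of an optional linear
#'   horizontal background gradient.
#' @param live_ratio_mean,live_ratio_sd GEDI ratio band of live neurons.
#' @param dead_ratio_mean,dead_ratio_sd GEDI ratio band after death; the dead
#'   mean must exceed the live mean.
#' @param decay_half_life_gedi,decay_half_life_morph post-death decay
#'   half-lives, hours.
#' @param jitter_px SD of the per-timepoint global integer stage drift.
#' @param soma_amp_mean,soma_amp_sdlog log-normal soma peak amplitude
#'   (morphology channel), intensity units.
#' @param neurite_rel_intensity neurite stroke intensity relative to the soma
#'   peak (kept well below segmentation thresholds).
#' @param min_spacing minimum centre-to-centre neuron distance, px.
#' @param fragmentation render death as the soma splitting into 2-4 sub-blobs
#'   (off by default, keeping segmentation tests clean).
#' @param weibull_shape shape of the death-time law; 1 (default) gives the
#'   exponential law.
#' @param seed integer RNG seed; identical config + seed reproduces the plate
#'   bit for bit.
#' @return a `plate_config` list.
#' @export
plate_config <- function(wells,
                         timepoints = seq(0, 96, by = 24),
                         image_shape = c(512L, 512L),
                         tile_grid = list(rows = 1L, cols = 1L, overlap = 0L),
                         psf_sigma = 3,
                         noise_sd = 50,
                         background_level = 500,
                         background_gradient = 0,
                         live_ratio_mean = 0.01, live_ratio_sd = 0.003,
                         dead_ratio_mean = 0.5, dead_ratio_sd = 0.05,
                         decay_half_life_gedi = 20.45,
                         decay_half_life_morph = 20.45,
                         jitter_px = 1.5,
                         soma_amp_mean = 20000, soma_amp_sdlog = 0.2,
                         neurite_rel_intensity = 0.1,
                         min_spacing = 50,
                         fragmentation = FALSE,
                         weibull_shape = 1,
                         seed = 1L) {
  if (inherits(wells, "well_spec")) wells <- list(wells)
  stopifnot(length(wells) >= 1L,
            all(vapply(wells, inherits, logical(1), "well_spec")))
  if (any(diff(timepoints) <= 0) || length(timepoints) < 1L)
    stop("`timepoints` must be strictly increasing")
  if (dead_ratio_mean <= live_ratio_mean)
    stop("`dead_ratio_mean` must exceed `live_ratio_mean`")
  for (v in c(psf_sigma, noise_sd, decay_half_life_gedi,
              decay_half_life_morph, soma_amp_mean, min_spacing,
              weibull_shape))
    if (v <= 0) stop("all scale parameters must be positive")
  structure(list(
    wells = wells, timepoints = as.numeric(timepoints),
    image_shape = as.integer(image_shape), tile_grid = tile_grid,
    psf_sigma = psf_sigma, noise_sd = noise_sd,
    background_level = background_level,
    background_gradient = background_gradient,
    live_ratio_mean = live_ratio_mean, live_ratio_sd = live_ratio_sd,
    dead_ratio_mean = dead_ratio_mean, dead_ratio_sd = dead_ratio_sd,
    decay_half_life_gedi = decay_half_life_gedi,
    decay_half_life_morph = decay_half_life_morph,
    jitter_px = jitter_px,
    soma_amp_mean = soma_amp_mean, soma_amp_sdlog = soma_amp_sdlog,
    neurite_rel_intensity = neurite_rel_intensity,
    min_spacing = min_spacing, fragmentation = isTRUE(fragmentation),
    weibull_shape = weibull_shape, seed = as.integer(seed)),
    class = "plate_config")
}

#' The default four-well demonstration plate
#'
#' Two vehicle wells and one treated well (hazard ratio `hr` over the vehicle
#' hazard) of 150 neurons each, plus a 50-neuron lethal positive-control well
#' used for dead-band threshold calibration: 500 neurons in total.
#'
#' @param hr true hazard ratio of the treated group.
#' @param baseline_rate vehicle death hazard, events/hour.
#' @param seed RNG seed.
#' @param ... further arguments to [plate_config()].
#' @return a `plate_config`.
#' @export
default_plate_config <- function(hr = 2, baseline_rate = 0.008, seed = 1L,
                                 ...) {
  plate_config(
    wells = list(
      well_spec("A1", "vehicle", 150, rate = baseline_rate),
      well_spec("A2", "vehicle", 150, rate = baseline_rate),
      well_spec("B1", "treated", 150, rate = baseline_rate * hr),
      well_spec("B2", "dead_control", 50, lethal = TRUE)),
    image_shape = c(1024L, 1024L), seed = seed, ...)
}

# truncated normal draw (positive support), simple rejection
rtnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Sample n centres with minimum pairwise spacing, margin from the border.
place_neurons <- function(n, h, w, spacing, margin) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 400L * n)
      stop("could not place ", n, " neurons with spacing ", spacing,
           " px in a ", h, "x", w, " image; use fewer neurons")
    x <- stats::runif(1, margin, w - 1 - margin)
    y <- stats::runif(1, margin, h - 1 - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= spacing^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

# Add a Gaussian blob of amplitude `amp`, scale `sigma`, centred at 0-based
# (x, y), into matrix `img` (in place value, returned). Used on small patch
# matrices only; full-frame rendering goes through precomputed patches.
add_blob <- function(img, x, y, amp, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  ci <- max(1, floor(x) + 1 - r):min(w, floor(x) + 1 + r)
  ri <- max(1, floor(y) + 1 - r):min(h, floor(y) + 1 + r)
  if (!length(ci) || !length(ri)) return(img)
  dx2 <- ((ci - 1) - x)^2
  dy2 <- ((ri - 1) - y)^2
  img[ri, ci] <- img[ri, ci] + amp * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  img
}

# Thin neurite stroke: points along a segment with small-Gaussian profile.
add_stroke <- function(img, x, y, angle, len, amp, sigma) {
  steps <- seq(2 * sigma, len, by = max(sigma / 2, 0.5))
  for (s in steps)
    img <- add_blob(img, x + s * cos(angle), y + s * sin(angle), amp, sigma)
  img
}

# Precompute unit-amplitude rendering patches for one neuron. The soma centre
# sits at local 0-based (r + fx, r + fy), baking the sub-pixel part of the
# neuron position into the patch (stage jitter is integer, so the fractional
# part is constant over time). `live`: soma + neurite strokes; `dead`: bare
# soma, or 2-4 sub-blobs when fragmentation is on. Neurite relative intensity
# is `neurite_rel` (strokes are reused for both channels, so the channel
# ratio stays uniform across the cell).
make_patches <- function(fx, fy, sigma, ang1, ang2, len, neurite_rel,
                         frag_off = NULL) {
  r <- ceiling(max(4 * sigma, len + 2 * sigma,
                   if (!is.null(frag_off)) max(abs(frag_off)) + 3.5 * sigma
                   else 0))
  side <- 2L * r + 1L
  cx <- r + fx; cy <- r + fy
  live <- add_blob(matrix(0, side, side), cx, cy, 1, sigma)
  if (neurite_rel > 0) {
    ns <- sigma / 2
    live <- add_stroke(live, cx, cy, ang1, len, neurite_rel, ns)
    live <- add_stroke(live, cx, cy, ang2, len, neurite_rel, ns)
  }
  dead <- if (is.null(frag_off)) {
    add_blob(matrix(0, side, side), cx, cy, 1, sigma)
  } else {
    k <- nrow(frag_off)
    m <- matrix(0, side, side)
    for (q in seq_len(k))
      m <- add_blob(m, cx + frag_off[q, 1], cy + frag_off[q, 2],
                    1 / sqrt(k), 0.7 * sigma)
    m
  }
  list(live = live, dead = dead, r = r)
}

# Add `amp * patch` into `img` with the patch centre at 0-based integer
# anchor (xi, yi) (the floor of the neuron position plus jitter), clipping at
# the borders.
blit <- function(img, patch, amp, xi, yi, r) {
  h <- nrow(img); w <- ncol(img)
  r0 <- yi - r + 1L; c0 <- xi - r + 1L        # 1-based top-left in img
  ri <- max(1L, r0):min(h, r0 + 2L * r)
  ci <- max(1L, c0):min(w, c0 + 2L * r)
  if (!length(ri) || !length(ci)) return(img)
  img[ri, ci] <- img[ri, ci] +
    amp * patch[ri - r0 + 1L, ci - c0 + 1L]
  img
}

#' Render one well of a synthetic plate
#'
#' Deterministic given the config and well id (an independent RNG substream
#' is derived from the config seed and the well's position in the config).
#' See [plate_config()] for the generative model.
#'
#' @param config a [plate_config()].
#' @param well well label present in `config$wells`.
#' @return list with `frames` (list of [frame_image()]s covering every
#'   timepoint x channel x tile), `truth` (per-neuron, per-timepoint table:
#'   `neuron_id`, `well`, `group`, `t`, `x`, `y`, `true_gedi_intensity`,
#'   `true_morph_intensity`, `death_time`, `disappear_time`, `censored`) and
#'   `neurons` (one row per neuron with its programmed fate).
#' @export
generate_well <- function(config, well) {
  stopifnot(inherits(config, "plate_config"))
  widx <- match(well, vapply(config$wells, `[[`, character(1), "well"))
  if (is.na(widx)) stop("unknown well: ", well)
  ws <- config$wells[[widx]]
  h <- config$image_shape[1]; w <- config$image_shape[2]
  tps <- config$timepoints
  last_t <- max(tps)
  floor_int <- 2 * config$noise_sd

  local_seed(config$seed + 7919L * widx, {
    n <- ws$n_neurons
    pos <- place_neurons(n, h, w, config$min_spacing,
                         margin = 6 * config$psf_sigma)
    amp <- if (n) stats::rlnorm(n, log(config$soma_amp_mean),
                                config$soma_amp_sdlog) else numeric(0)
    r_live <- if (n) rtnorm_pos(n, config$live_ratio_mean,
                                config$live_ratio_sd) else numeric(0)
    r_dead <- if (n) rtnorm_pos(n, config$dead_ratio_mean,
                                config$dead_ratio_sd) else numeric(0)
    death <- if (ws$lethal) rep(0, n)
      else if (ws$rate > 0)
        stats::rweibull(n, shape = config$weibull_shape,
                        scale = (1 / ws$rate) /
                          gamma(1 + 1 / config$weibull_shape))
      else rep(Inf, n)
    # time at which post-death decay brings the soma peak below the floor
    disappear <- ifelse(is.finite(death),
      death + config$decay_half_life_morph *
        pmax(log2(amp / floor_int), 0), Inf)
    n_ang <- if (n) stats::runif(n, 0, 2 * pi) else numeric(0)
    n_ang2 <- n_ang + stats::runif(max(n, 0), 2, 4)  # second neurite direction
    n_len <- if (n) stats::runif(n, 6, 10) * config$psf_sigma else numeric(0)
    frag_off <- if (config$fragmentation && n)
      lapply(seq_len(n), function(i) {
        k <- sample(2:4, 1)
        cbind(stats::rnorm(k, 0, 2 * config$psf_sigma),
              stats::rnorm(k, 0, 2 * config$psf_sigma))
      }) else NULL
    jit <- cbind(dx = c(0, round(stats::rnorm(length(tps) - 1, 0, config$jitter_px))),
                 dy = c(0, round(stats::rnorm(length(tps) - 1, 0, config$jitter_px))))
    patches <- lapply(seq_len(n), function(i) make_patches(
      pos[i, "x"] - floor(pos[i, "x"]), pos[i, "y"] - floor(pos[i, "y"]),
      config$psf_sigma, n_ang[i], n_ang2[i], n_len[i],
      config$neurite_rel_intensity,
      if (config$fragmentation) frag_off[[i]] else NULL))

    frames <- list(); truth <- list()
    grad <- if (config$background_gradient != 0)
      matrix(rep(config$background_gradient * (0:(w - 1)) / max(w - 1, 1),
                 each = h), h, w) else 0
    for (ti in seq_along(tps)) {
      t <- tps[ti]
      morph <- matrix(config$background_level, h, w) + grad
      gedi <- matrix(config$background_level, h, w) + grad
      pres <- logical(n); am_t <- ag_t <- numeric(n)
      for (i in seq_len(n)) {
        if (t >= disappear[i]) next
        dead_now <- t >= death[i]
        decay_m <- if (dead_now)
          2^(-(t - death[i]) / config$decay_half_life_morph) else 1
        decay_g <- if (dead_now)
          2^(-(t - death[i]) / config$decay_half_life_gedi) else 1
        a_m <- amp[i] * decay_m
        if (a_m < floor_int) next
        a_g <- amp[i] * decay_g * if (dead_now) r_dead[i] else r_live[i]
        pres[i] <- TRUE; am_t[i] <- a_m; ag_t[i] <- a_g
        p <- patches[[i]]
        pat <- if (dead_now) p$dead else p$live
        # in-place blit (no function call: keeps the matrix un-shared)
        xi <- floor(pos[i, "x"]) + jit[ti, "dx"]
        yi <- floor(pos[i, "y"]) + jit[ti, "dy"]
        r0 <- yi - p$r + 1L; c0 <- xi - p$r + 1L
        ri <- max(1L, r0):min(h, r0 + 2L * p$r)
        ci <- max(1L, c0):min(w, c0 + 2L * p$r)
        if (length(ri) && length(ci)) {
          morph[ri, ci] <- morph[ri, ci] +
            a_m * pat[ri - r0 + 1L, ci - c0 + 1L]
          gedi[ri, ci] <- gedi[ri, ci] +
            a_g * pat[ri - r0 + 1L, ci - c0 + 1L]
        }
      }
      if (any(pres)) {
        ii <- which(pres)
        truth[[length(truth) + 1L]] <- data.frame(
          neuron_id = paste0(ws$well, "_", ii), well = ws$well,
          group = ws$group, t = t,
          x = pos[ii, "x"] + jit[ti, "dx"], y = pos[ii, "y"] + jit[ti, "dy"],
          true_gedi_intensity = ag_t[ii], true_morph_intensity = am_t[ii],
          death_time = death[ii], disappear_time = disappear[ii],
          censored = !is.finite(death[ii]) | death[ii] > last_t)
      }
      morph <- quantize16(morph + stats::rnorm(h * w, 0, config$noise_sd))
      gedi <- quantize16(gedi + stats::rnorm(h * w, 0, config$noise_sd))
      for (ch in c("gedi", "morphology")) {
        full <- if (ch == "gedi") gedi else morph
        for (tl in slice_tiles(full, config$tile_grid)) {
          frames[[length(frames) + 1L]] <- frame_image(
            tl$pixels, well = ws$well, timepoint = t, channel = ch,
            tile = c(tl$row, tl$col))
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      neuron_id = character(0), well = character(0), group = character(0),
      t = numeric(0), x = numeric(0), y = numeric(0),
      true_gedi_intensity = numeric(0), true_morph_intensity = numeric(0),
      death_time = numeric(0), disappear_time = numeric(0),
      censored = logical(0))
    neurons <- data.frame(
      neuron_id = if (n) paste0(ws$well, "_", seq_len(n)) else character(0),
      well = rep(ws$well, n), group = rep(ws$group, n),
      x0 = pos[, "x"], y0 = pos[, "y"],
      death_time = death, disappear_time = disappear,
      censored = !is.finite(death) | death > last_t)
    list(frames = frames, truth = truth, neurons = neurons)
  })
}

quantize16 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}

# Cut a full image into the configured tile grid (with overlap). Tile size
# must divide evenly; tiles are indexed 0-based (row, col).
slice_tiles <- function(full, tile_grid) {
  rows <- tile_grid$rows; cols <- tile_grid$cols
  ov <- if (is.null(tile_grid$overlap)) 0L else tile_grid$overlap
  if (rows == 1L && cols == 1L)
    return(list(list(pixels = full, row = 0L, col = 0L)))
  H <- nrow(full); W <- ncol(full)
  th <- (H + (rows - 1) * ov) / rows
  tw <- (W + (cols - 1) * ov) / cols
  if (th != round(th) || tw != round(tw))
    stop("image shape is not divisible into the tile grid with this overlap")
  out <- list()
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    r0 <- r * (th - ov); c0 <- c * (tw - ov)
    out[[length(out) + 1L]] <- list(
      pixels = full[(r0 + 1):(r0 + th), (c0 + 1):(c0 + tw)],
      row = r, col = c)
  }
  out
}

#' Write a whole synthetic plate to disk
#'
#' One 16-bit grayscale TIFF per well/timepoint/channel/tile following the
#' naming scheme `{well}_T{t}_CH{channel}_X{col}_Y{row}.tif` (t is the
#' 0-based timepoint index), plus `truth.csv` (ground-truth table across
#' wells) and `plate_manifest.json` describing layout, timepoints, channels
#' and seed.
#'
#' @param config a [plate_config()].
#' @param output_dir directory to create.
#' @param overwrite allow writing into an existing directory.
#' @return (invisibly) list with `dir`, `truth` and the manifest.
#' @export
generate_plate <- function(config, output_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "plate_config"))
  if (dir.exists(output_dir) && !overwrite &&
      length(list.files(output_dir)))
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  truths <- list()
  for (ws in config$wells) {
    res <- generate_well(config, ws$well)
    truths[[ws$well]] <- res$truth
    for (fr in res$frames) {
      ti <- match(fr$timepoint, config$timepoints) - 1L
      fn <- sprintf("%s_T%d_CH%s_X%d_Y%d.tif", fr$well, ti, fr$channel,
                    fr$tile[2], fr$tile[1])
      tiff::writeTIFF(fr$pixels / 65535, file.path(output_dir, fn),
                      bits.per.sample = 16L, compression = "none")
    }
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  utils::write.csv(truth, file.path(output_dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    wells = lapply(config$wells, function(ws)
      list(well = ws$well, group = ws$group, n_neurons = ws$n_neurons,
           rate = ws$rate, lethal = ws$lethal)),
    timepoints = config$timepoints,
    channels = c("gedi", "morphology"),
    image_shape = config$image_shape,
    tile_grid = config$tile_grid,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(output_dir, "plate_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = output_dir, truth = truth, manifest = manifest))
}

#' Read plate images written by [generate_plate()]
#'
#' @param plate_dir plate directory containing `plate_manifest.json`.
#' @return list with `manifest` and `frames` (list of [frame_image()]s).
#' @export
read_plate <- function(plate_dir) {
  mpath <- file.path(plate_dir, "plate_manifest.json")
  if (!file.exists(mpath)) stop("no plate_manifest.json in ", plate_dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  tg <- manifest$tile_grid
  frames <- list()
  for (ws in manifest$wells) {
    for (ti in seq_along(manifest$timepoints)) {
      for (ch in manifest$channels) {
        for (r in 0:(tg$rows - 1)) for (c in 0:(tg$cols - 1)) {
          fn <- sprintf("%s_T%d_CH%s_X%d_Y%d.tif", ws$well, ti - 1L, ch, c, r)
          path <- file.path(plate_dir, fn)
          if (!file.exists(path))
            stop("missing image for well ", ws$well, ", timepoint index ",
                 ti - 1L, ", channel ", ch, ": ", fn)
          pixels <- round(tiff::readTIFF(path) * 65535)
          frames[[length(frames) + 1L]] <- frame_image(
            pixels, well = ws$well,
            timepoint = manifest$timepoints[ti], channel = ch,
            tile = c(r, c))
        }
      }
    }
  }
  list(manifest = manifest, frames = frames)
}
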