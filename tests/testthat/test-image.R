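test_that("median background subtraction zeroes constants and is idempotent", {
  expect_equal(subtract_background(matrix(7.5, 10, 10)),
               matrix(0, 10, 10))
  m <- matrix(c(0, 0, 0, 100), 2, 2)           # median 0: unchanged
  expect_equal(subtract_background(m), m)
  set.seed(1)
  r <- matrix(rpois(441, 50), 21, 21)        # odd count: clean median
  sub <- subtract_background(r)
  expect_equal(sub, pmax(r - median(r), 0))
  # at least half the pixels clamp to 0, so the new median is 0: idempotent
  expect_equal(median(sub), 0)
  expect_equal(subtract_background(sub), sub)
  # frame metadata is preserved
  fr <- frame_image(r, well = "A1", timepoint = 24, channel = "gedi")
  out <- subtract_background(fr)
  expect_s3_class(out, "frame_image")
  expect_identical(out$well, "A1")
})

test_that("montage stitching assembles grids and averages overlaps", {
  one <- matrix(3, 50, 40)
  expect_equal(px <- stitch_montage(list(one), 1, 1), one)   # identity
  tiles <- lapply(0:3, function(i)
    frame_image(matrix(i + 1, 100, 100), well = "w", timepoint = 0,
                channel = "morphology", tile = c(i %/% 2, i %% 2)))
  out <- stitch_montage(tiles, 2, 2, overlap = 0)
  expect_equal(dim(out$pixels), c(200L, 200L))
  expect_equal(out$pixels[1, 1], 1)
  expect_equal(out$pixels[200, 200], 4)
  # constant tiles a, b: vertical overlap strip averages to (a+b)/2
  ta <- frame_image(matrix(2, 60, 60), tile = c(0, 0), channel = "aux")
  tb <- frame_image(matrix(8, 60, 60), tile = c(0, 1), channel = "aux")
  out2 <- stitch_montage(list(ta, tb), 1, 2, overlap = 20)
  expect_equal(dim(out2$pixels), c(60L, 100L))
  expect_equal(unique(as.vector(out2$pixels[, 41:60])), 5)
  expect_equal(unique(as.vector(out2$pixels[, 1:40])), 2)
  expect_error(stitch_montage(list(ta), 1, 2, overlap = 20), "missing tile")
})

test_that("alignment recovers programmed shifts and applies caps", {
  set.seed(4)
  base <- matrix(rnorm(96 * 96)^2 * 100, 96, 96)
  expect_equal(align_timepoints(list(base, base)),
               matrix(0L, 2, 2, dimnames = list(NULL, c("dx", "dy"))))
  shifted <- roll_matrix(base, 3, -2)
  sh <- align_timepoints(list(base, shifted))
  expect_equal(sh[2, ], c(dx = 3, dy = -2))
  # randomized integer shifts, exact recovery
  for (k in 1:10) {
    dd <- sample(-8:8, 2)
    sh <- align_timepoints(list(base, roll_matrix(base, dd[1], dd[2])))
    expect_equal(unname(sh[2, ]), dd)
  }
  # cap: clamped with a warning
  far <- roll_matrix(base, 15, 0)
  expect_warning(shc <- align_timepoints(list(base, far), max_shift = 5),
                 "clamped")
  expect_equal(unname(shc[2, "dx"]), 5)
  # featureless frame: zero shift with a warning
  expect_warning(shz <- align_timepoints(list(base, matrix(1, 96, 96))),
                 "featureless")
  expect_equal(unname(shz[2, ]), c(0L, 0L))
  # noisy shifted copy: within +/- 1 px at 10% noise
  noisy <- roll_matrix(base, 4, 4) + matrix(rnorm(96 * 96, 0, 10), 96, 96)
  shn <- align_timepoints(list(base, noisy))
  expect_true(all(abs(shn[2, ] - c(4, 4)) <= 1))
})

test_that("applying negated shifts registers a translated series", {
  set.seed(5)
  base <- matrix(rexp(64 * 64) * 50, 64, 64)
  moved <- apply_shift(base, 3, -2)
  sh <- align_timepoints(list(base, moved))
  back <- apply_shift(moved, -sh[2, "dx"], -sh[2, "dy"])
  # interior agrees exactly (borders are zero-filled)
  expect_equal(back[10:50, 10:50], base[10:50, 10:50])
})

test_that("segmentation enforces the minimum size and finds centroids", {
  empty <- segment(matrix(0, 64, 64))
  expect_equal(nrow(empty$objects), 0)

  # a 150 px disk passes the 100 px floor, a 50 px disk does not
  img <- disk_image(128, 128, rbind(c(40, 40, 6.9), c(90, 90, 3.9)))
  expect_equal(sum(img[, 1:65] > 0) >= 100, TRUE)  # sanity on construction
  seg <- segment(img, min_size = 100, sigma = 1)
  expect_equal(nrow(seg$objects), 1)
  expect_lt(abs(seg$objects$centroid_x - 40), 1.5)

  # two disks: correct count and centroids
  img2 <- disk_image(128, 128, rbind(c(30, 35, 7), c(95, 80, 7)))
  seg2 <- segment(img2, min_size = 50, sigma = 1)
  expect_equal(nrow(seg2$objects), 2)
  cents <- seg2$objects[order(seg2$objects$centroid_x),
                        c("centroid_x", "centroid_y")]
  expect_equal(unlist(cents, use.names = FALSE), c(30, 95, 35, 80),
               tolerance = 0.05)
})

test_that("segment labels match brute-force connected components", {
  set.seed(12)
  for (k in 1:10) {
    img <- disk_image(96, 96,
                      cbind(runif(4, 12, 84), runif(4, 12, 84),
                            runif(4, 3, 6)))
    seg <- segment(img, min_size = 20, sigma = 0, floor_quantile = 0.5,
                   soma_cap = Inf)
    oracle <- oracle_label4(img > max(img) / 2)
    areas_o <- sort(as.integer(table(oracle[oracle > 0])))
    areas_o <- areas_o[areas_o >= 20]
    expect_equal(sort(seg$objects$area_px), areas_o)
    # identical partitions (labels may renumber)
    expect_equal(max(seg$labels), length(areas_o))
  }
})

test_that("oversized components are restricted to their bright core", {
  # a dim 30x30 plateau with a bright 6x6 core
  img <- matrix(0, 80, 80)
  img[20:49, 20:49] <- 100
  img[32:37, 32:37] <- 1000
  seg <- segment(img, min_size = 10, sigma = 0, soma_cap = 200,
                 soma_quantile = 0.9)
  expect_equal(nrow(seg$objects), 1)
  expect_lt(seg$objects$area_px, 200)
  expect_equal(seg$objects$centroid_x, 33.5, tolerance = 1)
})

test_that("feature extraction reports exact means and peaks per channel", {
  img <- matrix(0, 32, 32); img[10:19, 10:19] <- 500
  seg <- segment(img, min_size = 50, sigma = 0)
  gedi <- matrix(2, 32, 32)
  morph <- matrix(0, 32, 32)
  morph[10:19, 10:19] <- matrix(1:100, 10, 10)
  f <- extract_features(seg, list(gedi = gedi, morphology = morph),
                        well = "w", timepoint = 0)
  expect_equal(nrow(f), 1)
  expect_equal(f$mean_gedi, 2)
  expect_equal(f$peak_gedi, 2)
  expect_equal(f$mean_morph, mean(1:100))
  expect_equal(f$peak_morph, 100)
  # 4-pixel worked example
  img4 <- matrix(0, 20, 20); img4[5:6, 5:6] <- 10
  seg4 <- segment(img4, min_size = 2, sigma = 0)
  ch4 <- matrix(0, 20, 20); ch4[5:6, 5:6] <- c(1, 2, 3, 4)
  f4 <- extract_features(seg4, list(gedi = ch4, morphology = img4))
  expect_equal(f4$mean_gedi, 2.5)
  expect_equal(f4$peak_gedi, 4)
  # all-background channel gives mean 0
  f0 <- extract_features(seg4, list(gedi = matrix(0, 20, 20),
                                    morphology = img4))
  expect_equal(f0$mean_gedi, 0)
  expect_error(extract_features(seg4, list(gedi = matrix(0, 5, 5),
                                           morphology = img4)),
               "wrong shape")
})

test_that("feature means ignore constant offsets absorbed by the median", {
  set.seed(6)
  img <- matrix(0, 64, 64); img[20:29, 20:29] <- 800
  noise <- matrix(rnorm(64 * 64, 0, 1), 64, 64)
  a <- subtract_background(pmax(img + 50 + noise, 0))
  b <- subtract_background(pmax(img + 130 + noise, 0))
  sa <- segment(a, min_size = 50, sigma = 1)
  fa <- extract_features(sa, list(gedi = a, morphology = a))
  sb <- segment(b, min_size = 50, sigma = 1)
  fb <- extract_features(sb, list(gedi = b, morphology = b))
  expect_equal(fa$mean_morph, fb$mean_morph, tolerance = 0.02)
})

test_that("masked-area quantification normalizes to the first timepoint", {
  f0 <- matrix(0, 64, 64); f0[10:29, 10:29] <- 1000     # 400 px
  f1 <- matrix(0, 64, 64); f1[10:29, 10:19] <- 1000     # half removed
  expect_equal(quantify_masked_area(list(f0, f0, f0)), c(1, 1, 1))
  expect_equal(quantify_masked_area(list(f0, f1))[2], 0.5)
  # exclusion mask removes a known quadrant
  excl <- matrix(0, 64, 64); excl[10:29, 20:29] <- 1
  expect_equal(quantify_masked_area(list(f0, f1), exclusion_mask = excl),
               c(1, 1))
  expect_error(quantify_masked_area(list(matrix(0, 64, 64), f1)),
               "first timepoint")
})

test_that("ROI ratio divides channel means and guards the denominator", {
  g <- matrix(0, 32, 32); m <- matrix(0, 32, 32)
  roi <- matrix(0, 32, 32); roi[5:14, 5:14] <- 1
  g[5:14, 5:14] <- 30; m[5:14, 5:14] <- 60
  expect_equal(roi_ratio(g, m, roi), 0.5)
  expect_equal(roi_ratio(matrix(0, 32, 32), m, roi), 0)
  expect_error(roi_ratio(g, matrix(0, 32, 32), roi), "not positive")
  expect_error(roi_ratio(g, m, matrix(0, 32, 32)), "empty")
})
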