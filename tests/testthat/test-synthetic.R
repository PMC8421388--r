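test_that("decay traces follow the half-life law exactly at zero noise", {
  tr <- generate_decay_trace(1000, half_life = 7, times = c(0, 7, 14, 21))
  expect_equal(tr$values, c(1000, 500, 250, 125))
  # log-linearity on an arbitrary grid
  tr2 <- generate_decay_trace(123.4, 20.45, times = sort(runif(10, 0, 90)))
  lf <- stats::lm(log2(tr2$values) ~ tr2$times)
  expect_equal(unname(coef(lf)[2]), -1 / 20.45, tolerance = 1e-10)
  expect_error(generate_decay_trace(-5, 10, 0:5), "initial")
  expect_error(generate_decay_trace(5, 0, 0:5), "half_life")
})

test_that("survival cohorts honour censoring, exchangeability and determinism", {
  co0 <- generate_survival_cohort(c(50, 50), 0.01, 1, censor_time = 0, seed = 1)
  expect_true(all(!co0$event))
  expect_true(all(co0$time_h == 0))

  # hazard_ratio = 1: the two groups are exchangeable in distribution
  co1 <- generate_survival_cohort(c(a = 4000, b = 4000), 0.01, 1, 168, seed = 3)
  expect_gt(suppressWarnings(
    ks.test(co1$time_h[co1$group == "a"], co1$time_h[co1$group == "b"])$p.value),
    0.01)

  co2a <- generate_survival_cohort(c(100, 100), 0.02, 2, 100, seed = 9)
  co2b <- generate_survival_cohort(c(100, 100), 0.02, 2, 100, seed = 9)
  expect_identical(co2a, co2b)
  expect_error(generate_survival_cohort(c(10, 10), -1, 2, 100), "baseline_rate")
  expect_error(generate_survival_cohort(c(10, 10), 0.1, c(1, 2), 100),
               "one hazard ratio")
})

test_that("Kaplan-Meier estimate of a generated cohort converges to exp(-rate*t)", {
  co <- generate_survival_cohort(c(one = 5000, two = 2), 0.01, 1, 168, seed = 5)
  km <- km_estimator(co[co$group == "one", ])
  sup <- max(abs(km$survival - exp(-0.01 * km$time)))
  expect_lt(sup, 0.03)
})

test_that("the Cox fitter recovers the generator's hazard ratio", {
  co <- generate_survival_cohort(c(control = 1000, treated = 1000),
                                 baseline_rate = 0.01, hazard_ratio = 2,
                                 censor_time = 168, seed = 11)
  fit <- cox_fit(co, reference_group = "control")
  expect_gt(fit$hr, 1.8)
  expect_lt(fit$hr, 2.2)
})

test_that("well generation covers empty, all-censored and deterministic cases", {
  base <- list(well_spec("E1", "g", 0),
               well_spec("E2", "g", 10, rate = 0),
               well_spec("E3", "g", 10, rate = 0.02))
  cfg <- plate_config(base, timepoints = c(0, 24, 48),
                      image_shape = c(256L, 256L), seed = 21)
  empty <- generate_well(cfg, "E1")
  expect_equal(nrow(empty$truth), 0)
  expect_equal(length(empty$frames), 3 * 2)      # timepoints x channels
  bg <- empty$frames[[1]]$pixels
  expect_lt(abs(mean(bg) - 500), 5)              # background-only

  nodeath <- generate_well(cfg, "E2")
  expect_true(all(nodeath$neurons$censored))
  expect_true(all(!is.finite(nodeath$neurons$death_time)))
  expect_true(all(nodeath$truth$true_gedi_intensity /
                  nodeath$truth$true_morph_intensity < 0.05))

  again <- generate_well(cfg, "E3")
  again2 <- generate_well(cfg, "E3")
  expect_identical(again$frames, again2$frames)
  expect_identical(again$truth, again2$truth)
})

test_that("generated live and dead GEDI-ratio bands are well separated", {
  cfg <- plate_config(list(well_spec("W1", "g", 60, rate = 0.02),
                           well_spec("W2", "g", 60, lethal = TRUE)),
                      image_shape = c(768L, 768L), seed = 33)
  tw <- rbind(generate_well(cfg, "W1")$truth, generate_well(cfg, "W2")$truth)
  ratio <- tw$true_gedi_intensity / tw$true_morph_intensity
  dead <- tw$t >= tw$death_time
  cut <- mean(c(max(0.01, 3 * 0.003 + 0.01), 0.5 - 3 * 0.05))  # between bands
  overlap <- mean(ratio[!dead] > cut) + mean(ratio[dead] < cut)
  expect_lt(overlap, 0.01)
})

test_that("post-death truth intensities decay at the configured half-life", {
  cfg <- plate_config(list(well_spec("L1", "g", 25, lethal = TRUE)),
                      timepoints = seq(0, 72, 12),
                      image_shape = c(512L, 512L),
                      decay_half_life_gedi = 18, decay_half_life_morph = 18,
                      seed = 44)
  tw <- generate_well(cfg, "L1")$truth
  for (id in unique(tw$neuron_id)[1:5]) {
    r <- tw[tw$neuron_id == id, ]
    tr <- fluorescence_trace(r$t + 1e-9, r$true_morph_intensity,
                             baseline_window = 1)
    expect_equal(fit_log_decay(tr)$half_life, 18, tolerance = 1e-6)
  }
})

test_that("neuron packing fails loudly when the well is over-seeded", {
  cfg <- plate_config(list(well_spec("X1", "g", 500)),
                      image_shape = c(128L, 128L), seed = 1)
  expect_error(generate_well(cfg, "X1"), "fewer neurons")
})

test_that("plate writing produces the documented files and counts", {
  cfg <- plate_config(list(well_spec("P1", "g", 5, rate = 0.01),
                           well_spec("P2", "g", 3, lethal = TRUE)),
                      timepoints = c(0, 24), image_shape = c(256L, 256L),
                      seed = 8)
  dir <- withr::local_tempdir()
  pd <- file.path(dir, "plate")
  res <- generate_plate(cfg, pd)
  tifs <- list.files(pd, pattern = "\\.tif$")
  expect_equal(length(tifs), 2 * 2 * 2 * 1)      # wells x tps x channels x tiles
  expect_true(file.exists(file.path(pd, "truth.csv")))
  expect_equal(nrow(unique(res$truth[c("neuron_id")])), 8)
  expect_error(generate_plate(cfg, pd), "overwrite")

  # tiled layout: 2x2 grid quadruples the file count
  cfg2 <- plate_config(list(well_spec("P1", "g", 4, rate = 0.01)),
                       timepoints = c(0, 24), image_shape = c(256L, 256L),
                       tile_grid = list(rows = 2L, cols = 2L, overlap = 32L),
                       seed = 8)
  pd2 <- file.path(dir, "plate2")
  generate_plate(cfg2, pd2)
  expect_equal(length(list.files(pd2, pattern = "\\.tif$")), 1 * 2 * 2 * 4)

  # 16-bit TIFF round-trip preserves integer intensities
  back <- read_plate(pd)
  f1 <- back$frames[[1]]
  expect_true(all(f1$pixels == round(f1$pixels)))
  expect_true(max(f1$pixels) <= 65535)
})
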