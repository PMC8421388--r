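obj_table <- function(...) {
  # rows: list(t, label, x, y)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(well = "w", timepoint_h = r[1], object_label = r[2],
               centroid_x = r[3], centroid_y = r[4])))
}

test_that("a stationary object yields one unbroken track", {
  tab <- do.call(obj_table, lapply(seq(0, 96, 24), function(t) c(t, 1, 50, 60)))
  res <- link_tracks(tab, max_link_dist = 10)
  expect_equal(nrow(res$tracks), 1)
  expect_equal(nrow(res$observations), 5)
  expect_true(is.na(res$tracks$lost_at))
  expect_equal(res$tracks$first_t, 0)
  expect_equal(res$tracks$last_t, 96)
})

test_that("a vanished object is lost at the first missing timepoint", {
  tab <- obj_table(c(0, 1, 50, 60), c(24, 1, 51, 60),
                   c(48, 2, 200, 200), c(72, 2, 200, 200))
  res <- link_tracks(tab, max_link_dist = 10)
  t1 <- res$tracks[res$tracks$first_t == 0, ]
  expect_equal(t1$lost_at, 48)
  t2 <- res$tracks[res$tracks$first_t == 48, ]
  expect_true(is.na(t2$lost_at))
  # one-frame gap tolerance keeps the track alive across a single miss
  tab2 <- obj_table(c(0, 1, 50, 60), c(48, 1, 50, 60), c(72, 1, 50, 60))
  tab2 <- rbind(tab2, obj_table(c(24, 9, 400, 400))) # unrelated object
  res0 <- link_tracks(tab2, max_link_dist = 10, gap_tolerance = 0L)
  expect_equal(sum(res0$tracks$first_t == 0 | res0$tracks$first_t == 48), 2)
  res1 <- link_tracks(tab2, max_link_dist = 10, gap_tolerance = 1L)
  expect_equal(nrow(res1$tracks[res1$tracks$first_t == 0, ]), 1)
  expect_equal(res1$tracks$last_t[res1$tracks$first_t == 0], 72)
})

test_that("ambiguous assignments resolve by smallest distance, matching the oracle", {
  # two objects drift towards each other's previous positions but each stays
  # nearest its own: total-distance-optimal keeps identities
  tab <- obj_table(c(0, 1, 0, 0), c(0, 2, 6, 0),
                   c(24, 1, 2, 0), c(24, 2, 4, 0))
  res <- link_tracks(tab, max_link_dist = 10)
  expect_equal(nrow(res$tracks), 2)
  obs <- res$observations
  path1 <- obs$x[obs$track_id == obs$track_id[obs$timepoint_h == 0 & obs$x == 0]]
  expect_equal(sort(path1), c(0, 2))
  prev <- cbind(c(0, 6), c(0, 0)); cur <- cbind(c(2, 4), c(0, 0))
  expect_equal(oracle_match(prev, cur, 10), c(1L, 2L))
})

test_that("greedy linking agrees with exhaustive matching on small scenes", {
  set.seed(77)
  maxd <- 12
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    # spacing > 2*maxd, displacement < maxd/2: identities are recoverable
    prev <- cbind(x = runif(n, 0, 500), y = runif(n, 0, 500))
    while (n > 1 && min(dist(prev)) < 2 * maxd)
      prev <- cbind(x = runif(n, 0, 500), y = runif(n, 0, 500))
    cur <- prev + matrix(runif(2 * n, -maxd / 3, maxd / 3), n, 2)
    perm <- sample(n)                      # scramble labels at t1
    tab <- rbind(
      do.call(obj_table, lapply(seq_len(n), function(i)
        c(0, i, prev[i, 1], prev[i, 2]))),
      do.call(obj_table, lapply(seq_len(n), function(i)
        c(24, i, cur[perm[i], 1], cur[perm[i], 2]))))
    res <- link_tracks(tab, max_link_dist = maxd)
    expect_equal(nrow(res$tracks), n)
    # greedy assignment equals the exhaustive optimum
    oracle <- oracle_match(prev, cur[perm, , drop = FALSE], maxd)
    obs <- res$observations
    for (j in seq_len(n)) {
      tid <- obs$track_id[obs$timepoint_h == 24 & obs$object_label == j]
      first <- obs[obs$track_id == tid & obs$timepoint_h == 0, ]
      expect_equal(first$x, unname(prev[oracle[j], 1]))
    }
  }
})

test_that("tracking conserves objects and ignores label permutations", {
  set.seed(13)
  n <- 5
  base <- cbind(x = runif(n, 0, 400), y = runif(n, 0, 400))
  while (min(dist(base)) < 60)
    base <- cbind(x = runif(n, 0, 400), y = runif(n, 0, 400))
  tps <- seq(0, 72, 24)
  make_tab <- function(perm_per_t) {
    do.call(rbind, lapply(seq_along(tps), function(ti) {
      pp <- perm_per_t[[ti]]
      do.call(obj_table, lapply(seq_len(n), function(i)
        c(tps[ti], i, base[pp[i], 1] + ti, base[pp[i], 2] - ti)))
    }))
  }
  id_perm <- replicate(length(tps), seq_len(n), simplify = FALSE)
  rand_perm <- lapply(seq_along(tps), function(i) sample(n))
  res_a <- link_tracks(make_tab(id_perm), max_link_dist = 20)
  res_b <- link_tracks(make_tab(rand_perm), max_link_dist = 20)
  # conservation: every object appears in exactly one track
  expect_equal(nrow(res_a$observations), n * length(tps))
  expect_equal(nrow(res_b$observations), n * length(tps))
  expect_false(any(duplicated(
    res_a$observations[c("track_id", "timepoint_h")])))
  # permutation invariance of the centroid paths
  path_set <- function(res) {
    obs <- res$observations[order(res$observations$track_id,
                                  res$observations$timepoint_h), ]
    sort(unname(vapply(split(obs, obs$track_id), function(o)
      paste(round(o$x, 6), round(o$y, 6), collapse = ";"), character(1))))
  }
  expect_equal(path_set(res_a), path_set(res_b))
})

test_that("tracking recovers ground-truth identities on a synthetic well", {
  cfg <- plate_config(list(well_spec("T1", "g", 40, rate = 0.01)),
                      image_shape = c(640L, 640L), jitter_px = 1.5,
                      seed = 55)
  gw <- generate_well(cfg, "T1")
  truth <- gw$truth
  # perfect detections: feed truth positions to the tracker
  tab <- data.frame(well = "T1", timepoint_h = truth$t,
                    object_label = as.integer(factor(truth$neuron_id)),
                    centroid_x = truth$x, centroid_y = truth$y)
  res <- link_tracks(tab, max_link_dist = 24)
  obs <- res$observations
  obs$nid <- truth$neuron_id[match(
    paste(obs$timepoint_h, obs$x, obs$y),
    paste(truth$t, truth$x, truth$y))]
  purity <- vapply(split(obs, obs$track_id),
                   function(o) length(unique(o$nid)), numeric(1))
  expect_true(all(purity == 1))
  expect_equal(length(unique(obs$nid[!is.na(obs$nid)])),
               length(unique(res$observations$track_id)))
})

test_that("reversal artifacts are flagged only when a later timepoint drops back", {
  f <- flag_reversal_artifacts(c(0.01, 0.20, 0.01), c(0, 24, 48), 0.05)
  expect_equal(f$timepoint_h, 24)
  expect_equal(f$reason, "reversal")
  # monotone crossing: clean
  expect_equal(nrow(flag_reversal_artifacts(c(0.01, 0.02, 0.2, 0.4),
                                            c(0, 24, 48, 72), 0.05)), 0)
  # above threshold only at the last observation: no later evidence
  expect_equal(nrow(flag_reversal_artifacts(c(0.01, 0.02, 0.2),
                                            c(0, 24, 48), 0.05)), 0)
  # double reversal flags both excursions
  f2 <- flag_reversal_artifacts(c(0.2, 0.01, 0.3, 0.01), c(0, 24, 48, 72), 0.05)
  expect_equal(f2$timepoint_h, c(0, 48))
  # table interface
  rec <- data.frame(track_id = c(1, 1, 1, 2, 2),
                    timepoint_h = c(0, 24, 48, 0, 24),
                    gedi_ratio = c(0.01, 0.2, 0.01, 0.01, 0.02))
  fr <- flag_track_reversals(rec, 0.05)
  expect_equal(fr$track_id, 1)
  expect_equal(fr$timepoint_h, 24)
})
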