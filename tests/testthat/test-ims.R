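test_that("merge segmentation keeps alternating extrema and flags monotone input", {
  tp <- ims_segment(ppg_ts(c(0, 2, 0, 2, 0), 1), m = 1)
  expect_equal(tp$maxima$values, c(2, 2))
  expect_equal(tp$minima$values, c(0, 0, 0))
  expect_equal(tp$maxima$times, c(1, 3))
  expect_equal(tp$minima$times, c(0, 2, 4))

  ramp <- ims_segment(ppg_ts(0:4, 1), m = 1)
  expect_true(ramp$no_pulses)
  expect_length(ramp$maxima, 0)

  sn <- sine_ts(1.2, 10, 25)
  tp2 <- ims_segment(sn, m = 1)
  expect_true(abs(length(tp2$maxima) - 12) <= 1)
})

test_that("no same-sign slope triplet survives the merge (exhaustive oracle)", {
  set.seed(7)
  for (i in 1:40) {
    x <- cumsum(rnorm(120))
    tp <- ims_segment(ppg_ts(x, 10), m = sample(1:3, 1),
                      min_prominence = 0, refine = FALSE)
    il <- tp_interleaved(tp)
    expect_false(has_same_sign_triplet(il$times, il$values))
    # maxima and minima strictly alternate
    if (length(il$is_max) > 1)
      expect_true(all(diff(il$is_max) != 0))
  }
})

test_that("ripple pruning keeps one turning point pair per pulse", {
  # pulse train with a small dicrotic wiggle on each decay
  t <- seq(0, 10, by = 1 / 50)
  x <- sin(2 * pi * 1 * t) + 0.05 * sin(2 * pi * 7 * t)
  tp_raw <- ims_segment(ppg_ts(x, 50), min_prominence = 0)
  tp_pruned <- ims_segment(ppg_ts(x, 50), min_prominence = 0.3)
  expect_gt(length(tp_raw$maxima), length(tp_pruned$maxima))
  expect_true(abs(length(tp_pruned$maxima) - 10) <= 1)
})

test_that("RIIV of a constant envelope is flat; modulated envelope recovers its frequency", {
  beats <- seq(0.5, 39.5, by = 0.8)
  const <- structure(list(maxima = event_series(beats, rep(1, length(beats))),
                          minima = event_series(beats - 0.3,
                                                rep(0, length(beats))),
                          no_pulses = FALSE), class = "turning_points")
  expect_lt(max(abs(extract_riiv(const)$values)), 1e-8)

  env <- 1 + 0.2 * sin(2 * pi * 0.25 * beats)
  mod <- structure(list(maxima = event_series(beats, env),
                        minima = event_series(beats - 0.3,
                                              rep(0, length(beats))),
                        no_pulses = FALSE), class = "turning_points")
  riiv <- extract_riiv(mod)
  expect_lt(abs(dominant_freq(riiv, 0.05, 1) - 0.25), 0.02)

  few <- structure(list(maxima = event_series(1:3, rep(1, 3)),
                        minima = event_series(0.5 + 0:2, rep(0, 3)),
                        no_pulses = FALSE), class = "turning_points")
  expect_error(extract_riiv(few), "insufficient")
})

test_that("RIAV pairs each peak with the preceding trough", {
  beats <- seq(0.5, 39.5, by = 0.8)
  amp <- 1 + 0.3 * sin(2 * pi * 0.2 * beats)
  tp <- structure(list(maxima = event_series(beats, amp),
                       minima = event_series(beats - 0.3,
                                             rep(0, length(beats))),
                       no_pulses = FALSE), class = "turning_points")
  riav <- extract_riav(tp)
  expect_lt(abs(dominant_freq(riav, 0.05, 1) - 0.2), 0.02)

  flat <- structure(list(maxima = event_series(beats, rep(1, length(beats))),
                         minima = event_series(beats - 0.3,
                                               rep(0.2, length(beats))),
                         no_pulses = FALSE), class = "turning_points")
  expect_lt(max(abs(extract_riav(flat)$values)), 1e-8)
})

test_that("RIFV tachogram recovers rate modulation from beat times", {
  # integrate an instantaneous rate 1.2*(1 + 0.05 sin(2 pi 0.25 t)) Hz
  tf <- seq(0, 60, by = 1e-3)
  rate <- 1.2 * (1 + 0.05 * sin(2 * pi * 0.25 * tf))
  phase <- cumsum(rate) * 1e-3
  beat_t <- approx(phase, tf, xout = seq_len(floor(max(phase))))$y
  tp <- structure(list(maxima = event_series(beat_t + 0.3,
                                             rep(1, length(beat_t))),
                       minima = event_series(beat_t, rep(0, length(beat_t))),
                       no_pulses = FALSE), class = "turning_points")
  rifv <- extract_rifv(tp)
  expect_lt(abs(dominant_freq(rifv, 0.05, 0.6) - 0.25), 0.02)
  # same result from the systolic-peak landmark
  rifv_pk <- extract_rifv(tp, landmark = "maxima", differentiate = FALSE)
  expect_lt(abs(dominant_freq(rifv_pk, 0.05, 0.6) - 0.25), 0.02)

  # perfectly periodic pulses give a flat tachogram
  per <- seq(0, 40, by = 0.8)
  tpp <- structure(list(maxima = event_series(per + 0.3,
                                              rep(1, length(per))),
                        minima = event_series(per, rep(0, length(per))),
                        no_pulses = FALSE), class = "turning_points")
  expect_lt(max(abs(extract_rifv(tpp)$values)), 1e-6)

  few <- structure(list(maxima = event_series(1:4, rep(1, 4)),
                        minima = event_series(0.5 + 0:3, rep(0, 4)),
                        no_pulses = FALSE), class = "turning_points")
  expect_error(extract_rifv(few), "insufficient")
})

test_that("fusion arithmetic, permutation invariance and PCA of a rank-1 ensemble", {
  expect_equal(fuse_rivs(rr_per_riv = c(12, 15, 18), mode = "avg"), 15)
  expect_equal(fuse_rivs(rr_per_riv = c(12, 15, 18), mode = "median"), 15)
  expect_equal(fuse_rivs(rr_per_riv = c(12, 13, 20), mode = "avg"), 15)
  expect_equal(fuse_rivs(rr_per_riv = c(12, 13, 20), mode = "median"), 13)
  for (p in list(c(2, 1, 3), c(3, 2, 1))) {
    x <- c(12, 13, 20)
    expect_equal(fuse_rivs(rr_per_riv = x[p], mode = "avg"),
                 fuse_rivs(rr_per_riv = x, mode = "avg"))
    expect_equal(fuse_rivs(rr_per_riv = x[p], mode = "median"),
                 fuse_rivs(rr_per_riv = x, mode = "median"))
  }
  expect_error(fuse_rivs(rr_per_riv = c(12, NA, 15), mode = "avg"),
               "missing")

  common <- sine_ts(0.25, 30, 8)
  rivs <- structure(list(riiv = common, riav = common, rifv = common,
                         turning_points = NULL), class = "riv_set")
  fused <- fuse_rivs(rivs = rivs, mode = "pca")
  expect_gt(attr(fused, "explained"), 0.999)
  expect_gt(cor(fused$values,
                common$values[seq_along(fused$values)]), 0.999)
})
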