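test_that("segmentation produces the expected window grid", {
  ts <- ppg_ts(seq_len(100), 10)
  w <- segment_signal(ts, M = 100, K = 50)
  expect_length(w, 1)
  expect_identical(attr(w[[1]], "start"), 0L)

  ts10 <- ppg_ts(seq_len(10), 1)
  w4 <- segment_signal(ts10, M = 4, K = 2)
  expect_length(w4, 4)
  expect_equal(vapply(w4, attr, integer(1), "start"), c(0L, 2L, 4L, 6L))
  expect_equal(w4[[3]]$values, 5:8)

  # K = M tiles without overlap and concatenation restores the prefix
  w_tile <- segment_signal(ts10, M = 3, K = 3)
  expect_equal(unlist(lapply(w_tile, `[[`, "values")), as.numeric(1:9))

  expect_error(segment_signal(ts10, M = 11, K = 1), "longer than signal")
  expect_error(segment_signal(ts10, M = 4, K = 0), "invalid shift")
})

test_that("band-pass keeps the passband and rejects the stopband", {
  in_band <- sine_ts(0.5, 120, 8)
  out <- bandpass(in_band, 0.18, 1.0, order = 4)
  core <- 200:760  # interior, away from edge transients
  expect_lt(abs(1 - sd(out$values[core]) / sd(in_band$values[core])), 0.05)

  slow <- sine_ts(0.05, 240, 8)
  att <- bandpass(slow, 0.18, 1.0, order = 4)
  core2 <- 500:1400
  db <- 20 * log10(sd(att$values[core2]) / sd(slow$values[core2]))
  expect_lt(db, -20)

  zeros <- ppg_ts(rep(0, 100), 8)
  expect_equal(bandpass(zeros, 0.18, 1.0)$values, rep(0, 100))
  expect_error(bandpass(slow, 0.18, 5, order = 4), "invalid band")
})

test_that("range normalization maps endpoints to [-1, 1]", {
  expect_equal(normalize_range(ppg_ts(c(0, 5, 10), 1))$values, c(-1, 0, 1))
  expect_equal(normalize_range(ppg_ts(c(-2, 0, 2), 1))$values, c(-1, 0, 1))
  expect_equal(normalize_range(ppg_ts(c(1, 2, 4), 1))$values,
               c(-1, -1 / 3, 1))
  expect_error(normalize_range(ppg_ts(rep(3, 5), 1)), "degenerate")
})

test_that("artifact reduction is the spline derivative on a grid", {
  const <- event_series(0:9, rep(2, 10))
  expect_equal(max(abs(artifact_reduce(const)$values)), 0, tolerance = 1e-9)

  ramp <- event_series(0:9, 3 * (0:9))
  d <- artifact_reduce(ramp)
  interior <- 9:(length(d$values) - 8)
  expect_equal(d$values[interior], rep(3, length(interior)),
               tolerance = 1e-6)

  f <- 0.2
  tt <- seq(0, 20, by = 1 / (20 * f))   # 20 points per cycle
  sn <- event_series(tt, sin(2 * pi * f * tt))
  d2 <- artifact_reduce(sn, out_fs = 8)
  g <- ts_time(d2, t0 = tt[1])
  interior <- g > 1 & g < 19
  err <- d2$values[interior] - 2 * pi * f * cos(2 * pi * f * g[interior])
  expect_lt(sqrt(mean(err^2)) / (2 * pi * f), 0.02)

  expect_error(artifact_reduce(event_series(0:2, 1:3)), "insufficient")
})

test_that("spline-derivative operator is linear", {
  set.seed(42)
  tt <- sort(runif(30, 0, 10))
  x <- rnorm(30); y <- rnorm(30)
  a <- 2.5; b <- -1.3
  lhs <- artifact_reduce(event_series(tt, a * x + b * y), out_fs = 8)
  px <- artifact_reduce(event_series(tt, x), out_fs = 8)
  py <- artifact_reduce(event_series(tt, y), out_fs = 8)
  expect_equal(lhs$values, a * px$values + b * py$values,
               tolerance = 1e-8)
})

test_that("series round-trip through csv and rds preserves content", {
  ts <- ppg_ts(sin(1:100), 25, "roundtrip")
  csv <- tempfile(fileext = ".csv")
  write_series(ts, csv)
  back <- read_series(csv)
  expect_equal(back$values, ts$values)
  expect_equal(back$fs, ts$fs, tolerance = 1e-6)

  rds <- tempfile(fileext = ".rds")
  write_series(ts, rds)
  expect_equal(read_series(rds)$values, ts$values)

  # header line tolerated; jittered time column refused
  jit <- tempfile(fileext = ".csv")
  set.seed(1)
  writeLines(c("time_s,value",
               paste((0:49) / 10 + c(0, runif(49, 0, 0.03)),
                     rnorm(50), sep = ",")), jit)
  expect_error(read_series(jit), "resample")
})
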