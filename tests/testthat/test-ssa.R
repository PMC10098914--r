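test_that("embedding builds the Hankel trajectory matrix", {
  X <- ssa_embed(c(1, 2, 3, 4), L = 2)
  expect_equal(X, rbind(c(1, 2, 3), c(2, 3, 4)))

  x <- c(5, 1, 4, 2)
  expect_equal(as.vector(ssa_embed(x, L = 4)), x)  # single column

  set.seed(5)
  y <- rnorm(30)
  Xy <- ssa_embed(y, L = 7)
  for (s in 2:(7 + 24 - 1)) {
    vals <- Xy[row(Xy) + col(Xy) == s + 1]
    expect_lt(diff(range(vals)), 1e-15)
  }
  expect_error(ssa_embed(y, L = 1), "invalid embedding")
  expect_error(ssa_embed(y, L = 31), "invalid embedding")
})

test_that("SVD splits the trajectory into rank-1 matrices that sum back", {
  X <- ssa_embed(rep(3, 20), L = 5)
  dec <- ssa_decompose(X)
  expect_equal(sum(dec$singular_values > 1e-10), 1)

  sn <- sine_ts(1, 8, 25)   # 8 periods
  Xs <- ssa_embed(sn, L = 17)
  ds <- ssa_decompose(Xs)
  lam2 <- ds$singular_values^2
  expect_gt(sum(lam2[1:2]) / sum(lam2), 0.99)
  expect_true(all(diff(ds$singular_values) <= 1e-12))

  total <- Reduce(`+`, lapply(seq_len(ds$d), elementary_matrix,
                              dec = ds))
  expect_lt(max(abs(total - Xs)), 1e-8)
})

test_that("diagonal averaging matches the brute-force oracle", {
  expect_equal(hankelize(rbind(c(1, 3), c(5, 7))), c(1, 4, 7))

  set.seed(9)
  for (i in 1:50) {
    L <- sample(2:8, 1); K <- sample(2:9, 1)
    Xi <- matrix(rnorm(L * K), L, K)
    expect_equal(hankelize(Xi), hankelize_bruteforce(Xi),
                 tolerance = 1e-12)
  }

  # hankelize(embed(x)) is the identity
  x <- rnorm(40)
  expect_equal(hankelize(ssa_embed(x, L = 11)), x, tolerance = 1e-12)
})

test_that("components sum to the window and order by energy", {
  set.seed(21)
  for (i in 1:20) {
    w <- ppg_ts(rnorm(80), 25)
    res <- ssa_components(w, L = 17)
    total <- Reduce(`+`, lapply(res$components, `[[`, "values"))
    expect_lt(max(abs(total - w$values)), 1e-8)
    expect_true(all(res$singular_values >= 0))
    expect_true(all(diff(res$singular_values) <= 1e-12))
  }

  sn <- sine_ts(1, 8, 25)
  res <- ssa_components(sn, L = 17)
  z12 <- res$components[[1]]$values + res$components[[2]]$values
  expect_gt(cor(z12, sn$values), 0.999)
  rms <- vapply(res$components[1:4], function(z) sd(z$values), numeric(1))
  expect_true(all(diff(rms[1:2]) <= 1e-8 | rms[1] >= rms[2]))
})

test_that("SSA estimate applies band masking then max power", {
  mk <- function(f, amp) sine_ts(f, 60, 8, amp = amp)
  res <- structure(list(
    singular_values = c(3, 2, 1),
    eofs = NULL,
    components = list(mk(0.9, 5), mk(0.3, 2), mk(0.45, 0.5)),
    n_keep = 3L, fs = 8), class = "ssa_result")
  tab <- rr_from_ssa(res, freq_band(0.1, 0.5), postprocess = FALSE)
  # 0.9 Hz component is outside the band; 0.3 Hz wins on power
  expect_equal(tab$rr_bpm[tab$estimator == "RR_SSA"], 18,
               tolerance = 0.05)

  res2 <- structure(list(
    singular_values = c(2, 1, 0.5), eofs = NULL,
    components = list(mk(0.25, 3), mk(0.25, 1), mk(0.25, 0.5)),
    n_keep = 3L, fs = 8), class = "ssa_result")
  tab2 <- rr_from_ssa(res2, freq_band(0.1, 0.5), postprocess = FALSE)
  expect_equal(tab2$rr_bpm[tab2$estimator == "RR_SSA"], 15,
               tolerance = 0.05)

  flat <- structure(list(
    singular_values = c(0, 0, 0), eofs = NULL,
    components = list(ppg_ts(rep(0, 480), 8), ppg_ts(rep(0, 480), 8),
                      ppg_ts(rep(0, 480), 8)),
    n_keep = 3L, fs = 8), class = "ssa_result")
  tab3 <- rr_from_ssa(flat, freq_band(0.1, 0.5), postprocess = FALSE)
  rrssa <- tab3[tab3$estimator == "RR_SSA", ]
  expect_true(is.na(rrssa$rr_bpm) || rrssa$peak_power == 0)
})
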