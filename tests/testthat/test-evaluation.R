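test_that("error metrics follow their definitions and MAE <= RMSE", {
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 5)), sqrt(5 / 3))
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(rmse(1:5, 1:5), 0)

  set.seed(17)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    a <- rnorm(n, sd = runif(1, 0.1, 10))
    b <- rnorm(n, sd = runif(1, 0.1, 10))
    expect_lte(mae(a, b), rmse(a, b) + 1e-12)
  }
})

test_that("Bland-Altman bias, limits and proportional-bias slope", {
  h <- runif(50, 10, 30)
  perfect <- bland_altman(h, h)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$loa_hi - perfect$loa_lo, 0)

  offset <- bland_altman(h + 2, h)
  expect_equal(offset$bias, 2)
  expect_equal(offset$loa_hi - offset$loa_lo, 0, tolerance = 1e-12)

  # bias is exactly the difference of means
  set.seed(23)
  est <- rnorm(40, 20, 3); ref <- rnorm(40, 18, 3)
  ba <- bland_altman(est, ref)
  expect_equal(ba$bias, mean(est) - mean(ref))
  expect_lte(ba$loa_lo, ba$bias); expect_gte(ba$loa_hi, ba$bias)

  # proportional bias: est = 1.5 * ref shows a significant positive slope
  set.seed(0)
  ref2 <- runif(200, 10, 30)
  ba2 <- bland_altman(1.5 * ref2 + rnorm(200, 0, 0.5), ref2)
  expect_gt(ba2$trend_slope, 0)
  expect_lt(ba2$trend_p, 0.05)
})

test_that("normality gate flags non-normal and degenerate populations", {
  set.seed(0)
  normals <- matrix(rnorm(600), ncol = 3)
  g1 <- normality_gate(normals)
  expect_true(all(g1$shapiro_p > 0.001, na.rm = TRUE))

  withexp <- cbind(normals, rexp(200))
  g2 <- normality_gate(withexp)
  expect_true(g2$nonparametric)

  withconst <- cbind(normals, rep(1, 200))
  g3 <- normality_gate(withconst)
  expect_true(g3$degenerate[4])
  expect_true(g3$nonparametric)
})

test_that("Friedman/Nemenyi ranks, null behaviour and power", {
  same <- matrix(rep(1:20, 4), ncol = 4)
  rc <- friedman_nemenyi(same)
  expect_equal(unname(rc$friedman_stat), 0)
  expect_gte(rc$friedman_p, 0.99)

  # per-row ranks always sum to k(k+1)/2
  set.seed(3)
  m <- matrix(rnorm(15 * 6), ncol = 6)
  rc2 <- friedman_nemenyi(m)
  expect_equal(sum(rc2$avg_ranks), 6 * 7 / 2)
  expect_true(all(rc2$nemenyi_p >= 0 & rc2$nemenyi_p <= 1))

  # a clearly worse column is isolated by the post hoc test
  set.seed(4)
  pop <- matrix(rnorm(50 * 4, sd = 1), ncol = 4)
  pop[, 2] <- pop[, 2] + 3
  colnames(pop) <- paste0("e", 1:4)
  rc3 <- friedman_nemenyi(pop)
  expect_lt(rc3$friedman_p, 0.01)
  expect_true(all(rc3$nemenyi_p["e2", c("e1", "e3", "e4")] < 0.05))
  expect_gt(min(rc3$nemenyi_p["e1", c("e3", "e4")]), 0.05)

  expect_error(friedman_nemenyi(m[, 1:2]), "3 estimators")
})

test_that("robust effect size and magnitude labelling", {
  set.seed(6)
  a <- rnorm(100)
  g0 <- akinshin_gamma(a, a)
  expect_equal(g0$gamma, 0)
  expect_equal(g0$magnitude, "negligible")

  set.seed(0)
  a2 <- rnorm(500)
  g1 <- akinshin_gamma(a2, a2 + 1)
  expect_lt(abs(g1$gamma - 1), 0.15)
  expect_equal(g1$magnitude, "large")

  const <- rep(2, 20)
  expect_true(is.na(akinshin_gamma(const, const)$gamma))

  # labels around the 0.5 threshold
  expect_equal(gamma_magnitude(-0.493), "small")
  expect_equal(gamma_magnitude(-0.571), "medium")
  expect_equal(gamma_magnitude(c(0.1, -0.3, 0.79, -2)),
               c("negligible", "small", "medium", "large"))
})

test_that("bootstrap median CI brackets the sample median", {
  expect_equal(median_ci(1:5)$median, 3)

  cc <- median_ci(rep(4, 30))
  expect_equal(c(cc$ci_lo, cc$ci_hi), c(4, 4))

  set.seed(0)
  s <- rexp(200)
  ci <- median_ci(s, seed = 42)
  expect_lte(ci$ci_lo, ci$median)
  expect_gte(ci$ci_hi, ci$median)
  # seeded: reproducible
  ci2 <- median_ci(s, seed = 42)
  expect_equal(ci, ci2)
})

test_that("evaluation table ranks a visibly better estimator first", {
  set.seed(12)
  ref <- runif(60, 10, 30)
  est <- cbind(good = ref + rnorm(60, 0, 0.5),
               fair = ref + rnorm(60, 1, 2),
               poor = ref + rnorm(60, 4, 5))
  ev <- evaluate_estimators(est, ref)
  expect_equal(ev$table$estimator[1], "good")
  expect_equal(ev$table$gamma[1], 0)
  expect_true(all(diff(ev$table$rank) >= 0))
  expect_true(ev$gate$nonparametric %in% c(TRUE, FALSE))
})
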