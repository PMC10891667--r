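test_that("Bland-Altman reproduces hand-computed and closed-form values", {
  x <- c(1, 2, 3)
  ba0 <- bland_altman(x, x)
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$loa_low, 0)
  expect_identical(ba0$loa_high, 0)
  # diffs {-1, 0, 1}: bias 0, sd 1, LoA +/- 1.96
  ba1 <- bland_altman(c(10, 10, 10), c(9, 10, 11))
  expect_equal(ba1$bias, 0)
  expect_equal(ba1$sd_diff, 1)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(-1.96, 1.96))
  # large-sample normal-theory values
  set.seed(SUITE_SEED)
  fps <- rnorm(5000, 1, 0.2)
  mls <- fps + rnorm(5000, 0.10, 0.05)
  ba2 <- bland_altman(fps, mls)
  expect_true(ba2$bias > 0.098 && ba2$bias < 0.102)
  expect_lt(abs(ba2$loa_low - 0.002), 0.004)
  expect_lt(abs(ba2$loa_high - 0.198), 0.004)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "length")
  expect_error(bland_altman(1:4, 1:3), "mismatch")
})

test_that("relative fields are flagged undefined when a pair mean is zero", {
  ba <- bland_altman(c(-1, 2, 3), c(1, 2.2, 3.1))
  expect_true(ba$rel_undefined)
  expect_true(is.na(ba$rel_bias))
  expect_error(reliability_verdict(ba), "undefined")
})

test_that("LoA coverage converges to 95% on normal differences", {
  set.seed(SUITE_SEED)
  fps <- rnorm(1e4)
  mls <- fps + rnorm(1e4, 0.05, 0.3)
  ba <- bland_altman(fps, mls)
  inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
})

test_that("Shapiro-Wilk wrapper is calibrated and powered", {
  set.seed(SUITE_SEED)
  p_norm <- replicate(20, shapiro_normality(rnorm(500))$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- replicate(5, shapiro_normality(rexp(500))$p)
  expect_true(all(p_exp < 0.01))
  expect_error(shapiro_normality(c(1, 2)), "length")
  expect_error(shapiro_normality(rep(1, 10)), "constant")
  expect_error(shapiro_normality(rnorm(5001)), "5000")
})

test_that("reliability verdict applies a strict 10% rule", {
  mk_ba <- function(lo, hi) {
    structure(list(rel_loa_low = lo, rel_loa_high = hi, rel_undefined = FALSE),
              class = "gi_bland_altman")
  }
  expect_true(reliability_verdict(mk_ba(-8, 9))$reliable)
  v <- reliability_verdict(mk_ba(-25, 20))
  expect_false(v$reliable)
  expect_equal(v$worst_rel_limit_pct, 25)
  expect_false(reliability_verdict(mk_ba(-10, 10))$reliable)
  expect_true(reliability_verdict(mk_ba(-9.99, 9.99))$reliable)
})

test_that("JZS quadrature matches the brute-force Riemann oracle", {
  set.seed(SUITE_SEED)
  suppressWarnings(
    for (i in 1:20) {
      n <- sample(5:100, 1)
      r <- runif(1, 0.2, 1.6)
      fps <- rnorm(n, 1, 0.5)
      mls <- fps + rnorm(n, runif(1, -0.15, 0.15), runif(1, 0.1, 0.4))
      res <- jzs_bf01_paired(fps, mls, r = r, robustness = FALSE)
      oracle <- bf10_oracle(res$t, n, r)
      expect_lt(abs(res$bf10 - oracle) / oracle, 1e-4)
      expect_equal(res$bf01 * res$bf10, 1, tolerance = 1e-15)
    }
  )
})

test_that("null differences at moderate n yield evidence for H0", {
  set.seed(SUITE_SEED)
  fps <- rnorm(60, 1, 0.3)
  mls <- fps + rnorm(60, 0, 0.01)
  res <- jzs_bf01_paired(fps, mls, robustness = FALSE)
  expect_gt(res$bf01, 3)
  expect_match(res$evidence_label, "H0")
})

test_that("robustness curve is positive, smooth and carries the three marks", {
  set.seed(SUITE_SEED)
  fps <- rnorm(30); mls <- fps + rnorm(30, 0, 0.2)
  res <- jzs_bf01_paired(fps, mls)
  rc <- res$robustness
  expect_true(all(is.finite(rc$bf01) & rc$bf01 > 0))
  expect_true(all(c(0.707, 1) %in% rc$r))
  expect_true(any(abs(rc$r - sqrt(2)) < 1e-12))
  expect_gte(nrow(rc), 30)
  # smooth: no sign flips in the first difference beyond one extremum
  d <- diff(log(rc$bf01))
  expect_lte(sum(diff(sign(d)) != 0), 1)
  # the default-scale point on the curve equals the headline value
  expect_equal(rc$bf01[rc$r == 0.707], res$bf01, tolerance = 1e-10)
})

test_that("Bayes factor behaves consistently as evidence accumulates", {
  # true null: median BF01 non-decreasing in n; true effect 0.5 sd: BF01 -> 0
  set.seed(SUITE_SEED)
  med_null <- sapply(c(20, 80, 320), function(n) {
    stats::median(replicate(11, {
      d <- rnorm(n)
      1 / gaitinit:::jzs_bf10(mean(d) / (sd(d) / sqrt(n)), n, 0.707)
    }))
  })
  expect_true(all(diff(med_null) > 0))
  med_eff <- sapply(c(20, 80, 320), function(n) {
    stats::median(replicate(11, {
      d <- rnorm(n, 0.5, 1)
      1 / gaitinit:::jzs_bf10(mean(d) / (sd(d) / sqrt(n)), n, 0.707)
    }))
  })
  expect_true(all(diff(med_eff) < 0))
  expect_lt(med_eff[3], 1e-6)
})

test_that("degenerate Bayes-factor inputs error", {
  expect_error(jzs_bf01_paired(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  expect_error(jzs_bf01_paired(1:10, 1:9), "mismatch")
})
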