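test_that("polynomial fits recover exact and noisy coefficients", {
  a <- withr::with_seed(1, runif(120, 6, 30))
  # constant data
  f0 <- fit_trajectory(a, rep(3, 120), 1)
  expect_equal(unname(coef(f0)), c(3, 0), tolerance = 1e-12)
  # exact linear recovery
  f1 <- fit_trajectory(a, 4 - 0.02 * a, 1)
  expect_equal(f1$shape, -0.02, tolerance = 1e-12)
  expect_equal(unname(coef(f1)[1]), 4, tolerance = 1e-10)
  # noisy quadratic vs an independent pseudoinverse oracle
  a2 <- withr::with_seed(2, runif(300, 6, 30))
  y2 <- 3.2 - 0.04 * a2 + 0.001 * a2^2 + withr::with_seed(3, rnorm(300, 0, 0.1))
  f2 <- fit_trajectory(a2, y2, 2)
  expect_equal(unname(coef(f2)), pinv_poly_fit(a2, y2, 2), tolerance = 1e-8)
  expect_equal(f2$shape, unname(coef(f2)[3]))
  # cubic against the oracle too
  f3 <- fit_trajectory(a2, y2, 3)
  expect_equal(unname(coef(f3)), pinv_poly_fit(a2, y2, 3), tolerance = 1e-8)

  expect_error(fit_trajectory(rep(10, 20), rnorm(20), 1), "singular")
  expect_error(fit_trajectory(a[1:3], (4 - a)[1:3], 2), "observations")
})

test_that("the shape coefficient ignores constant thickness shifts", {
  a <- withr::with_seed(4, runif(80, 6, 30))
  y <- 3 - 0.03 * a + withr::with_seed(5, rnorm(80, 0, 0.05))
  for (d in 1:3) {
    f <- fit_trajectory(a, y, d)
    g <- fit_trajectory(a, y + 0.7, d)
    expect_equal(g$shape, f$shape, tolerance = 1e-10)
    expect_equal(unname(coef(g)[1] - coef(f)[1]), 0.7, tolerance = 1e-8)
  }
})

test_that("deviance test is calibrated under the null and powerful under signal", {
  # null: pure noise, p-values uniform
  ps <- withr::with_seed(6, vapply(1:500, function(i) {
    a <- runif(200, 6, 30)
    as.numeric(deviance_test(fit_trajectory(a, rnorm(200, 3, 0.1), 2)))
  }, numeric(1)))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  # strong linear trend: slope 10x the noise SD per year
  a <- withr::with_seed(7, runif(200, 6, 30))
  y <- 3 - 1 * a + withr::with_seed(8, rnorm(200, 0, 0.1))
  expect_lt(as.numeric(deviance_test(fit_trajectory(a, y, 1))), 1e-6)

  # data identical to its own mean: statistic 0, p = 1
  f <- fit_trajectory(a, rep(2.5, 200), 1)
  p <- deviance_test(f)
  expect_equal(attr(p, "statistic"), 0)
  expect_equal(as.numeric(p), 1)

  # perfect non-constant fit: p = 0 with the degeneracy flag
  pz <- deviance_test(fit_trajectory(a, 4 - 0.1 * a, 1))
  expect_equal(as.numeric(pz), 0)
  expect_true(attr(pz, "degenerate"))
})

test_that("FDR masking matches hand-coded Benjamini-Hochberg", {
  # worked example: all four pass since p(4) = 0.04 <= 4 * 0.05 / 4
  m <- fdr_mask(c(r1 = 0.01, r2 = 0.02, r3 = 0.03, r4 = 0.04), q = 0.05)
  expect_true(all(m))
  expect_false(any(fdr_mask(rep(1, 6))))

  # rule semantics: significant in TD only
  p2 <- cbind(ASD = c(0.5, 0.001), TD = c(0.001, 0.001))
  expect_equal(as.logical(fdr_mask(p2, rule = "both_groups")), c(FALSE, TRUE))
  expect_equal(as.logical(fdr_mask(p2, rule = "any_group")), c(TRUE, TRUE))

  # oracle sweep: 1,000 random p-vectors
  withr::with_seed(9, {
    for (i in 1:1000) {
      m <- sample(1:40, 1)
      p <- runif(m)^sample(1:3, 1)
      q <- runif(1, 0.01, 0.2)
      expect_identical(as.logical(fdr_mask(p, q = q)), bh_reject(p, q))
    }
  })
})

test_that("turning point of a negative-curvature quadratic is the midpoint", {
  a <- withr::with_seed(10, runif(100, 6, 30))
  f <- fit_trajectory(a, 2.5 + 0.05 * a - 0.001 * a^2, 2)
  tp <- turning_point(f)
  expect_equal(tp, 18, tolerance = 1e-9)

  # grid-search oracle at 0.001-yr resolution
  b <- coef(f)
  grid <- seq(6, 30, by = 0.001)
  fx <- b[1] + b[2] * grid + b[3] * grid^2
  chord <- fx[1] + (fx[length(grid)] - fx[1]) * (grid - 6) / 24
  expect_equal(grid[which.max(fx - chord)], tp, tolerance = 0.001)

  # midpoint for every admissible fit, and hence for any ROI average
  tps <- withr::with_seed(11, vapply(1:50, function(i) {
    f <- fit_trajectory(a, 3 + runif(1, -0.1, 0.1) * a -
                          runif(1, 1e-4, 5e-3) * a^2 + rnorm(100, 0, 0.05), 2)
    if (f$coefficients[3] >= 0) return(NA_real_)
    turning_point(f)
  }, numeric(1)))
  expect_true(all(abs(tps - 18) < 1e-9, na.rm = TRUE))
  expect_equal(mean(tps, na.rm = TRUE), 18, tolerance = 1e-9)

  fpos <- fit_trajectory(a, 2.5 - 0.05 * a + 0.001 * a^2, 2)
  expect_error(turning_point(fpos), "negative curvature")
  expect_error(turning_point(fit_trajectory(a, 3 - 0.02 * a, 1)), "quadratic")
})
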