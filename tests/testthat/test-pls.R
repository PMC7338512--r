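test_that("two-group mean-centered PLS matches its closed form and an SVD oracle", {
  withr::with_seed(31, {
    X <- matrix(rnorm(24), 6, 4)
    g <- factor(rep(c("ASD", "TD"), each = 3), levels = c("ASD", "TD"))
    res <- mean_centered_pls(X, g, n_perm = 0, n_boot = 0)
    d <- colMeans(X[1:3, ]) - colMeans(X[4:6, ])
    # brain saliences proportional to the mean difference, oriented ASD > TD
    expect_equal(res$brain_saliences[, 1], d / sqrt(sum(d^2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(res$design_saliences[, 1], c(ASD = 1, TD = -1) / sqrt(2),
                 tolerance = 1e-10)
    expect_equal(res$singular_values[1], sqrt(sum(d^2) / 2),
                 tolerance = 1e-10)
    # rank-1: exactly one nonzero singular value
    expect_lt(res$singular_values[2], 1e-12)
    # brute-force SVD oracle on the mean-deviation matrix
    M <- rbind(colMeans(X[1:3, ]), colMeans(X[4:6, ]))
    D <- sweep(M, 2, colMeans(M))
    expect_equal(res$singular_values[1], svd(D)$d[1], tolerance = 1e-12)

    # identical group means: zero contrast
    X0 <- rbind(X[1:3, ], X[1:3, ])
    res0 <- mean_centered_pls(X0, g, n_perm = 0, n_boot = 0)
    expect_lt(res0$singular_values[1], 1e-12)
  })
})

test_that("singular-value energy is invariant under feature permutation", {
  withr::with_seed(32, {
    X <- matrix(rnorm(120), 20, 6)
    g <- factor(rep(c("a", "b"), each = 10))
    perm <- sample(6)
    r1 <- mean_centered_pls(X, g, n_perm = 0, n_boot = 0)
    r2 <- mean_centered_pls(X[, perm], g, n_perm = 0, n_boot = 0)
    expect_equal(sum(r1$singular_values^2), sum(r2$singular_values^2),
                 tolerance = 1e-12)
    expect_equal(r2$brain_saliences[, 1],
                 r1$brain_saliences[perm, 1], ignore_attr = TRUE)
  })
})

test_that("permutation p-values are smoothed and respect effect size", {
  withr::with_seed(33, {
    # planted group shift: p at the smoothed floor 1/(n_perm + 1)
    X <- rbind(matrix(rnorm(200, 1), 20), matrix(rnorm(200, -1), 20))
    g <- factor(rep(c("a", "b"), each = 20))
    res <- mean_centered_pls(X, g, n_perm = 99, n_boot = 50)
    expect_equal(res$p_perm[1], 1 / 100)
    expect_true(all(res$p_perm > 0 & res$p_perm <= 1))
    # bootstrap ratios are large for a strong uniform contrast
    expect_true(all(abs(res$bootstrap_ratios[, 1]) > 2))
  })
})

test_that("behavioral PLS recovers a perfectly correlated feature", {
  withr::with_seed(34, {
    X <- matrix(rnorm(200), 50, 4)
    Y <- cbind(b1 = X[, 2]) # behavior equals one feature exactly
    res <- behavioral_pls(X, Y, n_perm = 0, n_boot = 0)
    expect_equal(which.max(abs(res$brain_saliences[, 1])), 2L,
                 ignore_attr = TRUE)
    # sigma_1 equals the norm of the correlation row
    expect_equal(res$singular_values[1],
                 sqrt(sum(cor(Y, X)^2)), tolerance = 1e-10)
    expect_gt(unname(res$behavior_correlations[1, 1]), 0.9)
    expect_error(behavioral_pls(X, cbind(rep(1, 50))), "constant behavior")
  })
})

test_that("behavioral PLS is calibrated when X and Y are independent", {
  ps <- withr::with_seed(35, vapply(1:30, function(i) {
    X <- matrix(rnorm(400 * 6), 400, 6)
    Y <- matrix(rnorm(400 * 3), 400, 3)
    behavioral_pls(X, Y, n_perm = 200, n_boot = 0)$p_perm[1]
  }, numeric(1)))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("group PLS on subsampled shapes flags planted contrasts, not nulls", {
  run_one <- function(preset, seed) {
    sim <- simulate_study(preset, n_asd = 120, n_td = 120, n_roi = 12,
                          seed = seed)
    adj <- remove_center_variance(sim$ct, sim$cohort, 2)
    a <- sim$cohort[sim$cohort$group == "ASD", ]
    t <- sim$cohort[sim$cohort$group == "TD", ]
    sa <- fit_subsamples(draw_and_select(a, 35, 150, 15,
                                         seed = child_seed(seed, 1)),
                         adj, sim$cohort)
    st <- fit_subsamples(draw_and_select(t, 35, 150, 15,
                                         seed = child_seed(seed, 2)),
                         adj, sim$cohort)
    run_group_pls(sa, st, ct = adj, cohort = sim$cohort, n_perm = 200,
                  n_boot = 100, seed = child_seed(seed, 3))
  }
  strong <- run_one("strong", 41)
  expect_lt(strong$p_corrected, 0.05)
  # monotone p across presets (in expectation; single paired comparison here)
  null <- run_one("null", 41)
  expect_gte(null$p_perm[1], strong$p_perm[1])

  # degenerate: cannot bootstrap a single subsample per group
  sim <- simulate_study("null", n_asd = 50, n_td = 50, n_roi = 4, seed = 42)
  a <- sim$cohort[sim$cohort$group == "ASD", ]
  t <- sim$cohort[sim$cohort$group == "TD", ]
  sa <- fit_subsamples(draw_and_select(a, 40, 5, 1, seed = 1), sim$ct,
                       sim$cohort)
  st <- fit_subsamples(draw_and_select(t, 40, 5, 1, seed = 2), sim$ct,
                       sim$cohort)
  expect_error(run_group_pls(sa, st, ct = sim$ct, cohort = sim$cohort),
               "at least 2 subsamples")
})

test_that("behavioral PLS over ASD subgroups uses only ADOS-complete subjects", {
  sim <- simulate_study("strong", n_asd = 350, n_td = 60, n_roi = 10,
                        seed = 43)
  adj <- remove_center_variance(sim$ct, sim$cohort, 2)
  cohort <- sim$cohort
  # knock out ADOS for a third of ASD subjects; TD rows are already missing
  asd_idx <- which(cohort$group == "ASD")
  cohort$ados_comm[asd_idx[1:50]] <- NA
  complete <- cohort$group == "ASD" &
    complete.cases(cohort[c("ados_comm", "ados_social", "ados_stereo")])
  pool <- cohort[complete, , drop = FALSE]
  set <- fit_subsamples(draw_and_select(pool, 20, 300, 100, seed = 3),
                        adj, cohort)
  res <- run_behavioral_pls(set, cohort, "curvature", n_perm = 500,
                            n_boot = 100, seed = 4)
  expect_lt(res$p_corrected, 0.05)
  # planted coupling is negative for all three subscores
  expect_true(all(res$behavior_correlations[, 1] < 0))
  expect_equal(res$p_corrected, min(1, res$p_perm[1] * 6))
})
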