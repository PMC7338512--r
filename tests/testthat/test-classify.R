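test_that("age-stratified splitting halves every group-by-bin cell", {
  co <- tiny_cohort(40, 40, n_centers = 1, seed = 50)
  # force 10 subjects per 2-year bin in one group to get exact 5/5 splits
  co$age[co$group == "ASD"] <- rep(seq(7, 13, by = 2), each = 10)
  sp <- stratified_age_split(co, seed = 1)
  asd_tr <- sp$train[sp$train$group == "ASD", ]
  for (b in unique(floor((asd_tr$age - 6) / 2))) {
    expect_equal(sum(floor((asd_tr$age - 6) / 2) == b), 5)
  }
  # disjoint and exhaustive
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 80)
  # deterministic
  sp2 <- stratified_age_split(co, seed = 1)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)

  # stratification keeps train/test age means close on uniform cohorts
  big <- tiny_cohort(300, 300, seed = 51)
  spb <- stratified_age_split(big, seed = 2)
  expect_lt(abs(mean(spb$train$age) - mean(spb$test$age)), 0.5)
})

test_that("a linearly separable shape contrast classifies perfectly", {
  sim <- simulate_study("strong", n_asd = 100, n_td = 100, n_roi = 8,
                        seed = 52, noise_sd = 0.02)
  adj <- remove_center_variance(sim$ct, sim$cohort, 2)
  sp <- stratified_age_split(sim$cohort, seed = 3)
  sets <- list()
  for (h in c("train", "test")) {
    for (g in c("ASD", "TD")) {
      pool <- sp[[h]][sp[[h]]$group == g, , drop = FALSE]
      sets[[paste(h, g)]] <- fit_subsamples(
        draw_and_select(pool, 30, 100, 10, seed = child_seed(52, paste(h, g))),
        adj, sim$cohort)
    }
  }
  m <- train_eval_svm(sets[["train ASD"]], sets[["train TD"]],
                      sets[["test ASD"]], sets[["test TD"]], "curvature")
  expect_equal(unname(m), c(100, 100, 100))
})

test_that("repeated cross-validation is deterministic and self-consistent", {
  sim <- simulate_study("paper-like", n_asd = 90, n_td = 90, n_roi = 8,
                        seed = 53)
  adj <- remove_center_variance(sim$ct, sim$cohort, 2)
  rep1 <- cross_validate(sim$cohort, adj, "curvature", n_repeats = 3,
                         seed = 7, n_per_subsample = 30, K = 10,
                         n_candidates = 80)
  rep2 <- cross_validate(sim$cohort, adj, "curvature", n_repeats = 3,
                         seed = 7, n_per_subsample = 30, K = 10,
                         n_candidates = 80)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_gt(sd(rep1$metrics$accuracy) + sd(rep1$metrics$sensitivity), 0)
  # balanced test classes: accuracy is the mean of sensitivity and specificity
  expect_equal(rep1$metrics$accuracy,
               (rep1$metrics$sensitivity + rep1$metrics$specificity) / 2,
               tolerance = 1e-10)
  # summary CIs are the empirical percentiles of the per-repeat values
  s <- summary(rep1)
  expect_equal(s["accuracy", "ci5"],
               unname(quantile(rep1$metrics$accuracy, 0.05)))
  expect_equal(s["accuracy", "ci95"],
               unname(quantile(rep1$metrics$accuracy, 0.95)))
})

test_that("model comparison flags real metric differences after FDR", {
  mk_report <- function(acc, coefficient) {
    structure(list(
      metrics = data.frame(accuracy = acc, sensitivity = acc,
                           specificity = acc),
      covariates = data.frame(mean_ados = numeric(0),
                              n_females = numeric(0)),
      coefficient = coefficient, n_repeats = length(acc), seed = 0
    ), class = "classification_report")
  }
  same <- withr::with_seed(54, rnorm(500, 70, 2))
  tab0 <- compare_models(list(a = mk_report(same, "a"),
                              b = mk_report(same, "b")))
  expect_true(all(tab0$t == 0))
  expect_true(all(!tab0$significant))

  shifted <- withr::with_seed(55, rnorm(500, 75, 2))
  tab1 <- compare_models(list(a = mk_report(same, "a"),
                              b = mk_report(shifted, "b")))
  expect_true(all(tab1$significant))
  expect_true(all(tab1$direction == "a<b"))
  expect_error(compare_models(list(a = mk_report(same, "a"))), "at least two")
})

test_that("covariate correlations match the closed-form Pearson estimate", {
  rep <- structure(list(
    metrics = data.frame(accuracy = c(70, 72, 68, 75, 71),
                         sensitivity = c(65, 70, 66, 73, 69),
                         specificity = c(75, 74, 70, 77, 73)),
    covariates = data.frame(mean_ados = c(4.2, 4.5, 4.0, 4.8, 4.4),
                            n_females = c(10, 12, 9, 13, 11)),
    coefficient = "curvature", n_repeats = 5, seed = 0
  ), class = "classification_report")
  tab <- metric_covariate_correlations(rep)
  manual <- cor(rep$covariates$mean_ados, rep$metrics$accuracy)
  expect_equal(tab$r[tab$covariate == "mean_ados" &
                       tab$metric == "accuracy"], manual, tolerance = 1e-12)

  rep$covariates$n_females <- rep(11, 5)
  expect_error(metric_covariate_correlations(rep), "constant")
})
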