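test_that("age entropy matches closed forms", {
  expect_equal(age_entropy(rep(12.3, 50)), 0)
  # exactly uniform over 24 one-year bins
  expect_equal(age_entropy(rep(6:29 + 0.5, each = 3)), log(24),
               tolerance = 1e-12)
  # hand histogram: two occupied bins with p = 1/2 each
  expect_equal(age_entropy(c(6.5, 6.7, 12.2, 12.9)), log(2),
               tolerance = 1e-12)
  expect_error(age_entropy(c(10, 31)), "coverage")
  expect_error(age_entropy(numeric(0)), "at least one")
})

test_that("entropy selection keeps the most uniform candidate draws", {
  co <- tiny_cohort(90, 0, n_centers = 1, seed = 20)
  asd <- co[co$group == "ASD", ]

  # group size exactly n: all candidates identical, first K kept
  set0 <- draw_and_select(asd, n = 90, n_candidates = 50, K = 10, seed = 1)
  expect_equal(length(unique(set0$entropy)), 1L)
  expect_true(all(apply(set0$subject_ids, 1, setequal, asd$subject_id)))

  set1 <- draw_and_select(asd, n = 40, n_candidates = 500, K = 30, seed = 2)
  # selection property: kept entropies dominate the candidate median
  expect_gte(min(set1$entropy), median(set1$candidate_entropy))
  expect_true(all(diff(set1$entropy) <= 0))
  # no duplicate subject within a subsample
  expect_true(all(apply(set1$subject_ids, 1, anyDuplicated) == 0))
  # determinism
  set1b <- draw_and_select(asd, n = 40, n_candidates = 500, K = 30, seed = 2)
  expect_identical(set1$subject_ids, set1b$subject_ids)

  # uniform-age pool, n = 70: mean selected entropy close to ln 24
  big <- tiny_cohort(400, 0, n_centers = 1, seed = 21)
  set2 <- draw_and_select(big[big$group == "ASD", ], n = 70,
                          n_candidates = 1000, K = 80, seed = 3)
  expect_lt(abs(mean(set2$entropy) - log(24)) / log(24), 0.05)

  expect_error(draw_and_select(asd, n = 200, n_candidates = 10, K = 5),
               "smaller")
  expect_error(draw_and_select(asd, n = 40, n_candidates = 10, K = 50),
               "n_candidates")
})

test_that("selected subsample entropies are comparable between groups under the null", {
  co <- tiny_cohort(150, 150, n_centers = 1, seed = 22)
  sa <- draw_and_select(co[co$group == "ASD", ], 70, 400, 40, seed = 4)
  st <- draw_and_select(co[co$group == "TD", ], 70, 400, 40, seed = 5)
  expect_gt(t.test(sa$entropy, st$entropy)$p.value, 0.01)
})

test_that("subsample fits reproduce planted and full-group coefficients", {
  co <- tiny_cohort(80, 80, n_centers = 1, seed = 23)
  spec <- flat_spec(n_roi = 3, slope = 0.05, curvature = -0.002,
                    offsets = c(site01 = 0))
  ct <- generate_ct(co, spec, seed = 24) # noiseless common quadratic
  asd <- co[co$group == "ASD", ]
  set <- draw_and_select(asd, n = 40, n_candidates = 100, K = 12, seed = 6)
  set <- fit_subsamples(set, ct, co)
  curv <- set$shape_matrix[, attr(set$shape_matrix, "coefficient") ==
                             "curvature"]
  expect_equal(unname(as.vector(curv)), rep(-0.002, 12 * 3),
               tolerance = 1e-9)

  # the full-group "subsample" equals the full-group fit
  noisy <- generate_ct(co, flat_spec(3, slope = -0.03, noise_sd = 0.1,
                                     offsets = c(site01 = 0)), seed = 25)
  full <- draw_and_select(asd, n = nrow(asd), n_candidates = 3, K = 1,
                          seed = 7)
  full <- fit_subsamples(full, noisy, co)
  ref <- fit_trajectory(asd$age, noisy[asd$subject_id, 2], 2)
  expect_equal(
    unname(full$shape_matrix[1, attr(full$shape_matrix, "roi") == "ROI002" &
                               attr(full$shape_matrix, "coefficient") ==
                                 "curvature"]),
    ref$shape, tolerance = 1e-10)

  # masking drops the masked ROI's columns
  m <- c(TRUE, FALSE, TRUE)
  masked <- fit_subsamples(set, ct, co, mask = m)
  expect_equal(ncol(masked$shape_matrix), 6)
  expect_false("ROI002" %in% attr(masked$shape_matrix, "roi"))
})

test_that("subsample coefficient variance shrinks like 1/n", {
  co <- tiny_cohort(600, 0, n_centers = 1, seed = 26)
  asd <- co[co$group == "ASD", ]
  ct <- generate_ct(co, flat_spec(1, slope = -0.02, noise_sd = 0.15,
                                  offsets = c(site01 = 0)), seed = 27)
  v <- vapply(c(35, 70, 140), function(n) {
    set <- draw_and_select(asd, n = n, n_candidates = 300, K = 100,
                           seed = 30 + n)
    set <- fit_subsamples(set, ct, co)
    var(set$shape_matrix[, 1]) # slope column
  }, numeric(1))
  # ratios approximately 2 with generous tolerance (overlapping subsamples
  # and finite pools deflate the large-n variances)
  expect_gt(v[1] / v[2], 1.3)
  expect_gt(v[2] / v[3], 1.3)
})
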