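test_that("cohort generation honors sizes, ranges, and determinism", {
  co <- generate_cohort(0, 10, c(one = 10), seed = 1)
  expect_equal(nrow(co), 10)
  expect_true(all(co$group == "TD"))

  a <- generate_cohort(25, 35, c(x = 30, y = 30), seed = 7)
  b <- generate_cohort(25, 35, c(x = 30, y = 30), seed = 7)
  expect_identical(a, b)
  expect_equal(as.vector(table(a$group)), c(25, 35))
  expect_true(all(a$age >= 6 & a$age <= 30))
  expect_true(all(is.na(a$severity[a$group == "TD"])))

  # design-scale group counts with 24 centers
  sizes <- rep(56L, 24)
  sizes[seq_len(1360 - sum(sizes))] <- 57L
  names(sizes) <- sprintf("c%02d", 1:24)
  big <- generate_cohort(674, 686, sizes, seed = 2)
  expect_equal(sum(big$group == "ASD"), 674)
  expect_equal(sum(big$group == "TD"), 686)
  expect_equal(length(unique(big$center)), 24)

  expect_error(generate_cohort(5, 5, c(a = 10, b = 0)), "empty center")
  expect_error(generate_cohort(5, 5, c(a = 10), age_range = c(4, 30)),
               "age_range")
})

test_that("noiseless thickness generation is an exact polynomial evaluation", {
  co <- tiny_cohort(10, 10, seed = 3)
  spec <- flat_spec(n_roi = 2, slope = -0.02)
  ct <- generate_ct(co, spec, seed = 1)
  expect_equal(unname(ct[, 1]), 3 - 0.02 * co$age, tolerance = 1e-12)

  # planted center offset shifts exactly
  spec2 <- flat_spec(n_roi = 2, offsets = c(site01 = 0, site02 = 0.3))
  ct2 <- generate_ct(co, spec2, seed = 1)
  shift <- ct2[co$center == "site02", 1] - 3
  expect_equal(unname(shift), rep(0.3, sum(co$center == "site02")),
               tolerance = 1e-12)

  expect_identical(generate_ct(co, spec, seed = 5),
                   generate_ct(co, spec, seed = 5))
  co_bad <- co
  co_bad$center[1] <- "elsewhere"
  expect_error(generate_ct(co_bad, spec, seed = 1), "elsewhere")
})

test_that("generated noise matches its nominal standard deviation", {
  co <- tiny_cohort(1000, 1000, seed = 9)
  spec <- flat_spec(n_roi = 4, slope = -0.03, curvature = 0.001,
                    noise_sd = 0.1)
  ct <- generate_ct(co, spec, seed = 21)
  planted <- 3 - 0.03 * co$age + 0.001 * co$age^2
  res_sd <- apply(ct - planted, 2, sd)
  expect_true(all(abs(res_sd - 0.1) / 0.1 < 0.05))
})

test_that("ADOS generation couples to severity only when requested", {
  spec0 <- ct_preset("null", n_roi = 5)
  co <- generate_cohort(400, 50, c(site01 = 150, site02 = 150, site03 = 100,
                                   site04 = 50), seed = 4)
  # zero coupling: no warning, scores independent of the latent trait
  expect_silent(co0 <- generate_ados(co, spec0, seed = 8))
  asd <- co0$group == "ASD"
  expect_true(abs(cor(co0$ados_comm[asd], co0$severity[asd])) < 0.1)
  expect_true(all(is.na(co0$ados_comm[!asd])))
  expect_true(all(co0$ados_comm[asd] >= 0 & co0$ados_comm[asd] <= 8))
  expect_true(all(co0$ados_stereo[asd] <= 4))

  spec1 <- ct_preset("strong", n_roi = 5)
  co1 <- generate_ados(co, spec1, seed = 8)
  expect_gt(cor(co1$ados_comm[asd], co1$severity[asd]), 0.5)

  # coupling without a planted curvature contrast degrades to pure noise
  coefs <- cbind(b0 = rep(3, 2), b1 = 0, b2 = 0, b3 = 0)
  spec_bad <- trajectory_spec(coefs, coefs, ados_coupling = 1)
  expect_warning(generate_ados(co, spec_bad, seed = 8), "pure noise")
})

test_that("presets plant the documented contrast structure", {
  spec <- ct_preset("paper-like", n_roi = 20)
  expect_equal(spec$planted_rois, 1:4)
  # ASD curvature negative in planted ROIs, equal elsewhere
  expect_true(all(spec$coef_asd[1:4, "b2"] < 0))
  expect_equal(spec$coef_asd[-(1:4), ], spec$coef_td[-(1:4), ])
  # the planted contrast leaves the age-averaged mean CT unchanged:
  # E[d(A)] = db0 + db1 E[A] + db2 E[A^2] with A ~ U(6, 30), so
  # E[A] = 18 and E[A^2] = 48 + 18^2 = 372.
  for (r in spec$planted_rois) {
    dd <- spec$coef_asd[r, ] - spec$coef_td[r, ]
    expect_lt(abs(dd["b0"] + 18 * dd["b1"] + 372 * dd["b2"]), 1e-10)
  }
  # generated values stay positive over the design range
  co <- tiny_cohort(200, 200, seed = 5)
  ct <- generate_ct(co, ct_preset("strong", n_roi = 10), seed = 6)
  expect_true(all(ct > 0))
})
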