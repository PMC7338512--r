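# Synthetic cohort and cortical-thickness generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: several acquisition centers with additive offsets, group-specific
# polynomial age trajectories per ROI, per-subject Gaussian noise, an age
# window of 6-30 years, unbalanced group sizes, and symptom scores coupled
# (negatively) to a planted curvature effect through a latent severity trait.

#' Specify group trajectories for the synthetic generator
#'
#' A trajectory specification holds, per ROI and diagnostic group, the raw-age
#' polynomial coefficients of the mean cortical-thickness trajectory
#' (intercept in mm, then mm/yr, mm/yr^2, mm/yr^3), the residual noise level,
#' additive per-center offsets, and the coupling between a latent ASD symptom
#' severity trait and both the planted curvature effect and the generated
#' ADOS subscores.
#'
#' @param coef_td,coef_asd numeric ROI x 4 matrices of polynomial coefficients
#'   (columns: intercept, age, age^2, age^3) for the TD and ASD group mean
#'   trajectories, in raw age (years).
#' @param noise_sd per-subject, per-ROI Gaussian noise SD in mm
#'   (non-negative).
#' @param center_offsets named numeric vector of additive center offsets (mm);
#'   names are the center identifiers the cohort must use.
#' @param ados_coupling dimensionless weight linking the latent severity trait
#'   to generated ADOS subscores. Zero decouples symptoms from the brain.
#' @param curvature_het per-subject curvature SD (mm/yr^2) in planted ROIs:
#'   an ASD subject with severity \eqn{s} deviates from the group quadratic by
#'   \eqn{-\mathrm{het}\, s\, ((a - 18)^2 - 48)}, which is mean-zero over a
#'   uniform 6-30 age distribution, so the group trajectory is unchanged while
#'   subgroup-mean curvature tracks subgroup-mean severity.
#' @param planted_rois integer indices of ROIs carrying the planted group
#'   contrast (used by [generate_ct()] for the severity term and recorded for
#'   downstream recovery checks).
#' @param roi_names optional ROI labels; defaults to the rownames of
#'   `coef_td` or `ROI001`-style labels.
#' @return An object of class `trajectory_spec`.
#' @seealso [ct_preset()] for ready-made specifications.
#' @export
trajectory_spec <- function(coef_td, coef_asd, noise_sd = 0.1,
                            center_offsets = c(site01 = 0),
                            ados_coupling = 0, curvature_het = 0,
                            planted_rois = integer(0), roi_names = NULL) {
  coef_td <- as.matrix(coef_td)
  coef_asd <- as.matrix(coef_asd)
  if (!identical(dim(coef_td), dim(coef_asd))) {
    stop("`coef_td` and `coef_asd` must have identical dimensions")
  }
  if (ncol(coef_td) != 4L) {
    stop("coefficient matrices need 4 columns (intercept, age, age^2, age^3)")
  }
  if (!all(is.finite(coef_td)) || !all(is.finite(coef_asd))) {
    stop("non-finite trajectory coefficients")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number")
  }
  if (is.null(names(center_offsets)) || any(!nzchar(names(center_offsets)))) {
    stop("`center_offsets` must be a named vector")
  }
  n_roi <- nrow(coef_td)
  roi_names <- roi_names %||% rownames(coef_td) %||%
    sprintf("ROI%03d", seq_len(n_roi))
  if (length(roi_names) != n_roi) stop("`roi_names` length mismatch")
  planted_rois <- as.integer(planted_rois)
  if (length(planted_rois) &&
      (min(planted_rois) < 1L || max(planted_rois) > n_roi)) {
    stop("`planted_rois` out of range")
  }
  dimnames(coef_td) <- dimnames(coef_asd) <-
    list(roi_names, c("b0", "b1", "b2", "b3"))
  structure(
    list(coef_td = coef_td, coef_asd = coef_asd, noise_sd = noise_sd,
         center_offsets = center_offsets, ados_coupling = ados_coupling,
         curvature_het = curvature_het, planted_rois = planted_rois,
         roi_names = roi_names),
    class = "trajectory_spec"
  )
}

#' @export
print.trajectory_spec <- function(x, ...) {
  cat("Trajectory specification:", length(x$roi_names), "ROIs,",
      length(x$center_offsets), "centers\n")
  cat("  noise SD:", x$noise_sd, "mm;",
      length(x$planted_rois), "planted ROIs\n")
  cat("  ADOS coupling:", x$ados_coupling,
      "; per-subject curvature SD:", x$curvature_het, "\n")
  invisible(x)
}

#' Named trajectory presets for the synthetic study conditions
#'
#' Three presets define the study conditions exercised by the test suite:
#'
#' * `"null"`: identical group trajectories, no symptom coupling. Used for
#'   type-I-error and chance-level calibration.
#' * `"paper-like"`: the ASD group deviates, in a contiguous block covering
#'   20% of the ROIs, by a less negative linear thinning rate and a negative
#'   curvature; the contrast is constructed so the age-averaged mean CT is
#'   equal across groups (no overall group difference). ADOS subscores are
#'   coupled negatively to the planted curvature effect through a latent
#'   severity trait.
#' * `"strong"`: the same structure with both contrast components doubled.
#'
#' The TD baseline is a gently U-shaped thinning trajectory
#' (slope -0.045 mm/yr, curvature +0.001 mm/yr^2) with per-ROI baseline
#' thickness spread over 2.9-3.5 mm; centers carry additive offsets spread
#' over -0.2 to +0.2 mm. No cubic (aberrancy) contrast is planted in any
#' preset.
#'
#' @param name preset name.
#' @param n_roi number of ROIs.
#' @param n_centers number of acquisition centers.
#' @param noise_sd per-subject Gaussian noise SD in mm.
#' @return A [trajectory_spec()].
#' @export
#' @examples
#' spec <- ct_preset("paper-like", n_roi = 20)
#' spec$planted_rois
ct_preset <- function(name = c("null", "paper-like", "strong"), n_roi = 40,
                      n_centers = 4, noise_sd = 0.1) {
  name <- match.arg(name)
  base_int <- seq(2.9, 3.5, length.out = n_roi)
  coef_td <- cbind(b0 = base_int, b1 = -0.045, b2 = 0.001, b3 = 0)
  coef_asd <- coef_td
  params <- switch(name,
    "null" = list(s = 0, c = 0, coupling = 0, het = 0),
    "paper-like" = list(s = 0.010, c = -0.0015, coupling = 1, het = 0.002),
    "strong" = list(s = 0.020, c = -0.003, coupling = 1.5, het = 0.003)
  )
  planted <- if (params$s != 0 || params$c != 0) {
    seq_len(max(1L, ceiling(0.2 * n_roi)))
  } else {
    integer(0)
  }
  if (length(planted)) {
    # Contrast decomposition: s*(a - 18) shifts the linear-fit slope without
    # touching the quadratic-fit curvature; c*((a - 18)^2 - 48) shifts the
    # curvature without touching the linear-fit slope. Both are mean-zero over
    # ages uniform on [6, 30], so overall CT stays group-equal.
    coef_asd[planted, "b0"] <- coef_asd[planted, "b0"] -
      18 * params$s + 276 * params$c
    coef_asd[planted, "b1"] <- coef_asd[planted, "b1"] +
      params$s - 36 * params$c
    coef_asd[planted, "b2"] <- coef_asd[planted, "b2"] + params$c
  }
  offsets <- if (n_centers == 1L) 0 else seq(-0.2, 0.2, length.out = n_centers)
  names(offsets) <- sprintf("site%02d", seq_len(n_centers))
  trajectory_spec(
    coef_td = coef_td, coef_asd = coef_asd, noise_sd = noise_sd,
    center_offsets = offsets, ados_coupling = params$coupling,
    curvature_het = params$het, planted_rois = planted
  )
}

#' Generate a synthetic cohort table
#'
#' Draws a multi-center cohort with uniformly distributed ages, diagnostic
#' groups allocated to centers by largest-remainder proportional rounding
#' (so every center carries both groups where sizes permit), sex assigned
#' with the female fractions of large autism imaging repositories (~14% ASD,
#' ~20% TD), and a latent standard-normal symptom `severity` trait for ASD
#' subjects. The severity column drives the ADOS/curvature coupling in
#' [generate_ct()] and [generate_ados()]; it is generator-internal and is not
#' written by [write_phenotypes()].
#'
#' @param n_asd,n_td group sizes (non-negative, at least one positive).
#' @param centers named vector of center sizes; must sum to `n_asd + n_td`.
#'   Unnamed vectors get `site01`-style names.
#' @param age_range closed age interval in years, inside `[6, 30]`.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A cohort data frame with columns `subject_id`, `group` (factor
#'   ASD/TD), `age`, `sex` (factor M/F), `center`, `ados_comm`,
#'   `ados_social`, `ados_stereo` (all `NA` until [generate_ados()]), and
#'   `severity`.
#' @export
#' @examples
#' cohort <- generate_cohort(30, 30, centers = c(a = 30, b = 30), seed = 1)
#' table(cohort$group, cohort$center)
generate_cohort <- function(n_asd, n_td, centers, age_range = c(6, 30),
                            seed = NULL) {
  if (n_asd < 0 || n_td < 0 || n_asd + n_td == 0) {
    stop("group sizes must be non-negative with at least one subject")
  }
  centers <- round(centers)
  if (any(centers < 1)) stop("empty center requested")
  if (is.null(names(centers))) {
    names(centers) <- sprintf("site%02d", seq_along(centers))
  }
  if (sum(centers) != n_asd + n_td) {
    stop("center sizes must sum to n_asd + n_td")
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 6 || age_range[2] > 30) {
    stop("`age_range` must be an increasing interval inside [6, 30]")
  }
  n <- n_asd + n_td
  # Largest-remainder allocation of ASD counts to centers.
  quota <- centers * n_asd / n
  k_asd <- floor(quota)
  rem <- n_asd - sum(k_asd)
  if (rem > 0) {
    extra <- order(quota - k_asd, decreasing = TRUE)[seq_len(rem)]
    k_asd[extra] <- k_asd[extra] + 1L
  }
  k_asd <- pmin(k_asd, centers)
  # Guard: rounding may not exactly exhaust n_asd when centers saturate.
  deficit <- n_asd - sum(k_asd)
  while (deficit > 0) {
    room <- which(k_asd < centers)
    k_asd[room[1]] <- k_asd[room[1]] + 1L
    deficit <- deficit - 1L
  }
  group <- unlist(lapply(seq_along(centers), function(i) {
    c(rep("ASD", k_asd[i]), rep("TD", centers[i] - k_asd[i]))
  }), use.names = FALSE)
  center <- rep(names(centers), centers)
  with_seed(seed, {
    age <- runif(n, age_range[1], age_range[2])
    p_f <- ifelse(group == "ASD", 0.14, 0.195)
    sex <- ifelse(rbinom(n, 1, p_f) == 1, "F", "M")
    severity <- ifelse(group == "ASD", rnorm(n), NA_real_)
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      group = factor(group, levels = c("ASD", "TD")),
      age = age,
      sex = factor(sex, levels = c("M", "F")),
      center = center,
      ados_comm = NA_real_, ados_social = NA_real_, ados_stereo = NA_real_,
      severity = severity,
      stringsAsFactors = FALSE
    )
  })
}

# Evaluate the group-mean polynomial for all subjects of one group:
# returns n x R matrix.
eval_group_poly <- function(ages, coefs) {
  P <- outer(ages, 0:3, "^")
  P %*% t(coefs)
}

#' Generate a cortical-thickness table for a cohort
#'
#' Every cell is the group-specific polynomial trajectory evaluated at the
#' subject's age, plus the additive offset of the subject's acquisition
#' center, plus (for ASD subjects in planted ROIs, when the specification
#' requests curvature heterogeneity) a severity-weighted mean-zero quadratic
#' deviation, plus Gaussian noise.
#'
#' @param cohort a cohort table from [generate_cohort()].
#' @param spec a [trajectory_spec()] covering every center in the cohort.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return A numeric subjects x ROIs matrix (mm) with subject IDs as row
#'   names, ROI labels as column names, and a `"parcellation"` attribute.
#' @export
generate_ct <- function(cohort, spec, seed = NULL) {
  check_cohort(cohort)
  stopifnot(inherits(spec, "trajectory_spec"))
  missing_centers <- setdiff(unique(cohort$center),
                             names(spec$center_offsets))
  if (length(missing_centers)) {
    stop("trajectory specification has no offset for center(s): ",
         paste(missing_centers, collapse = ", "))
  }
  n <- nrow(cohort)
  n_roi <- length(spec$roi_names)
  ct <- matrix(NA_real_, n, n_roi,
               dimnames = list(cohort$subject_id, spec$roi_names))
  is_asd <- cohort$group == "ASD"
  if (any(is_asd)) {
    ct[is_asd, ] <- eval_group_poly(cohort$age[is_asd], spec$coef_asd)
  }
  if (any(!is_asd)) {
    ct[!is_asd, ] <- eval_group_poly(cohort$age[!is_asd], spec$coef_td)
  }
  if (spec$curvature_het > 0 && length(spec$planted_rois) && any(is_asd)) {
    dev <- -spec$curvature_het * cohort$severity[is_asd] *
      ((cohort$age[is_asd] - 18)^2 - 48)
    ct[is_asd, spec$planted_rois] <- ct[is_asd, spec$planted_rois] + dev
  }
  ct <- ct + spec$center_offsets[cohort$center]
  with_seed(seed, {
    if (spec$noise_sd > 0) {
      ct <- ct + matrix(rnorm(n * n_roi, sd = spec$noise_sd), n, n_roi)
    }
    ct
  }) -> ct
  if (any(!is.finite(ct))) stop("generated CT contains non-finite values")
  n_bad <- sum(ct <= 0)
  if (n_bad > 0) {
    warning(sprintf("%d generated CT value(s) are non-positive", n_bad))
  }
  attr(ct, "parcellation") <- "custom"
  ct
}

#' Generate ADOS-Generic subscores for the ASD group
#'
#' Fills the `ados_comm` (0-8), `ados_social` (0-8) and `ados_stereo` (0-4)
#' columns for ASD subjects with rounded, range-clamped scores built from a
#' base level, the latent severity trait scaled by the specification's
#' `ados_coupling`, and additive noise. TD subjects keep missing scores.
#' Because [generate_ct()] makes a subject's planted-ROI curvature more
#' negative as severity rises, a positive coupling plants a negative
#' population-level association between subgroup-mean ADOS and subgroup
#' curvature.
#'
#' @inheritParams generate_ct
#' @return The cohort with ADOS columns filled for ASD subjects.
#' @export
generate_ados <- function(cohort, spec, seed = NULL) {
  check_cohort(cohort)
  stopifnot(inherits(spec, "trajectory_spec"))
  is_asd <- cohort$group == "ASD"
  if (!any(is_asd)) stop("no ASD subjects in cohort")
  w <- spec$ados_coupling
  if (w > 0 &&
      (spec$curvature_het <= 0 || length(spec$planted_rois) == 0L)) {
    warning("ADOS coupling requested but no curvature contrast is planted; ",
            "scores are pure noise")
    w <- 0
  }
  sev <- cohort$severity[is_asd]
  sev[!is.finite(sev)] <- 0
  m <- sum(is_asd)
  clamp <- function(x, hi) pmin(hi, pmax(0, round(x)))
  with_seed(seed, {
    cohort$ados_comm[is_asd] <-
      clamp(4 + 1.1 * w * sev + rnorm(m, sd = 1.1), 8)
    cohort$ados_social[is_asd] <-
      clamp(5 + 1.2 * w * sev + rnorm(m, sd = 1.2), 8)
    cohort$ados_stereo[is_asd] <-
      clamp(2 + 0.5 * w * sev + rnorm(m, sd = 0.7), 4)
    cohort
  })
}

#' Simulate a full synthetic study in one call
#'
#' Convenience wrapper chaining [generate_cohort()], [generate_ct()] and
#' [generate_ados()] with child seeds derived from one master seed.
#'
#' @param preset preset name passed to [ct_preset()], or a ready
#'   [trajectory_spec()].
#' @param n_asd,n_td group sizes.
#' @param n_centers number of centers (sizes as equal as possible); ignored
#'   when `spec` is supplied with its own centers.
#' @param n_roi number of ROIs (ignored when a spec object is supplied).
#' @param seed master seed.
#' @param noise_sd passed to [ct_preset()].
#' @return A list with elements `cohort`, `ct`, and `spec`.
#' @export
#' @examples
#' sim <- simulate_study("null", n_asd = 40, n_td = 40, n_roi = 10, seed = 1)
#' dim(sim$ct)
simulate_study <- function(preset = "paper-like", n_asd = 674, n_td = 686,
                           n_centers = 4, n_roi = 40, seed = 1,
                           noise_sd = 0.1) {
  spec <- if (inherits(preset, "trajectory_spec")) {
    preset
  } else {
    ct_preset(preset, n_roi = n_roi, n_centers = n_centers,
              noise_sd = noise_sd)
  }
  n <- n_asd + n_td
  k <- length(spec$center_offsets)
  sizes <- rep(floor(n / k), k)
  sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
  names(sizes) <- names(spec$center_offsets)
  cohort <- generate_cohort(n_asd, n_td, sizes, seed = child_seed(seed, 1L))
  ct <- generate_ct(cohort, spec, seed = child_seed(seed, 2L))
  if (n_asd > 0) {
    cohort <- generate_ados(cohort, spec, seed = child_seed(seed, 3L))
  }
  list(cohort = cohort, ct = ct, spec = spec)
}
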