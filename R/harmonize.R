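# Inter-center variance removal by ordinary least squares.
#
# For each ROI the model at degree d is
#   CT ~ 1 + center dummies + age + ... + age^d
#        + group + age:group + ... + age^d:group
# with centers dummy-coded against a reference level (all but one, since the
# intercept is included), the group coded +1 (ASD) / -1 (TD), and the fit
# pooling both groups. Only the variance carried by the center dummies is
# removed; age, group, and age-by-group variance is preserved.

# Build the pooled design matrix; returns the matrix plus column bookkeeping.
center_design <- function(cohort, degree) {
  stopifnot(degree %in% 1:3)
  centers <- factor(cohort$center)
  grp <- ifelse(cohort$group == "ASD", 1, -1)
  age <- cohort$age
  X <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  center_cols <- character(0)
  if (nlevels(centers) > 1L) {
    dm <- stats::model.matrix(~centers)[, -1, drop = FALSE]
    colnames(dm) <- paste0("center:", levels(centers)[-1])
    center_cols <- colnames(dm)
    X <- cbind(X, dm)
  }
  for (d in seq_len(degree)) {
    X <- cbind(X, age^d)
    colnames(X)[ncol(X)] <- if (d == 1) "Age" else paste0("Age", d)
  }
  X <- cbind(X, Group = grp)
  for (d in seq_len(degree)) {
    X <- cbind(X, (age^d) * grp)
    colnames(X)[ncol(X)] <-
      if (d == 1) "Age:Group" else paste0("Age", d, ":Group")
  }
  list(X = X, center_cols = center_cols, center_levels = levels(centers),
       reference = levels(centers)[1])
}

# QR with an explicit rank check; errors name the collinear columns.
qr_full_rank <- function(X) {
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dec
}

#' Fit the pooled center-effect model for one ROI
#'
#' @param ct_roi numeric thickness vector (mm), aligned with `cohort`.
#' @param cohort cohort table with at least two centers.
#' @param degree polynomial degree of the age terms (1, 2 or 3).
#' @return A `center_model` object carrying the coefficient vector, the
#'   per-center effects (reference center fixed at 0), and design metadata.
#' @export
fit_center_model <- function(ct_roi, cohort, degree) {
  check_cohort(cohort)
  if (length(ct_roi) != nrow(cohort)) stop("length mismatch with cohort")
  if (length(unique(cohort$center)) < 2L) {
    stop("at least two centers are required")
  }
  des <- center_design(cohort, degree)
  dec <- qr_full_rank(des$X)
  beta <- qr.coef(dec, ct_roi)
  effects <- c(0, beta[des$center_cols])
  names(effects) <- des$center_levels
  structure(
    list(coefficients = beta, center_effects = effects,
         center_cols = des$center_cols, reference = des$reference,
         degree = degree, n = nrow(cohort)),
    class = "center_model"
  )
}

#' @export
coef.center_model <- function(object, ...) object$coefficients

#' @export
print.center_model <- function(x, ...) {
  cat("Center-effect model (degree", x$degree, ",", x$n, "subjects)\n")
  cat("Center effects (mm; reference", x$reference, "= 0):\n")
  print(round(x$center_effects, 4))
  invisible(x)
}

#' Remove inter-center variance from a thickness table
#'
#' Fits the pooled center-effect model at the requested degree for every ROI
#' and subtracts each subject's estimated center effect, re-centered to a
#' size-weighted zero mean across subjects so the grand mean of every ROI is
#' preserved and adjusted values stay in physiological range regardless of
#' which center is the dummy-coding reference. With a single center the input
#' is returned unchanged. The adjustment is a projection: applying it twice
#' equals applying it once, and refitting the model on adjusted data yields
#' center coefficients of (numerically) zero.
#'
#' @param ct subjects x ROIs thickness matrix aligned with `cohort`.
#' @param cohort cohort table.
#' @param degree polynomial degree of the age terms in the model (the
#'   degree-d analysis downstream should consume the degree-d adjustment).
#' @return The adjusted thickness matrix.
#' @export
remove_center_variance <- function(ct, cohort, degree) {
  check_cohort(cohort)
  check_ct(ct, cohort)
  parc <- attr(ct, "parcellation")
  ct <- ct[cohort$subject_id, , drop = FALSE]
  if (length(unique(cohort$center)) < 2L) {
    attr(ct, "parcellation") <- parc
    return(ct)
  }
  des <- center_design(cohort, degree)
  dec <- qr_full_rank(des$X)
  beta <- qr.coef(dec, ct) # p x R, all ROIs in one solve
  b_center <- beta[des$center_cols, , drop = FALSE]
  dummies <- des$X[, des$center_cols, drop = FALSE]
  subject_effect <- dummies %*% b_center # n x R
  adj <- ct - subject_effect +
    matrix(colMeans(subject_effect), nrow(ct), ncol(ct), byrow = TRUE)
  n_bad <- sum(adj <= 0)
  if (n_bad > 0) {
    message(sprintf("%d adjusted CT value(s) are non-positive", n_bad))
  }
  dimnames(adj) <- dimnames(ct)
  attr(adj, "parcellation") <- parc
  adj
}
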