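# Per-group polynomial trajectory fitting, the deviance goodness-of-fit
# test, FDR masking of poorly fitting ROIs, and the turning-point statistic.

# Pascal-type transform: coefficients in (age - a0)^j -> raw age^j.
shift_poly_coefs <- function(coefs, a0) {
  d <- length(coefs) - 1L
  out <- numeric(d + 1L)
  for (j in 0:d) {
    for (i in 0:j) {
      out[i + 1L] <- out[i + 1L] + coefs[j + 1L] * choose(j, i) * (-a0)^(j - i)
    }
  }
  out
}

#' Fit a polynomial developmental trajectory for one ROI and group
#'
#' Ordinary least-squares fit of thickness on age for a group-pure sample.
#' The fit is computed on mean-centered ages for numerical conditioning and
#' the coefficients are transformed back to raw age units. The highest-order
#' coefficient is the trajectory *shape*: slope for degree 1 (mm/yr),
#' curvature for degree 2 (mm/yr^2), aberrancy for degree 3 (mm/yr^3).
#'
#' @param ages ages in years.
#' @param ct_roi thickness values in mm, same length.
#' @param degree polynomial degree (1, 2 or 3).
#' @param roi,group optional labels carried into the result.
#' @return A `trajectory_fit` object with components `coefficients` (b0..bd,
#'   raw age), `shape`, `degree`, `fitted`, `residuals`, `rss`, `null_rss`,
#'   and `n`.
#' @export
#' @examples
#' a <- runif(100, 6, 30)
#' fit <- fit_trajectory(a, 4 - 0.02 * a, degree = 1)
#' coef(fit)
fit_trajectory <- function(ages, ct_roi, degree, roi = NULL, group = NULL) {
  stopifnot(degree %in% 1:3)
  if (length(ages) != length(ct_roi)) stop("length mismatch")
  if (!all(is.finite(ages)) || !all(is.finite(ct_roi))) {
    stop("non-finite input")
  }
  n <- length(ages)
  if (n <= degree + 1L) stop("need more than degree + 1 observations")
  a0 <- mean(ages)
  X <- outer(ages - a0, 0:degree, "^")
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    stop("(near-)singular trajectory design; are all ages equal?")
  }
  bc <- qr.coef(dec, ct_roi)
  beta <- shift_poly_coefs(bc, a0)
  names(beta) <- paste0("b", 0:degree)
  fitted <- drop(X %*% bc)
  res <- ct_roi - fitted
  structure(
    list(coefficients = beta, shape = unname(beta[degree + 1L]),
         degree = degree, n = n, fitted = fitted, residuals = res,
         rss = sum(res^2), null_rss = sum((ct_roi - mean(ct_roi))^2),
         ages = ages, ct = ct_roi, roi = roi, group = group),
    class = "trajectory_fit"
  )
}

#' @export
coef.trajectory_fit <- function(object, ...) object$coefficients

#' @export
residuals.trajectory_fit <- function(object, ...) object$residuals

#' @export
predict.trajectory_fit <- function(object, ages = NULL, ...) {
  ages <- ages %||% object$ages
  drop(outer(ages, 0:object$degree, "^") %*% object$coefficients)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  kind <- c("linear (slope)", "quadratic (curvature)", "cubic (aberrancy)")
  cat("Trajectory fit:", kind[x$degree],
      if (!is.null(x$roi)) paste0("for ", x$roi), "\n")
  if (!is.null(x$group)) cat("  group:", x$group, "\n")
  cat("  n =", x$n, "; shape coefficient =", signif(x$shape, 5), "\n")
  cat("  coefficients:\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
plot.trajectory_fit <- function(x, ...) {
  ord <- order(x$ages)
  plot(x$ages, x$ct, xlab = "Age (years)", ylab = "CT (mm)",
       col = "grey50", ...)
  lines(x$ages[ord], x$fitted[ord], lwd = 2)
  invisible(x)
}

#' Deviance test of a trajectory fit against the constant model
#'
#' Likelihood-ratio statistic under Gaussian maximum likelihood,
#' \eqn{n \log(\mathrm{RSS}_0 / \mathrm{RSS}_1)}, referred to a chi-squared
#' distribution with `degree` degrees of freedom. Data identical to their own
#' mean give statistic 0 and p = 1; a perfect (zero-residual) polynomial fit
#' of non-constant data gives p = 0 with a `degenerate` attribute.
#'
#' @param fit a [fit_trajectory()] result.
#' @return The p-value, with attributes `statistic`, `df`, and `degenerate`.
#' @export
deviance_test <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  eps <- 1e-12 * max(fit$null_rss, 1)
  if (fit$null_rss <= eps) {
    # constant data: full and null models coincide
    stat <- 0
    p <- 1
    degen <- FALSE
  } else if (fit$rss <= eps) {
    stat <- Inf
    p <- 0
    degen <- TRUE
  } else {
    stat <- fit$n * log(fit$null_rss / fit$rss)
    p <- pchisq(stat, df = fit$degree, lower.tail = FALSE)
    degen <- FALSE
  }
  structure(p, statistic = stat, df = fit$degree, degenerate = degen)
}

#' Benjamini-Hochberg mask of ROIs by goodness of fit
#'
#' Adjusts the per-ROI deviance p-values within each group (each column is
#' one family) and keeps an ROI according to the configured rule:
#' `"both_groups"` requires a significant fit in every group,
#' `"any_group"` in at least one.
#'
#' @param pvals numeric matrix of p-values, ROIs x groups (a vector is
#'   treated as a single group).
#' @param q FDR level.
#' @param rule masking rule.
#' @return Named logical vector of ROIs to keep, with attributes `rule`, `q`
#'   and the `adjusted` p matrix.
#' @export
fdr_mask <- function(pvals, q = 0.05, rule = c("both_groups", "any_group")) {
  rule <- match.arg(rule)
  if (is.null(dim(pvals))) pvals <- matrix(pvals, ncol = 1)
  if (length(pvals) == 0L) stop("empty p-value input")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  adj <- apply(pvals, 2, p.adjust, method = "BH")
  adj <- matrix(adj, nrow = nrow(pvals), dimnames = dimnames(pvals))
  sig <- adj <= q
  keep <- if (rule == "both_groups") {
    apply(sig, 1, all)
  } else {
    apply(sig, 1, any)
  }
  names(keep) <- rownames(pvals)
  structure(keep, rule = rule, q = q, adjusted = adj)
}

#' Turning point of a negative-curvature quadratic trajectory
#'
#' Traces the chord between the fitted thickness at `age_lo` and `age_hi`
#' and returns the age at which the quadratic trajectory is furthest (in
#' vertical distance) from that chord — the transition from decreased to
#' increased cortical thinning. For a quadratic this maximizer is the
#' midpoint of the interval; the function computes it from the fitted
#' coefficients via the stationarity condition rather than asserting the
#' closed form.
#'
#' @param fit a degree-2 [fit_trajectory()] result with negative curvature.
#' @param age_lo,age_hi chord endpoints in years.
#' @return The turning-point age in years.
#' @export
turning_point <- function(fit, age_lo = 6, age_hi = 30) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (fit$degree != 2L) stop("turning point requires a quadratic fit")
  b <- fit$coefficients
  if (b[3] >= 0) stop("turning point requires negative curvature")
  f <- function(a) b[1] + b[2] * a + b[3] * a^2
  chord_slope <- (f(age_hi) - f(age_lo)) / (age_hi - age_lo)
  tp <- (chord_slope - b[2]) / (2 * b[3])
  unname(tp)
}
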