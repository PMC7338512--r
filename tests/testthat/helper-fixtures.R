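# Shared fixture builders and independent oracles used across test files.

# Small two-center cohort with both groups represented everywhere.
tiny_cohort <- function(n_asd = 30, n_td = 30, n_centers = 2, seed = 42,
                        age_range = c(6, 30)) {
  n <- n_asd + n_td
  sizes <- rep(floor(n / n_centers), n_centers)
  sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
  names(sizes) <- sprintf("site%02d", seq_len(n_centers))
  generate_cohort(n_asd, n_td, sizes, age_range = age_range, seed = seed)
}

# A noiseless specification with explicit coefficients for exactness checks.
flat_spec <- function(n_roi = 3, slope = 0, curvature = 0, noise_sd = 0,
                      offsets = c(site01 = 0, site02 = 0), intercept = 3) {
  coefs <- cbind(b0 = rep(intercept, n_roi), b1 = slope, b2 = curvature,
                 b3 = 0)
  trajectory_spec(coefs, coefs, noise_sd = noise_sd,
                  center_offsets = offsets)
}

# Independent OLS oracle: Moore-Penrose pseudoinverse via SVD on the raw
# polynomial basis.
pinv_poly_fit <- function(ages, y, degree) {
  X <- outer(ages, 0:degree, "^")
  sv <- svd(X)
  drop(sv$v %*% ((t(sv$u) %*% y) / sv$d))
}

# Independent normal-equations oracle for an arbitrary design matrix.
normal_eq_fit <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Hand-coded Benjamini-Hochberg: returns the logical rejection vector.
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
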