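# Partial least squares for group contrasts and brain-behavior association,
# with permutation p-values and bootstrap ratios. Implemented directly (the
# decompositions are small: a groups x features or behaviors x features
# matrix), not wrapped from a toolbox.

# Mean-centering decomposition: SVD of the group-mean deviation matrix.
mc_core <- function(X, labels) {
  counts <- table(labels)
  M <- rowsum(X, labels)
  M <- M[levels(labels), , drop = FALSE] /
    as.vector(counts[levels(labels)])
  D <- sweep(M, 2, colMeans(M)) # grand mean = unweighted mean of group means
  sv <- svd(D)
  L <- min(nrow(D), ncol(D))
  u <- sv$u[, seq_len(L), drop = FALSE]
  v <- sv$v[, seq_len(L), drop = FALSE]
  # Orient each LV so the first group loads positively (the "first group >
  # second group" reading of the contrast, e.g. ASD > TD).
  for (l in seq_len(L)) {
    if (u[1, l] < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  rownames(u) <- rownames(M)
  rownames(v) <- colnames(X)
  list(sigma = sv$d[seq_len(L)], u = u, v = v)
}

# Fast first singular value for the two-group case.
mc_sigma1_2g <- function(X, g1_rows) {
  d <- colMeans(X[g1_rows, , drop = FALSE]) -
    colMeans(X[-g1_rows, , drop = FALSE])
  sqrt(sum(d^2) / 2)
}

new_pls_result <- function(...) {
  structure(list(...), class = "pls_result")
}

#' Mean-centered partial least squares
#'
#' Builds the groups x features matrix of column means, subtracts the grand
#' mean (the unweighted mean of group means), and applies singular value
#' decomposition. Each latent variable (LV) couples a design salience vector
#' (the data-driven group contrast) with a unit-norm brain salience vector.
#' For two groups the decomposition has exactly one non-zero singular value
#' and the brain saliences are proportional to the difference of group means,
#' oriented as first group > second group.
#'
#' Significance is assessed by permuting group labels across observations
#' (`n_perm` times) and comparing each permuted singular value with the
#' observed one; the p-value uses the add-one smoothed estimator
#' \eqn{(1 + \#\{\sigma_{perm} \ge \sigma_{obs}\}) / (1 + n_{perm})}.
#' Reliability of each feature is assessed by bootstrap resampling of
#' observations within group: each resample's saliences are sign-aligned to
#' the original by dot product and the bootstrap ratio (z-score) is the
#' original salience divided by the bootstrap standard error.
#'
#' Note that when observations are subsamples sharing a subject pool, label
#' permutation at the observation level does not see the pool-level sampling
#' variance; [run_group_pls()] therefore permutes subjects instead.
#'
#' @param X observations x features matrix.
#' @param labels group label per observation (2 or more groups, at least 2
#'   observations each).
#' @param n_perm label permutations (0 skips the permutation test).
#' @param n_boot bootstrap resamples (0 skips the bootstrap).
#' @param seed integer seed for both resampling loops.
#' @return A `pls_result` with `singular_values`, `p_perm`,
#'   `brain_saliences`, `design_saliences`, `bootstrap_ratios`, and the run
#'   parameters.
#' @export
mean_centered_pls <- function(X, labels, n_perm = 1000, n_boot = 1000,
                              seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two groups")
  if (any(table(labels) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) {
    warning(sum(csd == 0), " constant feature(s); their saliences are 0")
  }
  obs <- mc_core(X, labels)
  L <- length(obs$sigma)
  two_groups <- nlevels(labels) == 2L
  with_seed(seed, {
    p_perm <- rep(NA_real_, L)
    if (n_perm > 0) {
      exceed <- numeric(L)
      for (b in seq_len(n_perm)) {
        lp <- sample(labels)
        if (two_groups) {
          s1 <- mc_sigma1_2g(X, which(lp == levels(labels)[1]))
          sp <- c(s1, rep(0, L - 1L))
        } else {
          sp <- mc_core(X, lp)$sigma
        }
        exceed <- exceed + (sp >= obs$sigma - 1e-12)
      }
      p_perm <- (1 + exceed) / (1 + n_perm)
    }
    z <- NULL
    boot_se <- NULL
    if (n_boot > 0) {
      idx_by_group <- split(seq_len(nrow(X)), labels)
      acc <- array(0, c(nrow(obs$v), L, 2)) # running sum and sum of squares
      for (b in seq_len(n_boot)) {
        idx <- unlist(lapply(idx_by_group, function(ii) {
          sample(ii, length(ii), replace = TRUE)
        }), use.names = FALSE)
        vb <- mc_core(X[idx, , drop = FALSE], labels[idx])$v
        sg <- sign(colSums(vb * obs$v))
        sg[sg == 0] <- 1
        vb <- sweep(vb, 2, sg, "*")
        acc[, , 1] <- acc[, , 1] + vb
        acc[, , 2] <- acc[, , 2] + vb^2
      }
      boot_se <- sqrt(pmax(0, acc[, , 2] / n_boot -
                             (acc[, , 1] / n_boot)^2) *
                        n_boot / max(1, n_boot - 1))
      z <- obs$v / boot_se
      z[boot_se == 0] <- NA_real_
      dimnames(z) <- dimnames(obs$v)
    }
    new_pls_result(
      mode = "mean_centered",
      singular_values = obs$sigma,
      p_perm = p_perm,
      brain_saliences = obs$v,
      design_saliences = obs$u,
      bootstrap_ratios = z,
      bootstrap_se = boot_se,
      groups = levels(labels),
      n_perm = n_perm, n_boot = n_boot, seed = seed,
      permutation = if (n_perm > 0) "rows" else "none"
    )
  })
}

#' Behavioral partial least squares
#'
#' Applies singular value decomposition to the behaviors x features
#' correlation matrix. Each LV couples a behavior salience vector (the LV
#' design over, e.g., ADOS subscores) with a unit-norm brain salience
#' vector; the overall correlation of each behavior with an LV is the
#' correlation between the LV-projected feature scores and that behavior.
#' The permutation test shuffles the row correspondence between `X` and `Y`;
#' the bootstrap resamples rows jointly, preserving correspondence.
#'
#' @param X observations x features matrix.
#' @param Y observations x behaviors matrix (non-constant columns).
#' @param n_perm,n_boot,seed as in [mean_centered_pls()].
#' @return A `pls_result` with `behavior_saliences` and
#'   `behavior_correlations` (behaviors x LVs) in place of design saliences.
#' @export
behavioral_pls <- function(X, Y, n_perm = 1000, n_boot = 1000, seed = NULL) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y need aligned rows")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite input")
  if (any(apply(Y, 2, sd) == 0)) stop("constant behavior column")
  const_x <- apply(X, 2, sd) == 0
  if (any(const_x)) {
    warning(sum(const_x), " constant feature(s); their saliences are 0")
  }
  n <- nrow(X)
  corr_mat <- function(Xm) {
    R <- suppressWarnings(cor(Y, Xm))
    R[!is.finite(R)] <- 0
    R
  }
  R0 <- corr_mat(X)
  sv <- svd(R0)
  L <- min(dim(R0))
  u <- sv$u[, seq_len(L), drop = FALSE]
  v <- sv$v[, seq_len(L), drop = FALSE]
  # Orient each LV so the brain saliences sum non-negatively. The LV-score
  # projection X %*% v is then a predominantly positively weighted feature
  # combination, so the sign of each reported behavior correlation carries
  # the direction of the raw brain-behavior association (e.g. negative when
  # higher symptom scores go with more negative curvature).
  for (l in seq_len(L)) {
    if (sum(v[, l]) < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  rownames(u) <- colnames(Y)
  rownames(v) <- colnames(X)
  sigma <- sv$d[seq_len(L)]
  scores <- X %*% v
  behav_cor <- suppressWarnings(cor(Y, scores))
  behav_cor[!is.finite(behav_cor)] <- 0
  with_seed(seed, {
    p_perm <- rep(NA_real_, L)
    if (n_perm > 0) {
      exceed <- numeric(L)
      for (b in seq_len(n_perm)) {
        sp <- svd(corr_mat(X[sample.int(n), , drop = FALSE]),
                  nu = 0, nv = 0)$d[seq_len(L)]
        exceed <- exceed + (sp >= sigma - 1e-12)
      }
      p_perm <- (1 + exceed) / (1 + n_perm)
    }
    z <- NULL
    boot_se <- NULL
    if (n_boot > 0) {
      sum1 <- matrix(0, nrow(v), L)
      sum2 <- matrix(0, nrow(v), L)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        Rb <- suppressWarnings(cor(Y[idx, , drop = FALSE],
                                   X[idx, , drop = FALSE]))
        Rb[!is.finite(Rb)] <- 0
        svb <- svd(Rb)
        vb <- svb$v[, seq_len(L), drop = FALSE]
        sg <- sign(colSums(vb * v))
        sg[sg == 0] <- 1
        vb <- sweep(vb, 2, sg, "*")
        sum1 <- sum1 + vb
        sum2 <- sum2 + vb^2
      }
      boot_se <- sqrt(pmax(0, sum2 / n_boot - (sum1 / n_boot)^2) *
                        n_boot / max(1, n_boot - 1))
      z <- v / boot_se
      z[boot_se == 0] <- NA_real_
      dimnames(z) <- dimnames(v)
    }
    new_pls_result(
      mode = "behavioral",
      singular_values = sigma,
      p_perm = p_perm,
      brain_saliences = v,
      behavior_saliences = u,
      behavior_correlations = behav_cor,
      bootstrap_ratios = z,
      bootstrap_se = boot_se,
      n_perm = n_perm, n_boot = n_boot, seed = seed,
      permutation = if (n_perm > 0) "rows" else "none"
    )
  })
}

#' @export
print.pls_result <- function(x, ...) {
  cat("PLS result (", x$mode, ")\n", sep = "")
  k <- min(3L, length(x$singular_values))
  for (l in seq_len(k)) {
    cat(sprintf("  LV%d: sigma = %.4g, p_perm = %s%s\n", l,
                x$singular_values[l],
                format.pval(x$p_perm[l]),
                if (!is.null(x$p_corrected) && l == 1L) {
                  paste0(" (corrected ", format.pval(x$p_corrected), ")")
                } else ""))
  }
  invisible(x)
}

#' @export
summary.pls_result <- function(object, lv = 1, ...) {
  z <- object$bootstrap_ratios
  cat("PLS (", object$mode, "), LV", lv, "\n", sep = "")
  cat("  sigma =", signif(object$singular_values[lv], 5),
      "; p_perm =", format.pval(object$p_perm[lv]), "\n")
  if (!is.null(object$p_corrected)) {
    cat("  corrected p =", format.pval(object$p_corrected), "\n")
  }
  if (!is.null(object$behavior_correlations)) {
    cat("  overall behavior correlations (LV", lv, "):\n")
    print(round(object$behavior_correlations[, lv], 3))
  }
  if (!is.null(z)) {
    zi <- z[, lv]
    top <- order(abs(zi), decreasing = TRUE)[seq_len(min(10, length(zi)))]
    cat("  largest |bootstrap ratios|:\n")
    print(round(zi[top], 2))
  }
  invisible(object)
}

#' @export
plot.pls_result <- function(x, lv = 1, ...) {
  z <- x$bootstrap_ratios
  if (is.null(z)) stop("no bootstrap ratios to plot")
  barplot(z[, lv], las = 2, cex.names = 0.5,
          ylab = paste0("bootstrap ratio (LV", lv, ")"), ...)
  invisible(x)
}

#' Group-difference PLS on subsampled trajectory shapes
#'
#' Stacks the two groups' subsample shape matrices as observations and runs
#' mean-centered PLS under the first-group > second-group contrast. The
#' permutation test is carried out at the *subject* level: each permutation
#' reassigns subjects across groups (without replacement), rebuilds every
#' subsample from the stored membership patterns, refits the shape
#' coefficients, and recomputes the first singular value. This respects the
#' fact that subsamples of one group share a subject pool; shuffling row
#' labels instead would ignore the pool-level sampling variance
#' (`permutation = "rows"` is available for comparison). Bootstrap ratios
#' resample subsample rows within group, as in [mean_centered_pls()]. The
#' reported corrected p applies a Bonferroni factor for the number of
#' parcellations analysed.
#'
#' @param asd_set,td_set fitted [fit_subsamples()] sets with identical
#'   feature layout.
#' @param ct harmonized thickness matrix (or per-degree list) covering both
#'   pools; required for subject-level permutation.
#' @param cohort cohort table covering both pools.
#' @param n_perm,n_boot,seed resampling controls.
#' @param n_parcellations Bonferroni factor (3 when all of HP, FSAP and MMP
#'   are analysed).
#' @param permutation `"subjects"` (default) or `"rows"`.
#' @return A `pls_result` with `p_corrected` and the permutation scheme
#'   recorded.
#' @export
run_group_pls <- function(asd_set, td_set, ct = NULL, cohort = NULL,
                          n_perm = 1000, n_boot = 1000, seed = NULL,
                          n_parcellations = 3,
                          permutation = c("subjects", "rows")) {
  permutation <- match.arg(permutation)
  stopifnot(inherits(asd_set, "subsample_set"),
            inherits(td_set, "subsample_set"))
  if (is.null(asd_set$shape_matrix) || is.null(td_set$shape_matrix)) {
    stop("run fit_subsamples() on both sets first")
  }
  if (!identical(colnames(asd_set$shape_matrix),
                 colnames(td_set$shape_matrix))) {
    stop("feature layout differs between groups")
  }
  if (asd_set$K < 2L || td_set$K < 2L) {
    stop("need at least 2 subsamples per group to bootstrap")
  }
  X <- rbind(asd_set$shape_matrix, td_set$shape_matrix)
  labels <- factor(rep(c(asd_set$group, td_set$group),
                       c(asd_set$K, td_set$K)),
                   levels = c(asd_set$group, td_set$group))
  res <- mean_centered_pls(
    X, labels,
    n_perm = if (permutation == "rows") n_perm else 0,
    n_boot = n_boot,
    seed = child_seed(seed %||% 0, "boot")
  )
  # Two-group mean-centering is a rank-1 contrast; assert it on every run.
  if (length(res$singular_values) > 1L &&
      res$singular_values[2] > 1e-8 * max(res$singular_values[1], 1e-300)) {
    stop("internal error: two-group decomposition is not rank 1")
  }
  if (permutation == "subjects" && n_perm > 0) {
    if (is.null(ct) || is.null(cohort)) {
      stop("subject-level permutation needs `ct` and `cohort`")
    }
    cts <- if (is.list(ct)) ct else list(ct, ct, ct)
    pool <- c(asd_set$pool_ids, td_set$pool_ids)
    if (anyDuplicated(pool)) stop("group pools overlap")
    ages <- cohort$age[match(pool, cohort$subject_id)]
    if (anyNA(ages)) stop("cohort is missing pool subjects")
    rois <- unique(attr(asd_set$shape_matrix, "roi"))
    Ys <- lapply(cts, function(m) m[pool, rois, drop = FALSE])
    # Rebuild the (ROI, degree) keep mask from the fitted feature layout.
    keep <- matrix(FALSE, length(rois), 3,
                   dimnames = list(rois, NULL))
    deg_of <- match(attr(asd_set$shape_matrix, "coefficient"),
                    c("slope", "curvature", "aberrancy"))
    keep[cbind(match(attr(asd_set$shape_matrix, "roi"), rois), deg_of)] <- TRUE
    nA <- length(asd_set$pool_ids)
    nP <- length(pool)
    kA <- asd_set$K
    sigma_obs <- res$singular_values[1]
    # Each permutation reassigns subjects across groups and re-runs the
    # entropy-guided subsample selection on the permuted pools, so permuted
    # statistics are produced by the identical procedure as the observed one.
    binA <- findInterval(ages, asd_set$bin_edges, rightmost.closed = TRUE)
    binB <- findInterval(ages, td_set$bin_edges, rightmost.closed = TRUE)
    nbA <- length(asd_set$bin_edges) - 1L
    nbB <- length(td_set$bin_edges) - 1L
    exceed <- 0L
    with_seed(child_seed(seed %||% 0, "perm"), {
      for (b in seq_len(n_perm)) {
        pm <- sample.int(nP)
        posA <- pm[seq_len(nA)]
        posB <- pm[(nA + 1L):nP]
        selA <- select_entropy_idx(binA[posA], asd_set$n, kA,
                                   asd_set$n_candidates %||% 2000, nbA)
        selB <- select_entropy_idx(binB[posB], td_set$n, td_set$K,
                                   td_set$n_candidates %||% 2000, nbB)
        gidx <- rbind(matrix(posA[selA$idx], kA),
                      matrix(posB[selB$idx], td_set$K))
        Xp <- shape_engine(ages, Ys[[1]], gidx,
                           mask = keep, Y_by_degree = Ys)
        s1 <- mc_sigma1_2g(Xp, seq_len(kA))
        if (s1 >= sigma_obs - 1e-12) exceed <- exceed + 1L
      }
    })
    res$p_perm <- (1 + exceed) / (1 + n_perm)
    res$n_perm <- n_perm
    res$permutation <- "subjects"
  }
  res$p_corrected <- min(1, res$p_perm[1] * n_parcellations)
  res$n_parcellations <- n_parcellations
  res$seed <- seed
  res
}

#' Behavioral PLS of ASD trajectory shapes against ADOS subscores
#'
#' Builds the subgroups x ROIs matrix of one shape coefficient from the ASD
#' subsample set and the subgroups x 3 matrix of mean ADOS subscores
#' (communication, social, stereotyped behavior) averaged over each
#' subsample's ADOS-complete members, then runs [behavioral_pls()].
#' Subgroups with fewer than `min_complete` ADOS-complete subjects are
#' dropped with a warning. The corrected p applies a Bonferroni factor for
#' the number of coefficient-by-parcellation analyses (six in the full
#' design: three coefficients times two parcellations).
#'
#' Because overlapping subgroups make both the coefficient rows and the
#' mean-ADOS rows mutually dependent through shared members, shuffling the
#' row correspondence would misalign that shared structure and overstate
#' significance. The permutation is therefore carried out at the subject
#' level (default): each permutation reassigns the ADOS records across the
#' pool's subjects, rebuilds the subgroup means over the unchanged
#' memberships, and recomputes the first singular value
#' (`permutation = "rows"` is available for comparison).
#'
#' @param asd_set fitted ASD [fit_subsamples()] set, drawn from
#'   ADOS-complete subjects.
#' @param cohort cohort table with ADOS columns.
#' @param coefficient which shape coefficient to relate to symptoms.
#' @param n_perm,n_boot,seed resampling controls.
#' @param n_analyses Bonferroni factor.
#' @param min_complete minimum ADOS-complete subjects per subgroup.
#' @param permutation `"subjects"` (default) or `"rows"`.
#' @return A `pls_result` with `p_corrected` and per-subscore overall
#'   correlations.
#' @export
run_behavioral_pls <- function(asd_set, cohort,
                               coefficient = c("curvature", "slope",
                                               "aberrancy"),
                               n_perm = 1000, n_boot = 1000, seed = NULL,
                               n_analyses = 6, min_complete = 3,
                               permutation = c("subjects", "rows")) {
  permutation <- match.arg(permutation)
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(asd_set, "subsample_set"))
  check_cohort(cohort, require_ados = TRUE)
  X <- shape_columns(asd_set, coefficient)
  ados <- cohort[match(asd_set$pool_ids, cohort$subject_id),
                 c("ados_comm", "ados_social", "ados_stereo")]
  complete <- stats::complete.cases(ados)
  Y <- matrix(NA_real_, asd_set$K, 3,
              dimnames = list(NULL, c("comm", "social", "stereo")))
  for (k in seq_len(asd_set$K)) {
    members <- asd_set$member_idx[k, ]
    ok <- members[complete[members]]
    if (length(ok) >= min_complete) {
      Y[k, ] <- colMeans(ados[ok, , drop = FALSE])
    }
  }
  keep <- stats::complete.cases(Y)
  if (!all(keep)) {
    warning(sum(!keep), " subgroup(s) dropped: fewer than ", min_complete,
            " ADOS-complete subjects")
  }
  if (sum(keep) < 3L) stop("too few subgroups with ADOS information")
  Xk <- X[keep, , drop = FALSE]
  Yk <- Y[keep, , drop = FALSE]
  res <- behavioral_pls(Xk, Yk,
                        n_perm = if (permutation == "rows") n_perm else 0,
                        n_boot = n_boot,
                        seed = child_seed(seed %||% 0, "boot"))
  if (permutation == "subjects" && n_perm > 0) {
    A <- as.matrix(ados)
    nP <- nrow(A)
    # membership indicator of the retained subgroups, for fast mean rebuilds
    M <- matrix(0, sum(keep), nP)
    for (j in seq_len(sum(keep))) {
      M[j, asd_set$member_idx[which(keep)[j], ]] <- 1
    }
    obs <- res$singular_values[1]
    L <- length(res$singular_values)
    exceed <- 0L
    with_seed(child_seed(seed %||% 0, "perm"), {
      for (b in seq_len(n_perm)) {
        Ap <- A[sample.int(nP), , drop = FALSE]
        ok <- !is.na(Ap)
        Yp <- (M %*% ifelse(ok, Ap, 0)) / (M %*% ok)
        good <- stats::complete.cases(Yp) & is.finite(rowSums(Yp))
        Rp <- suppressWarnings(cor(Yp[good, , drop = FALSE],
                                   Xk[good, , drop = FALSE]))
        Rp[!is.finite(Rp)] <- 0
        s1 <- svd(Rp, nu = 0, nv = 0)$d[1]
        if (s1 >= obs - 1e-12) exceed <- exceed + 1L
      }
    })
    res$p_perm <- c((1 + exceed) / (1 + n_perm), rep(NA_real_, L - 1L))
    res$n_perm <- n_perm
    res$permutation <- "subjects"
  }
  res$p_corrected <- min(1, res$p_perm[1] * n_analyses)
  res$n_analyses <- n_analyses
  res$coefficient <- coefficient
  res$seed <- seed
  res
}
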