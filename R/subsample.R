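# Entropy-guided subject subsampling.
#
# The shape coefficients are constants of a whole sample; to test them
# statistically the pipeline manufactures within-group variability by drawing
# many subject subsets, keeping those whose age distribution is most uniform
# (highest Shannon entropy of the age histogram), and fitting the three
# polynomial models to each retained subset.

#' Shannon entropy of an age histogram
#'
#' Ages are binned on `bin_edges` (default one-year bins on 6-30; internal
#' edges are right-open, the last bin closed) and the entropy
#' \eqn{-\sum_b p_b \ln p_b} of the normalized histogram is returned in nats.
#' Empty bins contribute zero. Entropy ranks are invariant to the logarithm
#' base, so only the binning matters for subsample selection.
#'
#' @param ages ages in years; must lie within the bin coverage.
#' @param bin_edges increasing vector of bin edges.
#' @return Entropy in nats.
#' @export
#' @examples
#' age_entropy(rep(12, 10))          # 0
#' age_entropy(6:29 + 0.5)           # log(24)
age_entropy <- function(ages, bin_edges = seq(6, 30, by = 1)) {
  if (!length(ages)) stop("need at least one age")
  if (min(ages) < bin_edges[1] || max(ages) > bin_edges[length(bin_edges)]) {
    stop("age outside bin coverage [", bin_edges[1], ", ",
         bin_edges[length(bin_edges)], "]")
  }
  bin <- findInterval(ages, bin_edges, rightmost.closed = TRUE)
  p <- tabulate(bin, nbins = length(bin_edges) - 1L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Draw candidate subsamples and keep the highest-entropy ones
#'
#' Draws `n_candidates` subject subsets of size `n` without replacement from
#' one group's pool, computes each subset's age-histogram entropy, and keeps
#' the `K` subsets with the highest entropy (ties broken by draw order;
#' duplicate subject sets across candidates are allowed). The full study used
#' 100,000 candidates and K = 80 subsamples of 70 subjects; the default
#' candidate count is a faster 2,000, with the one-center configuration using
#' n = 40 and K = 50.
#'
#' @param cohort_group cohort rows of a single group (the sampling pool).
#' @param n subjects per subsample.
#' @param n_candidates candidate draws.
#' @param K subsamples to keep (`K <= n_candidates`).
#' @param bin_edges age histogram bins for the entropy.
#' @param seed integer seed; fixes the draw sequence.
#' @return A `subsample_set` object: `subject_ids` (K x n), `member_idx`
#'   (K x n indices into the pool), `entropy` (nats, non-increasing),
#'   `pool_ids`, `group`, and slots filled later by [fit_subsamples()].
#' @export
draw_and_select <- function(cohort_group, n = 70, n_candidates = 2000,
                            K = 80, bin_edges = seq(6, 30, by = 1),
                            seed = NULL) {
  check_cohort(cohort_group)
  N <- nrow(cohort_group)
  if (N < n) {
    stop("group has ", N, " subjects but subsamples of ", n,
         " were requested; use a smaller `n` ",
         "(the one-center configuration uses n = 40, K = 50)")
  }
  if (K > n_candidates) stop("`K` cannot exceed `n_candidates`")
  grp <- unique(as.character(cohort_group$group))
  if (length(grp) > 1L) stop("`cohort_group` must contain a single group")
  bin_of <- findInterval(cohort_group$age, bin_edges, rightmost.closed = TRUE)
  if (any(bin_of < 1L | bin_of > length(bin_edges) - 1L)) {
    stop("age outside bin coverage")
  }
  nb <- length(bin_edges) - 1L
  with_seed(seed, {
    sel <- select_entropy_idx(bin_of, n, K, n_candidates, nb)
    structure(
      list(group = grp,
           subject_ids = matrix(cohort_group$subject_id[sel$idx], K, n),
           member_idx = sel$idx,
           entropy = sel$entropy,
           candidate_entropy = sel$candidate_entropy,
           pool_ids = cohort_group$subject_id,
           pool_ages = cohort_group$age,
           n = n, K = K, n_candidates = n_candidates, bin_edges = bin_edges,
           shape_matrix = NULL),
      class = "subsample_set"
    )
  })
}

# Draw `n_candidates` subsets of `n` from a pool described by its age-bin
# index vector; return the K highest-entropy index matrices. Shared by the
# observed selection and by subject-level permutations, so both follow the
# identical procedure.
select_entropy_idx <- function(bin_of, n, K, n_candidates, nb) {
  N <- length(bin_of)
  idx_mat <- matrix(0L, n_candidates, n)
  ent <- numeric(n_candidates)
  for (i in seq_len(n_candidates)) {
    idx <- sample.int(N, n)
    idx_mat[i, ] <- idx
    p <- tabulate(bin_of[idx], nbins = nb)
    p <- p[p > 0] / n
    ent[i] <- -sum(p * log(p))
  }
  keep <- order(ent, decreasing = TRUE, method = "radix")[seq_len(K)]
  list(idx = idx_mat[keep, , drop = FALSE], entropy = ent[keep],
       candidate_entropy = ent)
}

#' @export
print.subsample_set <- function(x, ...) {
  cat("Subsample set:", x$K, "subsamples of", x$n, x$group,
      "subjects (pool", length(x$pool_ids), ")\n")
  cat("  entropy range:", signif(min(x$entropy), 4), "-",
      signif(max(x$entropy), 4), "nats\n")
  if (!is.null(x$shape_matrix)) {
    cat("  shape matrix:", nrow(x$shape_matrix), "x",
        ncol(x$shape_matrix), "\n")
  }
  invisible(x)
}

# Core fitting engine: top polynomial coefficients for many subsamples.
#
# `ages` and `Y` are aligned to one pool; `idx_mat` is K x n of row indices;
# `ct_by_degree` optionally gives a distinct Y per degree (degree-specific
# harmonization). `mask` is an R x 3 logical matrix of (ROI, degree) cells to
# keep. Ages are shifted by -18 for conditioning; the leading coefficient is
# shift-invariant. Returns K x n_kept matrix plus per-column metadata.
shape_engine <- function(ages, Y, idx_mat, mask = NULL, Y_by_degree = NULL) {
  R <- ncol(Y)
  rois <- colnames(Y)
  if (is.null(mask)) {
    mask <- matrix(TRUE, R, 3)
  } else if (is.null(dim(mask))) {
    mask <- matrix(rep(as.logical(mask), 3), R, 3)
  }
  col_roi <- rep(seq_len(R), each = 3L)
  col_deg <- rep(1:3, R)
  keep_col <- mask[cbind(col_roi, col_deg)]
  K <- nrow(idx_mat)
  full <- matrix(NA_real_, K, 3L * R)
  P <- outer(ages - 18, 0:3, "^")
  # Degree-d cross-products are the leading blocks of the cubic ones, so one
  # crossprod per subsample (and per distinct thickness matrix) serves all
  # three degrees.
  same_y <- is.null(Y_by_degree) ||
    (identical(Y_by_degree[[1]], Y_by_degree[[2]]) &&
       identical(Y_by_degree[[2]], Y_by_degree[[3]]))
  k_cur <- 0L
  tryCatch({
    for (k in seq_len(K)) {
      k_cur <- k
      idx <- idx_mat[k, ]
      Xk <- P[idx, , drop = FALSE]
      XtX <- crossprod(Xk)
      if (same_y) {
        Yk <- if (is.null(Y_by_degree)) Y[idx, , drop = FALSE] else {
          Y_by_degree[[1]][idx, , drop = FALSE]
        }
        XtY <- crossprod(Xk, Yk)
        for (d in 1:3) {
          cols <- seq_len(d + 1L)
          b <- solve(XtX[cols, cols], XtY[cols, , drop = FALSE])
          full[k, (seq_len(R) - 1L) * 3L + d] <- b[d + 1L, ]
        }
      } else {
        for (d in 1:3) {
          cols <- seq_len(d + 1L)
          XtY <- crossprod(Xk[, cols, drop = FALSE],
                           Y_by_degree[[d]][idx, , drop = FALSE])
          b <- solve(XtX[cols, cols], XtY)
          full[k, (seq_len(R) - 1L) * 3L + d] <- b[d + 1L, ]
        }
      }
    }
  }, error = function(e) {
    stop("singular design in subsample ", k_cur, ": ", conditionMessage(e),
         call. = FALSE)
  })
  out <- full[, keep_col, drop = FALSE]
  coef_names <- c("slope", "curvature", "aberrancy")
  colnames(out) <- paste0(rois[col_roi[keep_col]], "_",
                          coef_names[col_deg[keep_col]])
  attr(out, "roi") <- rois[col_roi[keep_col]]
  attr(out, "coefficient") <- coef_names[col_deg[keep_col]]
  out
}

#' Fit the three polynomial models to every subsample
#'
#' For each retained subsample and each unmasked (ROI, degree) cell, fits the
#' degree-d polynomial to that subsample's subjects and stores the shape
#' coefficient (slope, curvature, aberrancy). Columns are ROI-major: for each
#' kept ROI, slope then curvature then aberrancy (cells masked at some degree
#' are omitted); column metadata is carried in the `"roi"` and
#' `"coefficient"` attributes of the shape matrix.
#'
#' @param set a [draw_and_select()] result.
#' @param ct harmonized thickness matrix covering the pool subjects, or a
#'   list of three matrices (one per degree) when degree-specific
#'   harmonization is used.
#' @param cohort cohort table (for ages).
#' @param mask optional [fdr_mask()] logical vector (same keep decision at
#'   all degrees) or an R x 3 logical matrix of per-degree keeps.
#' @return The set with `shape_matrix` filled.
#' @export
fit_subsamples <- function(set, ct, cohort, mask = NULL) {
  stopifnot(inherits(set, "subsample_set"))
  check_cohort(cohort)
  cts <- if (is.list(ct)) ct else list(ct, ct, ct)
  if (length(cts) != 3L) stop("`ct` list must have one matrix per degree")
  pool <- set$pool_ids
  if (!all(pool %in% cohort$subject_id)) {
    stop("cohort is missing pool subjects")
  }
  ages <- cohort$age[match(pool, cohort$subject_id)]
  Ys <- lapply(cts, function(m) {
    check_ct(m)
    m[pool, , drop = FALSE]
  })
  keep_mask <- NULL
  if (!is.null(mask)) {
    keep_mask <- if (is.null(dim(mask))) {
      matrix(rep(as.logical(mask), 3), ncol(Ys[[1]]), 3)
    } else {
      as.matrix(mask)
    }
  }
  set$shape_matrix <- shape_engine(ages, Ys[[1]], set$member_idx,
                                   mask = keep_mask, Y_by_degree = Ys)
  set
}

# Extract the columns of one shape coefficient from a fitted set.
shape_columns <- function(set, coefficient) {
  stopifnot(inherits(set, "subsample_set"), !is.null(set$shape_matrix))
  coefficient <- match.arg(coefficient, c("slope", "curvature", "aberrancy"))
  sel <- attr(set$shape_matrix, "coefficient") == coefficient
  out <- set$shape_matrix[, sel, drop = FALSE]
  colnames(out) <- attr(set$shape_matrix, "roi")[sel]
  out
}
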