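# Linear-SVM classification of developmental trajectory shapes under the
# split-then-subsample cross-validation scheme: subjects are halved within
# group x 2-year age bins, each half is subsampled independently, and the
# classifier is trained on one half's subgroup shape coefficients and
# evaluated on the other's.

#' Split a cohort into age-stratified train and test halves
#'
#' Within each group and 2-year age bin the subjects are randomly split in
#' two; an odd subject goes to train or test with probability one half,
#' independently per bin. Splitting is independent across groups; empty bins
#' are skipped.
#'
#' @param cohort cohort table.
#' @param bin_width age bin width in years.
#' @param seed integer seed.
#' @param age_range binning range.
#' @return List with `train` and `test` cohort tables (disjoint subjects).
#' @export
stratified_age_split <- function(cohort, bin_width = 2, seed = NULL,
                                 age_range = c(6, 30)) {
  check_cohort(cohort)
  if (!any(cohort$group == "ASD") || !any(cohort$group == "TD")) {
    stop("both groups must be non-empty")
  }
  edges <- seq(age_range[1], age_range[2], by = bin_width)
  bin <- findInterval(cohort$age, edges, rightmost.closed = TRUE)
  with_seed(seed, {
    to_train <- logical(nrow(cohort))
    for (g in c("ASD", "TD")) {
      for (b in unique(bin[cohort$group == g])) {
        rows <- which(cohort$group == g & bin == b)
        m <- length(rows)
        if (m == 0L) next
        n_train <- floor(m / 2) + if (m %% 2 == 1L) rbinom(1, 1, 0.5) else 0L
        picked <- if (n_train > 0) sample(rows, n_train) else integer(0)
        to_train[picked] <- TRUE
      }
    }
    train <- cohort[to_train, , drop = FALSE]
    test <- cohort[!to_train, , drop = FALSE]
    rownames(train) <- rownames(test) <- NULL
    list(train = train, test = test)
  })
}

#' Train and evaluate a linear SVM on subgroup shape coefficients
#'
#' Trains a linear-kernel support vector machine (unit box penalty, no
#' feature standardization — the stated defaults of the original tooling) on
#' the training halves' subgroup rows of one shape coefficient and evaluates
#' on the test halves' rows. With balanced test classes the accuracy equals
#' the mean of sensitivity and specificity.
#'
#' @param train_asd,train_td,test_asd,test_td fitted [fit_subsamples()] sets;
#'   train and test sets must come from disjoint subject halves.
#' @param coefficient `"slope"`, `"curvature"` or `"aberrancy"`.
#' @return Named vector: `accuracy`, `sensitivity` (ASD recall) and
#'   `specificity` (TD recall), in percent.
#' @export
train_eval_svm <- function(train_asd, train_td, test_asd, test_td,
                           coefficient) {
  xtr <- rbind(shape_columns(train_asd, coefficient),
               shape_columns(train_td, coefficient))
  xte <- rbind(shape_columns(test_asd, coefficient),
               shape_columns(test_td, coefficient))
  if (!identical(colnames(xtr), colnames(xte))) {
    stop("feature mismatch between train and test shape matrices")
  }
  ytr <- factor(rep(c("ASD", "TD"), c(train_asd$K, train_td$K)))
  yte <- factor(rep(c("ASD", "TD"), c(test_asd$K, test_td$K)))
  fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", cost = 1,
                    scale = FALSE)
  pred <- predict(fit, xte)
  c(accuracy = 100 * mean(pred == yte),
    sensitivity = 100 * mean(pred[yte == "ASD"] == "ASD"),
    specificity = 100 * mean(pred[yte == "TD"] == "TD"))
}

#' Repeated split-then-subsample cross-validation
#'
#' Repeats, `n_repeats` times with independent child seeds: age-stratified
#' half split, entropy-guided subsampling of each half and group, shape
#' fitting, SVM training on the train half, and evaluation on the test half.
#' Train and test subject sets are verified disjoint in every repeat. The
#' per-repeat subgroup-mean ADOS (ASD test half) and number of females (test
#' half) are recorded for covariate checks.
#'
#' @param cohort preprocessed cohort.
#' @param ct harmonized thickness matrix (or per-degree list).
#' @param coefficient shape coefficient used as features.
#' @param n_repeats cross-validation repeats (500 at full scale).
#' @param seed master seed; repeat r uses child seeds derived from it.
#' @param n_per_subsample,K,n_candidates,bin_edges subsampling controls per
#'   half and group.
#' @param split_bin_width age bin width of the half split.
#' @param mask optional goodness-of-fit mask (see [fit_subsamples()]).
#' @return A `classification_report`: per-repeat `metrics` (percent),
#'   per-repeat `covariates`, and run metadata.
#' @export
cross_validate <- function(cohort, ct, coefficient, n_repeats = 500,
                           seed = NULL, n_per_subsample = 70, K = 80,
                           n_candidates = 2000,
                           bin_edges = seq(6, 30, by = 1),
                           split_bin_width = 2, mask = NULL) {
  check_cohort(cohort)
  seed <- seed %||% 0
  metrics <- matrix(NA_real_, n_repeats, 3,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity")))
  covars <- matrix(NA_real_, n_repeats, 2,
                   dimnames = list(NULL, c("mean_ados", "n_females")))
  for (r in seq_len(n_repeats)) {
    res <- tryCatch({
      halves <- stratified_age_split(cohort, bin_width = split_bin_width,
                                     seed = child_seed(seed, 10L * r + 1L))
      stopifnot(length(intersect(halves$train$subject_id,
                                 halves$test$subject_id)) == 0L)
      sets <- list()
      half_names <- c("train", "test")
      for (h in 1:2) {
        for (g in c("ASD", "TD")) {
          pool <- halves[[h]][halves[[h]]$group == g, , drop = FALSE]
          set <- draw_and_select(pool, n = n_per_subsample,
                                 n_candidates = n_candidates, K = K,
                                 bin_edges = bin_edges,
                                 seed = child_seed(seed, 10L * r + 2L * h +
                                                     (g == "TD")))
          sets[[paste(half_names[h], g, sep = "_")]] <-
            fit_subsamples(set, ct, cohort, mask = mask)
        }
      }
      m <- train_eval_svm(sets$train_ASD, sets$train_TD,
                          sets$test_ASD, sets$test_TD, coefficient)
      test_asd <- halves$test[halves$test$group == "ASD", , drop = FALSE]
      ados_cols <- c("ados_comm", "ados_social", "ados_stereo")
      have_ados <- all(ados_cols %in% names(test_asd)) &&
        any(stats::complete.cases(test_asd[ados_cols]))
      list(m = m,
           mean_ados = if (have_ados) {
             mean(rowMeans(test_asd[ados_cols]), na.rm = TRUE)
           } else NA_real_,
           n_fem = sum(halves$test$sex == "F"))
    }, error = function(e) {
      stop("cross-validation repeat ", r, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    metrics[r, ] <- res$m
    covars[r, ] <- c(res$mean_ados, res$n_fem)
  }
  structure(
    list(metrics = as.data.frame(metrics),
         covariates = as.data.frame(covars),
         coefficient = coefficient, n_repeats = n_repeats, seed = seed),
    class = "classification_report"
  )
}

#' @export
summary.classification_report <- function(object, ...) {
  s <- t(vapply(object$metrics, function(v) {
    c(mean = mean(v), sd = sd(v),
      ci5 = unname(quantile(v, 0.05)), ci95 = unname(quantile(v, 0.95)))
  }, numeric(4)))
  as.data.frame(s)
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report (", x$coefficient, " features, ",
      x$n_repeats, " repeats)\n", sep = "")
  print(round(summary(x), 2))
  invisible(x)
}

#' Pairwise comparison of classification models
#'
#' Two-sample t-tests (equal variance, as in a standard independent t-test)
#' of each metric between every pair of coefficient models, with
#' Benjamini-Hochberg correction across all comparisons of the table.
#'
#' @param reports named list of two or more `classification_report`s with
#'   equal `n_repeats`.
#' @param q significance level on the adjusted p-values.
#' @return Data frame with one row per model pair and metric: means, t,
#'   raw and adjusted p, significance flag, and the direction of the
#'   difference.
#' @export
compare_models <- function(reports, q = 0.05) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  if (is.null(names(reports))) {
    names(reports) <- vapply(reports, `[[`, "", "coefficient")
  }
  n_rep <- vapply(reports, `[[`, 0, "n_repeats")
  if (length(unique(n_rep)) != 1L) stop("reports differ in n_repeats")
  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    for (metric in c("accuracy", "sensitivity", "specificity")) {
      a <- reports[[pr[1]]]$metrics[[metric]]
      b <- reports[[pr[2]]]$metrics[[metric]]
      tt <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
        list(statistic = c(t = 0), p.value = 1)
      } else {
        t.test(a, b, var.equal = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model_a = pr[1], model_b = pr[2], metric = metric,
        mean_a = mean(a), mean_b = mean(b),
        t = unname(tt$statistic), p = tt$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr < q
  out$direction <- ifelse(!out$significant, "x",
                          ifelse(out$mean_a > out$mean_b, "a>b", "a<b"))
  out
}

#' Correlate classification metrics with per-repeat covariates
#'
#' Pearson correlation (with p-value) of every metric against every recorded
#' covariate (subgroup-mean ADOS and number of females). A constant
#' covariate is an error: its correlation is undefined.
#'
#' @param report a `classification_report`.
#' @return Data frame with one row per metric x covariate.
#' @export
metric_covariate_correlations <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  rows <- list()
  for (cv in names(report$covariates)) {
    x <- report$covariates[[cv]]
    x_ok <- x[is.finite(x)]
    if (length(x_ok) < 3L || sd(x_ok) == 0) {
      stop("covariate '", cv, "' is constant or too sparse to correlate")
    }
    for (metric in names(report$metrics)) {
      y <- report$metrics[[metric]]
      ok <- is.finite(x) & is.finite(y)
      ct <- cor.test(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, metric = metric,
        r = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
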