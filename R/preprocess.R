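# Cohort filters and the per-center thickness outlier screen.

#' Restrict a cohort to a closed age window
#'
#' Boundary ages are retained (the window is a closed interval). Applying the
#' filter twice equals applying it once.
#'
#' @param cohort cohort table.
#' @param min_age,max_age window bounds in years.
#' @return The filtered cohort.
#' @export
filter_age <- function(cohort, min_age = 6, max_age = 30) {
  check_cohort(cohort)
  keep <- cohort$age >= min_age & cohort$age <= max_age
  if (!any(keep)) stop("no subjects left after the age filter")
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop centers that are too small in either group
#'
#' A center is retained only when it contributes at least `min_per_group`
#' subjects in both diagnostic groups; all subjects of dropped centers are
#' removed. This is required for the center-effect regression to be
#' estimable with useful precision.
#'
#' @param cohort cohort table.
#' @param min_per_group minimum subjects per group per center.
#' @return The filtered cohort.
#' @export
filter_small_centers <- function(cohort, min_per_group = 10) {
  check_cohort(cohort)
  tab <- table(cohort$center, factor(cohort$group, levels = c("ASD", "TD")))
  ok <- rownames(tab)[apply(tab >= min_per_group, 1, all)]
  if (!length(ok)) stop("no center has >= ", min_per_group,
                        " subjects in both groups")
  out <- cohort[cohort$center %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove subjects with extreme thickness values within their center
#'
#' For every center and ROI, thickness values are z-scored across that
#' center's subjects (both groups pooled), once, on the original data. A
#' subject is removed when any ROI's |z| exceeds `threshold`. ROIs with zero
#' within-center variance get z = 0 (logged via a message). This screens for
#' segmentation failures that survive visual quality control.
#'
#' @param ct subjects x ROIs thickness matrix.
#' @param cohort cohort aligned with `ct`.
#' @param threshold |z| cut-off.
#' @param log_path optional CSV path receiving the removed subject IDs for
#'   audit.
#' @return A list with the filtered `ct` and `cohort` plus `removed_ids`.
#' @export
zscore_outlier_filter <- function(ct, cohort, threshold = 3,
                                  log_path = NULL) {
  check_cohort(cohort)
  check_ct(ct, cohort)
  ct <- ct[cohort$subject_id, , drop = FALSE]
  removed <- character(0)
  for (ctr in unique(cohort$center)) {
    ids <- cohort$subject_id[cohort$center == ctr]
    if (length(ids) < 2L) {
      stop("center ", ctr, " has fewer than 2 subjects; cannot z-score")
    }
    sub <- ct[ids, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    zero_var <- sdv == 0
    if (any(zero_var)) {
      message(sprintf("center %s: %d ROI(s) with zero variance; z set to 0",
                      ctr, sum(zero_var)))
      sdv[zero_var] <- Inf # any deviation is 0/Inf = 0... values equal anyway
    }
    z <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
    out <- ids[apply(abs(z) > threshold, 1, any)]
    removed <- c(removed, out)
  }
  if (!is.null(log_path)) {
    write.csv(data.frame(SUB_ID = removed), log_path, row.names = FALSE,
              quote = FALSE)
  }
  keep <- !(cohort$subject_id %in% removed)
  cohort_out <- cohort[keep, , drop = FALSE]
  rownames(cohort_out) <- NULL
  parc <- attr(ct, "parcellation")
  ct_out <- ct[cohort_out$subject_id, , drop = FALSE]
  attr(ct_out, "parcellation") <- parc
  list(ct = ct_out, cohort = cohort_out, removed_ids = removed)
}
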