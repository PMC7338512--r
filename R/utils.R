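# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Multi-stage runs draw one child seed per stage from the master seed with a
#' fixed multiplicative-congruential scheme, so every stage is individually
#' reproducible. Character stage names are hashed to an integer first. The
#' result always lies in `[0, 2^31 - 20)`.
#'
#' @param master integer master seed.
#' @param stage integer stage index or character stage name.
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, 1)
#' child_seed(42, "subsample")
child_seed <- function(master, stage) {
  if (is.character(stage)) {
    codes <- utf8ToInt(stage)
    stage <- sum(codes * ((seq_along(codes) - 1L) %% 11L + 1L))
  }
  m <- 2147483629 # largest prime below 2^31
  s <- ((as.double(master) %% m) * 48271 + (as.double(stage) %% m) * 9973) %% m
  as.integer(s)
}

# Stop unless `x` is a cohort-like data frame with required columns.
check_cohort <- function(cohort, require_ados = FALSE) {
  if (!is.data.frame(cohort)) {
    stop("`cohort` must be a data frame", call. = FALSE)
  }
  needed <- c("subject_id", "group", "age", "sex", "center")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$subject_id)) {
    stop("duplicate subject_id in cohort", call. = FALSE)
  }
  if (!all(is.finite(cohort$age))) {
    stop("non-finite ages in cohort", call. = FALSE)
  }
  if (require_ados &&
      !all(c("ados_comm", "ados_social", "ados_stereo") %in% names(cohort))) {
    stop("cohort lacks ADOS columns", call. = FALSE)
  }
  invisible(cohort)
}

# Stop unless `ct` is a numeric subjects x ROIs matrix aligned with `cohort`.
check_ct <- function(ct, cohort = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix (subjects x ROIs)", call. = FALSE)
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("`ct` must carry subject row names and ROI column names",
         call. = FALSE)
  }
  if (!all(is.finite(ct))) {
    stop("`ct` contains non-finite values", call. = FALSE)
  }
  if (!is.null(cohort) && !all(cohort$subject_id %in% rownames(ct))) {
    stop("`ct` is missing rows for some cohort subjects", call. = FALSE)
  }
  invisible(ct)
}

# Full-precision numeric formatting for lossless CSV round trips.
fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}
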