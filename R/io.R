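# Readers and writers for phenotype tables, thickness tables, run
# configuration, and result serialization. The CSV dialect mirrors ABIDE
# phenotypic naming (SUB_ID, DX_GROUP, AGE_AT_SCAN, SEX, SITE_ID, ADOS_*).

PARCELLATION_SIZES <- c(HP = 2L, FSAP = 68L, MMP = 360L)

#' Number of ROIs of a named parcellation
#'
#' @param parcellation one of `"HP"` (2 ROIs), `"FSAP"` (68), `"MMP"` (360)
#'   or `"custom"` (any).
#' @return Integer ROI count, or `NA` for `"custom"`.
#' @export
parcellation_size <- function(parcellation) {
  if (parcellation %in% names(PARCELLATION_SIZES)) {
    PARCELLATION_SIZES[[parcellation]]
  } else {
    NA_integer_
  }
}

#' Read a phenotype table
#'
#' Reads an ABIDE-dialect phenotype CSV into a cohort table. Diagnostic codes
#' are mapped through `dx_codes` (numeric DX_GROUP codes are a repository
#' convention, not part of the format, so the mapping is data and lives in the
#' run configuration); literal `ASD`/`TD` values pass through unchanged.
#' Negative ADOS sentinels (for example -9999) are treated as missing.
#'
#' @param path CSV file with columns `SUB_ID`, `DX_GROUP`, `AGE_AT_SCAN`,
#'   `SEX`, `SITE_ID` and optionally `ADOS_COMM`, `ADOS_SOCIAL`,
#'   `ADOS_STEREO`.
#' @param dx_codes named character vector mapping DX_GROUP codes to group
#'   labels; the default follows the ABIDE convention 1 = ASD, 2 = TD.
#' @return A cohort data frame (see [generate_cohort()]; no `severity`
#'   column).
#' @export
read_phenotypes <- function(path, dx_codes = c("1" = "ASD", "2" = "TD")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("SUB_ID", "DX_GROUP", "AGE_AT_SCAN", "SEX", "SITE_ID")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("phenotype file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$SUB_ID)) {
    stop("duplicate SUB_ID in phenotype file: ",
         paste(unique(raw$SUB_ID[duplicated(raw$SUB_ID)]), collapse = ", "))
  }
  dx <- as.character(raw$DX_GROUP)
  mapped <- ifelse(dx %in% c("ASD", "TD"), dx, unname(dx_codes[dx]))
  if (anyNA(mapped)) {
    stop("unmapped DX_GROUP code(s): ",
         paste(unique(dx[is.na(mapped)]), collapse = ", "))
  }
  ados <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- as.numeric(raw[[col]])
    v[!is.na(v) & v < 0] <- NA_real_
    v
  }
  data.frame(
    subject_id = as.character(raw$SUB_ID),
    group = factor(mapped, levels = c("ASD", "TD")),
    age = as.numeric(raw$AGE_AT_SCAN),
    sex = factor(as.character(raw$SEX), levels = c("M", "F")),
    center = as.character(raw$SITE_ID),
    ados_comm = ados("ADOS_COMM"),
    ados_social = ados("ADOS_SOCIAL"),
    ados_stereo = ados("ADOS_STEREO"),
    stringsAsFactors = FALSE
  )
}

#' Write a phenotype table
#'
#' Writes the ABIDE-dialect columns at full numeric precision so that
#' write-then-read reproduces the cohort exactly. Missing ADOS scores become
#' empty cells; the generator-internal `severity` column is not serialized.
#'
#' @param cohort a cohort data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  check_cohort(cohort)
  out <- data.frame(
    SUB_ID = cohort$subject_id,
    DX_GROUP = as.character(cohort$group),
    AGE_AT_SCAN = fmt_full(cohort$age),
    SEX = as.character(cohort$sex),
    SITE_ID = cohort$center,
    ADOS_COMM = fmt_full(cohort$ados_comm %||% rep(NA_real_, nrow(cohort))),
    ADOS_SOCIAL = fmt_full(cohort$ados_social %||% rep(NA_real_, nrow(cohort))),
    ADOS_STEREO = fmt_full(cohort$ados_stereo %||% rep(NA_real_, nrow(cohort))),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cortical-thickness table
#'
#' Reads a wide CSV/TSV (first column `SUB_ID`, one numeric column per ROI)
#' into a subjects x ROIs matrix. The ROI count is validated against the
#' declared parcellation; a non-numeric cell is reported with its row and
#' column.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param parcellation declared parcellation (`"HP"`, `"FSAP"`, `"MMP"`, or
#'   `"custom"` to accept any ROI count).
#' @return A numeric matrix with subject row names, ROI column names, and a
#'   `"parcellation"` attribute.
#' @export
read_ct <- function(path, parcellation = "custom") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  if (names(raw)[1] != "SUB_ID") {
    stop("first column of a CT table must be SUB_ID")
  }
  if (anyDuplicated(raw$SUB_ID)) stop("duplicate SUB_ID in CT file")
  n_roi <- ncol(raw) - 1L
  expected <- parcellation_size(parcellation)
  if (!is.na(expected) && n_roi != expected) {
    stop(sprintf("parcellation %s expects %d ROIs but the file has %d",
                 parcellation, expected, n_roi))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric CT value '%s' at row %d, column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(vals)[bad[1, 2]]))
  }
  if (anyNA(num)) {
    stop("CT table has missing cells (first at row ",
         which(is.na(num), arr.ind = TRUE)[1, 1], ")")
  }
  dimnames(num) <- list(raw$SUB_ID, colnames(vals))
  attr(num, "parcellation") <- parcellation
  num
}

#' Write a cortical-thickness table
#'
#' @param ct subjects x ROIs matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(ct, path) {
  check_ct(ct)
  out <- data.frame(SUB_ID = rownames(ct),
                    apply(ct, 2, fmt_full),
                    stringsAsFactors = FALSE, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Align phenotype and thickness tables on shared subjects
#'
#' Subjects present in only one table are reported (message with counts) and
#' dropped.
#'
#' @param cohort cohort table.
#' @param ct thickness matrix.
#' @return List with aligned `cohort` and `ct` plus the dropped ID vectors
#'   `dropped_phenotype_only` and `dropped_ct_only`.
#' @export
align_tables <- function(cohort, ct) {
  check_cohort(cohort)
  common <- intersect(cohort$subject_id, rownames(ct))
  if (!length(common)) stop("no shared subjects between tables")
  only_ph <- setdiff(cohort$subject_id, common)
  only_ct <- setdiff(rownames(ct), common)
  if (length(only_ph) || length(only_ct)) {
    message(sprintf(
      "dropping %d subject(s) present only in phenotypes and %d only in CT",
      length(only_ph), length(only_ct)))
  }
  cohort <- cohort[match(common, cohort$subject_id), , drop = FALSE]
  rownames(cohort) <- NULL
  parc <- attr(ct, "parcellation")
  ct <- ct[common, , drop = FALSE]
  attr(ct, "parcellation") <- parc
  list(cohort = cohort, ct = ct,
       dropped_phenotype_only = only_ph, dropped_ct_only = only_ct)
}

#' Serialize a results list to JSON
#'
#' Numeric values are written at full precision; PLS z-score vectors keep
#' their ROI names as JSON keys.
#'
#' @param results a (possibly nested) list of results.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
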