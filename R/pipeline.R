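# End-to-end orchestration: configuration, seed management, stage ordering,
# and result serialization.

#' Default run configuration
#'
#' Returns the full configuration list consumed by [run_all()], with the
#' full-scale analysis settings: degrees 1-3, 70-subject subsamples from
#' 100,000 candidates keeping the 80 of highest age entropy, 10,000
#' permutations and bootstraps for PLS, behavioral PLS on 400 subgroups of
#' 20 ADOS-complete subjects, 500 cross-validation repeats, and the
#' both-groups FDR masking rule. `subsample$candidates` is the main knob for
#' fast runs. A `single_center` block (center name, n = 40, K = 50)
#' restricts the analysis to one acquisition site.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    parcellation = "custom",
    degrees = 1:3,
    dx_codes = list(`1` = "ASD", `2` = "TD"),
    preprocess = list(min_age = 6, max_age = 30, min_per_group = 10,
                      z_threshold = 3),
    mask_rule = "both_groups",
    fdr_q = 0.05,
    subsample = list(n = 70, candidates = 100000, K = 80, bin_width = 1),
    pls = list(n_perm = 10000, n_boot = 10000, n_parcellations = 3),
    behavioral = list(n = 20, K = 400, n_analyses = 6),
    classify = list(repeats = 500, bin_width = 2, candidates = 2000),
    single_center = NULL,
    seeds = list(master = 1)
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file.
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # keep bare `n`/`y` as strings (YAML 1.1 would read them as booleans,
  # clobbering the `n:` subsample-size key)
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x
  )
  user <- yaml::read_yaml(path, handlers = handlers)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    base
  }
  cfg <- merge_cfg(default_config(), user)
  counts <- c(cfg$subsample$n, cfg$subsample$candidates, cfg$subsample$K,
              cfg$pls$n_perm, cfg$pls$n_boot, cfg$classify$repeats)
  if (any(counts <= 0)) stop("all configuration counts must be positive")
  cfg
}

# Small stable content hash (FNV-1a over the deparsed configuration), so
# artifacts can be traced back to the exact settings that produced them.
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  h <- Reduce(function(a, b) (a * 31 + b) %% 2147483647,
              as.double(utf8ToInt(txt)), 0)
  sprintf("%08x", as.integer(h))
}

#' Run the full trajectory-shape analysis
#'
#' Executes the stages in pipeline order: read and align tables, age and
#' small-center filters, within-center z-score outlier screen, per-degree
#' center harmonization, full-group trajectory fits with deviance tests and
#' FDR masking, entropy-guided subsampling per group, group-difference PLS,
#' behavioral PLS per shape coefficient (when ADOS scores are present), and
#' (optionally) SVM classification. Every stage draws a child seed from the
#' configured master seed, so a rerun with the same inputs and configuration
#' is bit-identical.
#'
#' @param config configuration list (see [default_config()]).
#' @param phenotype_path,ct_path input CSV paths.
#' @param output_dir optional directory receiving `results.json`, subsample
#'   membership CSVs, and a plain-text run log.
#' @param run_classification set `FALSE` to skip the (slow) classification
#'   stage.
#' @return A results list with per-stage outputs, removal counts, the
#'   configuration hash and all child seeds.
#' @export
run_all <- function(config, phenotype_path, ct_path, output_dir = NULL,
                    run_classification = FALSE) {
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    paste0(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  master <- config$seeds$master
  stage_fail <- function(stage, e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         if (!is.null(output_dir)) paste0(" (see ", output_dir, "/run.log)"),
         call. = FALSE)
  }

  say("read: ", phenotype_path)
  dx <- unlist(config$dx_codes)
  inp <- tryCatch({
    cohort <- read_phenotypes(phenotype_path, dx_codes = dx)
    ct <- read_ct(ct_path, parcellation = config$parcellation)
    align_tables(cohort, ct)
  }, error = function(e) stage_fail("read", e))
  cohort <- inp$cohort
  ct <- inp$ct

  if (!is.null(config$single_center)) {
    keep <- cohort$center == config$single_center$center
    if (!any(keep)) stop("unknown center: ", config$single_center$center)
    cohort <- cohort[keep, , drop = FALSE]
    config$subsample$n <- config$single_center$n %||% 40
    config$subsample$K <- config$single_center$K %||% 50
    say("single-center mode: ", config$single_center$center,
        " (n = ", config$subsample$n, ", K = ", config$subsample$K, ")")
  }

  pre <- tryCatch({
    n0 <- nrow(cohort)
    cohort <- filter_age(cohort, config$preprocess$min_age,
                         config$preprocess$max_age)
    n_age <- n0 - nrow(cohort)
    if (is.null(config$single_center)) {
      cohort <- filter_small_centers(cohort, config$preprocess$min_per_group)
    }
    n_ctr <- n0 - n_age - nrow(cohort)
    flt <- zscore_outlier_filter(ct[cohort$subject_id, , drop = FALSE],
                                 cohort, config$preprocess$z_threshold)
    say("preprocess: removed ", n_age, " by age, ", n_ctr,
        " with small centers, ", length(flt$removed_ids), " outliers")
    flt
  }, error = function(e) stage_fail("preprocess", e))
  cohort <- pre$cohort
  ct <- pre$ct

  degrees <- config$degrees
  ct_by_degree <- tryCatch({
    out <- list()
    for (d in 1:3) {
      out[[d]] <- if (d %in% degrees) {
        remove_center_variance(ct, cohort, d)
      } else {
        ct
      }
    }
    say("harmonize: degree-specific center-variance removal done")
    out
  }, error = function(e) stage_fail("harmonize", e))

  fits <- tryCatch({
    rois <- colnames(ct)
    pmat <- array(NA_real_, c(length(rois), 2, 3),
                  dimnames = list(rois, c("ASD", "TD"), NULL))
    shapes <- array(NA_real_, c(length(rois), 2, 3),
                    dimnames = dimnames(pmat))
    for (d in degrees) {
      for (g in c("ASD", "TD")) {
        rows <- cohort$group == g
        for (roi in rois) {
          fit <- fit_trajectory(cohort$age[rows],
                                ct_by_degree[[d]][cohort$subject_id[rows],
                                                  roi],
                                degree = d, roi = roi, group = g)
          pmat[roi, g, d] <- deviance_test(fit)
          shapes[roi, g, d] <- fit$shape
        }
      }
    }
    say("trajectory: full-group fits and deviance tests done")
    list(pmat = pmat, shapes = shapes)
  }, error = function(e) stage_fail("trajectory", e))

  mask <- matrix(TRUE, ncol(ct), 3, dimnames = list(colnames(ct), NULL))
  for (d in degrees) {
    mask[, d] <- fdr_mask(fits$pmat[, , d], q = config$fdr_q,
                          rule = config$mask_rule)
  }
  say("mask: ", sum(mask[, degrees[1]]), "/", nrow(mask),
      " ROIs kept at degree ", degrees[1])

  sets <- tryCatch({
    out <- list()
    for (g in c("ASD", "TD")) {
      pool <- cohort[cohort$group == g, , drop = FALSE]
      set <- draw_and_select(
        pool, n = config$subsample$n,
        n_candidates = config$subsample$candidates, K = config$subsample$K,
        bin_edges = seq(config$preprocess$min_age, config$preprocess$max_age,
                        by = config$subsample$bin_width),
        seed = child_seed(master, paste0("subsample_", g))
      )
      out[[g]] <- fit_subsamples(set, ct_by_degree, cohort, mask = mask)
    }
    say("subsample: ", config$subsample$K, " subgroups of ",
        config$subsample$n, " per group")
    out
  }, error = function(e) stage_fail("subsample", e))

  group_pls <- tryCatch({
    res <- run_group_pls(
      sets$ASD, sets$TD, ct = ct_by_degree, cohort = cohort,
      n_perm = config$pls$n_perm, n_boot = config$pls$n_boot,
      seed = child_seed(master, "group_pls"),
      n_parcellations = config$pls$n_parcellations
    )
    say("group PLS: p = ", format.pval(res$p_perm[1]),
        " (corrected ", format.pval(res$p_corrected), ")")
    res
  }, error = function(e) stage_fail("group_pls", e))

  behavioral <- NULL
  asd_complete <- cohort$group == "ASD" &
    stats::complete.cases(cohort[c("ados_comm", "ados_social",
                                   "ados_stereo")])
  if (sum(asd_complete) >= config$behavioral$n) {
    behavioral <- tryCatch({
      pool <- cohort[asd_complete, , drop = FALSE]
      bset <- draw_and_select(
        pool, n = config$behavioral$n,
        n_candidates = config$subsample$candidates, K = config$behavioral$K,
        bin_edges = seq(config$preprocess$min_age, config$preprocess$max_age,
                        by = config$subsample$bin_width),
        seed = child_seed(master, "behavioral_subsample")
      )
      bset <- fit_subsamples(bset, ct_by_degree, cohort, mask = mask)
      out <- list()
      for (coefficient in c("slope", "curvature", "aberrancy")[degrees]) {
        out[[coefficient]] <- run_behavioral_pls(
          bset, cohort, coefficient = coefficient,
          n_perm = config$pls$n_perm, n_boot = config$pls$n_boot,
          seed = child_seed(master, paste0("behavioral_", coefficient)),
          n_analyses = config$behavioral$n_analyses
        )
        say("behavioral PLS (", coefficient, "): corrected p = ",
            format.pval(out[[coefficient]]$p_corrected))
      }
      out
    }, error = function(e) stage_fail("behavioral_pls", e))
  } else {
    say("behavioral PLS skipped: no (or too few) ADOS-complete subjects")
  }

  classification <- NULL
  if (isTRUE(run_classification)) {
    classification <- tryCatch({
      out <- list()
      for (coefficient in c("slope", "curvature", "aberrancy")[degrees]) {
        out[[coefficient]] <- cross_validate(
          cohort, ct_by_degree, coefficient,
          n_repeats = config$classify$repeats,
          seed = child_seed(master, paste0("classify_", coefficient)),
          n_per_subsample = config$subsample$n, K = config$subsample$K,
          n_candidates = config$classify$candidates,
          split_bin_width = config$classify$bin_width, mask = mask
        )
        say("classification (", coefficient, "): mean accuracy ",
            round(mean(out[[coefficient]]$metrics$accuracy), 1), "%")
      }
      out$comparison <- compare_models(out)
      out
    }, error = function(e) stage_fail("classify", e))
  }

  results <- list(
    config_hash = config_hash(config),
    seeds = list(master = master),
    n_subjects = nrow(cohort),
    removed_outliers = pre$removed_ids,
    mask = apply(mask, 2, sum),
    group_pls = list(
      p = group_pls$p_perm[1], p_corrected = group_pls$p_corrected,
      singular_value = group_pls$singular_values[1],
      z = as.list(stats::setNames(group_pls$bootstrap_ratios[, 1],
                                  rownames(group_pls$bootstrap_ratios)))
    ),
    behavioral = lapply(behavioral, function(r) {
      list(p = r$p_perm[1], p_corrected = r$p_corrected,
           correlations = as.list(stats::setNames(
             r$behavior_correlations[, 1],
             rownames(r$behavior_correlations))))
    }),
    classification = lapply(
      classification[setdiff(names(classification), "comparison")],
      function(r) as.list(summary(r))
    )
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(output_dir, "results.json"))
    for (g in names(sets)) {
      write.csv(as.data.frame(sets[[g]]$subject_ids),
                file.path(output_dir, paste0("subsamples_", g, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
    writeLines(log_lines, file.path(output_dir, "run.log"))
  }
  say("done")
  invisible(c(results, list(
    cohort = cohort, sets = sets, group_pls_full = group_pls,
    behavioral_full = behavioral, classification_full = classification
  )))
}
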