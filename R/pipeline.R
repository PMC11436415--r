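#' Data dictionary for participant-level input tables
#'
#' Column names, types and valid ranges for summary-mode participant
#' tables consumed by [validate_input()] and [score_summary()].
#'
#' @return data frame with columns `column`, `type`, `min`, `max`,
#'   `required`.
#' @export
mtd_data_dictionary <- function() {
  d <- function(column, type, min = NA, max = NA, required = TRUE) {
    data.frame(column = column, type = type, min = min, max = max,
               required = required)
  }
  rbind(
    d("id", "character"),
    d("age", "numeric", 18, 110),
    d("sex", "categorical"),
    d("education_years", "numeric", 0, 30),
    d("diagnosis", "categorical"),
    d("sls_t15_total", "numeric", 0, 115),
    d("sls_delay", "numeric", 0, 23),
    d("sls_max_span", "numeric", 2, 23),
    d("sym", "numeric", 0, Inf),
    d("sym_n_correct", "numeric", 0, 48),
    d("rt_seconds", "numeric", 0, Inf, required = FALSE),
    d("amyloid_suvr", "numeric", 0, Inf, required = FALSE),
    d("tau_meta_suvr", "numeric", 0, Inf, required = FALSE),
    d("tau_ec_suvr", "numeric", 0, Inf, required = FALSE),
    d("hv", "numeric", 0, Inf, required = FALSE),
    d("icv", "numeric", 0, Inf, required = FALSE),
    d("wmh", "numeric", 0, Inf, required = FALSE)
  )
}

#' Validate an input table against the data dictionary
#'
#' Per-column type and range checks; never mutates the data. Range
#' checks use strict bounds exclusion only where the dictionary range
#' is open (`sym`, `rt_seconds` and volumes must be strictly
#' positive).
#'
#' @param data data frame to check.
#' @param dictionary dictionary data frame (default
#'   [mtd_data_dictionary()]).
#' @return data frame of violations with columns `row`, `column`,
#'   `problem` (zero rows when the table is clean).
#' @export
validate_input <- function(data, dictionary = mtd_data_dictionary()) {
  violations <- list()
  add <- function(rows, column, problem) {
    if (length(rows) > 0) {
      violations[[length(violations) + 1]] <<-
        data.frame(row = rows, column = column, problem = problem)
    }
  }
  for (i in seq_len(nrow(dictionary))) {
    spec <- dictionary[i, ]
    col <- spec$column
    if (!col %in% names(data)) {
      if (isTRUE(spec$required)) add(0L, col, "required column missing")
      next
    }
    v <- data[[col]]
    if (spec$type == "numeric") {
      if (!is.numeric(v)) {
        add(0L, col, "not numeric")
        next
      }
      strict_pos <- is.finite(spec$min) && spec$min == 0 &&
        col %in% c("sym", "rt_seconds", "amyloid_suvr", "tau_meta_suvr",
                   "tau_ec_suvr", "hv", "icv", "wmh")
      low <- if (strict_pos) which(!is.na(v) & v <= spec$min) else
        which(!is.na(v) & v < spec$min)
      add(low, col, sprintf("below minimum %s", format(spec$min)))
      if (is.finite(spec$max)) {
        add(which(!is.na(v) & v > spec$max), col,
            sprintf("above maximum %s", format(spec$max)))
      }
    }
  }
  if (length(violations) == 0) {
    return(data.frame(row = integer(0), column = character(0),
                      problem = character(0)))
  }
  out <- do.call(rbind, violations)
  rownames(out) <- NULL
  out
}

#' Run the full simulate-score-prepare-analyze pipeline
#'
#' Orchestrates a complete analysis run on a synthetic cohort (or on a
#' pre-scored participant table) and writes table-shaped reports:
#' a characteristics table (per-group mean (SD), t/chi-square p,
#' Hedge's g with CI), a composite/subtest association table
#' (covariate-adjusted standardized estimates with CI and p for each
#' outcome x biomarker pair), a by-diagnosis Spearman table, and a
#' machine-readable JSON manifest (configuration, seed, versions and
#' complete-case counts). Re-running with the same configuration and
#' seed reproduces every file byte for byte.
#'
#' @param config list with elements `cohort` (a [cohort_config()]),
#'   `outcomes` (character vector of scored-variable names; default the
#'   two MTD composites and subtests), `biomarkers` (default all five
#'   prepared biomarkers), and `out_dir` (directory for reports, created
#'   if needed); or a path to a YAML/JSON file with those fields.
#' @return invisibly, a list with `scored`, `prepared`,
#'   `characteristics`, `associations`, `spearman`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- .read_run_config(config)
  if (is.null(config$cohort)) stop("run_pipeline: config$cohort is required")
  if (!inherits(config$cohort, "cohort_config")) {
    config$cohort <- do.call(cohort_config, config$cohort)
  }
  outcomes <- config$outcomes %||%
    c("mtd_sbcr", "mtd_sbcz", "sls_sum_of_trials", "sym", "symaw")
  biomarkers <- config$biomarkers %||%
    c("amyloid_z", "tau_meta_z", "tau_ec_z", "hv_adj_z", "wmh_pct_ln_z")
  out_dir <- config$out_dir %||% stop("run_pipeline: config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- generate_cohort(config$cohort)
  scored <- score_cohort(cohort)
  ref <- scored$diagnosis == "CU"
  if (!any(ref)) stop("run_pipeline: reference group (CU) is empty")
  prepared <- prepare_biomarkers(cohort$imaging, scored$sex, ref)

  impaired <- scored$diagnosis %in% c("MCI", "Dementia")
  group <- ifelse(ref, "CU", "MCI/Dementia")

  char_vars <- c("age", "education_years", outcomes)
  characteristics <- do.call(rbind, lapply(char_vars, function(v) {
    x <- scored[[v]]
    g <- hedges_g(x[ref], x[impaired])
    tt <- group_compare(x, group, kind = "t")
    data.frame(variable = v,
               cu_mean = mean(x[ref], na.rm = TRUE),
               cu_sd = stats::sd(x[ref], na.rm = TRUE),
               cu_n = sum(ref & !is.na(x)),
               imp_mean = mean(x[impaired], na.rm = TRUE),
               imp_sd = stats::sd(x[impaired], na.rm = TRUE),
               imp_n = sum(impaired & !is.na(x)),
               t_p = tt$p, g = g$g, g_ci_low = g$ci_low, g_ci_high = g$ci_high)
  }))
  sex_tab <- table(factor(scored$sex, c("F", "M")),
                   factor(group, c("CU", "MCI/Dementia")))
  sex_test <- if (any(stats::chisq.test(sex_tab)$expected < 5)) {
    group_compare(sex_tab, kind = "fisher")
  } else {
    group_compare(sex_tab, kind = "chisq")
  }

  associations <- do.call(rbind, lapply(outcomes, function(out_v) {
    do.call(rbind, lapply(biomarkers, function(bm) {
      res <- fit_adjusted_association(scored[[out_v]], prepared[[bm]],
                                      scored$age, scored$sex,
                                      scored$education_years, ref)
      cbind(data.frame(outcome = out_v, biomarker = bm), res)
    }))
  }))

  spearman_tab <- do.call(rbind, lapply(outcomes, function(out_v) {
    do.call(rbind, lapply(biomarkers, function(bm) {
      res <- spearman_by_group(scored[[out_v]], prepared[[bm]], group)
      cbind(data.frame(outcome = out_v, biomarker = bm), res)
    }))
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mtdrive")),
    r_version = R.version.string,
    seed = config$cohort$seed,
    n = config$cohort$n,
    diagnosis_counts = as.list(table(scored$diagnosis)),
    outcomes = outcomes,
    biomarkers = biomarkers,
    complete_cases = as.list(colSums(!is.na(scored[outcomes]))),
    sex_test = list(test = sex_test$test, p = sex_test$p),
    effects = as.list(config$cohort$effects)
  )

  utils::write.csv(scored, file.path(out_dir, "scored.csv"), row.names = FALSE)
  utils::write.csv(characteristics, file.path(out_dir, "characteristics.csv"),
                   row.names = FALSE)
  utils::write.csv(associations, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)
  utils::write.csv(spearman_tab, file.path(out_dir, "spearman_by_group.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(scored = scored, prepared = prepared,
                 characteristics = characteristics,
                 associations = associations, spearman = spearman_tab,
                 manifest = manifest))
}

.read_run_config <- function(path) {
  if (!file.exists(path)) stop("run_pipeline: config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("run_pipeline: the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
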