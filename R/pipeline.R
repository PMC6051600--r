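#' Configuration for a full audit run
#'
#' @param cohort_spec A [cohort_spec()] describing the synthetic cohort,
#'   or `NULL` when `cohort_csv` is given.
#' @param cohort_csv Optional path to a cohort CSV (see [read_cohort()]).
#' @param missing_mode How missing input values are handled before index
#'   construction: `"chained-imputation"` (impute with
#'   [impute_chained()], then construct -- the replication default) or
#'   `"as-category"` (missing treated as the reference category during
#'   construction).
#' @param models Named list of [fa_model_spec()]s; default [fa_models()].
#' @param mining_pool Candidate columns for alternative-index mining;
#'   default the Functional-Domains inputs plus three Burden deficits
#'   (a desk-scale pool of 12; the full 72-variable pool is
#'   `fa_pool()`).
#' @param mining_k Items per mined index (default 4).
#' @param covariates Adjustment covariates for all survival fits.
#' @param r2_target Variance fraction for the simplification count
#'   (default 0.9).
#' @param imputation_seed Seed for the imputation stage.
#' @param out_dir Optional directory; when given, intermediates and the
#'   report are written there.
#' @return A list of class `fa_run_config`.
#' @export
fa_run_config <- function(cohort_spec = NULL, cohort_csv = NULL,
                          missing_mode = c("chained-imputation",
                                           "as-category"),
                          models = fa_models(),
                          mining_pool = c(fa_models()$FD$input_columns,
                                          "hypertension", "diabetes",
                                          "stroke_history"),
                          mining_k = 4,
                          covariates = c("sex_male", "race_ethnicity",
                                         "education", "income_pc",
                                         "wealth_pc"),
                          r2_target = 0.9,
                          imputation_seed = 1L,
                          out_dir = NULL) {
  if (is.null(cohort_spec) && is.null(cohort_csv)) {
    stop("give either `cohort_spec` or `cohort_csv`", call. = FALSE)
  }
  structure(list(cohort_spec = cohort_spec, cohort_csv = cohort_csv,
                 missing_mode = match.arg(missing_mode), models = models,
                 mining_pool = mining_pool, mining_k = mining_k,
                 covariates = covariates, r2_target = r2_target,
                 imputation_seed = imputation_seed, out_dir = out_dir),
            class = "fa_run_config")
}

# internal: prevalence block for one model
.fa_prevalence_block <- function(cohort, model) {
  st <- cohort[[paste0("status_", model$model_id)]]
  w <- cohort$survey_weight
  elig <- cohort$age >= model$age_eligibility
  list(weighted_overall = weighted_prevalence(st, w),
       unweighted_overall = mean(st, na.rm = TRUE),
       weighted_eligible = weighted_prevalence(st[elig], w[elig]),
       unweighted_eligible = mean(st[elig], na.rm = TRUE),
       unweighted_below_age = mean(st[!elig], na.rm = TRUE),
       age_eligibility = model$age_eligibility)
}

#' Run the full audit pipeline
#'
#' End-to-end orchestration: simulate (or load) the cohort, handle
#' missing values, construct derived variables, domains, the three
#' indices and statuses, decompose each index into input and bias
#' variance shares, interpret each index with forward-stepwise selection
#' (reporting the simplification count), compare mortality prediction
#' across representations with discrete-time survival models, mine
#' equal-weight alternative indices, and assemble a report bundle. Every
#' stage is deterministic given the seeds in the config; with `out_dir`
#' set, intermediates (cohort CSV, bias columns, selection paths,
#' comparison tables, mining results) and a JSON report are written so
#' every reported number is traceable to a stored file.
#'
#' @param config An [fa_run_config()].
#' @return A list of class `fa_report_bundle` with elements `cohort`
#'   (the augmented analysis table), `prevalence`, `bias_share`,
#'   `interpretation`, `survival_comparison`, `mining`, and `log`
#'   (exclusion and imputation counts).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "fa_run_config"))
  log <- list()

  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort(config$cohort_csv)
  } else {
    generate_cohort(config$cohort_spec)
  }
  log$n_participants <- nrow(cohort)

  vars <- fa_variables()
  raw_cols <- intersect(vars$name[vars$role == "raw"], names(cohort))
  n_missing <- sum(vapply(cohort[raw_cols],
                          function(x) sum(is.na(x)), numeric(1)))
  log$n_missing_cells <- n_missing
  construct_missing <- "keep"
  if (n_missing > 0) {
    if (config$missing_mode == "chained-imputation") {
      cohort <- impute_chained(cohort, seed = config$imputation_seed)
      log$imputation <- sprintf("imputed %d cells by chained equations",
                                n_missing)
    } else {
      construct_missing <- "reference"
      log$imputation <- "missing treated as reference category"
    }
  }

  # survival-analysis exclusions, mirroring the reporting convention:
  # drop missing race/ethnicity first, then missing survival status
  n0 <- nrow(cohort)
  cohort <- cohort[!is.na(cohort$race_ethnicity), , drop = FALSE]
  log$n_excluded_race <- n0 - nrow(cohort)
  n1 <- nrow(cohort)
  cohort <- cohort[!is.na(cohort$followup_time) & !is.na(cohort$died), ,
                   drop = FALSE]
  log$n_excluded_survival <- n1 - nrow(cohort)

  cohort <- add_indices(cohort, models = config$models,
                        missing = construct_missing)
  cohort <- add_bias_variables(cohort)

  prevalence <- lapply(config$models, .fa_prevalence_block,
                       cohort = cohort)
  bias_share <- lapply(config$models, model_bias_share, cohort = cohort)

  interpretation <- lapply(config$models, function(m) {
    idx <- paste0("index_", m$model_id)
    path <- forward_stepwise(cohort, idx, m$input_columns,
                             family = "linear")
    list(path = path,
         n_to_target = variables_to_reach(path, config$r2_target),
         r2_target = config$r2_target,
         max_r2 = max(path$steps$r_squared))
  })

  survival_comparison <- lapply(config$models, function(m) {
    compare_representations(cohort, m, covariates = config$covariates)
  })

  mining <- NULL
  if (length(config$mining_pool) >= config$mining_k) {
    pool <- intersect(config$mining_pool, names(cohort))
    res <- mine_indices(cohort, pool, k = config$mining_k,
                        covariates = config$covariates)
    ref <- reference_index_fit(cohort, config$models[[1]],
                               covariates = config$covariates)
    mining <- list(results = res,
                   reference = list(model = config$models[[1]]$model_id,
                                    p_value = ref$p_value,
                                    deviance = ref$deviance),
                   summary = summarize_mining(res, ref$p_value,
                                              ref$deviance))
  }

  bundle <- structure(
    list(cohort = cohort, prevalence = prevalence,
         bias_share = bias_share, interpretation = interpretation,
         survival_comparison = survival_comparison, mining = mining,
         log = log),
    class = "fa_report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort_analyzed.csv"))
    for (m in names(config$models)) {
      utils::write.csv(interpretation[[m]]$path$steps,
                       file.path(config$out_dir,
                                 paste0("selection_path_", m, ".csv")),
                       row.names = FALSE)
      utils::write.csv(survival_comparison[[m]],
                       file.path(config$out_dir,
                                 paste0("survival_comparison_", m, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(mining)) {
      utils::write.csv(as.data.frame(mining$results),
                       file.path(config$out_dir, "mining_results.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report_tables(bundle),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Tabular summary of a report bundle
#'
#' Flattens a [run_full()] bundle into the two headline tables: per-model
#' prevalence and variance decomposition (characteristics table) and the
#' survival-analysis comparison plus mining summary.
#'
#' @param bundle An `fa_report_bundle`.
#' @return A list of plain lists/data.frames, JSON-serializable.
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "fa_report_bundle"))
  characteristics <- lapply(names(bundle$prevalence), function(m) {
    c(list(model = m), bundle$prevalence[[m]],
      bundle$bias_share[[m]],
      list(n_inputs_to_reach_target =
             bundle$interpretation[[m]]$n_to_target,
           r2_target = bundle$interpretation[[m]]$r2_target,
           max_r2 = bundle$interpretation[[m]]$max_r2))
  })
  names(characteristics) <- names(bundle$prevalence)
  survival <- lapply(bundle$survival_comparison, function(x) x)
  list(characteristics = characteristics,
       survival_comparison = survival,
       mining_summary = if (!is.null(bundle$mining))
         bundle$mining$summary else NULL,
       log = bundle$log)
}

#' @export
print.fa_report_bundle <- function(x, ...) {
  cat("<fa_report_bundle>\n")
  cat(sprintf("  participants analyzed: %d\n", nrow(x$cohort)))
  for (m in names(x$prevalence)) {
    p <- x$prevalence[[m]]
    b <- x$bias_share[[m]]
    cat(sprintf(
      "  %-7s weighted prevalence (age %d+): %.3f; below: %.3f; r2 inputs %.3f / bias %.3f / both %.6f\n",
      m, p$age_eligibility, p$weighted_eligible, p$unweighted_below_age,
      b$r2_inputs, b$r2_bias, b$r2_both))
  }
  if (!is.null(x$mining)) {
    s <- x$mining$summary
    cat(sprintf(
      "  mining: %d candidates, %d significant, %d with lower p than reference\n",
      s$n_candidates, s$n_significant, s$n_lower_p_than_reference))
  }
  invisible(x)
}
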