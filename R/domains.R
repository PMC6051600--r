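#' Add intermediate derived variables
#'
#' Computes the 19 default derived columns: [0,1]-rescaled versions of
#' every ordinal item (via [rescale_ordinal()]), the combined cognition
#' score, the exhaustion ("everything was an effort") flag, body-mass
#' index and its quartile group, the 8-to-15-foot walk-time conversion
#' (multiplication by 15/8), and the three stratified-quantile flags
#' (slowness, weakness, low energy expenditure). A within-sex
#' height-group column used only for stratification is added as well.
#'
#' @param cohort A cohort data.frame.
#' @param weighted_quantiles If `TRUE`, quantile-flag thresholds use the
#'   `survey_weight` column; default `FALSE` (unweighted percentiles, the
#'   replication default for the Biologic Syndrome model).
#' @param missing `"keep"` propagates `NA`s into derived values;
#'   `"reference"` treats a missing item as the reference (no-deficit)
#'   category and never flags a missing continuous measure -- the
#'   "missing as its own category" construction mode.
#' @return `cohort` with derived columns appended (existing columns of
#'   the same names are overwritten).
#' @export
add_derived_variables <- function(cohort,
                                  weighted_quantiles = FALSE,
                                  missing = c("keep", "reference")) {
  missing <- match.arg(missing)
  vars <- fa_variables()
  ords <- vars[vars$kind == "ordinal" & vars$role == "raw", ]
  fill0 <- function(x) if (missing == "reference") ifelse(is.na(x), 0, x) else x

  if (missing == "reference") {
    # binary deficits enter sums as their own scaled value: a missing
    # deficit scores as the reference (absent) category
    for (bv in intersect(vars$name[vars$kind == "binary"], names(cohort))) {
      cohort[[bv]] <- fill0(cohort[[bv]])
    }
  }

  for (i in seq_len(nrow(ords))) {
    nm <- ords$name[i]
    sc <- paste0("scaled_", nm)
    if (sc %in% vars$name) {
      cohort[[sc]] <- fill0(rescale_ordinal(cohort[[nm]],
                                            ords$n_categories[i]))
    }
  }
  cohort$cognition_combined <- (cohort$scaled_cognition_performance +
                                  cohort$scaled_cognition_proxy) / 2
  cohort$effort_flag <- as.integer(cohort$scaled_everything_effort >= 2 / 3)
  if (missing == "reference") cohort$effort_flag <- fill0(cohort$effort_flag)

  cohort$bmi <- cohort$weight_kg / cohort$height^2
  bq <- quantile(cohort$bmi, c(0.25, 0.5, 0.75), na.rm = TRUE)
  cohort$bmi_quartile <- findInterval(cohort$bmi, bq) + 1L
  cohort$walk_time_15ft <- cohort$walk_time_8ft * 15 / 8

  # stratifiers must be complete: fall back to the within-sex median/BMI
  # midpoint group for rows whose measure is missing
  med_h <- tapply(cohort$height, cohort$sex_male, median, na.rm = TRUE)
  hg <- as.integer(cohort$height >
                     med_h[as.character(cohort$sex_male)])
  hg[is.na(hg)] <- 0L
  cohort$height_group <- hg
  cohort$bmi_quartile[is.na(cohort$bmi_quartile)] <- 2L

  w <- if (weighted_quantiles) cohort$survey_weight else NULL
  cohort$slow_flag <- stratified_quantile_flag(
    cohort$walk_time_15ft, list(cohort$sex_male, cohort$height_group),
    q = 0.2, direction = "highest", weights = w)
  cohort$weak_flag <- stratified_quantile_flag(
    cohort$grip_strength, list(cohort$sex_male, cohort$bmi_quartile),
    q = 0.2, direction = "lowest", weights = w)
  cohort$low_activity_flag <- stratified_quantile_flag(
    cohort$activity_score, cohort$sex_male,
    q = 0.2, direction = "lowest", weights = w)
  if (missing == "reference") {
    for (cl in c("slow_flag", "weak_flag", "low_activity_flag")) {
      cohort[[cl]] <- fill0(cohort[[cl]])
    }
  }
  cohort
}

#' Build one domain variable
#'
#' Applies a domain recipe -- a right-censored sum of indicators, a
#' stratified-quantile flag, or a worst-of (maximum) rule -- yielding a
#' value in [0, 1] per participant. The nine default recipes cover the
#' four Functional-Domains domains (physical, nutritive/weight-loss,
#' cognitive, sensory), the five Biologic-Syndrome domains (weight loss
#' shared with the former, exhaustion, low energy expenditure, slowness,
#' weakness) and the Burden cognition domain.
#'
#' @param cohort A cohort data.frame containing the recipe's inputs
#'   (derived columns are added on the fly if absent).
#' @param domain Domain name, one of `names(frailtyaudit:::.fa_domain_recipes())`,
#'   or a recipe list with the same structure.
#' @param weights Optional survey weights for quantile-flag recipes.
#' @return Numeric vector in [0, 1].
#' @export
build_domain <- function(cohort, domain, weights = NULL) {
  recipes <- .fa_domain_recipes()
  recipe <- if (is.character(domain)) {
    if (!domain %in% names(recipes)) {
      stop("unknown domain: ", domain, call. = FALSE)
    }
    recipes[[domain]]
  } else {
    domain
  }
  need <- switch(recipe$type,
                 censored_sum = recipe$inputs,
                 max = recipe$inputs,
                 quantile_flag = c(recipe$value, recipe$strata))
  if (!all(need %in% names(cohort))) {
    cohort <- add_derived_variables(cohort)
    miss <- setdiff(need, names(cohort))
    if (length(miss)) {
      stop("missing required column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  switch(recipe$type,
         censored_sum = censored_sum(cohort[recipe$inputs],
                                     cap = recipe$cap),
         max = do.call(pmax, cohort[recipe$inputs]),
         quantile_flag = stratified_quantile_flag(
           cohort[[recipe$value]],
           cohort[recipe$strata],
           q = recipe$q, direction = recipe$direction,
           weights = weights))
}

#' Add all nine domain variables
#'
#' @inheritParams add_derived_variables
#' @return `cohort` with the nine domain columns appended.
#' @export
build_domains <- function(cohort, weighted_quantiles = FALSE,
                          missing = c("keep", "reference")) {
  missing <- match.arg(missing)
  cohort <- add_derived_variables(cohort,
                                  weighted_quantiles = weighted_quantiles,
                                  missing = missing)
  w <- if (weighted_quantiles) cohort$survey_weight else NULL
  for (d in names(.fa_domain_recipes())) {
    val <- build_domain(cohort, d, weights = w)
    if (missing == "reference") val[is.na(val)] <- 0
    cohort[[d]] <- val
  }
  cohort
}

#' Compute a frailty index
#'
#' Functional-Domains and Biologic-Syndrome indices are the plain sum of
#' their 4 and 5 domain variables (ranges [0,4] and [0,5]); the Burden
#' index is the sum of its 24 equal-weight [0,1] items divided by the
#' divisor (default 24), giving a [0,1] deficit-accumulation proportion.
#'
#' @param cohort A cohort data.frame with the model's domain/item columns
#'   (see [build_domains()]).
#' @param model An [fa_model_spec()].
#' @return Numeric index vector within `model$index_range`.
#' @export
build_index <- function(cohort, model) {
  stopifnot(inherits(model, "fa_model_spec"))
  if (!is.null(model$domains)) {
    miss <- setdiff(model$domains, names(cohort))
    if (length(miss)) {
      stop("domain column(s) not in cohort: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    expected <- diff(model$index_range)
    if (length(model$domains) != expected) {
      stop("model declares range width ", expected, " but ",
           length(model$domains), " domains", call. = FALSE)
    }
    unname(rowSums(as.matrix(cohort[model$domains])))
  } else {
    miss <- setdiff(model$items, names(cohort))
    if (length(miss)) {
      stop("item column(s) not in cohort: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    unname(rowSums(as.matrix(cohort[model$items]))) / model$divisor
  }
}

#' Dichotomize an index into a frailty status
#'
#' Status is 1 iff the index meets or exceeds the model cutoff
#' (inclusive: an index exactly at the cutoff is frail). The shipped
#' cutoffs are 2 (Functional Domains), 0.2 (Burden) and 3 (Biologic
#' Syndrome).
#'
#' @param index Numeric index vector, inside `model$index_range`.
#' @param model An [fa_model_spec()].
#' @return Integer 0/1 status vector (`NA` passed through).
#' @export
#' @examples
#' m <- fa_models()$burden
#' dichotomize(c(0.19, 0.2), m)  # 0 1
dichotomize <- function(index, model) {
  stopifnot(inherits(model, "fa_model_spec"))
  rng <- model$index_range
  bad <- !is.na(index) & (index < rng[1] - 1e-9 | index > rng[2] + 1e-9)
  if (any(bad)) {
    stop("index value outside declared range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  as.integer(index >= model$cutoff)
}

#' Add indices and statuses for a set of models
#'
#' Convenience wrapper: derived variables, the nine domains, then
#' `index_<id>` and `status_<id>` columns for every model.
#'
#' @inheritParams build_domains
#' @param models List of [fa_model_spec()]s; default [fa_models()].
#' @return Augmented cohort data.frame.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(300, seed = 1))
#' cohort <- add_indices(cohort)
#' summary(cohort$index_burden)
add_indices <- function(cohort, models = fa_models(),
                        weighted_quantiles = FALSE,
                        missing = c("keep", "reference")) {
  missing <- match.arg(missing)
  cohort <- build_domains(cohort, weighted_quantiles = weighted_quantiles,
                          missing = missing)
  for (m in models) {
    idx <- build_index(cohort, m)
    cohort[[paste0("index_", m$model_id)]] <- idx
    cohort[[paste0("status_", m$model_id)]] <- dichotomize(idx, m)
  }
  cohort
}
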