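#' Default variable registry
#'
#' The package ships a default menu of 72 analysis variables mirroring the
#' structure of the three classic frailty models: 44 raw input variables,
#' 19 intermediate derived variables (rescaled ordinals, body-mass index,
#' the 8-to-15-foot walk-time conversion, stratified-quantile flags), and
#' 9 domain variables (4 Functional-Domains + 5 Biologic-Syndrome domains
#' with weight loss shared between the two, plus the Burden cognition
#' domain). The registry records, for each variable, its measurement kind
#' and its role in the pipeline; generation parameters live in
#' [generate_cohort()].
#'
#' @return A data.frame with columns `name`, `kind` (`"binary"`,
#'   `"ordinal"`, `"continuous"`), `n_categories` (ordinal only, else
#'   `NA`), and `role` (`"raw"`, `"derived"`, `"domain"`).
#' @export
#' @examples
#' v <- fa_variables()
#' table(v$role)
fa_variables <- function() {
  raw_binary <- c(
    # Functional Domains inputs
    "dizziness", "lift_difficulty", "climb_difficulty",
    "weight_loss", "underweight",
    "cognitive_impairment", "memory_problem",
    "poor_hearing", "poor_eyesight",
    # Biologic Syndrome inputs
    "cannot_get_going", "sex_male",
    # Burden deficits
    "hypertension", "diabetes", "heart_disease", "stroke_history",
    "lung_disease", "cancer_history", "arthritis", "incontinence",
    "fall_history", "adl_bathing", "adl_dressing", "adl_eating",
    "iadl_meals", "iadl_shopping", "iadl_medications",
    # pool-only deficits
    "balance_problem"
  )
  raw_ordinal <- c(
    everything_effort = 4L,
    cognition_performance = 5L, cognition_proxy = 5L,
    self_rated_health = 5L, mobility_difficulty = 4L,
    adl_difficulty = 5L, iadl_difficulty = 5L,
    depressive_symptoms = 4L, pain_level = 3L,
    fatigue_scale = 4L, social_activity = 3L,
    self_rated_memory = 3L
  )
  raw_continuous <- c("activity_score", "walk_time_8ft", "grip_strength",
                      "height", "weight_kg")
  derived <- c(
    "scaled_self_rated_health", "scaled_mobility_difficulty",
    "scaled_adl_difficulty", "scaled_iadl_difficulty",
    "scaled_depressive_symptoms", "scaled_pain_level",
    "scaled_fatigue_scale", "scaled_social_activity",
    "scaled_cognition_performance", "scaled_cognition_proxy",
    "cognition_combined", "scaled_everything_effort", "effort_flag",
    "bmi", "bmi_quartile", "walk_time_15ft",
    "slow_flag", "weak_flag", "low_activity_flag"
  )
  domains <- c("fd_physical", "fd_cognitive", "sensory",
               "weight_loss_domain", "bs_exhaustion", "bs_low_energy",
               "bs_slowness", "bs_weakness", "burden_cognition")

  rbind(
    data.frame(name = raw_binary, kind = "binary", n_categories = NA_integer_,
               role = "raw"),
    data.frame(name = names(raw_ordinal), kind = "ordinal",
               n_categories = as.integer(raw_ordinal), role = "raw"),
    data.frame(name = raw_continuous, kind = "continuous",
               n_categories = NA_integer_, role = "raw"),
    data.frame(name = derived,
               kind = ifelse(derived %in% c("bmi", "walk_time_15ft"),
                             "continuous",
                             ifelse(derived == "bmi_quartile", "ordinal",
                                    "continuous")),
               n_categories = ifelse(derived == "bmi_quartile", 4L,
                                     NA_integer_),
               role = "derived"),
    data.frame(name = domains, kind = "continuous",
               n_categories = NA_integer_, role = "domain")
  )
}

#' Default 72-variable mining pool
#'
#' All raw, derived and domain variables of the default registry, in
#' registry order. This is the candidate universe for equal-weight
#' alternative-index mining.
#'
#' @return Character vector of 72 variable names.
#' @export
fa_pool <- function() fa_variables()$name

# internal: domain construction recipes.  Each entry gives the rule used to
# build the [0,1] domain value and the design columns for its bias
# regression (scaled representations of its own theory-based inputs).
.fa_domain_recipes <- function() {
  list(
    fd_physical = list(
      type = "censored_sum",
      inputs = c("dizziness", "lift_difficulty", "climb_difficulty"),
      bias_inputs = c("dizziness", "lift_difficulty", "climb_difficulty"),
      cap = 1),
    fd_cognitive = list(
      type = "censored_sum",
      inputs = c("cognitive_impairment", "memory_problem"),
      bias_inputs = c("cognitive_impairment", "memory_problem"),
      cap = 1),
    sensory = list(
      type = "censored_sum",
      inputs = c("poor_hearing", "poor_eyesight"),
      bias_inputs = c("poor_hearing", "poor_eyesight"),
      cap = 1),
    weight_loss_domain = list(
      type = "censored_sum",
      inputs = c("weight_loss", "underweight"),
      bias_inputs = c("weight_loss", "underweight"),
      cap = 1),
    bs_exhaustion = list(
      type = "censored_sum",
      inputs = c("effort_flag", "cannot_get_going"),
      bias_inputs = c("scaled_everything_effort", "cannot_get_going"),
      cap = 1),
    bs_low_energy = list(
      type = "quantile_flag",
      value = "activity_score", strata = "sex_male",
      q = 0.2, direction = "lowest",
      bias_inputs = c("activity_score", "sex_male")),
    bs_slowness = list(
      type = "quantile_flag",
      value = "walk_time_15ft", strata = c("sex_male", "height_group"),
      q = 0.2, direction = "highest",
      bias_inputs = c("walk_time_8ft", "sex_male", "height")),
    bs_weakness = list(
      type = "quantile_flag",
      value = "grip_strength", strata = c("sex_male", "bmi_quartile"),
      q = 0.2, direction = "lowest",
      bias_inputs = c("grip_strength", "sex_male", "height", "weight_kg")),
    burden_cognition = list(
      type = "max",
      inputs = c("scaled_cognition_performance", "scaled_cognition_proxy"),
      bias_inputs = c("scaled_cognition_performance",
                      "scaled_cognition_proxy"))
  )
}

# internal: Burden item columns (scaled representations), 23 + cognition
# domain = 24 items under the default divisor
.fa_burden_items <- function() {
  c("hypertension", "diabetes", "heart_disease", "stroke_history",
    "lung_disease", "cancer_history", "arthritis", "incontinence",
    "fall_history", "adl_bathing", "adl_dressing", "adl_eating",
    "iadl_meals", "iadl_shopping", "iadl_medications",
    "scaled_self_rated_health", "scaled_mobility_difficulty",
    "scaled_adl_difficulty", "scaled_iadl_difficulty",
    "scaled_depressive_symptoms", "scaled_pain_level",
    "scaled_fatigue_scale", "scaled_social_activity",
    "burden_cognition")
}

#' Frailty model specification
#'
#' Constructor for the metadata describing one frailty model: which
#' domains (or items) it sums, the index range, the frailty cutoff, and
#' the age-eligibility criterion. The three shipped models are available
#' through [fa_models()].
#'
#' @param model_id One of `"FD"`, `"burden"`, `"BS"` (or a custom id).
#' @param label Human-readable model name.
#' @param domains Character vector of domain columns summed by the index
#'   (FD/BS style), or `NULL` for item-sum models.
#' @param items Character vector of scaled item columns (Burden style),
#'   or `NULL`.
#' @param divisor Divisor applied to the item sum (Burden style); default
#'   the number of items.
#' @param index_range Numeric length-2, inclusive range of the index.
#' @param cutoff Frailty cutoff; status is 1 iff index >= cutoff.
#' @param age_eligibility Minimum age in years for the model's eligible
#'   subsample.
#' @param input_columns Design columns (scaled representations) used when
#'   the index is regressed on its own inputs.
#' @return An object of class `fa_model_spec`.
#' @export
fa_model_spec <- function(model_id, label, domains = NULL, items = NULL,
                          divisor = length(items),
                          index_range, cutoff, age_eligibility,
                          input_columns) {
  if (is.null(domains) && is.null(items)) {
    stop("one of `domains` or `items` must be given", call. = FALSE)
  }
  if (length(index_range) != 2L || index_range[1] >= index_range[2]) {
    stop("`index_range` must be an increasing length-2 numeric",
         call. = FALSE)
  }
  if (cutoff < index_range[1] || cutoff > index_range[2]) {
    stop("`cutoff` must lie inside `index_range`", call. = FALSE)
  }
  structure(
    list(model_id = model_id, label = label, domains = domains,
         items = items, divisor = divisor, index_range = index_range,
         cutoff = cutoff, age_eligibility = age_eligibility,
         input_columns = input_columns),
    class = "fa_model_spec")
}

#' @export
print.fa_model_spec <- function(x, ...) {
  cat(sprintf("<fa_model_spec> %s (%s)\n", x$model_id, x$label))
  if (!is.null(x$domains)) {
    cat("  domains:", paste(x$domains, collapse = ", "), "\n")
  } else {
    cat(sprintf("  items: %d (divisor %g)\n", length(x$items), x$divisor))
  }
  cat(sprintf("  range [%g, %g], frail iff index >= %g, age >= %d\n",
              x$index_range[1], x$index_range[2], x$cutoff,
              x$age_eligibility))
  invisible(x)
}

#' The three shipped frailty model specifications
#'
#' Functional Domains (4 domains, range 0-4, cutoff 2, age 65+), Burden
#' (24 equal-weight items divided by 24, range 0-1, cutoff 0.2, age 70+)
#' and Biologic Syndrome (5 domains, range 0-5, cutoff 3, age 65+). The
#' weight-loss domain is shared between the Functional Domains and
#' Biologic Syndrome models.
#'
#' @return Named list of three [fa_model_spec()] objects
#'   (`FD`, `burden`, `BS`).
#' @export
#' @examples
#' fa_models()$FD
fa_models <- function() {
  list(
    FD = fa_model_spec(
      "FD", "Functional Domains",
      domains = c("fd_physical", "weight_loss_domain", "fd_cognitive",
                  "sensory"),
      index_range = c(0, 4), cutoff = 2, age_eligibility = 65,
      input_columns = c("dizziness", "lift_difficulty", "climb_difficulty",
                        "weight_loss", "underweight",
                        "cognitive_impairment", "memory_problem",
                        "poor_hearing", "poor_eyesight")),
    burden = fa_model_spec(
      "burden", "Burden (deficit accumulation)",
      items = .fa_burden_items(), divisor = 24,
      index_range = c(0, 1), cutoff = 0.2, age_eligibility = 70,
      input_columns = c(.fa_burden_items()[1:23],
                        "scaled_cognition_performance",
                        "scaled_cognition_proxy")),
    BS = fa_model_spec(
      "BS", "Biologic Syndrome",
      domains = c("weight_loss_domain", "bs_exhaustion", "bs_low_energy",
                  "bs_slowness", "bs_weakness"),
      index_range = c(0, 5), cutoff = 3, age_eligibility = 65,
      input_columns = c("weight_loss", "underweight",
                        "scaled_everything_effort", "cannot_get_going",
                        "activity_score", "walk_time_8ft", "grip_strength",
                        "height", "weight_kg", "sex_male"))
  )
}
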