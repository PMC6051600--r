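#' Specification of a synthetic cohort
#'
#' Collects every generative parameter of the synthetic aging-panel cohort:
#' sample size, seed, age range, the strength of the latent frailty factor
#' that correlates deficits, the discrete-time mortality hazard, follow-up
#' length, missingness, and survey-weight dispersion.
#'
#' The generator draws one latent frailty propensity per participant
#' (standardized age effect plus standard-normal noise); every deficit,
#' ordinal symptom scale and performance measure loads on it with strength
#' proportional to `frailty_loading`. Mortality follows a yearly
#' discrete-time logistic hazard with per-year intercepts
#' `hazard_intercepts` and log-odds coefficients `hazard_betas` on cohort
#' columns.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; the whole table is deterministic given it.
#' @param age_range Length-2 numeric, baseline age range in years.
#' @param frailty_loading Non-negative scalar scaling every variable's
#'   loading on the latent frailty factor; 0 makes all health variables
#'   mutually independent.
#' @param hazard_intercepts Per-year baseline log-odds of death, length
#'   `max_followup`. Default: yearly hazard rising from 3.5% to 8%.
#'   `-Inf` entries give zero hazard in that year.
#' @param hazard_betas Named numeric vector of log-odds coefficients; the
#'   names must be cohort columns. Default: 0.8 on the latent factor
#'   `frailty_z`.
#' @param max_followup Maximum follow-up in whole years (1..13).
#' @param missing_rate Fraction of maskable cells set missing, in [0, 1).
#' @param missing_mechanism `"MCAR"` or `"MAR-age"` (missingness
#'   probability increasing with age).
#' @param weight_dispersion Variance of the gamma survey weights
#'   (mean fixed at 1); must be positive.
#' @return An object of class `fa_cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cohort_spec(n_participants = 100, seed = 1)
cohort_spec <- function(n_participants,
                        seed,
                        age_range = c(50, 95),
                        frailty_loading = 1,
                        hazard_intercepts = NULL,
                        hazard_betas = c(frailty_z = 0.8),
                        max_followup = 13,
                        missing_rate = 0,
                        missing_mechanism = c("MAR-age", "MCAR"),
                        weight_dispersion = 0.5) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("`age_range` must be an increasing length-2 numeric", call. = FALSE)
  }
  if (frailty_loading < 0) stop("`frailty_loading` must be >= 0", call. = FALSE)
  if (max_followup < 1 || max_followup > 13) {
    stop("`max_followup` must be between 1 and 13 years", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  if (weight_dispersion <= 0) {
    stop("`weight_dispersion` must be positive", call. = FALSE)
  }
  max_followup <- as.integer(max_followup)
  if (is.null(hazard_intercepts)) {
    hazard_intercepts <- qlogis(seq(0.035, 0.08, length.out = max_followup))
  }
  if (length(hazard_intercepts) != max_followup) {
    stop("`hazard_intercepts` must have length `max_followup`",
         call. = FALSE)
  }
  if (length(hazard_betas) && is.null(names(hazard_betas))) {
    stop("`hazard_betas` must be a named numeric vector", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         seed = as.integer(seed),
         age_range = age_range,
         frailty_loading = frailty_loading,
         hazard_intercepts = hazard_intercepts,
         hazard_betas = hazard_betas,
         max_followup = max_followup,
         missing_rate = missing_rate,
         missing_mechanism = match.arg(missing_mechanism),
         weight_dispersion = weight_dispersion),
    class = "fa_cohort_spec")
}

#' @export
print.fa_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<fa_cohort_spec> n = %d, seed = %d, ages %g-%g, loading %g\n",
    x$n_participants, x$seed, x$age_range[1], x$age_range[2],
    x$frailty_loading))
  cat(sprintf("  follow-up <= %d y, missing %g%% (%s), weight var %g\n",
              x$max_followup, 100 * x$missing_rate, x$missing_mechanism,
              x$weight_dispersion))
  invisible(x)
}
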