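# Generative parameters for the raw variable menu.  Baseline prevalences /
# category masses approximate what a community-dwelling 50+ panel looks
# like; the loading multipliers are scaled by `frailty_loading`.

.fa_binary_params <- function() {
  c(dizziness = 0.06, lift_difficulty = 0.15, climb_difficulty = 0.18,
    weight_loss = 0.07, underweight = 0.03,
    cognitive_impairment = 0.07, memory_problem = 0.10,
    poor_hearing = 0.12, poor_eyesight = 0.09,
    cannot_get_going = 0.12,
    hypertension = 0.35, diabetes = 0.13, heart_disease = 0.10,
    stroke_history = 0.05, lung_disease = 0.06, cancer_history = 0.09,
    arthritis = 0.32, incontinence = 0.12, fall_history = 0.16,
    adl_bathing = 0.05, adl_dressing = 0.04, adl_eating = 0.02,
    iadl_meals = 0.04, iadl_shopping = 0.06, iadl_medications = 0.03,
    balance_problem = 0.09)
}

.fa_ordinal_probs <- function(k) {
  switch(as.character(k),
         "3" = c(0.70, 0.20, 0.10),
         "4" = c(0.60, 0.20, 0.12, 0.08),
         "5" = c(0.55, 0.20, 0.13, 0.08, 0.04),
         stop("unsupported category count: ", k, call. = FALSE))
}

#' Generate a synthetic aging-panel cohort
#'
#' Draws one row per participant: demographics (age, sex, race/ethnicity,
#' education, per-capita income and wealth), a gamma survey weight with
#' mean 1, a latent frailty propensity `frailty_z` (standardized age
#' effect plus standard-normal noise), binary deficits with logistic
#' probabilities `plogis(a_j + b_j * frailty_z)`, ordinal symptom scales
#' via a thresholded latent variable, continuous performance measures
#' (8-foot walk time, grip strength, activity score) with sex and
#' body-size effects, age-eligibility flags for the 65+ and 70+ model
#' subsamples, and yearly mortality follow-up drawn by
#' [generate_survival()]. Missingness is injected afterwards when
#' `spec$missing_rate > 0` (see [inject_missingness()]).
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame ("cohort table") with one row per participant.
#'   Deterministic given `spec$seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 200, seed = 1))
#' dim(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fa_cohort_spec"))
  n <- spec$n_participants
  L <- spec$frailty_loading

  tab <- with_seed(spec$seed, {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex_male <- rbinom(n, 1, 0.45)
    race_ethnicity <- sample(c("white", "black", "hispanic"), n,
                             replace = TRUE, prob = c(0.70, 0.15, 0.15))
    education <- pmin(pmax(round(rnorm(n, 12.5, 3)), 0), 17)
    income_pc <- exp(rnorm(n, log(25000), 0.8))
    wealth_pc <- exp(rnorm(n, log(90000), 1.1))
    survey_weight <- rgamma(n, shape = 1 / spec$weight_dispersion,
                            rate = 1 / spec$weight_dispersion)

    z_raw <- as.numeric(scale(age)) + rnorm(n)
    frailty_z <- if (n > 1) as.numeric(scale(z_raw)) else z_raw

    out <- data.frame(id = seq_len(n), age = age,
                      sex = ifelse(sex_male == 1, "male", "female"),
                      sex_male = sex_male, race_ethnicity = race_ethnicity,
                      education = education, income_pc = income_pc,
                      wealth_pc = wealth_pc, survey_weight = survey_weight,
                      frailty_z = frailty_z,
                      stringsAsFactors = FALSE)

    prev <- .fa_binary_params()
    for (nm in names(prev)) {
      out[[nm]] <- rbinom(n, 1, plogis(qlogis(prev[[nm]]) + L * frailty_z))
    }

    vars <- fa_variables()
    ords <- vars[vars$kind == "ordinal" & vars$role == "raw", ]
    for (i in seq_len(nrow(ords))) {
      k <- ords$n_categories[i]
      lam <- 0.8 * L
      latent <- lam * frailty_z + rnorm(n)
      thr <- qnorm(cumsum(.fa_ordinal_probs(k))[-k],
                   sd = sqrt(lam^2 + 1))
      out[[ords$name[i]]] <- findInterval(latent, thr) + 1L
    }

    height <- ifelse(sex_male == 1, 1.75, 1.62) + rnorm(n, 0, 0.07)
    bmi <- pmax(27 + rnorm(n, 0, 4) - 0.8 * L * frailty_z, 15)
    out$height <- height
    out$weight_kg <- bmi * height^2
    out$walk_time_8ft <- exp(log(2.4) + 0.25 * L * frailty_z +
                               0.10 * (sex_male == 0) -
                               0.6 * (height - 1.68) + rnorm(n, 0, 0.25))
    out$grip_strength <- pmax(32 + 10 * sex_male - 3 * L * frailty_z +
                                0.25 * (bmi - 27) + rnorm(n, 0, 5), 2)
    out$activity_score <- exp(1.3 - 0.5 * L * frailty_z + rnorm(n, 0, 0.6))

    out$eligible_65 <- as.integer(age >= 65)
    out$eligible_70 <- as.integer(age >= 70)
    out
  })

  tab <- generate_survival(tab, spec)
  if (spec$missing_rate > 0) {
    tab <- inject_missingness(tab, rate = spec$missing_rate,
                              mechanism = spec$missing_mechanism,
                              seed = spec$seed + 2L)
  }
  tab
}

#' Draw discrete-time mortality follow-up
#'
#' For each participant and each year `t = 1..max_followup`, death occurs
#' with probability `plogis(hazard_intercepts[t] + sum(hazard_betas * x))`.
#' `followup_time` is the first death year, or `max_followup` with
#' `died = 0` for survivors. Existing `followup_time`/`died` columns are
#' overwritten, so the hazard can be re-drawn under a different
#' specification for an already generated table.
#'
#' @param table A cohort data.frame.
#' @param spec A [cohort_spec()]; `hazard_betas` names must be columns of
#'   `table`.
#' @param seed Seed for the survival draws; defaults to `spec$seed + 1`.
#' @return `table` with `followup_time` (whole years in
#'   `1..max_followup`) and `died` (0/1) columns. Deterministic given
#'   `seed`.
#' @export
generate_survival <- function(table, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "fa_cohort_spec"), is.data.frame(table))
  betas <- spec$hazard_betas
  missing_cols <- setdiff(names(betas), names(table))
  if (length(missing_cols)) {
    stop("hazard_betas name(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  lin <- if (length(betas)) {
    as.numeric(as.matrix(table[names(betas)]) %*% betas)
  } else {
    rep(0, n)
  }
  with_seed(seed, {
    followup <- rep(spec$max_followup, n)
    died <- integer(n)
    alive <- rep(TRUE, n)
    for (t in seq_len(spec$max_followup)) {
      p <- plogis(spec$hazard_intercepts[t] + lin)
      dies <- alive & (runif(n) < p)
      followup[dies] <- t
      died[dies] <- 1L
      alive <- alive & !dies
    }
    table$followup_time <- as.integer(followup)
    table$died <- died
    table
  })
}

#' Inject missing values into maskable cells
#'
#' Masks the stated fraction of deficit, symptom-scale and performance
#' cells. Demographics, survey weight, the latent factor and the survival
#' outcome are never masked. Under `"MAR-age"` the per-row missingness
#' probability increases with age (mean across rows still equals `rate`).
#'
#' @param table A cohort data.frame.
#' @param rate Fraction of cells to mask, in [0, 1).
#' @param mechanism `"MCAR"` or `"MAR-age"`.
#' @param seed Integer seed.
#' @param columns Columns eligible for masking; defaults to every raw
#'   registry variable present except sex.
#' @return The table with `NA`s injected. Deterministic given `seed`;
#'   `rate = 0` returns the table unchanged.
#' @export
inject_missingness <- function(table, rate, mechanism = c("MCAR", "MAR-age"),
                               seed, columns = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stop("`rate` must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(table)
  if (is.null(columns)) {
    vars <- fa_variables()
    columns <- intersect(setdiff(vars$name[vars$role == "raw"], "sex_male"),
                         names(table))
  }
  n <- nrow(table)
  p_row <- if (mechanism == "MAR-age") {
    w <- exp(0.7 * as.numeric(scale(table$age)))
    pmin(rate * w / mean(w), 0.95)
  } else {
    rep(rate, n)
  }
  with_seed(seed, {
    for (cl in columns) {
      table[[cl]][runif(n) < p_row] <- NA
    }
    table
  })
}
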