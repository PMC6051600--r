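#' Expand a cohort into a person-period table
#'
#' One row per participant per follow-up year: a participant followed
#' `followup_time` years contributes exactly that many rows, with
#' `event = 1` only on the last row of participants who died. The period
#' enters downstream models as a factor (one baseline hazard intercept
#' per year).
#'
#' @param cohort Cohort data.frame with `followup_time` (whole years
#'   >= 1) and `died` (0/1).
#' @return data.frame with `id`, `period`, `event` and all baseline
#'   columns repeated within participant.
#' @export
#' @examples
#' d <- data.frame(id = 1, followup_time = 3, died = 1)
#' to_person_period(d)$event  # 0 0 1
to_person_period <- function(cohort) {
  ft <- cohort$followup_time
  if (is.null(ft) || is.null(cohort$died)) {
    stop("cohort needs `followup_time` and `died` columns", call. = FALSE)
  }
  if (any(is.na(ft) & cohort$died == 1)) {
    stop("died = 1 with missing followup_time", call. = FALSE)
  }
  if (any(ft < 1, na.rm = TRUE)) {
    stop("followup_time must be >= 1", call. = FALSE)
  }
  rows <- rep(seq_len(nrow(cohort)), ft)
  pp <- cohort[rows, , drop = FALSE]
  pp$period <- sequence(ft)
  pp$event <- as.integer(pp$period == pp$followup_time & pp$died == 1)
  rownames(pp) <- NULL
  pp
}

#' Kaplan-Meier survival curve at yearly steps
#'
#' Product-limit estimate of the survival function from the cohort's
#' yearly follow-up, optionally stratified.
#'
#' @param cohort Cohort data.frame with `followup_time` and `died`.
#' @param by Optional name of a stratifying column (e.g. `"sex"` or an
#'   index tertile).
#' @return data.frame with `year`, `n_risk`, `n_event`, `survival` (and
#'   `stratum` when `by` is given).
#' @export
km_curve <- function(cohort, by = NULL) {
  if (nrow(cohort) < 1L) stop("need >= 1 participant", call. = FALSE)
  f <- if (is.null(by)) {
    survival::survfit(survival::Surv(followup_time, died) ~ 1,
                      data = cohort)
  } else {
    survival::survfit(
      as.formula(paste("survival::Surv(followup_time, died) ~", by)),
      data = cohort)
  }
  s <- summary(f, censored = TRUE)
  out <- data.frame(year = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    survival = s$surv)
  if (!is.null(by)) {
    out$stratum <- sub("^[^=]*=", "", as.character(s$strata))
  }
  out
}

#' Fit a discrete-time (person-period logistic) hazard model
#'
#' Logistic regression of the yearly event indicator on period dummies,
#' the predictors of interest, and adjustment covariates, by maximum
#' likelihood. With saturated period dummies and nothing else, the
#' predicted yearly hazards reproduce the Kaplan-Meier estimate exactly.
#' Non-convergence and separation are flagged on the returned object,
#' never raised as errors.
#'
#' @param pp Person-period table from [to_person_period()].
#' @param predictors Character vector of predictor columns (may be empty
#'   for a baseline-only fit).
#' @param covariates Character vector of adjustment columns (factors
#'   allowed). Rows with missing covariates are dropped with a logged
#'   count.
#' @return Object of class `fa_hazard_fit`: `coefficients` (data.frame
#'   with estimate, std_error, z, p_value), `log_lik`, `aic`, `deviance`,
#'   `null_deviance`, `fitted` (per-row event probabilities), `n_rows`,
#'   `n_dropped`, `converged`, `separation`, `predictors`, and the
#'   underlying `glm` object.
#' @export
fit_discrete_time <- function(pp, predictors = character(0),
                              covariates = character(0)) {
  cols <- c("event", "period", predictors, covariates)
  miss <- setdiff(cols, names(pp))
  if (length(miss)) {
    stop("person-period table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dat <- pp[cols]
  keep <- complete.cases(dat)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  for (v in predictors) {
    if (var(as.numeric(dat[[v]])) == 0) {
      stop("predictor '", v, "' is constant in the person-period table",
           call. = FALSE)
    }
  }
  rhs <- c("factor(period)", predictors, covariates)
  f <- as.formula(paste("event ~", paste(rhs, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) separation <<- TRUE
      if (grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- separation  # convergence captured from fit object
      }
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      std_error = cf[, 2], z = cf[, 3], p_value = cf[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(coefficients = coefs,
         log_lik = as.numeric(logLik(fit)),
         aic = AIC(fit),
         deviance = fit$deviance,
         null_deviance = fit$null.deviance,
         fitted = as.numeric(fitted(fit)),
         events = dat$event,
         n_rows = nrow(dat), n_dropped = n_dropped,
         converged = fit$converged, separation = separation,
         predictors = predictors, covariates = covariates,
         glm = fit),
    class = "fa_hazard_fit")
}

#' @export
print.fa_hazard_fit <- function(x, ...) {
  cat(sprintf(
    "<fa_hazard_fit> %d person-years (%d dropped), deviance %.2f, AIC %.2f\n",
    x$n_rows, x$n_dropped, x$deviance, x$aic))
  if (!x$converged) cat("  ** did not converge **\n")
  if (x$separation) cat("  ** separation flagged **\n")
  show <- x$coefficients[!grepl("^factor\\(period\\)|^\\(Intercept\\)",
                                x$coefficients$term), ]
  if (nrow(show)) print(show, row.names = FALSE, digits = 3)
  invisible(x)
}

# internal: Wald p-value of a single term in an fa_hazard_fit
.fa_term_p <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) NA_real_ else fit$coefficients$p_value[i]
}

#' Compare mortality prediction across index representations
#'
#' Fits one discrete-time hazard model per representation of the same
#' frailty model -- the continuous index, the dichotomous status, the
#' domain variables, the bias variables, and the raw input columns --
#' with identical adjustment covariates, and reports AUC (of the
#' predicted per-row event probabilities against the observed events,
#' with DeLong 95% CI), AIC, residual deviance, and the number of the
#' representation's own terms with Wald p < 0.05.
#'
#' @param cohort Cohort with index/status/domain/bias columns (see
#'   [add_indices()], [add_bias_variables()]).
#' @param model An [fa_model_spec()].
#' @param covariates Adjustment columns; default sex, race/ethnicity,
#'   education, per-capita income and wealth.
#' @param representations Named list mapping representation name to
#'   column set; `NULL` for the default five.
#' @return data.frame with one row per representation: `representation`,
#'   `n_predictors`, `auc`, `ci_low`, `ci_high`, `aic`, `deviance`,
#'   `n_significant`, `converged`.
#' @export
compare_representations <- function(cohort, model,
                                    covariates = c("sex_male",
                                                   "race_ethnicity",
                                                   "education",
                                                   "income_pc",
                                                   "wealth_pc"),
                                    representations = NULL) {
  stopifnot(inherits(model, "fa_model_spec"))
  id <- model$model_id
  if (is.null(representations)) {
    domain_cols <- if (!is.null(model$domains)) model$domains else
      model$items
    representations <- list(
      index = paste0("index_", id),
      status = paste0("status_", id),
      domains = domain_cols,
      bias = intersect(.fa_model_bias_cols(model), names(cohort)),
      inputs = model$input_columns)
  }
  pp <- to_person_period(cohort)
  covariates <- intersect(covariates, names(pp))
  out <- lapply(names(representations), function(nm) {
    preds <- representations[[nm]]
    fit <- fit_discrete_time(pp, predictors = preds,
                             covariates = covariates)
    a <- auc_with_ci(fit$fitted, fit$events)
    own <- fit$coefficients[fit$coefficients$term %in% preds, , drop = FALSE]
    data.frame(representation = nm, n_predictors = length(preds),
               auc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
               aic = fit$aic, deviance = fit$deviance,
               n_significant = sum(own$p_value < 0.05),
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
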