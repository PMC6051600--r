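#' Enumerate all k-variable equal-weight index definitions
#'
#' Streams (as a column-indexed matrix) every size-`k` subset of the
#' variable pool in lexicographic order, duplicate free. Over the default
#' 72-variable pool with `k = 4` this is `choose(72, 4) = 1,028,790`
#' definitions. An index must combine more than one variable, so `k >= 2`.
#'
#' @param pool Character vector of variable names (distinct).
#' @param k Subset size (2 <= k <= length(pool)).
#' @return Object of class `fa_index_definitions`: list with `pool`,
#'   `k`, `count`, and `subsets` (a `k x count` integer matrix of
#'   positions into `pool`).
#' @export
#' @examples
#' enumerate_k_subsets(letters[1:12], 4)$count  # 495
enumerate_k_subsets <- function(pool, k) {
  if (anyDuplicated(pool)) stop("pool names must be distinct", call. = FALSE)
  if (k < 2) stop("an index needs more than one variable (k >= 2)",
                  call. = FALSE)
  if (k > length(pool)) stop("k exceeds pool size", call. = FALSE)
  subsets <- combn(length(pool), k)
  structure(list(pool = pool, k = as.integer(k),
                 count = ncol(subsets), subsets = subsets),
            class = "fa_index_definitions")
}

#' @export
print.fa_index_definitions <- function(x, ...) {
  cat(sprintf("<fa_index_definitions> %d definitions: C(%d, %d)\n",
              x$count, length(x$pool), x$k))
  invisible(x)
}

#' Mine equal-weight k-item alternative indices
#'
#' For every size-`k` subset of the pool, forms the equal-weight index
#' (sum of the subset's [0,1]-scaled columns), fits the covariate-
#' adjusted discrete-time hazard model, and records the Wald p-value of
#' the index term, the model AIC and the residual deviance. Definitions
#' touching a variable with missing values in the analysis sample are
#' skipped with a logged count (`applicable = FALSE`); non-convergent
#' fits are recorded with `converged = FALSE` and excluded from
#' significance counts by [summarize_mining()].
#'
#' The per-candidate fits reuse one prebuilt design matrix (period
#' dummies + covariates) for speed; a test verifies the results equal
#' independent one-at-a-time `glm` refits.
#'
#' @param cohort Cohort with survival outcome and pool columns on a
#'   [0,1]-compatible numeric scale.
#' @param pool Character vector of candidate columns.
#' @param k Items per index (default 4).
#' @param covariates Adjustment columns (numeric or factor).
#' @return Object of class `fa_mining_results`: data.frame with
#'   `definition` (";"-joined names), `p_value`, `aic`,
#'   `residual_deviance`, `converged`, `applicable`; attributes `pool`,
#'   `k`, `n_skipped`.
#' @export
mine_indices <- function(cohort, pool, k = 4,
                         covariates = c("sex_male", "race_ethnicity",
                                        "education", "income_pc",
                                        "wealth_pc")) {
  miss <- setdiff(pool, names(cohort))
  if (length(miss)) {
    stop("pool column(s) not in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  covariates <- intersect(covariates, names(cohort))
  pp <- to_person_period(cohort)
  base_cols <- c("event", "period", covariates)
  keep <- complete.cases(pp[base_cols])
  pp <- pp[keep, , drop = FALSE]

  X0 <- model.matrix(
    as.formula(paste("~ factor(period)",
                     if (length(covariates))
                       paste("+", paste(covariates, collapse = " + "))
                     else "")),
    data = pp)
  y <- pp$event
  P <- as.matrix(sapply(pool, function(cl) as.numeric(pp[[cl]])))
  applicable_var <- !apply(P, 2, anyNA)

  defs <- enumerate_k_subsets(pool, k)
  m <- defs$count
  p_value <- aic <- dev <- rep(NA_real_, m)
  converged <- rep(NA, m)
  applicable <- rep(TRUE, m)
  idx_col <- ncol(X0) + 1L

  for (j in seq_len(m)) {
    sel <- defs$subsets[, j]
    if (!all(applicable_var[sel])) {
      applicable[j] <- FALSE
      next
    }
    X <- cbind(X0, index = rowSums(P[, sel, drop = FALSE]))
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(), control = list(maxit = 50)))
    converged[j] <- fit$converged
    dev[j] <- fit$deviance
    aic[j] <- fit$deviance + 2 * fit$rank
    # Wald p of the index term (dispersion fixed at 1)
    p1 <- seq_len(fit$rank)
    covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    est <- fit$coefficients[idx_col]
    pos <- match(idx_col, fit$qr$pivot[p1])
    if (!is.na(pos) && !is.na(est)) {
      se <- sqrt(covmat[pos, pos])
      p_value[j] <- 2 * pnorm(-abs(est / se))
    }
  }

  res <- data.frame(
    definition = apply(defs$subsets, 2,
                       function(s) paste(pool[s], collapse = ";")),
    p_value = p_value, aic = aic, residual_deviance = dev,
    converged = converged, applicable = applicable,
    stringsAsFactors = FALSE)
  structure(res, class = c("fa_mining_results", "data.frame"),
            pool = pool, k = k, n_skipped = sum(!applicable))
}

#' Summarize mining results against a reference index
#'
#' Counts the alternative indices that (a) are significant at `alpha`,
#' (b) have a lower p-value than the reference index's own hazard-model
#' p-value, and (c) have a lower residual deviance than the reference
#' fit; reports the best-performing definition and the variables common
#' to the top performers. Non-convergent or non-applicable candidates are
#' excluded from the significance counts and reported separately.
#'
#' @param results An [mine_indices()] table.
#' @param reference_p P-value of the reference index term in the same
#'   covariate-adjusted hazard model.
#' @param reference_deviance Residual deviance of the reference fit.
#' @param alpha Significance level (default 0.05).
#' @param top_n How many top performers to scan for common variables.
#' @return List of counts and the best definition.
#' @export
summarize_mining <- function(results, reference_p, reference_deviance,
                             alpha = 0.05, top_n = 10) {
  if (!nrow(results)) stop("empty mining results", call. = FALSE)
  ok <- results$applicable & !is.na(results$converged) & results$converged &
    !is.na(results$p_value)
  r <- results[ok, , drop = FALSE]
  n_sig <- sum(r$p_value < alpha)
  n_lower_p <- sum(r$p_value < reference_p)
  n_better_dev <- sum(r$residual_deviance < reference_deviance)
  best <- r$definition[which.min(r$p_value)]
  top <- r$definition[order(r$p_value)][seq_len(min(top_n, nrow(r)))]
  top_vars <- table(unlist(strsplit(top, ";")))
  common <- names(top_vars)[top_vars >= length(top) / 2]
  list(n_candidates = nrow(results),
       n_applicable = sum(results$applicable),
       n_converged = sum(ok),
       n_significant = n_sig,
       n_lower_p_than_reference = n_lower_p,
       n_better_deviance_than_reference = n_better_dev,
       best_definition = if (length(best)) best else NA_character_,
       common_top_variables = common,
       alpha = alpha)
}

#' Reference hazard fit for a model's own index
#'
#' Fits the covariate-adjusted discrete-time model with the model's
#' continuous index as sole predictor and returns the Wald p-value of
#' the index term plus the residual deviance -- the comparison baseline
#' for [summarize_mining()].
#'
#' @inheritParams mine_indices
#' @param model An [fa_model_spec()].
#' @return List `p_value`, `deviance`, `fit` (the `fa_hazard_fit`).
#' @export
reference_index_fit <- function(cohort, model,
                                covariates = c("sex_male",
                                               "race_ethnicity",
                                               "education", "income_pc",
                                               "wealth_pc")) {
  idx <- paste0("index_", model$model_id)
  pp <- to_person_period(cohort)
  fit <- fit_discrete_time(pp, predictors = idx,
                           covariates = intersect(covariates, names(pp)))
  list(p_value = .fa_term_p(fit, idx), deviance = fit$deviance, fit = fit)
}
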