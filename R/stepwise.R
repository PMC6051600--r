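# internal: fit statistics for a stepwise model
.fa_fit_stats <- function(fit, family, null_ll = NULL) {
  if (family == "linear") {
    s <- suppressWarnings(summary(fit))  # perfect fits are expected
    list(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         auc = NA_real_)
  } else {
    ll <- as.numeric(logLik(fit))
    k <- attr(logLik(fit), "df")
    mcf <- 1 - ll / null_ll
    adj <- 1 - (ll - k) / null_ll
    y <- fit$y
    auc <- if (length(unique(y)) == 2L && length(unique(fitted(fit))) > 1L) {
      as.numeric(pROC::auc(pROC::roc(y, fitted(fit), quiet = TRUE,
                                     direction = "<")))
    } else {
      NA_real_
    }
    list(r_squared = mcf, adj_r_squared = adj, auc = auc)
  }
}

#' Forward-stepwise variable selection by AIC
#'
#' At each step, every remaining candidate is added in turn to the
#' current model and the candidate giving the lowest AIC is accepted if
#' it strictly lowers the AIC; otherwise selection stops. Candidates that
#' are factors enter as a full dummy block. Exact AIC ties are broken by
#' candidate name order. Logistic candidates whose fit shows complete
#' separation are skipped and logged, never a crash.
#'
#' For the linear family the recorded fit statistic is (adjusted)
#' R-squared; for the logistic family it is McFadden's pseudo-R-squared
#' (`1 - logLik/logLik0`), an `adj_r_squared` penalizing the parameter
#' count (`1 - (logLik - k)/logLik0`), and the in-sample AUC.
#'
#' @param data data.frame holding response and candidates.
#' @param response Name of the response column (numeric for linear, 0/1
#'   for logistic).
#' @param candidates Character vector of candidate column names.
#' @param family `"linear"` or `"logistic"`.
#' @param max_steps Maximum number of accepted steps (default: all
#'   candidates).
#' @param include Columns forced into every model (e.g. demographic
#'   adjusters), never reported as selected steps.
#' @return An object of class `fa_selection_path`: list with `steps`
#'   (data.frame: step, variable, aic, r_squared, adj_r_squared, auc),
#'   `null_aic`, `family`, `response`, `skipped`.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), x1 = rnorm(50), x2 = rnorm(50))
#' d$y <- d$x1 + 0.1 * rnorm(50)
#' forward_stepwise(d, "y", c("x1", "x2"))$steps$variable[1]
forward_stepwise <- function(data, response, candidates,
                             family = c("linear", "logistic"),
                             max_steps = length(candidates),
                             include = NULL) {
  family <- match.arg(family)
  if (length(candidates) < 1L) stop("need >= 1 candidate", call. = FALSE)
  if (var(as.numeric(data[[response]]), na.rm = TRUE) == 0) {
    stop("response is constant", call. = FALSE)
  }
  candidates <- sort(unique(candidates))
  fitter <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    f <- as.formula(paste(response, "~", rhs))
    if (family == "linear") {
      lm(f, data = data)
    } else {
      glm(f, data = data, family = binomial())
    }
  }
  base_terms <- include
  cur_fit <- fitter(base_terms)
  null_ll <- if (family == "logistic") {
    as.numeric(logLik(glm(as.formula(paste(response, "~ 1")),
                          data = data, family = binomial())))
  } else {
    NULL
  }
  cur_aic <- AIC(cur_fit)
  null_aic <- cur_aic
  chosen <- character(0)
  skipped <- character(0)
  steps <- list()

  while (length(chosen) < max_steps) {
    remaining <- setdiff(candidates, c(chosen, skipped))
    if (!length(remaining)) break
    aics <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      sep_flag <- FALSE
      fit <- withCallingHandlers(
        fitter(c(base_terms, chosen, remaining[i])),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                    conditionMessage(w))) {
            sep_flag <<- TRUE
          }
          invokeRestart("muffleWarning")
        })
      if (family == "logistic" && !isTRUE(fit$converged)) sep_flag <- TRUE
      if (sep_flag) {
        skipped <- c(skipped, remaining[i])
      } else {
        aics[i] <- AIC(fit)
        fits[[i]] <- fit
      }
    }
    if (all(is.na(aics))) break
    best <- which.min(aics)  # remaining is name-sorted: ties -> first name
    if (aics[best] >= cur_aic) break
    chosen <- c(chosen, remaining[best])
    cur_fit <- fits[[best]]
    cur_aic <- aics[best]
    st <- .fa_fit_stats(cur_fit, family, null_ll)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(chosen), variable = remaining[best], aic = cur_aic,
      r_squared = st$r_squared, adj_r_squared = st$adj_r_squared,
      auc = st$auc, stringsAsFactors = FALSE)
    # a numerically perfect linear fit cannot be improved further: stop
    # before rounding noise in the AIC fabricates extra steps
    if (family == "linear" && st$r_squared >= 1 - 1e-12) break
  }

  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(0), variable = character(0),
               aic = numeric(0), r_squared = numeric(0),
               adj_r_squared = numeric(0), auc = numeric(0))
  structure(list(steps = steps, null_aic = null_aic, family = family,
                 response = response, include = include,
                 skipped = unique(skipped)),
            class = "fa_selection_path")
}

#' @export
print.fa_selection_path <- function(x, ...) {
  cat(sprintf("<fa_selection_path> %s response '%s': %d step(s)\n",
              x$family, x$response, nrow(x$steps)))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  if (length(x$skipped)) {
    cat("skipped (separation):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit-statistic curve of a selection path
#'
#' Tabulates the fit statistic per accepted step (the data behind an
#' R-squared-by-number-of-variables curve). For the linear family the
#' unadjusted R-squared sequence is non-decreasing because the models are
#' nested.
#'
#' @param path An [forward_stepwise()] result.
#' @return data.frame with `step`, `variable`, `r_squared`,
#'   `adj_r_squared`, `auc`.
#' @export
r2_curve <- function(path) {
  stopifnot(inherits(path, "fa_selection_path"))
  if (!nrow(path$steps)) stop("empty selection path", call. = FALSE)
  path$steps[c("step", "variable", "r_squared", "adj_r_squared", "auc")]
}

#' Number of variables needed to reach a variance-explained target
#'
#' Smallest accepted step at which the path's R-squared reaches
#' `fraction` times the maximum R-squared over the whole path (e.g. how
#' many input variables explain 90% of the explainable index variance).
#'
#' @param path An [forward_stepwise()] result.
#' @param fraction Target fraction in (0, 1].
#' @return Integer step count, or `NA` if the target is never reached.
#' @export
variables_to_reach <- function(path, fraction) {
  stopifnot(inherits(path, "fa_selection_path"))
  if (!nrow(path$steps)) stop("empty selection path", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  r2 <- path$steps$r_squared
  target <- fraction * max(r2)
  hit <- which(r2 >= target - 1e-12)
  if (length(hit)) path$steps$step[hit[1]] else NA_integer_
}

#' AUC with a DeLong 95% confidence interval
#'
#' Rank-based area under the ROC curve (the probability that a random
#' positive outscores a random negative, ties counted one half) with a
#' DeLong-type 95% CI, clipped to [0, 1].
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes must be present).
#' @return List `auc`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' auc_with_ci(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc  # 1
auc_with_ci <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels[!is.na(labels)])) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
    error = function(e) rep(as.numeric(pROC::auc(r)), 3))
  list(auc = as.numeric(pROC::auc(r)),
       ci_low = max(0, ci[1]), ci_high = min(1, ci[3]))
}
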