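# internal: least-squares R^2 of y on the columns of X (with intercept).
# lm's pivoting handles rank-deficient designs (minimum-norm style
# pseudo-inverse behaviour): residuals remain valid least-squares
# residuals, never an error.
.fa_r2 <- function(y, X) {
  X <- as.matrix(X)
  fit <- lm(y ~ X)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance", call. = FALSE)
  1 - sum(resid(fit)^2) / tss
}

#' Bias variable of a domain
#'
#' The bias of a derived domain variable is the part of it that its own
#' theory-based input variables cannot explain: the residual of an
#' ordinary-least-squares regression (with intercept) of the domain on
#' its input design columns. By construction the bias has mean zero and
#' is orthogonal to the inputs; it is nonzero exactly where manipulation
#' (right-censoring, categorization, thresholding) created information
#' not linearly present in the inputs. Rank-deficient designs are handled
#' through `lm`'s pivoting and never crash.
#'
#' @param domain Numeric domain-value vector.
#' @param inputs data.frame/matrix of the domain's input design columns
#'   (binary/ordinal inputs on their scaled values).
#' @return List with `bias` (residual vector), `fitted`, and `r_squared`
#'   (of the domain on its inputs).
#' @export
#' @examples
#' h <- c(0, 1, 0, 1); e <- c(0, 0, 1, 1)
#' sens <- pmin(h + e, 1)
#' domain_bias(sens, cbind(h, e))$bias  # nonzero only where h = e = 1
domain_bias <- function(domain, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) < 1L) stop("need at least one input column", call. = FALSE)
  if (nrow(inputs) != length(domain)) {
    stop("rows of `inputs` must align with `domain`", call. = FALSE)
  }
  fit <- lm(domain ~ inputs)
  res <- as.numeric(resid(fit))
  tss <- sum((domain - mean(domain))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(res^2) / tss
  list(bias = res, fitted = as.numeric(fitted(fit)), r_squared = r2)
}

#' Dichotomization bias
#'
#' The information added by thresholding a continuous index into a 0/1
#' status: `status - index`, where status is 1 iff the index meets the
#' cutoff. An index of 0.9 at cutoff 0.2 needs +0.1 of bias to become the
#' status 1; an index of 0.1 needs -0.1 to become the status 0.
#'
#' @param index Numeric index values.
#' @param cutoff Frailty cutoff (status = 1 iff index >= cutoff).
#' @param index_range Optional length-2 range for validation.
#' @return Numeric bias vector (`status - index`).
#' @export
#' @examples
#' dichotomization_bias(c(0.9, 0.1), cutoff = 0.2)  # 0.1 -0.1
dichotomization_bias <- function(index, cutoff, index_range = NULL) {
  if (!is.null(index_range)) {
    if (cutoff < index_range[1] || cutoff > index_range[2]) {
      stop("`cutoff` outside `index_range`", call. = FALSE)
    }
    if (any(index < index_range[1] | index > index_range[2], na.rm = TRUE)) {
      stop("index value outside `index_range`", call. = FALSE)
    }
  }
  as.integer(index >= cutoff) - index
}

#' Append the nine domain-level bias columns
#'
#' Runs [domain_bias()] for every domain recipe and appends the residual
#' as `bias__<domain>`. Dichotomization bias is reported separately (see
#' [dichotomization_bias()]) and is not part of the nine default bias
#' variables.
#'
#' @param cohort A cohort data.frame with domain columns (see
#'   [build_domains()]).
#' @return `cohort` with `bias__*` columns appended; the per-domain
#'   input R-squared values are attached as attribute `"bias_r2"`.
#' @export
add_bias_variables <- function(cohort) {
  recipes <- .fa_domain_recipes()
  miss <- setdiff(names(recipes), names(cohort))
  if (length(miss)) cohort <- build_domains(cohort)
  r2s <- numeric(0)
  for (d in names(recipes)) {
    db <- domain_bias(cohort[[d]], cohort[recipes[[d]]$bias_inputs])
    cohort[[paste0("bias__", d)]] <- db$bias
    r2s[d] <- db$r_squared
  }
  attr(cohort, "bias_r2") <- r2s
  cohort
}

#' Variance shares of an index: inputs vs bias
#'
#' Regresses a constructed index on (a) its own input design columns,
#' (b) its domain-level bias variables, and (c) both, reporting the three
#' R-squared values. Because every domain equals its input fit plus its
#' bias, the index is an exact linear combination of inputs and bias, so
#' `r2_both` is 1 up to machine precision; `1 - r2_inputs` is the share
#' of index variance created purely by data manipulation.
#'
#' @param index Numeric index vector.
#' @param inputs data.frame/matrix of the model's input design columns.
#' @param bias data.frame/matrix of the model's bias columns.
#' @return List `r2_inputs`, `r2_bias`, `r2_both`, and
#'   `unexplained_by_inputs` (= 1 - r2_inputs).
#' @export
index_bias_share <- function(index, inputs, bias) {
  inputs <- as.matrix(inputs)
  bias <- as.matrix(bias)
  if (nrow(inputs) != length(index) || nrow(bias) != length(index)) {
    stop("rows of `inputs`/`bias` must align with `index`", call. = FALSE)
  }
  r2_inputs <- .fa_r2(index, inputs)
  r2_bias <- .fa_r2(index, bias)
  r2_both <- .fa_r2(index, cbind(inputs, bias))
  list(r2_inputs = r2_inputs, r2_bias = r2_bias, r2_both = r2_both,
       unexplained_by_inputs = 1 - r2_inputs)
}

# internal: bias columns belonging to one model
.fa_model_bias_cols <- function(model) {
  if (!is.null(model$domains)) {
    paste0("bias__", model$domains)
  } else {
    "bias__burden_cognition"
  }
}

#' Variance decomposition for a fitted model on a cohort
#'
#' Convenience wrapper around [index_bias_share()] using the model's
#' declared input columns and its domains' bias columns.
#'
#' @param cohort Cohort with index and bias columns (see [add_indices()]
#'   and [add_bias_variables()]).
#' @param model An [fa_model_spec()].
#' @return See [index_bias_share()].
#' @export
model_bias_share <- function(cohort, model) {
  idx_col <- paste0("index_", model$model_id)
  if (!idx_col %in% names(cohort)) {
    stop("cohort lacks ", idx_col, "; run add_indices() first",
         call. = FALSE)
  }
  index_bias_share(cohort[[idx_col]],
                   cohort[model$input_columns],
                   cohort[.fa_model_bias_cols(model)])
}
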