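#' Chained-equations imputation (single completed dataset)
#'
#' Iterative conditional imputation: starting from random draws of each
#' incomplete variable's observed values, every incomplete variable is
#' regressed in turn on the other imputation variables plus demographic
#' predictors, and its missing cells are replaced by stochastic draws
#' from the fitted conditional (linear model with residual noise for
#' continuous variables, Bernoulli draws from a logistic fit for binary
#' ones, a rounded and range-clamped linear latent fit for ordinal
#' ranks), cycling `n_iterations` times. One completed dataset is
#' returned; the whole procedure is deterministic given `seed`.
#'
#' @param table Cohort data.frame with missing cells only in the
#'   variables to impute.
#' @param columns Columns to impute; default every raw registry variable
#'   present that contains `NA`s.
#' @param predictors Complete columns used (with the other imputation
#'   variables) on the right-hand side; default age, sex, education.
#' @param n_iterations Number of full cycles (default 10).
#' @param seed Integer seed.
#' @return The completed table; returned unchanged if nothing is
#'   missing.
#' @export
impute_chained <- function(table, columns = NULL,
                           predictors = c("age", "sex_male", "education"),
                           n_iterations = 10, seed = 1L) {
  vars <- fa_variables()
  if (is.null(columns)) {
    cand <- intersect(vars$name[vars$role == "raw"], names(table))
    columns <- cand[vapply(table[cand], anyNA, logical(1))]
  }
  if (!length(columns)) return(table)
  for (cl in columns) {
    if (all(is.na(table[[cl]]))) {
      stop("column '", cl, "' has no observed values", call. = FALSE)
    }
  }
  predictors <- setdiff(intersect(predictors, names(table)), columns)
  kind <- setNames(vars$kind, vars$name)
  ncat <- setNames(vars$n_categories, vars$name)
  miss_idx <- lapply(table[columns], function(x) which(is.na(x)))

  with_seed(seed, {
    # initialization: random draws from the observed marginal
    for (cl in columns) {
      i <- miss_idx[[cl]]
      obs <- table[[cl]][!is.na(table[[cl]])]
      table[[cl]][i] <- sample(obs, length(i), replace = TRUE)
    }
    for (iter in seq_len(n_iterations)) {
      for (cl in columns) {
        i <- miss_idx[[cl]]
        if (!length(i)) next
        rhs <- c(setdiff(columns, cl), predictors)
        X <- cbind(1, as.matrix(table[rhs]))
        y <- table[[cl]]
        obs_rows <- setdiff(seq_len(nrow(X)), i)  # truly observed rows
        k <- if (cl %in% names(kind)) kind[[cl]] else "continuous"
        if (k == "binary") {
          fit <- suppressWarnings(
            glm.fit(X[obs_rows, , drop = FALSE], y[obs_rows],
                    family = binomial()))
          cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          p <- plogis(drop(X[i, , drop = FALSE] %*% cf))
          table[[cl]][i] <- rbinom(length(i), 1, p)
        } else {
          fit <- lm.fit(X[obs_rows, , drop = FALSE], y[obs_rows])
          cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
          mu_all <- drop(X %*% cf)
          if (k == "ordinal") {
            sigma <- sqrt(sum(fit$residuals^2) /
                            max(1, length(obs_rows) - fit$rank))
            draw <- mu_all[i] + rnorm(length(i), 0, sigma)
            table[[cl]][i] <- as.integer(pmin(pmax(round(draw), 1L),
                                              ncat[[cl]]))
          } else {
            # predictive mean matching (5 donors) keeps continuous
            # measures on their observed support (e.g. non-negative);
            # donors located on the sorted fitted values
            o <- obs_rows[order(mu_all[obs_rows])]
            mu_o <- mu_all[o]
            n_o <- length(o)
            pos <- findInterval(mu_all[i], mu_o)
            for (jj in seq_along(i)) {
              win <- max(1L, pos[jj] - 5L):min(n_o, pos[jj] + 5L)
              d <- abs(mu_o[win] - mu_all[i[jj]])
              donors <- o[win[order(d)[seq_len(min(5L, length(win)))]]]
              table[[cl]][i[jj]] <- y[sample(donors, 1L)]
            }
          }
        }
      }
    }
    table
  })
}
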