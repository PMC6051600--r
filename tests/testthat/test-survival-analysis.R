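test_that("person-period expansion conserves rows and places events last", {
  d1 <- data.frame(id = 1, followup_time = 3L, died = 1L)
  pp1 <- to_person_period(d1)
  expect_equal(nrow(pp1), 3)
  expect_equal(pp1$event, c(0L, 0L, 1L))
  expect_equal(pp1$period, 1:3)

  d2 <- data.frame(id = 1, followup_time = 13L, died = 0L)
  expect_equal(sum(to_person_period(d2)$event), 0)
  expect_equal(nrow(to_person_period(d2)), 13)

  ch <- small_cohort(400, seed = 1)
  pp <- to_person_period(ch)
  expect_equal(nrow(pp), sum(ch$followup_time))
  expect_equal(sum(pp$event), sum(ch$died))
  expect_error(to_person_period(data.frame(followup_time = NA, died = 1L)),
               "missing followup_time")
})

test_that("Kaplan-Meier handles degenerate and hand-checked cohorts", {
  none <- data.frame(followup_time = rep(5L, 4), died = 0L)
  expect_true(all(km_curve(none)$survival == 1))

  all1 <- data.frame(followup_time = rep(1L, 4), died = 1L)
  expect_equal(km_curve(all1)$survival, 0)

  # 6 participants: deaths at years 1, 2, 2; censored at 1, 3, 3
  six <- data.frame(followup_time = c(1L, 1L, 2L, 2L, 3L, 3L),
                    died = c(1L, 0L, 1L, 1L, 0L, 0L))
  km <- km_curve(six)
  expect_equal(km$survival[km$year == 1], 1 - 1 / 6)
  expect_equal(km$survival[km$year == 2], (1 - 1 / 6) * (1 - 2 / 4))
})

test_that("an intercept-only discrete-time fit recovers the logit hazard", {
  ch <- null_cohort(2500, seed = 2, hazard = 0.1, followup = 8)
  pp <- to_person_period(ch)
  fit <- glm(event ~ 1, data = pp, family = binomial())
  est <- coef(summary(fit))
  expect_lt(abs(est[1, 1] - qlogis(0.1)), 2 * est[1, 2])
})

test_that("saturated period dummies reproduce the Kaplan-Meier curve", {
  ch <- small_cohort(1500, seed = 3)
  pp <- to_person_period(ch)
  fit <- fit_discrete_time(pp)
  hz <- tapply(fit$fitted, pp$period, mean)
  surv_glm <- cumprod(1 - hz)
  km <- km_curve(ch)
  expect_equal(as.numeric(surv_glm[as.character(km$year)]), km$survival,
               tolerance = 1e-8)
})

test_that("generator hazard coefficients are recovered", {
  ch <- small_cohort(2500, seed = 4, max_followup = 8,
                     hazard_betas = c(frailty_z = 0.5))
  fit <- fit_discrete_time(to_person_period(ch), predictors = "frailty_z")
  cf <- fit$coefficients[fit$coefficients$term == "frailty_z", ]
  expect_lt(abs(cf$estimate - 0.5), 2 * cf$std_error)
  expect_lt(cf$p_value, 0.05)
})

test_that("adding predictors never increases residual deviance", {
  ch <- indexed_cohort(600, seed = 5)
  pp <- to_person_period(ch)
  base <- fit_discrete_time(pp, predictors = "index_FD")
  more <- fit_discrete_time(pp, predictors = c("index_FD", "age"))
  expect_lte(more$deviance, base$deviance + 1e-8)
  expect_equal(base$aic, 2 * (nrow(base$coefficients)) - 2 * base$log_lik,
               tolerance = 1e-8)
})

test_that("the input representation nests the equal-weight index", {
  ch <- indexed_cohort(800, seed = 6)
  pool <- c("dizziness", "poor_hearing", "weight_loss", "stroke_history")
  ch$ew_index <- rowSums(ch[pool])
  pp <- to_person_period(ch)
  f_idx <- fit_discrete_time(pp, predictors = "ew_index",
                             covariates = "sex_male")
  f_inp <- fit_discrete_time(pp, predictors = pool,
                             covariates = "sex_male")
  expect_lte(f_inp$deviance, f_idx$deviance + 1e-8)
})

test_that("representation comparison returns a coherent table", {
  ch <- indexed_cohort(900, seed = 7)
  tab <- compare_representations(ch, fa_models()$FD)
  expect_setequal(tab$representation,
                  c("index", "status", "domains", "bias", "inputs"))
  expect_true(all(tab$auc >= 0.5 & tab$auc <= 1))
  expect_true(all(tab$ci_low <= tab$auc & tab$auc <= tab$ci_high))
  expect_true(all(tab$converged))
  # inputs span the index's information: never a worse deviance
  expect_lte(tab$deviance[tab$representation == "inputs"],
             tab$deviance[tab$representation == "index"] + 1e-8)
})

test_that("on a zero-effect cohort predictive power collapses to chance", {
  ch <- null_cohort(1200, seed = 8)
  ch <- add_bias_variables(add_indices(ch))
  tab <- compare_representations(ch, fa_models()$FD,
                                 covariates = character(0))
  # single-coefficient representations: CI covers 0.5; multi-parameter
  # ones carry only the small in-sample optimism of fitting noise
  one <- tab$representation %in% c("index", "status")
  expect_true(all(tab$ci_low[one] <= 0.5 & 0.5 <= tab$ci_high[one]))
  expect_true(all(abs(tab$auc - 0.5) < 0.06))
})
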