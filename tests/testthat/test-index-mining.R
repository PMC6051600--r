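test_that("subset enumeration is exact, lexicographic and duplicate-free", {
  expect_equal(enumerate_k_subsets(letters[1:4], 4)$count, 1)
  e <- enumerate_k_subsets(paste0("v", 1:12), 4)
  expect_equal(e$count, 495)
  expect_equal(e$count, choose(12, 4))
  keys <- apply(e$subsets, 2, paste, collapse = "-")
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(diff(order(keys)) != 0))  # returned in a stable order
  # closed form vs explicit generation across a grid
  for (n in c(5, 9, 14)) {
    for (k in c(2, 3, 4)) {
      expect_equal(enumerate_k_subsets(paste0("x", 1:n), k)$count,
                   choose(n, k))
    }
  }
  expect_error(enumerate_k_subsets(letters[1:5], 1), "more than one")
  expect_error(enumerate_k_subsets(letters[1:3], 4), "exceeds")
})

test_that("mining equals independent one-at-a-time glm refits", {
  ch <- indexed_cohort(500, seed = 1)
  pool <- c("dizziness", "poor_hearing", "weight_loss", "stroke_history",
            "diabetes", "incontinence", "fall_history", "arthritis")
  res <- mine_indices(ch, pool, k = 4, covariates = "sex_male")
  expect_equal(nrow(res), choose(8, 4))
  pp <- to_person_period(ch)
  defs <- enumerate_k_subsets(pool, 4)
  for (j in seq(1, defs$count, by = 7)) {  # spot-check a sixth of them
    sel <- pool[defs$subsets[, j]]
    pp$alt <- rowSums(pp[sel])
    fit <- glm(event ~ factor(period) + sex_male + alt, data = pp,
               family = binomial())
    cf <- coef(summary(fit))["alt", ]
    expect_equal(res$p_value[j], unname(cf[4]), tolerance = 1e-6)
    expect_equal(res$residual_deviance[j], fit$deviance, tolerance = 1e-8)
    expect_equal(res$aic[j], AIC(fit), tolerance = 1e-8)
  }
})

test_that("mining is deterministic and skips unmeasured variables", {
  ch <- indexed_cohort(300, seed = 2)
  ch$holey <- ch$dizziness
  ch$holey[1:5] <- NA
  pool <- c("holey", "poor_hearing", "weight_loss", "stroke_history",
            "diabetes")
  r1 <- mine_indices(ch, pool, k = 4, covariates = character(0))
  r2 <- mine_indices(ch, pool, k = 4, covariates = character(0))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  skipped <- !r1$applicable
  expect_equal(sum(skipped), choose(4, 3))  # every subset containing holey
  expect_true(all(grepl("holey", r1$definition[skipped])))
  expect_true(all(is.na(r1$p_value[skipped])))
  expect_equal(attr(r1, "n_skipped"), sum(skipped))
})

test_that("summaries count significance and reference comparisons", {
  fixture <- structure(
    data.frame(definition = paste0("d", 1:5),
               p_value = c(0.01, 0.2, 0.04, 0.5, 0.001),
               aic = 101:105,
               residual_deviance = c(90, 95, 85, 99, 80),
               converged = TRUE, applicable = TRUE),
    class = c("fa_mining_results", "data.frame"))
  s <- summarize_mining(fixture, reference_p = 0.03,
                        reference_deviance = 88)
  expect_equal(s$n_significant, 3)
  expect_equal(s$n_lower_p_than_reference, 2)
  expect_equal(s$n_better_deviance_than_reference, 2)
  expect_equal(s$best_definition, "d5")

  # self-comparison: nothing beats the reference itself
  self <- fixture[1, ]
  s2 <- summarize_mining(self, reference_p = self$p_value,
                         reference_deviance = self$residual_deviance)
  expect_equal(s2$n_lower_p_than_reference, 0)
  expect_equal(s2$n_better_deviance_than_reference, 0)

  # summaries are order-invariant
  s3 <- summarize_mining(fixture[5:1, ], reference_p = 0.03,
                         reference_deviance = 88)
  expect_equal(s3$n_significant, s$n_significant)
  expect_equal(s3$n_lower_p_than_reference, s$n_lower_p_than_reference)
})

test_that("a true hazard driver beats noise inside candidate indices", {
  ch <- small_cohort(4000, seed = 3, frailty_loading = 0,
                     hazard_betas = c(frailty_z = 1.0))
  ch$driver <- (ch$frailty_z - min(ch$frailty_z)) /
    diff(range(ch$frailty_z))
  set.seed(990)  # well away from the cohort/survival seed stream
  for (j in 1:3) ch[[paste0("noise", j)]] <- runif(nrow(ch))
  pool <- c("driver", paste0("noise", 1:3), "dizziness", "poor_hearing")
  res <- mine_indices(ch, pool, k = 4, covariates = character(0))
  with_driver <- grepl("driver", res$definition)
  expect_gt(min(-log10(res$p_value[with_driver])),
            max(-log10(res$p_value[!with_driver])))
})

test_that("the reference index fit exposes its p-value and deviance", {
  ch <- indexed_cohort(800, seed = 5)
  ref <- reference_index_fit(ch, fa_models()$FD,
                             covariates = "sex_male")
  expect_true(ref$p_value > 0 && ref$p_value < 1)
  expect_true(ref$deviance > 0)
  expect_s3_class(ref$fit, "fa_hazard_fit")
})
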