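test_that("a perfect predictor is chosen first and stops the path", {
  set.seed(1)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
  d$y <- 2 * d$x2
  p <- forward_stepwise(d, "y", c("x1", "x2", "x3"), family = "linear")
  expect_equal(p$steps$variable[1], "x2")
  expect_equal(p$steps$r_squared[1], 1, tolerance = 1e-12)
  expect_equal(nrow(p$steps), 1)
})

test_that("selection order matches descending |correlation| for orthonormal candidates", {
  set.seed(2)
  n <- 64
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  d <- as.data.frame(Q)
  names(d) <- paste0("c", 1:4)
  d$y <- 0.9 * Q[, 3] + 0.5 * Q[, 1] + 0.2 * Q[, 4] + 0.05 * Q[, 2] +
    rnorm(n, 0, 0.01)
  p <- forward_stepwise(d, "y", paste0("c", 1:4), family = "linear")
  ord <- order(-abs(cor(d$y, Q)))
  expect_equal(p$steps$variable, paste0("c", 1:4)[ord])
})

test_that("stepwise choices equal the exhaustive single-step search and stats::step", {
  set.seed(3)
  n <- 200
  d <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(d) <- paste0("v", 1:8)
  d$y <- 1.5 * d$v2 - 1.0 * d$v5 + 0.6 * d$v7 + rnorm(n)
  cands <- paste0("v", 1:8)
  p <- forward_stepwise(d, "y", cands, family = "linear")

  # oracle 1: brute-force per-step refits
  chosen <- character(0)
  cur_aic <- AIC(lm(y ~ 1, data = d))
  oracle <- character(0)
  repeat {
    rem <- setdiff(cands, chosen)
    if (!length(rem)) break
    aics <- sapply(rem, function(v) {
      AIC(lm(as.formula(paste("y ~", paste(c(chosen, v), collapse = "+"))),
             data = d))
    })
    if (min(aics) >= cur_aic) break
    best <- rem[which.min(aics)]
    chosen <- c(chosen, best)
    oracle <- c(oracle, best)
    cur_aic <- min(aics)
  }
  expect_equal(p$steps$variable, oracle)

  # oracle 2: stats::step forward selection picks the same sequence
  st <- stats::step(lm(y ~ 1, data = d),
                    scope = as.formula(paste("~", paste(cands,
                                                        collapse = "+"))),
                    direction = "forward", trace = 0)
  step_vars <- setdiff(all.vars(formula(st)), "y")
  expect_setequal(p$steps$variable, step_vars)
})

test_that("pure-noise candidates only enter on strict AIC improvement", {
  set.seed(4)
  d <- as.data.frame(matrix(rnorm(500 * 10), 500, 10))
  names(d) <- paste0("n", 1:10)
  d$y <- rnorm(500)
  p <- forward_stepwise(d, "y", paste0("n", 1:10), family = "linear")
  expect_lte(nrow(p$steps), 5)
  aics <- c(p$null_aic, p$steps$aic)
  expect_true(all(diff(aics) < 0))
  # every recorded AIC equals an independent refit from the log-likelihood
  for (i in seq_len(nrow(p$steps))) {
    fit <- lm(as.formula(paste("y ~", paste(p$steps$variable[1:i],
                                            collapse = "+"))), data = d)
    expect_equal(p$steps$aic[i],
                 2 * attr(logLik(fit), "df") - 2 * as.numeric(logLik(fit)),
                 tolerance = 1e-8)
  }
})

test_that("logistic paths record a pseudo-R2 and AUC and drop separation", {
  set.seed(5)
  n <- 300
  d <- data.frame(x = rnorm(n), junk = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1.5 * d$x))
  d$sep <- d$y  # perfectly separating candidate
  p <- forward_stepwise(d, "y", c("x", "junk", "sep"), family = "logistic")
  expect_true("sep" %in% p$skipped)
  expect_equal(p$steps$variable[1], "x")
  expect_true(all(p$steps$auc > 0.5 & p$steps$auc <= 1))
  expect_true(all(p$steps$r_squared >= 0 & p$steps$r_squared <= 1))
})

test_that("the R2 curve equals refit-from-scratch values and is monotone", {
  ch <- indexed_cohort(800, seed = 9)
  m <- fa_models()$FD
  p <- forward_stepwise(ch, "index_FD", m$input_columns, family = "linear")
  curve <- r2_curve(p)
  expect_true(all(diff(curve$r_squared) > -1e-12))
  for (i in seq_len(nrow(curve))) {
    fit <- lm(as.formula(paste("index_FD ~",
                               paste(curve$variable[1:i], collapse = "+"))),
              data = ch)
    expect_equal(curve$r_squared[i], summary(fit)$r.squared,
                 tolerance = 1e-10)
  }
  # with bias variables added the curve reaches R2 = 1
  p2 <- forward_stepwise(ch, "index_FD",
                         c(m$input_columns,
                           paste0("bias__", m$domains)),
                         family = "linear")
  expect_equal(max(p2$steps$r_squared), 1, tolerance = 1e-8)
})

test_that("variables_to_reach reports the simplification count", {
  set.seed(6)
  d <- data.frame(x = rnorm(50))
  d$y <- d$x
  p <- forward_stepwise(d, "y", "x", family = "linear")
  expect_equal(variables_to_reach(p, 0.9), 1)

  # a Burden-like sum of exchangeable items can be simplified
  ch <- indexed_cohort(1500, seed = 10)
  m <- fa_models()$burden
  pb <- forward_stepwise(ch, "index_burden", m$input_columns,
                         family = "linear")
  n90 <- variables_to_reach(pb, 0.90)
  expect_lt(n90, 24)
  expect_equal(variables_to_reach(pb, 1.0), nrow(pb$steps))
})

test_that("AUC matches the brute-force pairwise probability", {
  a <- auc_with_ci(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(a$auc, 1)

  set.seed(7)
  scores <- round(rnorm(120), 1)  # ties on purpose
  labels <- rbinom(120, 1, 0.4)
  a2 <- auc_with_ci(scores, labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(a2$auc, mean(cmp), tolerance = 1e-12)
  expect_true(a2$ci_low <= a2$auc && a2$auc <= a2$ci_high)

  set.seed(8)
  a3 <- auc_with_ci(rnorm(2000), rbinom(2000, 1, 0.5))
  expect_true(a3$ci_low <= 0.5 && 0.5 <= a3$ci_high)
  expect_error(auc_with_ci(1:5, rep(1, 5)), "both classes")
})
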