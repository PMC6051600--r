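test_that("ordinal rescaling maps ranks linearly onto [0,1]", {
  expect_equal(rescale_ordinal(1:5, 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(rescale_ordinal(4, 5), 0.75)
  expect_equal(rescale_ordinal(1, 7), 0)
  expect_equal(rescale_ordinal(2, 4), 1 / 3)
  expect_equal(rescale_ordinal(1:2, 2), c(0, 1))  # dichotomous
  expect_true(is.na(rescale_ordinal(NA, 5)))
  expect_error(rescale_ordinal(6, 5), "out of range")
  expect_error(rescale_ordinal(1, 1), ">= 2")
})

test_that("censored sums cap at one as the sensory-domain rule requires", {
  expect_equal(censored_sum(c(1, 1)), 1)  # two problems, one subtracted
  expect_equal(censored_sum(c(0, 0)), 0)
  expect_equal(censored_sum(c(1, 0)), 1)
  m <- cbind(hearing = c(0, 1, 0, 1), eyesight = c(0, 0, 1, 1))
  expect_equal(censored_sum(m), c(0, 1, 1, 1))
  expect_error(censored_sum(c(0, 2)), "0/1")
})

test_that("quantile flags pick the empirical tail with deterministic ties", {
  expect_equal(stratified_quantile_flag(1:10, rep(1, 10), q = 0.2),
               c(1, 1, rep(0, 8)))
  expect_equal(stratified_quantile_flag(1:10, rep(1, 10), q = 0.2,
                                        direction = "highest"),
               c(rep(0, 8), 1, 1))
  # all-equal values: the tie rule flags everyone, never a partial split
  expect_equal(stratified_quantile_flag(rep(2, 6), rep(1, 6), q = 0.2),
               rep(1, 6))
  # strata are respected
  f <- stratified_quantile_flag(c(1:5, 1:5), rep(1:2, each = 5), q = 0.2)
  expect_equal(f, rep(c(1, 0, 0, 0, 0), 2))
})

test_that("unweighted percentiles over-cover skew-weighted populations", {
  set.seed(42)
  n <- 2000
  v <- rnorm(n)
  w <- exp(2 * v)  # weight skewed towards high values
  unw <- stratified_quantile_flag(v, rep(1, n), q = 0.2)
  cov_unw <- sum(w[unw == 1]) / sum(w)
  expect_lt(cov_unw, 0.1)  # far from 20% of the weighted population
  wt <- stratified_quantile_flag(v, rep(1, n), q = 0.2, weights = w)
  cov_wt <- sum(w[wt == 1]) / sum(w)
  expect_within(cov_wt, 0.2, max(w) / sum(w))
})

test_that("domains follow their recipes", {
  ch <- add_derived_variables(small_cohort(800, seed = 6))
  zero <- ch
  for (v in c("poor_hearing", "poor_eyesight")) zero[[v]] <- 0
  expect_true(all(build_domain(zero, "sensory") == 0))
  both <- ch
  for (v in c("poor_hearing", "poor_eyesight")) both[[v]] <- 1
  expect_true(all(build_domain(both, "sensory") == 1))

  # slowness flag equals a brute-force stratum quantile recomputation
  slow <- build_domain(ch, "bs_slowness")
  strat <- interaction(ch$sex_male, ch$height_group)
  manual <- rep(NA_integer_, nrow(ch))
  for (s in levels(strat)) {
    in_s <- strat == s
    v <- ch$walk_time_15ft[in_s]
    o <- sort(v, decreasing = TRUE)
    thr <- o[match(TRUE, seq_along(o) / length(o) >= 0.2 - 1e-12)]
    manual[in_s] <- as.integer(v >= thr)
  }
  expect_equal(slow, manual)
  dom <- build_domains(ch)
  expect_true(all(as.matrix(dom[fa_models()$FD$domains]) >= 0 &
                    as.matrix(dom[fa_models()$FD$domains]) <= 1))
})

test_that("indices sum their components into the declared ranges", {
  m <- fa_models()
  ch <- build_domains(small_cohort(600, seed = 8))

  zero <- ch
  for (d in unique(c(m$FD$domains, m$BS$domains, m$burden$items))) {
    zero[[d]] <- 0
  }
  expect_true(all(build_index(zero, m$FD) == 0))
  expect_true(all(build_index(zero, m$burden) == 0))
  expect_true(all(build_index(zero, m$BS) == 0))

  maxed <- ch
  for (d in m$burden$items) maxed[[d]] <- 1
  expect_true(all(build_index(maxed, m$burden) == 1))  # 24/24

  fd2 <- ch[1, ]
  fd2[m$FD$domains] <- list(1, 1, 0, 0)
  expect_equal(build_index(fd2, m$FD), 2)
  expect_equal(dichotomize(2, m$FD), 1L)  # meets the >= 2 cutoff
})

test_that("dichotomization uses inclusive model cutoffs", {
  m <- fa_models()
  expect_equal(dichotomize(c(0.19, 0.2, 0.21), m$burden), c(0L, 1L, 1L))
  expect_equal(dichotomize(c(2.9, 3), m$BS), c(0L, 1L))
  expect_error(dichotomize(1.5, m$burden), "outside")
})

test_that("weighted prevalence equals the explicit weighted sum", {
  expect_equal(weighted_prevalence(c(1, 0), c(1, 3)), 0.25)
  expect_equal(weighted_prevalence(c(1, 0, 1, 1), rep(2, 4)), 0.75)
  set.seed(7)
  st <- rbinom(200, 1, 0.3)
  w <- rgamma(200, 1)
  expect_equal(weighted_prevalence(st, w), sum(w * st) / sum(w))
  expect_error(weighted_prevalence(c(1, 0), c(0, 0)), "positive")
})

test_that("constructed indices always lie in their declared ranges", {
  m <- fa_models()
  for (seed in 1:3) {
    ch <- add_indices(small_cohort(400, seed = seed,
                                   frailty_loading = c(0.3, 1, 2)[seed]))
    expect_true(all(ch$index_FD >= 0 & ch$index_FD <= 4))
    expect_true(all(ch$index_burden >= 0 & ch$index_burden <= 1))
    expect_true(all(ch$index_BS >= 0 & ch$index_BS <= 5))
  }
})

test_that("the Burden index is item-order invariant and divisor-exact", {
  m <- fa_models()$burden
  ch <- build_domains(small_cohort(300, seed = 10))
  idx <- build_index(ch, m)
  shuffled <- m
  set.seed(1)
  shuffled$items <- sample(m$items)
  expect_equal(build_index(ch, shuffled), idx)

  # a constant-zero extra item changes the index via the divisor only
  ch$zero_item <- 0
  wider <- fa_model_spec("burden25", "burden + null item",
                         items = c(m$items, "zero_item"), divisor = 25,
                         index_range = c(0, 1), cutoff = 0.2,
                         age_eligibility = 70,
                         input_columns = m$input_columns)
  expect_equal(build_index(ch, wider), idx * 24 / 25)
})

test_that("raising a single deficit never lowers an index or status", {
  m <- fa_models()
  ch <- small_cohort(300, seed = 12)
  base <- add_indices(ch)
  for (v in c("weight_loss", "poor_hearing", "stroke_history")) {
    bumped <- ch
    bumped[[v]] <- pmax(bumped[[v]], 1)
    after <- add_indices(bumped)
    for (id in names(m)) {
      expect_true(all(after[[paste0("index_", id)]] >=
                        base[[paste0("index_", id)]] - 1e-12))
      expect_true(all(after[[paste0("status_", id)]] >=
                        base[[paste0("status_", id)]]))
    }
  }
})
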