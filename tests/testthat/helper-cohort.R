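# shared fixture builders (all generated in code, nothing stored)

small_cohort <- function(n = 500, seed = 1, ...) {
  generate_cohort(cohort_spec(n_participants = n, seed = seed, ...))
}

indexed_cohort <- function(n = 500, seed = 1, ...) {
  add_bias_variables(add_indices(small_cohort(n = n, seed = seed, ...)))
}

# cohort with no age gradient and zero hazard effect: pure-noise survival
null_cohort <- function(n = 1000, seed = 1, hazard = 0.08, followup = 8) {
  generate_cohort(cohort_spec(
    n_participants = n, seed = seed, frailty_loading = 0,
    hazard_intercepts = rep(qlogis(hazard), followup),
    hazard_betas = numeric(0) |> setNames(character(0)),
    max_followup = followup))
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("|%g - %g| <= %g", x, target, tol))
}
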