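# Shared fixtures: random centred weight vectors, random moment models, and
# the catalogue of tests used by the calibration and power checks.

random_centred_weights <- function(n) {
  w <- stats::rnorm(n - 1)
  w - mean(w)
}

# Random alternative shape: neutral 1/i perturbed by lognormal noise.
random_shape <- function(n, sd = 0.5) {
  (1 / seq_len(n - 1)) * exp(stats::rnorm(n - 1, 0, sd))
}

random_moment_model <- function(n, theta = 0.1, L = 100, sd = 0.5) {
  moment_model(n, theta, L, xibar = random_shape(n, sd))
}

# The full battery of implemented tests for a scenario shape, known theta.
build_test_battery <- function(xibar, n, theta, L) {
  mod <- moment_model(n, theta, L, xibar)
  cov0 <- cov_independent_sites(n, theta, L)
  list(
    tajima_d = classic_test("tajima_d", n, theta, L),
    fay_wu_h = classic_test("fay_wu_h", n, theta, L),
    zeng_e   = classic_test("zeng_e", n, theta, L),
    fu_li_f  = classic_test("fu_li_f", n, theta, L),
    opt1sc   = linear_test(optimal_weights(xibar), cov0, "opt1sc"),
    tunable  = linear_test(tunable_weights(0.5, xibar), cov0, "tunable"),
    opt2sc   = quadratic_sc_optimal(mod),
    opt1wc   = linear_wc_optimal(mod),
    opt2wc   = quadratic_wc_optimal(mod),
    fu_g     = fu_g_test(mod)
  )
}

# Expected value of an unnormalised polynomial statistic under independent
# Poisson counts with mean mu (independent oracle for the identity checks).
poly_expectation <- function(test, mu) {
  test$gamma + sum(vapply(seq_along(test$multisets), function(k)
    test$coef[k] * poisson_moment(mu, test$multisets[[k]]), numeric(1)))
}
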