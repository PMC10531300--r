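test_that("Poisson moments reproduce the printed low-order formulas", {
  mu <- c(2, 1, 0.5)
  expect_equal(poisson_moment(mu, c(1, 2)), 2 * 1)
  expect_equal(poisson_moment(mu, c(1, 1)), 2 + 4)
  expect_equal(poisson_moment(mu, c(2, 2, 2)), 1^3 + 3 * 1^2 + 1)
  expect_equal(poisson_moment(0 * mu, c(1, 2)), 0)
  # Monte-Carlo cross-check of a third moment
  set.seed(6)
  x <- stats::rpois(2e5, 2)
  se <- stats::sd(x^3) / sqrt(2e5)
  expect_lt(abs(mean(x^3) - poisson_moment(mu, c(1, 1, 1))), 3 * se)
})

test_that("moment Taylor coefficients expand mu_I in powers of theta*L", {
  shape <- c(1, 1 / 2, 1 / 3)
  tl <- 0.7
  for (I in list(1L, c(1L, 2L), c(2L, 2L), c(1L, 2L, 2L))) {
    co <- sfstests:::poisson_moment_taylor(shape, I)
    direct <- poisson_moment(tl * shape, I)
    expect_equal(sum(co * tl^seq_along(co)), direct, tolerance = 1e-12)
  }
})

test_that("renormalised Fu's G is centred and order-equivalent to G_xi", {
  set.seed(14)
  n <- 12; theta <- 0.1; L <- 300
  mod <- moment_model(n, theta, L)
  tg <- fu_g_test(mod)
  # exact null mean spectrum: quadratic form zero, statistic -(n-1)/sd
  mu <- mod$mu
  expect_equal(evaluate_polynomial(tg, mu), -(n - 1) / sqrt(tg$var),
               tolerance = 1e-10)
  # unnormalised quadratic form has mean n-1 under the null
  reps <- 3e4
  X <- sample_sfs(mu, reps)
  q <- rowSums(sweep((sweep(X, 2, mu))^2, 2, mu, "/"))
  se <- stats::sd(q) / sqrt(reps)
  expect_lt(abs(mean(q) - (n - 1)), 3 * se)
  # T_G is a monotone map of the diagonal G_xi statistic: same rejection
  # regions at matched thresholds
  s <- evaluate_polynomial(tg, X[1:500, ])
  gxi <- apply(X[1:500, ], 1, fu_g_diagonal, model = mod)
  expect_true(all(diff(s[order(gxi)]) > -1e-9))
})

test_that("explicit optimal quadratic tests satisfy the maximal identities", {
  set.seed(25)
  for (r in 1:100) {
    n <- sample(5:12, 1)
    mod <- random_moment_model(n, theta = stats::runif(1, 0.02, 0.5),
                               L = sample(50:500, 1))
    t_sc <- quadratic_sc_optimal(mod)
    t_wc <- quadratic_wc_optimal(mod)
    e_sc <- poly_expectation(t_sc, mod$mubar)
    e_wc <- poly_expectation(t_wc, mod$mubar)
    # Var under null equals E under alternative, to 1e-9 relative
    expect_equal(t_sc$var, e_sc, tolerance = 1e-9)
    expect_equal(t_wc$var, e_wc, tolerance = 1e-9)
    # both centred at the plugged-in theta
    expect_lt(abs(poly_expectation(t_sc, mod$mu)),
              1e-9 * max(1, abs(e_sc)))
    expect_lt(abs(poly_expectation(t_wc, mod$mu)),
              1e-9 * max(1, abs(e_wc)))
  }
  expect_error(quadratic_sc_optimal(moment_model(8, 0.1, 100)), "degenerate")
})

test_that("strong centring survives a wrong plug-in theta; weak does not", {
  set.seed(33)
  n <- 10
  mod <- random_moment_model(n, theta = 0.1, L = 200)
  t_sc <- quadratic_sc_optimal(mod)
  t_wc <- quadratic_wc_optimal(mod)
  # analytic expectations under the true null at theta/2, theta, 2*theta
  for (f in c(0.5, 1, 2)) {
    e <- poly_expectation(t_sc, f * mod$mu)
    expect_lt(abs(e), 1e-8 * max(1, t_sc$var))
  }
  expect_gt(abs(poly_expectation(t_wc, 2 * mod$mu)), 1e-3)
  # Monte-Carlo confirmation at 2*theta for the weak test
  reps <- 3e4
  X <- sample_sfs(2 * mod$mu, reps)
  s_wc <- evaluate_polynomial(t_wc, X)
  expect_gt(abs(mean(s_wc)), 3 * stats::sd(s_wc) / sqrt(reps))
  s_sc <- evaluate_polynomial(t_sc, X)
  expect_lt(abs(mean(s_sc)), 4 * stats::sd(s_sc) / sqrt(reps))
})

test_that("optimal quadratic tests are standardised under the null", {
  set.seed(37)
  n <- 10
  mod <- random_moment_model(n, theta = 0.1, L = 300)
  reps <- 5e4
  X <- sample_sfs(mod$mu, reps)
  for (tst in list(quadratic_sc_optimal(mod), quadratic_wc_optimal(mod))) {
    s <- evaluate_polynomial(tst, X)
    expect_lt(abs(mean(s)), 3 * stats::sd(s) / sqrt(reps))
    expect_lt(abs(stats::var(s) - 1), 0.08)
  }
})

test_that("weakly centred linear optimum dominates the strongly centred one", {
  set.seed(45)
  n <- 9
  for (r in 1:1000) {
    mod <- random_moment_model(n, theta = stats::runif(1, 0.05, 0.3), L = 100)
    expect_gte(wc_linear_max(mod), sc_linear_max(mod) - 1e-12)
  }
  # Monte-Carlo check of the weakly centred maximum formula
  mod <- random_moment_model(n, theta = 0.2, L = 200)
  tw <- linear_wc_optimal(mod)
  reps <- 4e4
  Xa <- sample_sfs(mod$mubar, reps)
  s <- evaluate_polynomial(tw, Xa)
  se <- stats::sd(s) / sqrt(reps)
  expect_lt(abs(mean(s) - wc_linear_max(mod)), 3 * se)
})

test_that("the general construction matches the closed forms", {
  set.seed(53)
  mod <- random_moment_model(7, theta = 0.3, L = 60)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  g2s <- general_optimal(mod, 2, "strong")
  g2w <- general_optimal(mod, 2, "weak")
  t_sc <- quadratic_sc_optimal(mod)
  t_wc <- quadratic_wc_optimal(mod)
  expect_lt(rel(g2s$coef, t_sc$coef), 1e-6)
  expect_lt(rel(g2w$coef, t_wc$coef), 1e-6)
  expect_equal(g2w$gamma, t_wc$gamma, tolerance = 1e-6)
  # d = 1 strong reproduces the optimal linear weights up to scale
  g1 <- general_optimal(mod, 1, "strong")
  i <- seq_len(6)
  wlin <- i * mod$xibar - sum(mod$xibar) / harmonic_number(7)
  expect_lt(rel(g1$coef / sqrt(sum(g1$coef^2)),
                wlin / sqrt(sum(wlin^2))), 1e-9)
  # second-moment substitution leaves the strong test unchanged
  g2s_m2 <- general_optimal(mod, 2, "strong", use_second_moments = TRUE)
  expect_lt(rel(g2s_m2$coef, g2s$coef), 1e-6)
  expect_error(general_optimal(mod, 2, "weak", use_second_moments = TRUE),
               "strongly centred")
  expect_error(general_optimal(mod, 3, "strong", max_multisets = 10), "cap")
})

test_that("higher degree increases the attainable alternative expectation", {
  set.seed(61)
  for (r in 1:100) {
    mod <- random_moment_model(6, theta = stats::runif(1, 0.1, 0.4), L = 50)
    e1 <- poly_expectation(general_optimal(mod, 1, "strong"), mod$mubar)
    e2 <- poly_expectation(general_optimal(mod, 2, "strong"), mod$mubar)
    # normalised maxima are sqrt of the unnormalised expectations (Var = E)
    expect_gte(sqrt(e2), sqrt(e1) * (1 - 1e-9))
  }
})

test_that("folded moment models pass the same identities", {
  set.seed(71)
  n <- 11
  half <- n %/% 2
  xibarf <- null_shape(n, folded = TRUE) * exp(stats::rnorm(half, 0, 0.4))
  mod <- moment_model(n, 0.1, 200, xibar = xibarf, folded = TRUE)
  t_sc <- quadratic_sc_optimal(mod)
  t_wc <- quadratic_wc_optimal(mod)
  expect_equal(t_sc$var, poly_expectation(t_sc, mod$mubar), tolerance = 1e-9)
  expect_equal(t_wc$var, poly_expectation(t_wc, mod$mubar), tolerance = 1e-9)
  expect_lt(abs(poly_expectation(t_sc, 1.7 * mod$mu)), 1e-8)
})

test_that("degree-1 strong polynomials reduce to linear tests", {
  set.seed(77)
  n <- 8; theta <- 0.1; L <- 150
  xibar <- random_shape(n)
  mod <- moment_model(n, theta, L, xibar)
  g1 <- general_optimal(mod, 1, "strong")
  lt <- linear_test(optimal_weights(xibar), cov_independent_sites(n, theta, L))
  x <- stats::rpois(n - 1, mod$mu)
  expect_equal(evaluate_polynomial(g1, x), evaluate_test(lt, x),
               tolerance = 1e-9)
})
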