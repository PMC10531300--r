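test_that("centering realisation matches hand arithmetic and zeroes the sum", {
  # Omega(f) = f at n = 5: correction is mean(1:4/5) = 1/2
  sch <- weight_scheme(Omega = weight_fun("custom", list(fun = function(f) f)),
                       scaling = "centering")
  expect_equal(realise_centering(sch, 5), c(-0.3, -0.1, 0.1, 0.3))
  # pure singleton contrast: budget already zero, no correction
  sch2 <- weight_scheme(Omega = weight_fun("zero", ds = 1, as = -1),
                        scaling = "centering")
  w <- realise_centering(sch2, 6)
  expect_equal(w, c(1, 0, 0, 0, -1))
  # divergent schemes are refused
  schw <- weight_scheme(Omega = weight_fun("watterson"), scaling = "centering")
  expect_error(realise_centering(schw, 10), "ratio")
})

test_that("ratio realisation reproduces Fay & Wu's H and Fu's F(r,r')", {
  n <- 10
  sch <- weight_scheme(omega = weight_fun("two_one_minus_f"),
                       omega_prime = weight_fun("two_f"))
  W <- realise_ratio(sch, n)
  i <- 1:(n - 1)
  expect_equal(attr(W, "omega"), 2 * (n - i) / (n * (n - 1)))
  expect_equal(attr(W, "omega_prime"), 2 * i / (n * (n - 1)))
  expect_equal(sum(W), 0)
  # omega = omega' gives the zero vector
  sch0 <- weight_scheme(omega = weight_fun("two_f"),
                        omega_prime = weight_fun("two_f"))
  expect_equal(as.numeric(realise_ratio(sch0, 7)), rep(0, 6))
  # Fu's F(r, r'): omega_i = i^-r / sum_j j^-r, via (1-r) f^-r functions
  r <- 0.4
  schf <- weight_scheme(omega = weight_fun("power", list(r = r)),
                        omega_prime = weight_fun("constant"))
  Wf <- realise_ratio(schf, n)
  expect_equal(attr(Wf, "omega"), i^(-r) / sum(i^(-r)), tolerance = 1e-12)
})

test_that("binomial sampling scaling is exact for Dirac and uniform parts", {
  n <- 12
  i <- 1:(n - 1)
  sch <- weight_scheme(omega = weight_fun("dirac", list(at = 0.5, mass = 1)),
                       omega_prime = weight_fun("constant"),
                       scaling = "binomial")
  b <- realise_binomial(sch, n)
  expect_equal(b$omega, choose(n, i) * 2^(-n) / (1 - 2^(-n + 1)),
               tolerance = 1e-12)
  expect_equal(b$omega_prime, rep(1 / (n - 1), n - 1), tolerance = 1e-12)
  # smooth part: omega(f) = 2(1-f) has a Beta-integral closed form
  sch2 <- weight_scheme(omega = weight_fun("two_one_minus_f"),
                        omega_prime = weight_fun("constant"),
                        scaling = "binomial")
  b2 <- realise_binomial(sch2, n)
  num <- 2 * choose(n, i) * beta(i + 1, n - i + 2)
  den <- sum(sapply(i, function(k) 2 * choose(n, k) * beta(k + 1, n - k + 2)))
  # denominator of the scaling is the integral against 1 - f^n - (1-f)^n,
  # which for normalised omega equals the sum of the numerators
  expect_equal(b2$omega, num / den, tolerance = 1e-9)
})

test_that("Watterson weights are (1/i)/a_n and defeat the centering form", {
  expect_equal(watterson_weights(4), c(6, 3, 2) / 11)
  # For bounded Omega(f) the subtractive correction of the centering form is
  # O(1/n) relative to the weights; for the divergent Watterson function it
  # is O(log(n)/n): n * relative-correction grows like log n instead of
  # staying bounded.
  ns <- c(10, 100, 1000, 10000)
  rel_corr <- function(fun, n) {
    v <- fun((1:(n - 1)) / n)
    n * abs(mean(v)) / mean(abs(v))
  }
  # both functions have zero integral over the cutoff range
  watt <- sapply(ns, function(n)
    rel_corr(function(f) 1 / (f * log(1e6)) - 1, n))
  bounded <- sapply(ns, function(n) rel_corr(function(f) f^2 - 1 / 3, n))
  expect_true(all(diff(watt) > 0))
  expect_gt(watt[4] / watt[1], 3)               # ~ a_n growth
  expect_lt(max(bounded) / min(bounded), 1.2)   # stays O(1)
  expect_gt(watt[4], 10 * bounded[4])
})

test_that("classic catalogue reproduces the printed numerators", {
  # Tajima's D numerator on xi = (3,2,1), n = 4: Pi - S/a_n = 10/3 - 36/11
  w <- classic_test_weights("tajima_d", 4)
  xi <- c(3, 2, 1)
  num <- sum(1:3 * w$Omega * xi)
  expect_equal(num, 10 / 3 - 36 / 11, tolerance = 1e-12)
  # Fu & Li's F numerator is xi_1 - S/a_n
  for (n in c(5, 12)) {
    wf <- classic_test_weights("fu_li_f", n)
    xi <- stats::rpois(n - 1, 3)
    expect_equal(sum(1:(n - 1) * wf$Omega * xi),
                 xi[1] - sum(xi) / harmonic_number(n), tolerance = 1e-12)
  }
  # Zeng's E numerator is S/a_n - sum i xi_i/(n-1)
  n <- 8
  we <- classic_test_weights("zeng_e", n)
  xi <- stats::rpois(n - 1, 2)
  expect_equal(sum(1:(n - 1) * we$Omega * xi),
               sum(xi) / harmonic_number(n) - sum((1:(n - 1)) * xi) / (n - 1),
               tolerance = 1e-12)
  # every catalogue weight vector is centred
  for (nm in c("tajima_d", "fay_wu_h", "zeng_e", "fu_li_f",
               "achaz_admixture")) {
    expect_lt(abs(sum(classic_test_weights(nm, 15)$Omega)), 1e-9)
  }
  expect_lt(abs(sum(classic_test_weights(
    "fu_f", 15, list(r = 0.3, r_prime = -0.5))$Omega)), 1e-9)
  expect_lt(abs(sum(classic_test_weights(
    "achaz_bottleneck", 15, list(beta = 5))$Omega)), 1e-9)
  expect_error(classic_test_weights("nope", 10), "unknown")
  expect_error(classic_test_weights("fu_f", 10, list(r = 1.5, r_prime = 0)),
               "divergent")
})

test_that("bottleneck parameter map and scaling equivalence hold", {
  expect_identical(achaz_bottleneck_beta(0.9, 30), 27)
  # ratio and centering realisations are proportional, so the normalised
  # tests coincide
  both <- bottleneck_both_scalings(27, 30)
  ratio <- both$ratio / sqrt(sum(both$ratio^2))
  cent <- both$centering / sqrt(sum(both$centering^2))
  expect_equal(ratio, cent, tolerance = 1e-9)
})

test_that("error correction zeroes singleton classes and recentres", {
  for (nm in c("tajima_d", "fay_wu_h")) {
    w <- classic_test_weights(nm, 12, error_corrected = TRUE)
    expect_identical(w$Omega[c(1, 11)], c(0, 0))
    expect_lt(abs(sum(w$Omega)), 1e-12)
    expect_equal(sum(w$omega), 1, tolerance = 1e-12)
  }
})

test_that("bounded schemes realised by either scaling differ by O(1/n)", {
  set.seed(7)
  ns <- c(20, 200, 2000)
  # the ratio form normalises each side to sum 1, so its weights carry an
  # overall 1/n relative to the centering form (irrelevant for the normalised
  # test); rescale before comparing
  disc_of <- function(omega, omega_prime) {
    sch_r <- weight_scheme(
      omega = weight_fun("custom", list(fun = omega)),
      omega_prime = weight_fun("custom", list(fun = omega_prime)))
    sch_c <- weight_scheme(
      Omega = weight_fun("custom", list(
        fun = function(f) omega(f) - omega_prime(f))),
      scaling = "centering")
    sapply(ns, function(n)
      max(abs(realise_centering(sch_c, n) -
              n * as.numeric(realise_ratio(sch_r, n)))))
  }
  # smooth schemes: the discretisation constant is stable across n
  for (rep in 1:12) {
    a <- stats::runif(3, 0.2, 2); b <- stats::runif(3, 0.2, 2)
    f1 <- function(f) a[1] + a[2] * f + a[3] * f^2
    f2 <- function(f) b[1] + b[2] * f^3 + b[3] * (1 - f)
    i1 <- stats::integrate(f1, 0, 1)$value
    i2 <- stats::integrate(f2, 0, 1)$value
    disc <- disc_of(function(f) f1(f) / i1, function(f) f2(f) / i2)
    C <- ns[1] * disc[1]
    expect_lt(disc[2], 1.5 * C / ns[2])
    expect_lt(disc[3], 1.5 * C / ns[3])
  }
  # piecewise-continuous schemes with a step: still O(1/n), but the constant
  # wobbles with the alignment of the step on the frequency grid
  for (rep in 1:8) {
    b <- stats::runif(2, 0.2, 2)
    step_at <- stats::runif(1, 0.2, 0.8)
    f2 <- function(f) b[1] + b[2] * (f > step_at)
    i2 <- stats::integrate(f2, 0, 1)$value
    disc <- disc_of(function(f) 2 * (1 - f), function(f) f2(f) / i2)
    C <- ns[1] * disc[1]
    expect_lt(disc[2], 4 * C / ns[2])
    expect_lt(disc[3], 4 * C / ns[3])
  }
})

test_that("multiplying omega sides by constants leaves the test invariant", {
  set.seed(3)
  n <- 15
  w <- classic_test_weights("tajima_d", n)
  cov <- cov_independent_sites(n, 0.05, 1000)
  t1 <- linear_test(w$Omega, cov)
  # scaling Omega by any positive constant leaves the normalised value
  t2 <- linear_test(3.7 * w$Omega, cov)
  x <- stats::rpois(n - 1, 4)
  expect_equal(evaluate_test(t1, x), evaluate_test(t2, x), tolerance = 1e-12)
})

test_that("weight schemes round-trip through JSON", {
  sch <- weight_scheme(omega = weight_fun("power", list(r = 0.25), ds = 0.1),
                       omega_prime = weight_fun("constant"),
                       scaling = "ratio", N = 5e5)
  sch2 <- scheme_from_json(scheme_to_json(sch))
  expect_equal(realise_weights(sch2, 11), realise_weights(sch, 11))
  schc <- weight_scheme(Omega = weight_fun("custom", list(fun = identity)),
                        scaling = "centering")
  expect_error(scheme_to_json(schc), "not serialisable")
})

test_that("admixture average weights flip sign with sample size", {
  expect_equal(admixture_average_weight(10, 0.3, 0.4), 0.5, tolerance = 0.01)
  expect_equal(admixture_average_weight(100, 0.3, 0.4), -0.75,
               tolerance = 0.01)
  expect_equal(admixture_average_weight(1000, 0.3, 0.4), -1.0,
               tolerance = 0.01)
  expect_error(admixture_average_weight(10, 0.31, 0.39), "no allele-count")
})
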