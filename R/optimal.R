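#' Scenario spectra
#'
#' Bundles the null mean shape `xi0_i = 1/i`, an alternative mean shape
#' `xibar_i` (both per unit `theta*L`), the mutation parameters, and the
#' covariance models under the null and (optionally) the alternative. The
#' default covariance is the independent-sites Poisson model, diagonal with
#' variance equal to the mean.
#'
#' @param xibar alternative mean shape (length `n - 1`), per unit `theta*L`.
#' @param n haploid sample size.
#' @param theta scaled mutation rate per base.
#' @param L sequence length in bases.
#' @param cov_null,cov_alt optional `cov_model` objects; by default Poisson
#'   diagonal models at the null and alternative means.
#' @return An object of class `scenario_spectra`.
#' @export
scenario_spectra <- function(xibar, n, theta, L,
                             cov_null = NULL, cov_alt = NULL) {
  n <- as.integer(n)
  if (length(xibar) != n - 1L) stop("'xibar' must have length n - 1")
  if (any(xibar < 0)) stop("'xibar' must be entry-wise non-negative")
  xi0 <- 1 / seq_len(n - 1L)
  if (is.null(cov_null)) cov_null <- cov_independent_sites(n, theta, L)
  if (is.null(cov_alt)) {
    mubar <- theta * L * xibar
    cov_alt <- structure(list(kind = "independent_sites", mean = mubar,
                              matrix = diag(mubar), n = n, theta = theta,
                              L = L, folded = FALSE), class = "cov_model")
  }
  structure(list(xi0 = xi0, xibar = xibar, n = n, theta = theta, L = L,
                 cov_null = cov_null, cov_alt = cov_alt),
            class = "scenario_spectra")
}

#' Scalar product between spectra
#'
#' `<x, y> = sum_ij x_i (c^-1)_ij y_j` with `c` the covariance of the
#' spectrum. Symmetric and positive semi-definite; singular covariances are
#' handled by an eigenvalue-floored pseudo-inverse.
#'
#' @param x,y numeric spectrum vectors.
#' @param cov a `cov_model`.
#' @return The scalar product (a number).
#' @export
sfs_scalar_product <- function(x, y, cov) {
  stopifnot(inherits(cov, "cov_model"))
  drop(crossprod(x, pseudo_solve(cov$matrix, y)))
}

#' Optimal linear test in geometric form
#'
#' The linear test with maximum expectation under an alternative scenario
#' with mean shape `xibar`. In terms of the scalar product `< , >` defined by
#' the inverse null covariance,
#' `T_O = (<xi, xibar> - <xi, xi0> <xi0, xibar> / <xi0, xi0>) / sqrt(D)` with
#' `D = <xibar, xibar> - <xi0, xibar>^2 / <xi0, xi0>`: the projection of the
#' data orthogonal to the null direction, scored along the alternative. The
#' statistic is zero on the null mean, maximal (equal to
#' `theta*L*sqrt(D)`) on the alternative mean, and unchanged by adding any
#' multiple of `xi0` to `xibar`.
#'
#' @param spec an [sfs] object or numeric spectrum vector.
#' @param scen a [scenario_spectra].
#' @return The normalised statistic.
#' @export
optimal_linear_test <- function(spec, scen) {
  stopifnot(inherits(scen, "scenario_spectra"))
  x <- if (inherits(spec, "sfs")) spec$counts else spec
  cov <- scen$cov_null
  xi0 <- scen$xi0; xibar <- scen$xibar
  g00 <- sfs_scalar_product(xi0, xi0, cov)
  g0b <- sfs_scalar_product(xi0, xibar, cov)
  gbb <- sfs_scalar_product(xibar, xibar, cov)
  D <- gbb - g0b^2 / g00
  if (D <= 1e-12 * gbb)
    stop("degenerate alternative: xibar is proportional to xi0")
  num <- sfs_scalar_product(x, xibar, cov) -
    sfs_scalar_product(x, xi0, cov) * g0b / g00
  num / sqrt(D)
}

#' Maximum value of the optimal linear test
#'
#' The expectation of the optimal test when the data follow the alternative
#' mean spectrum `theta*L*xibar`; no linear test can exceed it.
#'
#' @param scen a [scenario_spectra].
#' @return `theta*L*sqrt(<xibar,xibar> - <xi0,xibar>^2/<xi0,xi0>)`.
#' @export
optimal_max_value <- function(scen) {
  cov <- scen$cov_null
  g00 <- sfs_scalar_product(scen$xi0, scen$xi0, cov)
  g0b <- sfs_scalar_product(scen$xi0, scen$xibar, cov)
  gbb <- sfs_scalar_product(scen$xibar, scen$xibar, cov)
  scen$theta * scen$L * sqrt(gbb - g0b^2 / g00)
}

#' Optimal linear weights (lambda -> 0+ limit)
#'
#' The centred weights maximising the expectation of the test under the
#' alternative: `Omega_i = xibar_i - (1/i) sum_j xibar_j / a_n`.
#'
#' @param xibar alternative mean shape.
#' @return Centred weight vector.
#' @export
optimal_weights <- function(xibar) {
  n <- length(xibar) + 1L
  i <- seq_len(n - 1L)
  xibar - (1 / i) * sum(xibar) / harmonic_number(n)
}

#' Gaussian-approximation power of a linear test
#'
#' For a test with raw coefficients `w_i = i * Omega_i` on the counts, the
#' right-tail power at significance level `alpha` when both the null and the
#' alternative distribution of the numerator are Gaussian:
#' `Power = Phi((mubar.w - tau * sqrt(w' c w)) / sqrt(w' cbar w))` with
#' `tau = Phi^-1(1 - alpha) = sqrt(2) * erfinv(1 - 2*alpha)` the critical
#' z-value. The erf-based and Phi-based z-value conventions describe the
#' same quantity and are interconvertible by the `sqrt(2)`; this function
#' uses the Phi form throughout, which is the one consistent with the
#' criteria in [optimisation_criterion] and with Monte-Carlo power. The
#' formula reduces to `alpha` when the alternative mean contribution is zero
#' and `cbar = c`.
#'
#' @param Omega centred weight vector of the test.
#' @param scen a [scenario_spectra] with an alternative covariance.
#' @param alpha one-tail significance level in (0, 0.5].
#' @return Power in `[0, 1]`.
#' @export
gaussian_power <- function(Omega, scen, alpha = 0.05) {
  stopifnot(inherits(scen, "scenario_spectra"))
  if (is.null(scen$cov_alt))
    stop("no alternative covariance: estimate power by simulation instead")
  if (!(alpha > 0 && alpha <= 0.5)) stop("alpha must be in (0, 0.5]")
  tau <- stats::qnorm(1 - alpha)
  w <- seq_along(Omega) * Omega
  mubar <- scen$theta * scen$L * scen$xibar
  v0 <- drop(t(w) %*% scen$cov_null$matrix %*% w)
  v1 <- drop(t(w) %*% scen$cov_alt$matrix %*% w)
  if (v0 <= 0 || v1 <= 0) stop("degenerate test: zero variance")
  stats::pnorm((sum(mubar * w) - tau * sqrt(v0)) / sqrt(v1))
}

#' Tunable optimal test weights
#'
#' One-parameter family of centred weights
#' `Omega_i(lambda) = (1/i) * (1 - a_n / ((1 + lambda*i*xibar_i) *
#'  sum_j 1/(j (1 + lambda*j*xibar_j))))`.
#' For every optimisation criterion `M(E, V)` based on the mean and variance
#' of the test under the alternative (with independent-sites covariances),
#' the maximising weights lie in this family; `lambda -> 0+` recovers the
#' usual optimal weights [optimal_weights] as the leading direction.
#' `lambda` may be negative (criteria that reward a small alternative
#' variance relative to the mean need `lambda < 0`) as long as every factor
#' `1 + lambda*i*xibar_i` stays positive, i.e.
#' `lambda > -1 / max(i * xibar_i)`.
#'
#' @param lambda tuning parameter, `lambda > -1 / max(i * xibar_i)`.
#' @param xibar alternative mean shape (length `n - 1`).
#' @return Centred weight vector `Omega(lambda)`.
#' @export
tunable_weights <- function(lambda, xibar) {
  n <- length(xibar) + 1L
  i <- seq_len(n - 1L)
  g <- 1 + lambda * i * xibar
  if (any(g <= 0)) stop("lambda leaves 1 + lambda*i*xibar_i <= 0")
  s <- sum(1 / (i * g))
  (1 / i) * (1 - harmonic_number(n) / (g * s))
}

# E and V of the normalised tunable test under the alternative scenario.
tunable_EV <- function(Omega, scen) {
  w <- seq_along(Omega) * Omega
  v0 <- drop(t(w) %*% scen$cov_null$matrix %*% w)
  E <- scen$theta * scen$L * sum(w * scen$xibar) / sqrt(v0)
  V <- drop(t(w) %*% scen$cov_alt$matrix %*% w) / v0
  list(E = E, V = V)
}

#' Optimisation criteria M(E, V)
#'
#' Criteria for selecting a test from the tunable family, as functions of the
#' mean `E` and variance `V` of the normalised test under the alternative
#' scenario (the null mean and variance are 0 and 1 by construction):
#' * `mean_max`: `M = E` (usual optimal tests; maximised at `lambda -> 0+`).
#' * `one_tail_power`: `M = (E - tau') / sqrt(V)`, `tau' = qnorm(1 - alpha)`.
#' * `two_tail_power`: Gaussian two-tail power with `tau' = qnorm(1-alpha/2)`.
#' * `variance_penalty`: `M = E / (1 + V)^nu`.
#'
#' These use the `qnorm` z-value convention; see [gaussian_power] for the
#' erf-based convention used in the power formula itself.
#'
#' @param kind criterion name.
#' @param alpha significance level in (0, 0.5].
#' @param nu variance-penalty exponent.
#' @return An object of class `optimisation_criterion` (callable on `E, V`).
#' @export
optimisation_criterion <- function(kind = c("mean_max", "one_tail_power",
                                            "two_tail_power",
                                            "variance_penalty"),
                                   alpha = 0.05, nu = 1) {
  kind <- match.arg(kind)
  if (!(alpha > 0 && alpha <= 0.5)) stop("alpha must be in (0, 0.5]")
  f <- switch(kind,
    mean_max = function(E, V) E,
    one_tail_power = {
      tau <- stats::qnorm(1 - alpha)
      function(E, V) (E - tau) / sqrt(V)
    },
    two_tail_power = {
      tau <- stats::qnorm(1 - alpha / 2)
      function(E, V) {
        1 - stats::pnorm((tau - E) / sqrt(V)) +
          stats::pnorm((-tau - E) / sqrt(V))
      }
    },
    variance_penalty = function(E, V) E / (1 + V)^nu
  )
  structure(list(kind = kind, alpha = alpha, nu = nu, M = f),
            class = "optimisation_criterion")
}

#' Optimise a criterion over the tunable family
#'
#' Scans `M(E(lambda), V(lambda))` over a logarithmic grid of positive
#' `lambda` plus a grid filling the admissible negative range
#' `(-1/max(i*xibar_i), 0)`, includes the analytic `lambda = 0+` limit,
#' refines every local maximum by golden-section search, and returns the
#' global maximiser together with all local maxima found (the criterion
#' surface can have several).
#'
#' @param criterion an [optimisation_criterion].
#' @param scen a [scenario_spectra].
#' @param lambda_grid grid of positive `lambda` values; default 200 points
#'   log-spaced on `[1e-4, 1e4]`. An equally sized negative grid is added
#'   automatically inside the admissible range.
#' @return List with `lambda` (0 for the `0+` limit), `Omega`, `M`, and a
#'   data frame `local_maxima`.
#' @export
optimise_tunable <- function(criterion, scen,
                             lambda_grid = 10^seq(-4, 4, length.out = 200)) {
  stopifnot(inherits(criterion, "optimisation_criterion"),
            inherits(scen, "scenario_spectra"))
  weights_at <- function(lam) {
    if (lam == 0) optimal_weights(scen$xibar) else
      tunable_weights(lam, scen$xibar)
  }
  score <- function(lam) {
    ev <- tunable_EV(weights_at(lam), scen)
    criterion$M(ev$E, ev$V)
  }
  lam_min <- -1 / max(seq_along(scen$xibar) * scen$xibar)
  neg_grid <- lam_min * (1 - 10^seq(-4, 0, length.out = length(lambda_grid)))
  neg_grid <- neg_grid[neg_grid > 0.9999 * lam_min & neg_grid < 0]
  lams <- c(sort(neg_grid), 0, sort(lambda_grid))
  Ms <- vapply(lams, score, numeric(1))
  # local maxima on the grid (plateau-safe comparisons)
  is_max <- vapply(seq_along(Ms), function(k) {
    left <- if (k == 1L) -Inf else Ms[k - 1L]
    right <- if (k == length(Ms)) -Inf else Ms[k + 1L]
    Ms[k] >= left && Ms[k] >= right
  }, logical(1))
  refine <- function(k) {
    lo <- lams[max(1L, k - 1L)]
    hi <- lams[min(length(lams), k + 1L)]
    if (lo == hi) return(c(lams[k], Ms[k]))
    opt <- stats::optimize(score, c(lo, hi), maximum = TRUE,
                           tol = 1e-10 * (hi - lo) + 1e-12)
    if (opt$objective >= Ms[k]) c(opt$maximum, opt$objective)
    else c(lams[k], Ms[k])
  }
  ref <- t(vapply(which(is_max), refine, numeric(2)))
  local <- data.frame(lambda = ref[, 1], M = ref[, 2])
  best <- which.max(local$M)
  lam_star <- local$lambda[best]
  zero_idx <- which(lams == 0)
  if (local$M[best] <= Ms[zero_idx] + 1e-12 * abs(Ms[zero_idx]))
    lam_star <- 0
  list(lambda = lam_star, Omega = weights_at(lam_star),
       M = max(local$M[best], Ms[zero_idx]), local_maxima = local)
}
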