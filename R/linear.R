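#' Covariance models for the spectrum
#'
#' Under the independent-sites (unlinked, small-theta) model the SFS class
#' counts are independent Poisson variables, so the covariance is diagonal
#' with `c_ii = mu_i`, the null mean counts. An empirical model can be
#' estimated from simulated replicates for scenarios where linkage matters.
#'
#' @param n haploid sample size.
#' @param theta scaled mutation rate per base.
#' @param L sequence length in bases.
#' @param folded build the model over folded classes?
#' @return An object of class `cov_model` with fields `mean` (null mean
#'   vector), `matrix` (covariance) and `kind`.
#' @export
cov_independent_sites <- function(n, theta, L, folded = FALSE) {
  mu <- null_mean_spectrum(n, theta, L, folded = folded)$counts
  structure(list(kind = "independent_sites", mean = mu, matrix = diag(mu),
                 n = n, theta = theta, L = L, folded = folded),
            class = "cov_model")
}

#' @rdname cov_independent_sites
#' @param replicates a matrix of simulated spectra, one replicate per row.
#' @export
cov_empirical <- function(replicates, n, theta = NA, L = NA, folded = FALSE) {
  m <- colMeans(replicates)
  structure(list(kind = "empirical", mean = m, matrix = stats::cov(replicates),
                 n = n, theta = theta, L = L, folded = folded),
            class = "cov_model")
}

# Eigenvalue-floored pseudo-inverse: eigenvalues below floor_rel * max(eigen)
# are dropped. Keeps empirical, possibly rank-deficient covariances usable.
pseudo_solve <- function(A, b = NULL, floor_rel = 1e-12) {
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > floor_rel * max(e$values)
  if (!any(keep)) stop("covariance matrix is numerically zero")
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  if (is.null(b)) inv else inv %*% b
}

#' Linear neutrality tests
#'
#' A linear test pairs a centred weight vector `Omega` (summing to zero) with
#' a covariance model; its value on a spectrum is the normalised contrast
#' `T = sum_i i Omega_i xi_i / sqrt(Var(sum_j j Omega_j xi_j))`, which has
#' zero mean and unit variance when the data follow the null model and the
#' covariance model is exact. The coefficient on the raw counts is
#' `Omega_i / s_i` with `s_i` the null mean shape (`1/i` unfolded,
#' `n/(i(n-i)(1+delta))` folded), so that centredness `sum Omega_i = 0`
#' guarantees a zero null mean for folded tests too.
#'
#' @param Omega centred weight vector (length `n - 1` unfolded or
#'   `floor(n/2)` folded).
#' @param cov a [cov_independent_sites] / [cov_empirical] model.
#' @param name label for output tables.
#' @return An object of class `linear_test`.
#' @export
linear_test <- function(Omega, cov, name = "custom") {
  stopifnot(inherits(cov, "cov_model"))
  if (length(Omega) != length(cov$mean))
    stop("weight vector and covariance model dimensions differ")
  if (abs(sum(Omega)) > 1e-9 * max(1, sum(abs(Omega))))
    stop("weights must sum to zero (centredness)")
  w <- Omega / null_shape(cov$n, folded = cov$folded)  # coefficients on counts
  v <- drop(t(w) %*% cov$matrix %*% w)
  if (v <= 0) stop("degenerate test: zero variance under the covariance model")
  structure(list(Omega = Omega, coef = w, var = v, cov = cov, name = name),
            class = "linear_test")
}

#' Evaluate a linear test on a spectrum
#'
#' @param test a [linear_test].
#' @param spec an [sfs] object, or a matrix of spectra (replicates in rows).
#' @return The normalised statistic (scalar, or vector over replicate rows).
#' @export
evaluate_test <- function(test, spec) {
  stopifnot(inherits(test, "linear_test"))
  x <- if (inherits(spec, "sfs")) spec$counts else spec
  if (is.matrix(x)) {
    if (ncol(x) != length(test$coef)) stop("spectrum dimension mismatch")
    drop(x %*% test$coef) / sqrt(test$var)
  } else {
    if (length(x) != length(test$coef)) stop("spectrum dimension mismatch")
    sum(test$coef * x) / sqrt(test$var)
  }
}

#' Build a catalogue linear test
#'
#' Convenience wrapper: classic weights plus an independent-sites covariance
#' at the given null parameters.
#'
#' @inheritParams classic_test_weights
#' @inheritParams cov_independent_sites
#' @return A [linear_test].
#' @export
classic_test <- function(name, n, theta, L, params = list(),
                         error_corrected = FALSE) {
  w <- classic_test_weights(name, n, params, error_corrected)
  linear_test(w$Omega, cov_independent_sites(n, theta, L), name = w$name)
}

#' Undetectable deviation from the neutral spectrum
#'
#' For any single centred weight vector there exists a spectrum shape that is
#' maximally different from the neutral `1/(i a_n)` shape in some frequency
#' range (one class has exactly zero density) and yet gives the test a zero
#' expectation. This constructor realises such a shape: it picks, from an
#' orthonormal basis of the null space of the constraint
#' `sum_i i Omega_i Delta_i = 0`, the direction with the largest angle to the
#' neutral shape `1/i` (tie-break: lowest index), flips it so it has a
#' negative entry, and solves for the mixing parameter `alpha` in `[0,1]` such
#' that the mixture `alpha/(i a_n) + (1-alpha) Delta_i` has minimum exactly
#' zero. The mixture is linear in `alpha` within each class, so the binding
#' `alpha` is the maximum of the per-class roots, computed in closed form.
#'
#' @param Omega centred weight vector.
#' @return List with `Delta` (the deviation direction), `alpha`, and
#'   `spectrum` (the undetectable composite shape, entry-wise >= 0 with a
#'   zero entry).
#' @export
undetectable_deviation <- function(Omega) {
  n <- length(Omega) + 1L
  if (n < 4L) stop("need n >= 4")
  if (abs(sum(Omega)) > 1e-9 * max(1, sum(abs(Omega))))
    stop("weights must sum to zero")
  if (all(Omega == 0)) stop("weights must not be identically zero")
  i <- seq_len(n - 1L)
  v <- i * Omega                       # constraint row: sum v_i Delta_i = 0
  # orthonormal basis of the null space of v (dimension n - 2)
  Q <- qr.Q(qr(cbind(v, diag(n - 1L))))[, -1L, drop = FALSE]
  u <- 1 / i
  u <- u / sqrt(sum(u^2))
  cosang <- abs(drop(t(Q) %*% u))
  Delta <- Q[, which.min(cosang)]
  if (min(Delta) >= 0) Delta <- -Delta
  neutral <- 1 / (i * harmonic_number(n))
  neg <- which(Delta < 0)
  roots <- -Delta[neg] / (neutral[neg] - Delta[neg])
  alpha <- max(roots)
  binding <- neg[which.max(roots)]
  spectrum <- alpha * neutral + (1 - alpha) * Delta
  spectrum[binding] <- 0
  spectrum[spectrum < 0] <- 0          # guards rounding in near-ties
  list(Delta = Delta, alpha = alpha, spectrum = spectrum)
}
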