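#' Moment model for nonlinear tests
#'
#' Under the independent-sites approximation (unlinked sites, small per-site
#' theta) the SFS class counts are independent Poisson variables, so all
#' moments of the spectrum under the null and the alternative are determined
#' by the first moments `mu_i = theta*L*xi0_i` and `mubar_i = theta*L*xibar_i`.
#' This object carries those first moments and the shape vectors, and is the
#' input to all optimal polynomial test constructors.
#'
#' @param n haploid sample size.
#' @param theta scaled mutation rate per base (the plug-in value; use
#'   [theta_watterson] for the Watterson estimate of an observed spectrum).
#' @param L sequence length in bases.
#' @param xibar alternative mean shape per unit `theta*L`; defaults to the
#'   null shape.
#' @param folded build the model over folded classes (supply folded shapes)?
#' @return An object of class `moment_model`.
#' @export
moment_model <- function(n, theta, L, xibar = NULL, folded = FALSE) {
  shape0 <- null_shape(n, folded = folded)
  if (is.null(xibar)) xibar <- shape0
  if (length(xibar) != length(shape0))
    stop("'xibar' has the wrong number of classes")
  if (any(xibar < 0)) stop("'xibar' must be non-negative")
  structure(list(n = as.integer(n), theta = theta, L = L, folded = folded,
                 xi0 = shape0, xibar = xibar,
                 mu = theta * L * shape0, mubar = theta * L * xibar),
            class = "moment_model")
}

#' Watterson plug-in estimate of theta
#'
#' `theta_hat = S / (a_n * L)` per base, the default plug-in for evaluating
#' nonlinear tests when theta is not known.
#'
#' @param spec an [sfs] object.
#' @return Estimated theta per base.
#' @export
theta_watterson <- function(spec) {
  stopifnot(inherits(spec, "sfs"))
  segregating_sites(spec) / (harmonic_number(spec$n) * spec$L)
}

# Stirling numbers of the second kind S(k, j), small k.
stirling2 <- function(k, j) {
  if (j == 0) return(as.numeric(k == 0))
  if (j > k) return(0)
  S <- matrix(0, k + 1L, k + 1L)
  S[1L, 1L] <- 1
  for (kk in seq_len(k)) {
    for (jj in seq_len(kk)) {
      S[kk + 1L, jj + 1L] <- jj * S[kk, jj + 1L] + S[kk, jj]
    }
  }
  S[k + 1L, j + 1L]
}

# Raw moment E[X^k] of X ~ Poisson(m): the Touchard polynomial
# sum_j S(k,j) m^j.
poisson_raw_moment <- function(m, k) {
  if (k == 0) return(rep(1, length(m)))
  j <- seq_len(k)
  S <- vapply(j, function(jj) stirling2(k, jj), numeric(1))
  out <- 0
  for (jj in j) out <- out + S[jj] * m^jj
  out
}

#' Moments of the spectrum under the independent-sites model
#'
#' `mu_I = E(xi_i xi_j xi_k ...)` for a multiset of class indices `I`, with
#' independent Poisson class counts with mean vector `mu`. Each distinct
#' index contributes its raw Poisson moment of order equal to its
#' multiplicity; e.g. `mu_ij = mu_i mu_j` for `i != j` and
#' `mu_ii = mu_i + mu_i^2`.
#'
#' @param mu mean count vector.
#' @param I integer vector of class indices (repeats allowed, any order).
#' @return The moment (a number).
#' @examples
#' poisson_moment(c(2, 1), c(1, 1))  # 2 + 4 = 6
#' @export
poisson_moment <- function(mu, I) {
  tab <- table(I)
  out <- 1
  for (k in seq_along(tab)) {
    idx <- as.integer(names(tab)[k])
    out <- out * poisson_raw_moment(mu[idx], as.integer(tab[k]))
  }
  out
}

# Taylor coefficients in theta*L of mu_I when mu_i = thetaL * shape_i:
# product over distinct indices of sum_j S(k,j) shape_i^j (thetaL)^j.
# Returns coefficients of orders 1..n_I (order 0 is zero for n_I >= 1).
poisson_moment_taylor <- function(shape, I) {
  tab <- table(I)
  poly <- 1  # polynomial coefficients, constant term first
  for (k in seq_along(tab)) {
    idx <- as.integer(names(tab)[k])
    kk <- as.integer(tab[k])
    fac <- c(0, vapply(seq_len(kk), function(jj)
      stirling2(kk, jj) * shape[idx]^jj, numeric(1)))
    # convolve
    newpoly <- numeric(length(poly) + length(fac) - 1L)
    for (a in seq_along(poly)) {
      newpoly[a + seq_along(fac) - 1L] <-
        newpoly[a + seq_along(fac) - 1L] + poly[a] * fac
    }
    poly <- newpoly
  }
  out <- numeric(length(I))
  coefs <- poly[-1L]  # drop constant term
  out[seq_along(coefs)] <- coefs
  out[seq_len(length(I))]
}

# All ordered multisets (non-decreasing index tuples) over classes 1..m of
# sizes 1..d, as a list of integer vectors.
multisets_upto <- function(m, d) {
  out <- list()
  current <- lapply(seq_len(m), function(i) i)
  out <- c(out, current)
  if (d >= 2) {
    for (size in 2:d) {
      nxt <- list()
      for (tup in current) {
        last <- tup[length(tup)]
        for (j in last:m) nxt[[length(nxt) + 1L]] <- c(tup, j)
      }
      out <- c(out, nxt)
      current <- nxt
    }
  }
  out
}

# Number of distinct permutations of a multiset.
multiset_sigma <- function(I) {
  factorial(length(I)) / prod(factorial(table(I)))
}

#' Polynomial neutrality tests
#'
#' A polynomial test of degree `d` is a polynomial in the SFS class counts,
#' normalised to zero mean and unit variance under the null model. It is
#' stored as a constant `gamma` plus one coefficient per ordered multiset of
#' class indices (the coefficient multiplies the corresponding monomial once,
#' i.e. permutation multiplicities are already absorbed). Strongly centred
#' tests have zero mean under the null for any plugged-in theta; weakly
#' centred tests only when the plug-in equals the true theta.
#'
#' @param multisets list of ordered integer index vectors.
#' @param coef monomial coefficients, one per multiset.
#' @param gamma constant term.
#' @param centring `"strong"` or `"weak"`.
#' @param model the [moment_model] the test was built from (fixes the
#'   plugged-in theta and the null variance).
#' @param name label.
#' @return An object of class `polynomial_test`. The null variance of the
#'   unnormalised statistic is precomputed under the model's Poisson null.
#' @export
polynomial_test <- function(multisets, coef, gamma, centring, model,
                            name = "polynomial") {
  stopifnot(inherits(model, "moment_model"))
  d <- max(vapply(multisets, length, integer(1)))
  m <- length(model$mu)
  # dense forms for fast evaluation up to degree 2
  b1 <- numeric(m); B2 <- NULL
  if (d >= 2) B2 <- matrix(0, m, m)
  for (k in seq_along(multisets)) {
    I <- multisets[[k]]
    if (length(I) == 1L) b1[I] <- b1[I] + coef[k]
    else if (length(I) == 2L) {
      B2[I[1L], I[2L]] <- B2[I[1L], I[2L]] + coef[k] / 2
      B2[I[2L], I[1L]] <- B2[I[2L], I[1L]] + coef[k] / 2
    }
  }
  v <- polynomial_null_variance(multisets, coef, model$mu)
  if (v <= 0) stop("degenerate polynomial test: zero variance under the null")
  structure(list(multisets = multisets, coef = coef, gamma = gamma,
                 degree = d, centring = centring, model = model,
                 b1 = b1, B2 = B2, var = v, name = name),
            class = "polynomial_test")
}

# Var of sum_I coef_I * prod(xi_I) under independent Poisson with mean mu.
polynomial_null_variance <- function(multisets, coef, mu) {
  m <- length(multisets)
  mom <- vapply(multisets, function(I) poisson_moment(mu, I), numeric(1))
  v <- 0
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      un <- poisson_moment(mu, c(multisets[[a]], multisets[[b]]))
      v <- v + coef[a] * coef[b] * (un - mom[a] * mom[b])
    }
  }
  v
}

#' Evaluate a polynomial test
#'
#' Computes `(gamma + sum_I coef_I prod(xi_I)) / sqrt(Var)` with the null
#' variance taken under the Poisson model at the test's plugged-in theta.
#' Tests of degree up to two evaluate through dense linear/quadratic forms
#' and accept a matrix of replicate spectra (rows).
#'
#' @param test a [polynomial_test].
#' @param spec an [sfs] object, numeric spectrum vector, or replicate matrix.
#' @return The normalised statistic (scalar or per-row vector).
#' @export
evaluate_polynomial <- function(test, spec) {
  stopifnot(inherits(test, "polynomial_test"))
  x <- if (inherits(spec, "sfs")) spec$counts else spec
  sd0 <- sqrt(test$var)
  if (is.matrix(x)) {
    if (test$degree > 2L) stop("matrix evaluation supported up to degree 2")
    num <- test$gamma + drop(x %*% test$b1)
    if (!is.null(test$B2)) num <- num + rowSums((x %*% test$B2) * x)
    return(num / sd0)
  }
  if (test$degree <= 2L) {
    num <- test$gamma + sum(test$b1 * x)
    if (!is.null(test$B2)) num <- num + drop(t(x) %*% test$B2 %*% x)
  } else {
    num <- test$gamma + sum(vapply(seq_along(test$multisets), function(k)
      test$coef[k] * prod(x[test$multisets[[k]]]), numeric(1)))
  }
  num / sd0
}

#' Renormalised Fu's G test
#'
#' Fu's G statistic is the Hotelling-type quadratic form
#' `G = sum_ij c^-1_ij (xi_i - theta*L*xi0_i)(xi_j - theta*L*xi0_j)`; its
#' diagonal approximation `G_xi = G/(n-1)` (with `c = diag`) is the form
#' originally proposed. The renormalised version
#' `T_G = (G - (n-1)) / sqrt(Var(G))` has zero mean and unit variance under
#' the null and the same power as `G` at any threshold. The variance is
#' computed under the independent-sites Poisson model at the plugged-in
#' theta.
#'
#' @param model a [moment_model] fixing `mu` (and the plug-in theta).
#' @param cov optional covariance matrix `c_ij`; defaults to the Poisson
#'   diagonal `diag(mu)`.
#' @return A [polynomial_test] (weakly centred, degree 2) whose evaluation
#'   yields `T_G`; the unnormalised `G` can be recovered as
#'   `T * sqrt(test$var) + (n-1) + gamma_offset` (see `attr(test, "offset")`).
#' @export
fu_g_test <- function(model, cov = NULL) {
  stopifnot(inherits(model, "moment_model"))
  mu <- model$mu
  m <- length(mu)
  A <- if (is.null(cov)) diag(1 / mu) else pseudo_solve(cov)
  # expand (xi - mu)' A (xi - mu) - (m) into polynomial coefficients
  ms <- multisets_upto(m, 2L)
  coef <- numeric(length(ms))
  for (k in seq_along(ms)) {
    I <- ms[[k]]
    if (length(I) == 1L) coef[k] <- -2 * sum(A[I, ] * mu)
    else if (I[1L] == I[2L]) coef[k] <- A[I[1L], I[1L]]
    else coef[k] <- 2 * A[I[1L], I[2L]]
  }
  gamma <- drop(t(mu) %*% A %*% mu) - m
  test <- polynomial_test(ms, coef, gamma, centring = "weak", model = model,
                          name = "fu_g")
  attr(test, "offset") <- m
  test
}

#' Diagonal Fu's G statistic
#'
#' The unnormalised diagonal approximation
#' `G_xi = (1/(n-1)) sum_i (xi_i - mu_i)^2 / mu_i`.
#'
#' @param spec an [sfs] object or spectrum vector.
#' @param model a [moment_model].
#' @return The statistic value.
#' @export
fu_g_diagonal <- function(spec, model) {
  x <- if (inherits(spec, "sfs")) spec$counts else spec
  mu <- model$mu
  sum((x - mu)^2 / mu) / length(mu)
}

#' Explicit optimal quadratic tests (independent sites)
#'
#' Closed-form weights of the optimal quadratic tests under the
#' independent-sites Poisson model, in terms of the first moments `mu_i`
#' (null) and `mubar_i` (alternative) and their totals `Smu = sum mu_i`,
#' `Smubar = sum mubar_i`.
#'
#' Strongly centred (`quadratic_sc_optimal`):
#' \deqn{Omega^{(1)}_i = (Smu + 2 - Smubar)(mubar_i/mu_i - Smubar/Smu)
#'       - (1/2)(mubar_i^2/mu_i^2 - Smubar^2/Smu^2)}
#' \deqn{Omega^{(2)}_{ii} = -(mubar_i/mu_i - Smubar/Smu)
#'       + (1/2)(mubar_i^2/mu_i^2 - Smubar^2/Smu^2)}
#' \deqn{Omega^{(2)}_{ij} = (1/2)[(mubar_i mubar_j/(mu_i mu_j) -
#'       Smubar^2/Smu^2) - (mubar_i/mu_i - Smubar/Smu) -
#'       (mubar_j/mu_j - Smubar/Smu)]}
#'
#' Weakly centred (`quadratic_wc_optimal`):
#' \deqn{Gamma^{(1)}_i = (Smu + 2 - Smubar)(mubar_i/mu_i - 1)
#'       - (1/2)(mubar_i^2/mu_i^2 - 1)}
#' \deqn{Gamma^{(2)}_{ij} = (1/2)(mubar_i/mu_i - 1)(mubar_j/mu_j - 1)}
#' \deqn{gamma = (1/2)(Smu - Smubar)(Smu + 2 - Smubar)}
#'
#' Both satisfy the maximal-test identity: the variance of the unnormalised
#' statistic under the null equals its expectation under the alternative.
#' The formulas hold verbatim for the folded spectrum with folded moments.
#'
#' @param model a [moment_model] with distinct `mu` and `mubar`.
#' @return A [polynomial_test] of degree 2.
#' @export
quadratic_sc_optimal <- function(model) {
  stopifnot(inherits(model, "moment_model"))
  mu <- model$mu; mubar <- model$mubar
  if (isTRUE(all.equal(mu, mubar)))
    stop("degenerate: alternative equals the null model")
  Smu <- sum(mu); Smubar <- sum(mubar)
  r <- mubar / mu
  A <- r - Smubar / Smu
  B <- r^2 - (Smubar / Smu)^2
  m <- length(mu)
  ms <- multisets_upto(m, 2L)
  coef <- numeric(length(ms))
  for (k in seq_along(ms)) {
    I <- ms[[k]]
    if (length(I) == 1L) {
      i <- I
      coef[k] <- (Smu + 2 - Smubar) * A[i] - 0.5 * B[i]
    } else if (I[1L] == I[2L]) {
      i <- I[1L]
      coef[k] <- -A[i] + 0.5 * B[i]
    } else {
      i <- I[1L]; j <- I[2L]
      # full symmetric tensor entry, times 2 for the two ordered pairs
      coef[k] <- 2 * 0.5 *
        ((r[i] * r[j] - (Smubar / Smu)^2) - A[i] - A[j])
    }
  }
  polynomial_test(ms, coef, gamma = 0, centring = "strong", model = model,
                  name = "quadratic_sc_optimal")
}

#' @rdname quadratic_sc_optimal
#' @export
quadratic_wc_optimal <- function(model) {
  stopifnot(inherits(model, "moment_model"))
  mu <- model$mu; mubar <- model$mubar
  if (isTRUE(all.equal(mu, mubar)))
    stop("degenerate: alternative equals the null model")
  Smu <- sum(mu); Smubar <- sum(mubar)
  r <- mubar / mu - 1
  m <- length(mu)
  ms <- multisets_upto(m, 2L)
  coef <- numeric(length(ms))
  for (k in seq_along(ms)) {
    I <- ms[[k]]
    if (length(I) == 1L) {
      i <- I
      coef[k] <- (Smu + 2 - Smubar) * r[i] - 0.5 * ((r[i] + 1)^2 - 1)
    } else if (I[1L] == I[2L]) {
      coef[k] <- 0.5 * r[I[1L]]^2
    } else {
      coef[k] <- 2 * 0.5 * r[I[1L]] * r[I[2L]]
    }
  }
  gamma <- 0.5 * (Smu - Smubar) * (Smu + 2 - Smubar)
  polynomial_test(ms, coef, gamma = gamma, centring = "weak", model = model,
                  name = "quadratic_wc_optimal")
}

#' Optimal weakly centred linear test
#'
#' First-order weakly centred optimal test: `Gamma_i = sum_j c^-1_ij
#' (mubar_j - mu_j)`, `gamma = -sum_jk mu_j c^-1_jk (mubar_k - mu_k)`, with
#' `c_ij = mu_ij - mu_i mu_j` the null covariance (diagonal `mu_i` under the
#' Poisson model). Its expectation under the alternative is
#' `sqrt((mubar-mu)' c^-1 (mubar-mu))`, which always dominates the maximum of
#' the strongly centred linear test for the same scenario.
#'
#' @param model a [moment_model].
#' @param cov optional covariance matrix; defaults to `diag(mu)`.
#' @return A [polynomial_test] (weak, degree 1).
#' @export
linear_wc_optimal <- function(model, cov = NULL) {
  stopifnot(inherits(model, "moment_model"))
  mu <- model$mu; mubar <- model$mubar
  if (isTRUE(all.equal(mu, mubar)))
    stop("degenerate: alternative equals the null model")
  d <- mubar - mu
  g <- if (is.null(cov)) d / mu else drop(pseudo_solve(cov, d))
  gamma <- -sum(mu * g)
  ms <- lapply(seq_along(mu), function(i) i)
  polynomial_test(ms, g, gamma = gamma, centring = "weak", model = model,
                  name = "linear_wc_optimal")
}

#' Maximal expectations of first-order optimal tests
#'
#' `wc_linear_max` is the alternative expectation of the optimal weakly
#' centred linear test; `sc_linear_max` the corresponding maximum for
#' strongly centred (classic) linear tests. The weakly centred maximum always
#' dominates.
#'
#' @param model a [moment_model].
#' @return A number.
#' @export
wc_linear_max <- function(model) {
  d <- model$mubar - model$mu
  sqrt(sum(d^2 / model$mu))
}

#' @rdname wc_linear_max
#' @export
sc_linear_max <- function(model) {
  d <- model$mubar - model$mu
  q <- sum(d^2 / model$mu)
  proj <- sum(model$mu * d / model$mu)  # <mu, c^-1 (mubar - mu)>
  norm0 <- sum(model$mu^2 / model$mu)
  sqrt(q - proj^2 / norm0)
}

#' General optimal polynomial tests
#'
#' Builds the optimal polynomial test of any degree `d`, strongly or weakly
#' centred, from the moment machinery over ordered multisets of class
#' indices. Writing `b` for the vector of monomial coefficients over ordered
#' multisets, `mu` and `mubar` for the null/alternative moment vectors, `C`
#' for the null covariance of the monomials (`C_IJ = mu_{I u J} - mu_I
#' mu_J`), and `P` for the matrix of Taylor coefficients of `mu_I` in powers
#' of `theta*L`:
#' * weak: `b = C^-1 (mubar - mu)`, `gamma = -mu . b`;
#' * strong: `b = C^-1 mubar - C^-1 P (P' C^-1 P)^-1 P' C^-1 mubar`, i.e. the
#'   weak solution projected onto the strong-centredness constraints
#'   (`P' b = 0`, order-by-order in `theta*L`).
#'
#' In both cases the variance of the unnormalised statistic under the null
#' equals its expectation under the alternative. For `d = 1` the strong
#' construction reproduces the optimal linear test, for `d = 2` the explicit
#' quadratic formulas.
#'
#' @param model a [moment_model].
#' @param degree polynomial degree `d >= 1`.
#' @param centring `"strong"` or `"weak"`.
#' @param max_multisets guard on the number of ordered multisets (matrix
#'   dimension); increase deliberately for large `n` or `d`.
#' @param use_second_moments replace the monomial covariance `C` by the raw
#'   second-moment matrix `mu_{I u J}` throughout. For strongly centred tests
#'   this leaves the test exactly unchanged (the rank-one difference
#'   `mu mu'` lies in the span of the centredness constraints) and can be
#'   numerically more convenient; it is refused for weakly centred tests,
#'   where the substitution changes the test.
#' @return A [polynomial_test].
#' @export
general_optimal <- function(model, degree = 2L, centring = c("strong", "weak"),
                            max_multisets = 5000L,
                            use_second_moments = FALSE) {
  centring <- match.arg(centring)
  stopifnot(inherits(model, "moment_model"), degree >= 1L)
  m <- length(model$mu)
  ms <- multisets_upto(m, degree)
  M <- length(ms)
  if (M > max_multisets)
    stop(sprintf("%d ordered multisets exceed the cap of %d", M, max_multisets))
  muI <- vapply(ms, function(I) poisson_moment(model$mu, I), numeric(1))
  mubarI <- vapply(ms, function(I) poisson_moment(model$mubar, I), numeric(1))
  if (use_second_moments && centring == "weak")
    stop("the second-moment substitution is exact only for strongly centred tests")
  C <- matrix(0, M, M)
  for (a in seq_len(M)) {
    for (b in a:M) {
      un <- poisson_moment(model$mu, c(ms[[a]], ms[[b]]))
      C[a, b] <- C[b, a] <- un -
        (if (use_second_moments) 0 else muI[a] * muI[b])
    }
  }
  if (centring == "weak") {
    bvec <- drop(pseudo_solve(C, mubarI - muI))
    gamma <- -sum(muI * bvec)
  } else {
    P <- matrix(0, M, degree)
    for (a in seq_len(M)) {
      tay <- poisson_moment_taylor(model$xi0, ms[[a]])
      P[a, seq_along(tay)] <- tay
    }
    CinvMubar <- drop(pseudo_solve(C, mubarI))
    CinvP <- pseudo_solve(C, P)
    G <- crossprod(P, CinvP)                  # P' C^-1 P
    corr <- CinvP %*% pseudo_solve(G, crossprod(P, CinvMubar))
    bvec <- CinvMubar - drop(corr)
    gamma <- 0
  }
  polynomial_test(ms, bvec, gamma = gamma, centring = centring, model = model,
                  name = sprintf("optimal_%s_d%d", centring, degree))
}
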