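#' Continuum weight functions
#'
#' A weight function is the large-sample limit of the per-class weights of a
#' theta estimator: a function `omega(f)` of the population allele frequency
#' `f` in (0,1), optionally with point masses on derived singletons (`ds`) and
#' ancestral singletons (`as`), which capture alleles at population frequency
#' below `1/n`. Functions are represented by symbolic tags so that schemes can
#' be serialised and so that divergent behaviour near `f = 0` (like the
#' Watterson `1/f` weight) is declared rather than guessed.
#'
#' Available tags:
#' * `"constant"`: `omega(f) = c` (parameter `c`, default 1).
#' * `"two_one_minus_f"`: `omega(f) = 2(1-f)` (pairwise-diversity weights).
#' * `"two_f"`: `omega(f) = 2f`.
#' * `"watterson"`: divergent `omega(f) = 1/(f log N)`; only usable with the
#'   ratio scaling, where the population-size cutoff `N` cancels.
#' * `"power"`: `omega(f) = (1-r) f^(-r)` (parameter `r`); divergent when
#'   the exponent is 1 or larger.
#' * `"exp_decay"`: `omega(f) = beta exp(-beta f) / (1 - exp(-beta))`
#'   (parameter `beta`).
#' * `"dirac"`: point mass `mass` at `f = at`; only meaningful under the
#'   binomial-sampling scaling.
#' * `"zero"`: identically zero (used when only singleton masses carry weight).
#' * `"custom"`: arbitrary R function in `params$fun` (not serialisable).
#'
#' @param tag character tag from the list above.
#' @param params named list of parameters for the tag.
#' @param ds,as singleton point masses added to classes 1 and `n - 1`.
#' @return An object of class `weight_fun`.
#' @export
weight_fun <- function(tag = "constant", params = list(), ds = 0, as = 0) {
  known <- c("constant", "two_one_minus_f", "two_f", "watterson", "power",
             "exp_decay", "dirac", "zero", "custom")
  if (!tag %in% known) stop("unknown weight function tag: ", tag)
  if (tag == "power" && is.null(params$r)) stop("'power' needs params$r")
  if (tag == "exp_decay" && is.null(params$beta)) stop("'exp_decay' needs params$beta")
  if (tag == "dirac" && (is.null(params$at))) stop("'dirac' needs params$at")
  if (tag == "custom" && !is.function(params$fun)) stop("'custom' needs params$fun")
  structure(list(tag = tag, params = params, ds = ds, as = as),
            class = "weight_fun")
}

wf_is_divergent <- function(wf) {
  wf$tag == "watterson" || (wf$tag == "power" && wf$params$r >= 1)
}

# Evaluate the smooth part of a weight function on frequencies f in (0,1).
# The Watterson tag needs the cutoff population size N; it is kept explicit so
# that its cancellation in the ratio scaling is visible in the formulas.
wf_eval <- function(wf, f, N = 1e6) {
  switch(wf$tag,
    constant = rep(if (is.null(wf$params$c)) 1 else wf$params$c, length(f)),
    two_one_minus_f = 2 * (1 - f),
    two_f = 2 * f,
    watterson = 1 / (f * log(N)),
    power = (1 - wf$params$r) * f^(-wf$params$r),
    exp_decay = {
      b <- wf$params$beta
      b * exp(-b * f) / (1 - exp(-b))
    },
    dirac = stop("a Dirac weight function has no pointwise values; ",
                 "use the binomial-sampling scaling"),
    zero = rep(0, length(f)),
    custom = wf$params$fun(f)
  )
}

#' Weight schemes
#'
#' A weight scheme fixes how the discrete per-class weights `Omega_i(n)` of a
#' neutrality test are produced from continuum weight functions for any sample
#' size `n`, making the test's interpretation (approximately) independent of
#' `n`. Three scalings are supported:
#'
#' * `"centering"`: `Omega_i = Omega(i/n) + Omega_ds d_{i,1} + Omega_as
#'   d_{i,n-1} - mean_j(...)`, a subtractive correction restoring exact
#'   centredness. Requires a single bounded difference function `Omega(f)`.
#' * `"ratio"`: each of the two estimator weight functions `omega`, `omega'`
#'   is discretised as `omega(i/n)` (plus singleton masses) and renormalised
#'   to sum to 1 separately; `Omega_i` is their difference. This is the form
#'   implicitly used by most classic tests and the only valid one for
#'   divergent weights such as Watterson's `1/f`.
#' * `"binomial"`: `omega_i` proportional to the binomial-kernel integral
#'   `int C(n,i) f^i (1-f)^(n-i) omega(f) df`, normalised by
#'   `int (1 - f^n - (1-f)^n) omega(f) df`; Dirac components are integrated
#'   analytically, smooth parts with 256-node Gauss-Legendre quadrature.
#'
#' @param omega,omega_prime [weight_fun] objects for the two estimators
#'   (ratio/binomial scalings).
#' @param Omega a single [weight_fun] difference function (centering scaling).
#' @param scaling one of `"centering"`, `"ratio"`, `"binomial"`.
#' @param N cutoff population size entering divergent weight functions.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(omega = NULL, omega_prime = NULL, Omega = NULL,
                          scaling = c("ratio", "centering", "binomial"),
                          N = 1e6) {
  scaling <- match.arg(scaling)
  if (scaling == "centering") {
    if (is.null(Omega)) stop("centering scaling needs the difference function 'Omega'")
  } else if (is.null(omega) || is.null(omega_prime)) {
    stop("ratio/binomial scalings need both 'omega' and 'omega_prime'")
  }
  structure(list(omega = omega, omega_prime = omega_prime, Omega = Omega,
                 scaling = scaling, N = N),
            class = "weight_scheme")
}

#' Realise discrete weights by the centering form
#'
#' `Omega_i(n) = Omega(i/n) + Omega_ds d_{i,1} + Omega_as d_{i,n-1} -
#'  (1/(n-1)) (Omega_ds + Omega_as + sum_j Omega(j/n))`. The subtractive
#' correction enforces `sum_i Omega_i = 0` exactly. Divergent weight
#' functions are refused: for those the correction term carries a strong
#' dependence on `n` and on the population-size cutoff, and the ratio form
#' must be used instead.
#'
#' @param scheme a [weight_scheme] with a difference function `Omega`.
#' @param n haploid sample size.
#' @return Numeric weight vector of length `n - 1` summing to zero.
#' @export
realise_centering <- function(scheme, n) {
  stopifnot(inherits(scheme, "weight_scheme"))
  wf <- scheme$Omega
  if (is.null(wf)) stop("scheme has no difference function 'Omega'")
  if (wf_is_divergent(wf))
    stop("divergent weight functions cannot use the centering form; ",
         "use the ratio scaling")
  i <- seq_len(n - 1L)
  base <- wf_eval(wf, i / n, N = scheme$N)
  base[1L] <- base[1L] + wf$ds
  base[n - 1L] <- base[n - 1L] + wf$as
  w <- base - sum(base) / (n - 1L)
  w - sum(w) / (n - 1L)  # second pass kills residual rounding
}

# Discretise one side of a ratio-scaled scheme: singleton masses plus the
# function values at i/n, normalised to sum to one.
realise_ratio_side <- function(wf, n, N) {
  i <- seq_len(n - 1L)
  v <- wf_eval(wf, i / n, N = N)
  v[1L] <- v[1L] + wf$ds
  v[n - 1L] <- v[n - 1L] + wf$as
  s <- sum(v)
  if (abs(s) < 1e-300) stop("degenerate weight scheme: zero normalisation sum")
  v / s
}

#' Realise discrete weights by the ratio form
#'
#' Each estimator weight vector is discretised and renormalised separately;
#' the test weights are their difference, so `sum_i Omega_i = 0` exactly. For
#' the divergent Watterson function the cutoff `N` cancels between numerator
#' and denominator and the realised side equals `(1/i)/a_n`.
#'
#' @inheritParams realise_centering
#' @return Numeric weight vector of length `n - 1` summing to zero, with the
#'   two normalised sides attached as attributes `omega` and `omega_prime`.
#' @export
realise_ratio <- function(scheme, n) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (is.null(scheme$omega) || is.null(scheme$omega_prime))
    stop("ratio scaling needs both 'omega' and 'omega_prime'")
  w1 <- realise_ratio_side(scheme$omega, n, scheme$N)
  w2 <- realise_ratio_side(scheme$omega_prime, n, scheme$N)
  out <- w1 - w2
  attr(out, "omega") <- w1
  attr(out, "omega_prime") <- w2
  out
}

# Binomial-kernel integrals of one weight function side: numerator vector
# int C(n,i) f^i (1-f)^(n-i) w(f) df for i = 1..n-1 and the normalising
# denominator int (1 - f^n - (1-f)^n) w(f) df. Dirac masses analytic, smooth
# parts by fixed Gauss-Legendre quadrature.
binomial_side <- function(wf, n, N, nodes = 256L) {
  i <- seq_len(n - 1L)
  num <- numeric(n - 1L)
  den <- 0
  if (wf$tag == "dirac") {
    at <- wf$params$at
    mass <- if (is.null(wf$params$mass)) 1 else wf$params$mass
    num <- num + mass * stats::dbinom(i, n, at)
    den <- den + mass * (1 - at^n - (1 - at)^n)
  } else if (wf$tag != "zero") {
    gl <- pracma::gaussLegendre(nodes, 0, 1)
    wvals <- wf_eval(wf, gl$x, N = N)
    if (any(!is.finite(wvals)))
      stop("weight function is not integrable against the binomial kernel")
    kern <- vapply(i, function(k) sum(gl$w * wvals * stats::dbinom(k, n, gl$x)),
                   numeric(1))
    num <- num + kern
    den <- den + sum(gl$w * wvals * (1 - gl$x^n - (1 - gl$x)^n))
  }
  if (abs(den) < 1e-300) stop("degenerate weight scheme: zero denominator")
  num / den
}

#' Realise estimator weights by binomial sampling
#'
#' Assigns `omega_i` from `omega(f)` through the same binomial sampling that
#' produces allele counts from population frequencies. This is the scaling
#' obeyed by Achaz's admixture test (Dirac mass at `f = 1/2` against a uniform
#' weight) and by optimal tests.
#'
#' @inheritParams realise_centering
#' @return List with normalised vectors `omega`, `omega_prime` and their
#'   difference `Omega`.
#' @export
realise_binomial <- function(scheme, n) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (is.null(scheme$omega) || is.null(scheme$omega_prime))
    stop("binomial scaling needs both 'omega' and 'omega_prime'")
  w1 <- binomial_side(scheme$omega, n, scheme$N)
  w2 <- binomial_side(scheme$omega_prime, n, scheme$N)
  list(omega = w1, omega_prime = w2, Omega = w1 - w2)
}

#' Realise a weight scheme at sample size n
#'
#' Dispatches on the scheme's scaling and returns the centred test weight
#' vector `Omega_i(n)`.
#'
#' @inheritParams realise_centering
#' @return Numeric weight vector of length `n - 1`.
#' @export
realise_weights <- function(scheme, n) {
  switch(scheme$scaling,
         centering = realise_centering(scheme, n),
         ratio = realise_ratio(scheme, n),
         binomial = realise_binomial(scheme, n)$Omega)
}

#' Watterson estimator weights
#'
#' Ratio-scaled weights of the divergent `omega(f) = 1/(f log N)` function:
#' `omega_i = (1/i) / a_n`, independent of the cutoff `N`, which cancels
#' between numerator and normalisation.
#'
#' @param n haploid sample size.
#' @return Normalised weight vector of length `n - 1`.
#' @examples
#' watterson_weights(4)  # (1/i) / a_4 = 6/11, 3/11, 2/11
#' @export
watterson_weights <- function(n) {
  i <- seq_len(n - 1L)
  (1 / i) / harmonic_number(n)
}

#' Weight schemes of the classic neutrality tests
#'
#' Builds the discrete weights of the classic SFS-based tests from their
#' continuum weight functions:
#'
#' * `tajima_d`: pairwise diversity `omega(f) = 2(1-f)` against Watterson.
#' * `fay_wu_h`: `omega(f) = 2(1-f)` against `omega'(f) = 2f`; sensitive to an
#'   excess of high-frequency derived alleles.
#' * `zeng_e`: Watterson against the uniform `omega'(f) = 1`; high-frequency
#'   derived alleles versus low-frequency alleles.
#' * `fu_li_f`: derived-singleton mass (`omega_ds = 1`) against Watterson;
#'   numerator `xi_1 - S/a_n`.
#' * `fu_f`: Fu's `F(r, r')` family, `omega_i = i^(-r) / sum_j j^(-r)`;
#'   requires exponents at most 1 (exponent 1 is the Watterson weight; larger ones
#'   give divergent weight functions with no agreed finite-sample
#'   normalisation and are refused).
#' * `achaz_bottleneck`: `omega(f) = beta exp(-beta f)/(1 - exp(-beta))`
#'   against uniform; `params$beta` or `params$alpha` (with `beta = alpha*n`).
#' * `achaz_admixture`: binomial-sampled Dirac mass at `f = 1/2` against
#'   uniform, `omega_i = C(n,i) 2^(-n) / (1 - 2^(-n+1))`.
#'
#' Any catalogue entry can be error-corrected (`error_corrected = TRUE`),
#' which zeroes the weights of derived and ancestral singletons on each
#' estimator side and renormalises over the interior classes, removing the
#' classes where sequencing errors concentrate.
#'
#' @param name catalogue entry name.
#' @param n haploid sample size.
#' @param params named list of test parameters (`r`, `r_prime`, `beta`,
#'   `alpha` as applicable).
#' @param error_corrected zero singleton-class weights?
#' @return A list with elements `Omega` (centred weight vector), `omega`,
#'   `omega_prime` (normalised estimator weights, where defined) and `name`.
#' @examples
#' classic_test_weights("tajima_d", n = 10)$Omega
#' @export
classic_test_weights <- function(name, n, params = list(),
                                 error_corrected = FALSE) {
  i <- seq_len(n - 1L)
  an <- harmonic_number(n)
  watt <- watterson_weights(n)
  unif <- rep(1 / (n - 1), n - 1L)
  res <- switch(name,
    tajima_d = {
      w <- (2 * (n - i)) / (n * (n - 1))
      list(omega = w, omega_prime = watt)
    },
    fay_wu_h = {
      list(omega = (2 * (n - i)) / (n * (n - 1)),
           omega_prime = (2 * i) / (n * (n - 1)))
    },
    zeng_e = list(omega = watt, omega_prime = unif),
    fu_li_f = {
      w <- numeric(n - 1L); w[1L] <- 1
      list(omega = w, omega_prime = watt)
    },
    fu_f = {
      r <- params$r; rp <- params$r_prime
      if (is.null(r) || is.null(rp)) stop("fu_f needs params$r and params$r_prime")
      if (r > 1 || rp > 1)
        stop("fu_f with exponents > 1 has a divergent weight function with no ",
             "agreed finite-sample normalisation; not provided")
      list(omega = i^(-r) / sum(i^(-r)),
           omega_prime = i^(-rp) / sum(i^(-rp)))
    },
    achaz_bottleneck = {
      beta <- params$beta
      if (is.null(beta)) {
        if (is.null(params$alpha)) stop("achaz_bottleneck needs params$beta or params$alpha")
        beta <- achaz_bottleneck_beta(params$alpha, n)
      }
      w <- exp(-beta * i / n)
      list(omega = w / sum(w), omega_prime = unif)
    },
    achaz_admixture = {
      list(omega = stats::dbinom(i, n, 0.5) / (1 - 2^(-n + 1)),
           omega_prime = unif)
    },
    stop("unknown classic test: ", name)
  )
  if (error_corrected) {
    zero_ends <- function(w) {
      w[c(1L, n - 1L)] <- 0
      s <- sum(w)
      if (abs(s) < 1e-300) stop("error correction leaves no weight mass")
      w / s
    }
    res$omega <- zero_ends(res$omega)
    res$omega_prime <- zero_ends(res$omega_prime)
  }
  res$Omega <- res$omega - res$omega_prime
  res$name <- if (error_corrected) paste0(name, "_nosingletons") else name
  res
}

#' Bottleneck-test parameter correspondence
#'
#' Achaz's original bottleneck test used weights `exp(-alpha * i)`, whose
#' shape depends on the sample size; the weight-consistent version uses
#' `exp(-beta * i/n)`. The two coincide when `beta = alpha * n`.
#'
#' @param alpha decay rate per allele-count class.
#' @param n haploid sample size.
#' @return The weight-consistent decay rate `beta`.
#' @examples
#' achaz_bottleneck_beta(0.9, 30)  # 27
#' @export
achaz_bottleneck_beta <- function(alpha, n) alpha * n

#' Bottleneck scheme in both scalings
#'
#' Returns the bottleneck weight scheme realised with the ratio scaling and
#' with the centering scaling; the two differ by an overall multiplicative
#' factor only, so the normalised tests coincide.
#'
#' @param beta weight-consistent decay rate.
#' @param n haploid sample size.
#' @return List with weight vectors `ratio` and `centering`.
#' @export
bottleneck_both_scalings <- function(beta, n) {
  ratio <- classic_test_weights("achaz_bottleneck", n, list(beta = beta))$Omega
  Om <- weight_fun("custom", params = list(
    fun = function(f) beta * exp(-beta * f) / (1 - exp(-beta)) - 1))
  centering <- realise_centering(
    weight_scheme(Omega = Om, scaling = "centering"), n)
  list(ratio = ratio, centering = centering)
}

#' Rescaled average admixture-test weight over a frequency window
#'
#' Averages the sample-size-rescaled weight `n * (omega_i - omega'_i)` of
#' Achaz's admixture test over the allele-count classes whose frequency `i/n`
#' lies in `[f_lo, f_hi]` (endpoints inclusive). The strong sample-size
#' dependence of this quantity (positive at `n = 10`, negative at larger `n`
#' for the 0.3-0.4 window) illustrates why weight-consistent scalings matter.
#'
#' @param n haploid sample size.
#' @param f_lo,f_hi frequency window, `0 < f_lo < f_hi < 1`.
#' @return Mean rescaled weight over the classes in the window.
#' @examples
#' admixture_average_weight(10, 0.3, 0.4)
#' @export
admixture_average_weight <- function(n, f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi < 1 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi < 1")
  w <- classic_test_weights("achaz_admixture", n)
  i <- seq_len(n - 1L)
  keep <- i / n >= f_lo & i / n <= f_hi
  if (!any(keep)) stop("no allele-count class falls in the frequency window")
  mean(n * (w$omega[keep] - w$omega_prime[keep]))
}

#' Serialise a weight scheme to JSON
#'
#' Schemes built from tagged weight functions round-trip through JSON; custom
#' R functions are refused.
#'
#' @param scheme a [weight_scheme].
#' @return A JSON string.
#' @export
scheme_to_json <- function(scheme) {
  stopifnot(inherits(scheme, "weight_scheme"))
  ser_wf <- function(wf) {
    if (is.null(wf)) return(NULL)
    if (wf$tag == "custom") stop("custom weight functions are not serialisable")
    list(tag = wf$tag, params = wf$params, ds = wf$ds, as = wf$as)
  }
  jsonlite::toJSON(list(omega = ser_wf(scheme$omega),
                        omega_prime = ser_wf(scheme$omega_prime),
                        Omega = ser_wf(scheme$Omega),
                        scaling = scheme$scaling, N = scheme$N),
                   auto_unbox = TRUE, digits = I(17), null = "null")
}

#' @rdname scheme_to_json
#' @param json a JSON string produced by `scheme_to_json`.
#' @export
scheme_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  de_wf <- function(w) {
    if (is.null(w)) return(NULL)
    weight_fun(w$tag, params = as.list(w$params), ds = w$ds, as = w$as)
  }
  weight_scheme(omega = de_wf(x$omega), omega_prime = de_wf(x$omega_prime),
                Omega = de_wf(x$Omega), scaling = x$scaling, N = x$N)
}
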