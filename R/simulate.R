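#' Scenario configurations for the simulator
#'
#' Three demographic scenarios are supported:
#' * `"neutral"`: the standard constant-size Wright-Fisher coalescent.
#' * `"subdivision"`: two demes of equal size exchanging migrants at
#'   symmetric scaled rate `M` (`M = 4*N*m`, per-lineage migration rate `M/2`
#'   on the coalescent time scale); all `n` lineages are sampled from one
#'   deme.
#' * `"expansion"`: a stepwise size change by a factor `growth = N0/N` (10 by
#'   default) at time `T` before present, `T` in units of `4N` generations;
#'   sizes are referred to the present population, so the ancestral epoch
#'   coalesces `growth` times faster and `T -> Inf` recovers neutrality.
#'
#' @param kind scenario kind.
#' @param n haploid sample size.
#' @param theta scaled mutation rate per base.
#' @param L sequence length in bases.
#' @param M symmetric scaled migration rate (subdivision).
#' @param T time of the size change in units of `4N` generations (expansion).
#' @param growth expansion factor `N0/N`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("neutral", "subdivision", "expansion"),
                            n = 20, theta = 0.05, L = 1000,
                            M = NULL, T = NULL, growth = 10) {
  kind <- match.arg(kind)
  if (kind == "subdivision" && (is.null(M) || M <= 0))
    stop("subdivision needs a migration rate M > 0")
  if (kind == "expansion" && (is.null(T) || T <= 0 || growth <= 0))
    stop("expansion needs T > 0 and growth > 0")
  structure(list(kind = kind, n = as.integer(n), theta = theta, L = L,
                 M = M, T = T, growth = growth),
            class = "scenario_config")
}

#' Expected spectrum shape of a scenario
#'
#' Mean SFS shape per unit `theta*L` (so that the neutral scenario gives
#' exactly `1/i`). The neutral case is analytic; subdivision and expansion
#' shapes are Monte-Carlo means of per-class branch lengths from the
#' structured/piecewise coalescent genealogy samplers, normalised by the
#' branch-length scale of their neutral limit (`M -> Inf`, respectively
#' `T -> Inf`), so that the neutral limit returns `1/i`. Monte-Carlo standard
#' errors are attached as attribute `"se"`.
#'
#' @param config a [scenario_config].
#' @param genealogies number of sampled genealogies for the Monte-Carlo
#'   scenarios.
#' @param seed optional seed applied via [set.seed()].
#' @return Numeric shape vector of length `n - 1` with attribute `se`.
#' @export
expected_branch_spectrum <- function(config, genealogies = 1e5, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  if (config$kind == "neutral") {
    out <- 1 / seq_len(n - 1L)
    attr(out, "se") <- rep(0, n - 1L)
    return(out)
  }
  if (genealogies < 1e3)
    warning("fewer than 1000 genealogies: shape estimates will be noisy")
  if (config$kind == "subdivision") {
    raw <- sim_subdivision_branch(n, config$M, as.integer(genealogies))
    scale <- 4  # neutral M->Inf limit: total population 2N, branches x2
  } else {
    raw <- sim_expansion_branch(n, 2 * config$T, config$growth,
                                as.integer(genealogies))
    scale <- 2  # branch lengths in 2N units; E[l_i] = 2/i neutrally
  }
  out <- raw[1, ] / scale
  attr(out, "se") <- raw[2, ] / scale
  out
}

#' Poisson replicates of the spectrum
#'
#' Independent-sites sampling: each replicate draws every class count
#' independently from `Poisson(mu_i)`.
#'
#' @param mu mean count vector.
#' @param replicates number of replicates.
#' @param seed optional seed applied via [set.seed()].
#' @return Matrix with `replicates` rows and `length(mu)` columns.
#' @export
sample_sfs <- function(mu, replicates, seed = NULL) {
  if (any(mu < 0)) stop("'mu' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rpois(replicates * length(mu), rep(mu, each = replicates)),
         nrow = replicates)
}

# Evaluate any supported test object on a replicate matrix or spectrum.
evaluate_any <- function(test, x) {
  if (inherits(test, "linear_test")) evaluate_test(test, x)
  else if (inherits(test, "polynomial_test")) evaluate_polynomial(test, x)
  else stop("unsupported test object")
}

#' Empirical critical values under a null configuration
#'
#' Simulates the test statistic under the null scenario and returns the
#' empirical quantiles used as rejection thresholds: the `alpha` and
#' `1 - alpha` quantiles for separate one-tail use, or `alpha/2` and
#' `1 - alpha/2` when `two_tail = TRUE`.
#'
#' @param test a `linear_test` or `polynomial_test`.
#' @param config a null [scenario_config] (its `n`, `theta`, `L` are used).
#' @param alpha significance level.
#' @param replicates number of null replicates (>= 1000).
#' @param seed optional seed.
#' @param two_tail halve `alpha` per tail?
#' @return Named vector `c(lower, upper)`.
#' @export
critical_values <- function(test, config, alpha = 0.05, replicates = 1e5,
                            seed = NULL, two_tail = FALSE) {
  if (replicates < 1e3) stop("need at least 1000 replicates")
  mu <- null_mean_spectrum(config$n, config$theta, config$L)$counts
  X <- sample_sfs(mu, replicates, seed = seed)
  s <- evaluate_any(test, X)
  if (stats::sd(s) == 0)
    warning("degenerate statistic distribution under the null")
  a <- if (two_tail) alpha / 2 else alpha
  q <- stats::quantile(s, c(a, 1 - a), names = FALSE, type = 1)
  c(lower = q[1], upper = q[2])
}

#' Power study over demographic scenarios
#'
#' For each scenario: builds the alternative mean spectrum (by genealogy
#' sampling where needed), draws independent-sites Poisson replicates of the
#' alternative, and reports for each test the fraction of replicates beyond
#' the empirical null threshold of the requested tail(s), with 95% binomial
#' confidence intervals. Thresholds are estimated once per null configuration
#' from `replicates` null replicates; each tail is tested at level `alpha`
#' (the convention of one-tail power at the 5% tail).
#'
#' @param tests named list of `linear_test` / `polynomial_test` objects.
#' @param scenarios list of [scenario_config] objects.
#' @param alpha per-tail significance level.
#' @param replicates Poisson replicates per scenario (and for thresholds).
#' @param genealogies genealogy samples behind each Monte-Carlo shape.
#' @param seed root seed; scenario- and stage-specific seeds are derived
#'   from it deterministically.
#' @param tails named list mapping test names to character vectors from
#'   `c("right", "left")`; defaults to `"right"` for every test.
#' @param shapes optional list of precomputed alternative shape vectors, one
#'   per scenario (e.g. the shapes the optimal tests were built against);
#'   when omitted, shapes are estimated internally.
#' @return A data frame with columns scenario, parameter, test, tail, power,
#'   ci_lo, ci_hi, replicates, seed.
#' @export
power_study <- function(tests, scenarios, alpha = 0.05, replicates = 1e5,
                        genealogies = 2e4, seed = 1, tails = NULL,
                        shapes = NULL) {
  stopifnot(is.list(tests), length(names(tests)) == length(tests))
  if (is.null(tails)) tails <- stats::setNames(
    rep(list("right"), length(tests)), names(tests))
  # thresholds on the shared null configuration
  cfg1 <- scenarios[[1]]
  for (sc in scenarios) {
    if (sc$n != cfg1$n || sc$theta != cfg1$theta || sc$L != cfg1$L)
      stop("all scenarios must share n, theta and L")
  }
  mu0 <- null_mean_spectrum(cfg1$n, cfg1$theta, cfg1$L)$counts
  X0 <- sample_sfs(mu0, replicates, seed = seed)
  thresholds <- lapply(tests, function(tst) {
    s <- evaluate_any(tst, X0)
    stats::quantile(s, c(alpha, 1 - alpha), names = FALSE, type = 1)
  })
  rows <- list()
  for (j in seq_along(scenarios)) {
    sc <- scenarios[[j]]
    par <- switch(sc$kind, neutral = NA_real_, subdivision = sc$M,
                  expansion = sc$T)
    shape <- if (!is.null(shapes)) shapes[[j]] else
      expected_branch_spectrum(sc, genealogies = genealogies,
                               seed = seed + 1000L + j)
    Xa <- sample_sfs(sc$theta * sc$L * shape, replicates,
                     seed = seed + 2000L + j)
    for (nm in names(tests)) {
      s <- evaluate_any(tests[[nm]], Xa)
      for (tail in tails[[nm]]) {
        p <- if (tail == "right") mean(s > thresholds[[nm]][2]) else
          mean(s < thresholds[[nm]][1])
        half <- 1.96 * sqrt(p * (1 - p) / replicates)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$kind, parameter = par, test = nm, tail = tail,
          power = p, ci_lo = max(0, p - half), ci_hi = min(1, p + half),
          replicates = replicates, seed = seed)
      }
    }
  }
  do.call(rbind, rows)
}
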