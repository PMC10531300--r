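# sfstests

Neutrality tests that are linear or polynomial functions of the site
frequency spectrum (SFS), for population geneticists who want to test a
sample of sequences against the standard Wright–Fisher neutral model — or
against a *specific* alternative demographic/selective scenario with close to
maximal power.

For `n` haploid sequences over `L` bases with scaled mutation rate `θ` per
base, the neutral expectation of the unfolded spectrum is `E(ξ_i) = θL/i`. A
linear neutrality test is the normalised contrast of two unbiased `θ`
estimators,

    T_Ω = Σ_i i Ω_i ξ_i / sqrt(Var Σ_j j Ω_j ξ_j),   Σ_i Ω_i = 0,

with zero mean and unit variance under the null. The package provides:

* the **classic test catalogue** (Tajima's *D*, Fay & Wu's *H*, Zeng's *E*,
  Fu & Li's *F*, Fu's *F(r,r′)*, Achaz's bottleneck and admixture tests)
  reconstructed from continuum weight functions `ω(f)` with sample-size
  consistent scalings, so that a test means the same thing at `n = 20` and
  `n = 2000`;
* **optimal linear tests** against an alternative mean spectrum `ξ̄`, in
  their geometric (scalar-product) form, plus the **tunable-λ family**
  `Ω_i(λ)` that contains the maximiser of any optimisation criterion
  `M(E, V)` (mean, one-/two-tail Gaussian power, variance penalties);
* **nonlinear (polynomial) tests** of any degree, strongly centred (robust
  to a wrong plug-in `θ̂`) or weakly centred (more powerful when `θ` is
  known), with closed-form optimal quadratic tests and a renormalised
  version of Fu's *G*, all under the independent-sites Poisson model;
* a **coalescent/Poisson simulator** (two-deme subdivision, stepwise
  expansion; Rcpp genealogy samplers) for expected spectra, empirical
  critical values, type-I-error calibration and power studies;
* SFS TSV and VCF (ancestral-allele aware) ingestion, JSON serialisation of
  weight schemes and tests, and a thin command line
  (`inst/cli/sfstests.R`) with `stats`, `weights`, `optimal`, `simulate`
  and `power` subcommands.

## Worked example

Build the alternative mean spectrum of an island model (two demes, symmetric
migration `M = 1`, all 20 lineages sampled from one deme), draw one
independent-sites data set from it, and test it against neutrality with
`θ = 0.05`/base, `L = 1000`:

```r
library(sfstests)
set.seed(1)
n <- 20; theta <- 0.05; L <- 1000
shape <- expected_branch_spectrum(
  scenario_config("subdivision", M = 1), genealogies = 2e4, seed = 1)
mod  <- moment_model(n, theta, L, as.numeric(shape))
spec <- sfs(sample_sfs(theta * L * as.numeric(shape), 1)[1, ], n = n, L = L)
evaluate_tests(list(
  tajima_d = classic_test("tajima_d", n, theta, L),
  opt1sc = linear_test(optimal_weights(as.numeric(shape)),
                       cov_independent_sites(n, theta, L), "opt1sc"),
  opt2sc = quadratic_sc_optimal(mod),
  opt2wc = quadratic_wc_optimal(mod)), spec)
#>       test statistic
#> 1 tajima_d  3.102214
#> 2   opt1sc  2.040302
#> 3   opt2sc  4.139048
#> 4   opt2wc  4.450089
```

All four statistics are standard normal under neutrality, so this draw (151
segregating sites, skewed toward intermediate/high frequencies) is a clear
rejection — and the optimal quadratic tests built against the true scenario
score it around `4σ` where Tajima's *D* reaches `3.1σ` and the optimal
*linear* test `2.0σ`. Significance thresholds for real analyses come from
`critical_values()` (empirical null quantiles), not from the asymptotic
normal.

The methods vignette (`vignettes/sfs-neutrality-tests.Rmd`) documents the
weight scalings, the undetectable-deviation construction, the optimality
theory (including the maximal-test identities and the λ-family domain), the
moment machinery behind the polynomial tests, and the simulator conventions.

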