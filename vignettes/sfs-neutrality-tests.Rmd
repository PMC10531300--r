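---
title: "Neutrality tests on the site frequency spectrum: models, scalings and optimality"
author: "sfstests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrality tests on the site frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfstests)
```

## The model

For a sample of $n$ haploid sequences from a panmictic Wright–Fisher
population at mutation–drift equilibrium, the unfolded site frequency
spectrum $\xi_i$ (number of segregating sites whose derived allele is carried
by $i$ sequences, $1 \le i \le n-1$) has expectation
$E(\xi_i) = \theta L / i$, where $\theta = 2 p \mu N_e$ is the scaled
mutation rate **per base** and $L$ the sequence length. Without an outgroup
only the folded spectrum $\eta_i$ (minor-allele counts,
$1 \le i \le \lfloor n/2 \rfloor$) is observable, with
$E(\eta_i) = \theta L\, n / (i (n-i) (1 + \delta_{i,n-i}))$.

A linear neutrality test contrasts two unbiased estimators of $\theta$,
$\hat\theta_\omega = \frac1L \sum_i i\,\omega_i\,\xi_i$ with
$\sum_i \omega_i = 1$:
$$
T_\Omega \;=\; \frac{\sum_i i\,\Omega_i\,\xi_i}
                   {\sqrt{\operatorname{Var}\sum_j j\,\Omega_j\,\xi_j}},
\qquad \Omega_i = \omega_i - \omega'_i,\quad \sum_i \Omega_i = 0 ,
$$
so that $E(T_\Omega) = 0$ and $\operatorname{Var}(T_\Omega) = 1$ under the
null model. Tajima's $D$, Fay & Wu's $H$, Zeng's $E$, Fu & Li's $F$, Fu's
$F(r,r')$ and Achaz's bottleneck/admixture tests are all of this form and are
available through `classic_test_weights()` / `classic_test()`.

Throughout, the default second-moment model is the **independent-sites
approximation**: unlinked sites with small per-site $\theta$, under which the
class counts are independent Poisson variables,
$\operatorname{Cov}(\xi_i, \xi_j) = \delta_{ij} \mu_i$ with
$\mu_i = \theta L/i$. This is the regime in which all closed-form results for
the nonlinear tests hold and the regime emulated by the simulator
($\rho = \infty$). A pluggable empirical covariance (`cov_empirical()`)
accommodates linked-sites null distributions estimated from replicates; no
linked-sites formulas are hard-coded.

## Weight scaling with sample size

A test is only interpretable across studies if the weight it gives to a
*population* allele frequency $f$ does not depend on the sample size $n$.
`sfstests` therefore defines tests by continuum weight functions
$\omega(f)$, $f \in (0,1)$, realised as discrete weights by one of three
scalings:

* **centering** (`realise_centering`): $\Omega_i = \Omega(i/n) -$ mean; valid
  for bounded $\Omega$, where the correction is $O(1/n)$;
* **ratio** (`realise_ratio`): each side discretised and renormalised
  separately; the form implicitly used by classic tests and the only valid
  one for weights that diverge like $1/f$ (Watterson), whose normalisation
  otherwise depends on the population-size cutoff $N$. The realised
  Watterson side is $(1/i)/a_n$ with $a_n = \sum_{j<n} 1/j$, and the $N$
  cancellation happens only because that side carries no singleton point
  masses — the catalogue never combines the two;
* **binomial sampling** (`realise_binomial`): $\omega_i \propto \int
  \binom{n}{i} f^i (1-f)^{n-i} \omega(f)\,df$; Dirac components are
  integrated analytically (the admixture test is exact by construction),
  smooth parts by 256-node Gauss–Legendre quadrature (`pracma`), which is
  exact for polynomial weights of degree < 512 and accurate to machine
  precision for the smooth catalogue functions.

For bounded piecewise-continuous weight functions the centering and (suitably
rescaled) ratio forms differ by $O(\Omega)/n$; the test suite verifies the
decay over $n \in \{20, 200, 2000\}$, with a wider slack for schemes with a
step discontinuity, where the discretisation constant wobbles with the
alignment of the step on the grid $i/n$. Singleton point masses
($\Omega_{ds}$, $\Omega_{as}$) are applied directly to classes $1$ and
$n-1$ rather than materialising a frequency cutoff $\phi$; this is exact as
long as $n \ll 2/\phi$.

## Undetectable deviations and optimal tests

No single linear test is generic: for every centred weight vector there is a
spectrum shape, maximally different from neutral (one class empty), on which
the test has expectation zero. `undetectable_deviation()` constructs one
deterministically: it takes an orthonormal basis of the null space of the
constraint $\sum_i i \Omega_i \Delta_i = 0$, picks the basis direction with
the largest angle to $1/i$ (lowest index on ties), flips it to have a
negative entry and mixes it with the neutral shape. Because the mixture is
linear in the mixing parameter within each class, the binding $\alpha$ is the
maximum of per-class closed-form roots; we use that exact expression rather
than a numerical root search. Conversely, $n-2$ linearly independent tests
pin the spectrum down to the neutral direction.

Against a specific alternative with mean shape $\bar\xi$ the optimal linear
test has the geometric form (with $\langle x, y\rangle = x^\top c^{-1} y$):
$$
T_O = \frac{\langle \xi, \bar\xi\rangle -
            \langle \xi, \xi^0\rangle \langle \xi^0, \bar\xi\rangle /
            \langle \xi^0, \xi^0\rangle}
           {\sqrt{\langle \bar\xi, \bar\xi\rangle -
            \langle \xi^0, \bar\xi\rangle^2 / \langle \xi^0, \xi^0\rangle}} ,
$$
zero on the null mean, maximal ($\theta L \sqrt{\cdot}$) on the alternative
mean, and invariant under $\bar\xi \to \bar\xi + c\,\xi^0$. Ill-conditioned
covariances go through an eigenvalue-floored pseudo-inverse (floor
$10^{-12}\times$ the largest eigenvalue), so empirical covariance matrices of
deficient rank are usable.

### Gaussian power and the tunable family

With Gaussian null and alternative distributions, the right-tail power of a
test with count coefficients $w_i = i\,\Omega_i$ at level $\alpha$ is
$$
\mathrm{Power} = \Phi\!\left(
  \frac{\bar\mu^\top w - \tau \sqrt{w^\top c\, w}}{\sqrt{w^\top \bar c\, w}}
  \right), \qquad \tau = \Phi^{-1}(1-\alpha).
$$
The same critical z-value can be written $\tau = \sqrt2\,
\mathrm{erf}^{-1}(1-2\alpha)$; `sfstests` uses the $\Phi$ convention
consistently in `gaussian_power()` and in every optimisation criterion —
mixing the two conventions silently introduces a $\sqrt2$ error on the mean
term, which Monte-Carlo power immediately exposes, so a single convention is
a correctness requirement, not a style choice.

Any criterion $M(E, V)$ in the mean $E$ and variance $V$ of the normalised
test under the alternative (mean maximisation, one- or two-tail Gaussian
power, variance penalisation) is maximised inside the one-parameter family
$$
\Omega_i(\lambda) = \frac1i\left(1 -
  \frac{a_n}{(1 + \lambda i \bar\xi_i)\sum_j \frac{1}{j (1+\lambda j \bar\xi_j)}}
  \right),
$$
whose $\lambda \to 0^+$ direction is the usual optimal weight vector
$\bar\xi_i - (1/i)\sum_j \bar\xi_j / a_n$. The natural domain of the family
is $1 + \lambda i \bar\xi_i > 0$, i.e. $\lambda > -1/\max_i(i\bar\xi_i)$:
criteria that penalise the alternative variance relative to the mean attain
their maximum at negative $\lambda$, so `optimise_tunable()` scans a
logarithmic grid on both branches, refines every local maximum by
golden-section search and reports all of them (the criterion surface can
carry several, and the maximiser can move abruptly with the scenario).
One boundary is worth stating: if the alternative is so weak that even the
optimal expectation lies below $\tau$, the one-tail-power criterion rewards
*large* variance and its maximiser is no longer an interior stationary
point of the weight space — it then escapes the family. This is the same
degenerate corner as the $\tau \gg 1$ variance-ratio regime and is of no
practical interest; the test suite restricts its brute-force comparisons to
detectable alternatives, where the family matches full weight-space
maximisation to machine precision.

## Nonlinear tests

Polynomial tests generalise the linear form to
$T = (\gamma + \sum_I c_I\, \xi_{i_1}\cdots\xi_{i_{|I|}}) / \sqrt{\mathrm{Var}}$
over multisets $I$ of class indices. Because their weights depend on
$\theta$, a plug-in $\hat\theta$ enters, and two classes arise:

* **strongly centred** — zero null mean for *any* plug-in value (the
  centring conditions hold order-by-order in $\theta L$); robust, the class
  containing all linear tests and the renormalised Fu's $G$ analogue
  `quadratic_sc_optimal()`;
* **weakly centred** — centred only when $\hat\theta = \theta$; a strictly
  larger class, hence at least as powerful, but sensitive to biased
  $\theta$ estimates (`linear_wc_optimal()`, `quadratic_wc_optimal()`).

Under independent sites the moments of any monomial follow from products of
raw Poisson moments (Touchard polynomials; `poisson_moment()`), and the
optimal weights of any degree $d$ are solutions of linear systems over the
ordered multisets up to size $d$ (`general_optimal()`, with a configurable
cap on the number of multisets). For degree 2 the closed forms implemented in
`quadratic_sc_optimal()` / `quadratic_wc_optimal()` agree with the general
construction to $10^{-6}$ and satisfy the maximal-test identity
$\operatorname{Var}_0(\text{unnormalised}) = E_{\mathrm{alt}}(\text{unnormalised})$
to machine precision, which also fixes the normalised maxima as
$\sqrt{(\bar\mu - \mu)^\top c^{-1} (\bar\mu - \mu)}$ (weak, degree 1) and its
projected strongly centred counterpart — the weak maximum always dominates.
Replacing the monomial covariance by raw second moments leaves strongly
centred optima exactly unchanged (the rank-one difference $\mu\mu^\top$ lies
in the span of the centring constraints); for weakly centred tests it changes
the test, so the shortcut is refused there. The denominator of every
polynomial test is computed under the Poisson model at the plugged-in
$\hat\theta$ (known $\theta$ or the Watterson estimate,
`theta_watterson()`); this convention is documented rather than prescribed by
theory.

The renormalised Fu's $G$, $T_G = (Q - (n-1))/\sqrt{\operatorname{Var} Q}$
with $Q$ the Hotelling-type quadratic form, is exposed by `fu_g_test()`; it
is an affine map of the diagonal $G_\xi$ statistic, so its power at matched
thresholds is identical.

## The simulator and what the power study shows

`expected_branch_spectrum()` produces alternative mean shapes per unit
$\theta L$ from genealogy samplers written in C++:

* **subdivision** — two demes of equal size, symmetric scaled migration $M$
  (interpreted as $4Nm$; per-lineage rate $M/2$, within-deme pair coalescence
  rate 1 on the $2N$ time scale), all $n$ lineages sampled from one deme.
  Shapes are normalised by the $M \to \infty$ branch-length scale so that the
  strong-migration limit returns exactly $1/i$.
* **expansion** — a stepwise size change by $N_0/N = 10$ at time $T$ (in
  units of $4N$ generations) before present. Sizes are referred to the
  present population: the recent epoch coalesces at rate 1 and the ancestral
  epoch 10 times faster, so $T \to \infty$ recovers neutrality exactly and
  the distortion (excess rare variants, deficit of segregating sites at fixed
  $\theta$) is maximal at intermediate $T$. This matches the standard
  ms-style convention; the migration-rate and time-unit conventions only
  shift the parameter axis, not the qualitative power trends that are
  asserted.

Study conditions follow the simulation design the package reproduces at desk
scale: $n = 20$, $\theta = 0.05$ per base, $L = 1000$, free recombination.
Data replicates are independent Poisson draws per class
(`sample_sfs()`), critical values are empirical quantiles of $10^5$ null
replicates (the original study used $10^6$; at $10^5$ the binomial CI
half-width on a 5% tail is about $0.003$, adequate for ordering and
calibration claims while keeping the default suite within minutes), and
power is the fraction of alternative replicates beyond the matching null
threshold. Optimal tests are evaluated on their right tail (they are built to
be maximal under their alternative); Tajima's $D$ on both tails separately.
Thresholds used in the calibration checks are estimated from $2\times10^5$
null replicates and applied to $10^5$ fresh ones, so that quantile noise does
not consume the $\pm 3\,\mathrm{SE}$ calibration band.

The power study reproduces, at these conditions, the qualitative findings:
weakly centred optimal tests (degree 1 and 2, nearly indistinguishable)
dominate, strongly centred quadratic beats strongly centred linear, all
optimal tests beat Tajima's $D$, and every power decays toward $\alpha$ as
$M$ or $T$ grows. What passing these checks does **not** show: behaviour
under linkage ($\rho < \infty$), real sampling noise in $\hat\theta$ for the
weakly centred tests (the study conditions assume $\theta$ known — the best
case), sequencing error, or demographic scenarios outside the two families.

```{r example}
# a worked example at the study conditions
set.seed(1)
n <- 20; theta <- 0.05; L <- 1000
shape <- expected_branch_spectrum(
  scenario_config("subdivision", M = 1), genealogies = 2e4, seed = 1)
mod <- moment_model(n, theta, L, as.numeric(shape))
spec <- sfs(sample_sfs(theta * L * as.numeric(shape), 1)[1, ], n = n, L = L)
evaluate_tests(list(
  tajima_d = classic_test("tajima_d", n, theta, L),
  opt1sc = linear_test(optimal_weights(as.numeric(shape)),
                       cov_independent_sites(n, theta, L), "opt1sc"),
  opt2sc = quadratic_sc_optimal(mod),
  opt2wc = quadratic_wc_optimal(mod)), spec)
```

## Numerical choices and limitations

* Normalisation and centredness checks use a relative tolerance of
  $10^{-9}$; the sums involved are short and well conditioned.
* Pseudo-inverse floor: $10^{-12} \times$ largest eigenvalue.
* The $\lambda$ grid is 200 log-spaced points per branch over
  $[10^{-4}, 10^4]$ (positive) and the mirrored fill of the admissible
  negative range, plus the analytic $0^+$ limit.
* Counts are stored as reals so expected and observed spectra share one
  type; `integral = TRUE` validates whole-number counts on request.
* $\theta$ is reported per base everywhere; the command-line `stats` tool
  offers a per-sequence display toggle since much of the literature quotes
  per-locus values.
* Folded variants reuse the same machinery with folded shapes and moments;
  missing-data projection of the SFS and diploid genotype subtleties beyond
  allele counting are out of scope.
* `fu_f` weights with exponent above 1 are refused rather than guessing the
  $n^{1-k}$ normalisation of a divergent weight function.
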