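Package: sfstests
Title: Linear and Nonlinear Neutrality Tests Based on the Site Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of neutrality tests that are linear or
    polynomial functions of the site frequency spectrum (SFS). Classic tests
    (Tajima's D, Fay and Wu's H, Zeng's E, Fu and Li's F, Fu's F(r,r'), Achaz's
    bottleneck and admixture tests) are reconstructed from continuum weight
    functions with sample-size-consistent scalings, so that the interpretation
    of a test does not depend on the sample size. Optimal linear tests against a
    specified alternative mean spectrum are provided in their geometric form,
    together with a one-parameter tunable family that contains the maximiser of
    any optimisation criterion based on the mean and variance of the test under
    the alternative. Nonlinear (polynomial) tests of arbitrary degree are
    supported in both strongly and weakly centred form, including explicit
    optimal quadratic tests under the independent-sites Poisson model. A
    structured-coalescent simulator generates expected spectra for island-model
    subdivision and stepwise population expansion, and Poisson sampling of
    unlinked sites drives empirical critical values, type-I-error calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
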