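Package: broodskew
Title: Offspring Sex-Ratio Analysis for Long-Term Raptor Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for detecting and explaining deviations from
    parity in nestling sex ratios recorded by long-term territorial monitoring
    programmes, motivated by mainland and island populations of the Egyptian
    vulture (Neophron percnopterus) in Spain. Provides finite-pool Monte Carlo
    parity tests with an exact hypergeometric oracle, exact two-sided binomial
    tests on brood sex combinations and on same-sex run prevalence in per-unit
    offspring sequences, latent-scale repeatability of a binary trait with a
    parametric bootstrap, AICc-based selection and full model averaging over
    additive logistic mixed-model candidate sets, Bonferroni post hoc contrasts,
    variance-inflation diagnostics, Gaussian models for annual-ratio density and
    population-trend effects, and a synthetic-data generator that emulates the
    monitoring design for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
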