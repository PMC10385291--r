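---
title: "Methods: sex-ratio parity testing, repeatability and AICc selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-ratio parity testing, repeatability and AICc selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodskew)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The scientific setting

Long-term monitoring of Egyptian vulture territories in Spain yields one row
per sexed nestling: region (four mainland nuclei, two island groups),
territory, year, brood size (1 or 2), hatching order and date, breeding-unit
type (pair or trio), parental identities and ages. The analysis questions
are (i) whether any population's secondary sex ratio departs from 1:1,
(ii) whether double broods are skewed toward particular sex combinations,
(iii) whether individual breeding units systematically over-produce one sex,
and (iv) which individual and environmental covariates explain the
probability that a nestling is male. Food availability enters through the
three regulatory stages of the "mad-cow" crisis — carcass disposal was
unrestricted through 2001, curtailed in 2002–2011, and relaxed from 2012 —
encoded by `assign_madcow_period()` as a pure function of year with
inclusive calendar boundaries.

## Finite-pool parity testing

`mc_parity_test()` draws, in each of `n_sims = 1000` randomisations, `n`
individuals **without replacement** from a conceptual pool of
`pool_size = 3000` nestlings at exactly 1:1 and records the male proportion.
The male count per draw is `Hypergeometric(3000, 1500, n)`, so the null is
narrower than the binomial one, markedly so when `n` approaches the pool
size (at `n = 3000` the draw is exhaustive and the ratio is exactly 0.5).
The without-replacement reading is not cosmetic: at `n = 1112` the
hypergeometric 95% interval rounds to 0.48–0.52 while a binomial null would
give 0.47–0.53, and only the former matches the intervals the regional
counts are evaluated against. `exact_parity_interval()` encodes this null
deterministically: the lower bound is the largest male count whose lower
tail is ≤ α/2, the upper bound the smallest whose upper tail is ≤ α/2, so
the interval always carries ≥ 1−α mass.

Numerical conventions, chosen once:

* The simulated interval is the pair of order statistics at ranks
  `floor(0.025·n_sims)` and `ceiling(0.975·n_sims) + 1` — the 25th and 976th
  of 1000 sorted ratios.
* Tail probabilities are inclusive (`≥` / `≤`), and a doubled two-sided
  summary `min(1, 2·min(p_ge, p_le))` is reported alongside; the
  significance flag, however, is interval exclusion, matching how the
  regional table marks ratios in bold.
* Ratios are kept at full precision internally and rounded to 2 dp only for
  printing.

One caveat surfaced by the exact oracle: at the smallest stratum (`n = 50`)
the 97.5% bound rounds to 0.64, not the 0.62 that a single 1000-draw
randomisation can occasionally produce — the order statistic at `n = 50`
falls on 31/50 vs 32/50 with roughly a 1:8 frequency. The package reports
the oracle-consistent value.

## Exact binomial tests

`binom_two_sided()` doubles the smaller tail and caps at 1. Under the
symmetric null `p = 0.5` — the only null used here — this coincides with the
minimum-likelihood two-sided rule, so there is no rule ambiguity to resolve;
the equivalence is verified against exhaustive enumeration for all `n ≤ 12`
in the test suite. Double broods are classified by `pair_double_broods()`
into `mm/ff/mf/fm` with the first-hatched sex first; broods missing a
nestling, a sex, or the hatching order are excluded and counted, never
imputed. "Single-sex" means `{mm, ff}` and "mixed" `{mf, fm}` regardless of
order. Pooled strata (Peninsular, Islands, All) are sums of their region
strata; the accounting identity `classified + excluded = double broods` is
asserted on generated data.

## Sex sequences and run bias

`build_sequences()` orders each unit's offspring by year, then by hatching
order within year (singles and first-hatched before second-hatched; if the
order is unknown the input order is kept). Gap years do not break a run:
the offspring sequence, not the calendar, is treated as consecutive, which
is the reading under which a trio sampled over nine seasons can accumulate a
nine-male run. A unit qualifying for both a ≥4-male and a ≥4-female run
counts in both tallies of `run_bias_test()`; the data that motivated the
test (11 male-run vs 3 female-run females, `p = 0.0574`) are unaffected by
this choice, but it must be fixed for the test to be well defined.
Identities: a "female" unit is the mother's identity; pair and trio units
are the parent combination restricted to the corresponding breeding-unit
type.

## Repeatability of a binary trait

The model is `y_ij ~ Bernoulli(logit⁻¹(μ + u_i))`, `u_i ~ N(0, σ²)`, fitted
by maximum likelihood in `fit_binary_intercept_model()`. The per-group
marginal likelihood is a one-dimensional integral evaluated by fixed-order
Gauss–Hermite quadrature (default 20 nodes, minimum 15); the optimiser works
on `(μ, log σ)` with σ floored at 1e-10, so the variance cannot go negative,
and stops when successive objective values agree to ~1e-8. The quadrature
log-likelihood is checked against adaptive per-group integration (agreement
to 1e-4) and against an independent adaptive-quadrature mixed-model fit in
the test suite.

Repeatability is reported on the **latent (link) scale**,
`r = σ² / (σ² + π²/3)`, the standard definition for binary traits, with the
logistic residual variance `π²/3`. For near-zero variance components the
latent- and original-scale versions are indistinguishable in practice, so
this choice cannot be discriminated by data with `r ≈ 0`; it is simply the
convention adopted. Only an intercept enters the fixed part: repeatability
of the raw probability is wanted, not a covariate-adjusted one.
Uncertainty comes from a parametric bootstrap (`rpt_binary()`): datasets are
simulated from the fitted model on the observed group structure, refitted,
and the SD and 2.5%/97.5% percentiles of the replicate `r` values reported.
The CI is truncated at 0 by construction; a run in which more than 10% of
refits fail aborts with diagnostics rather than returning a silently
unstable interval.

## AICc selection, weights, averaging

Candidate sets are **all additive subsets** of each scale's variable pool
(no interactions), always including the null model: insularity, region,
mad-cow period, brood size, hatching order and hatching date at the full
scale; region replaces insularity at the peninsular scale; breeding unit
joins at the Canary scale; the Balearic pool is brood size and period only
(no phenology data exist there). Two exclusions keep designs full-rank:
`region` and `insularity` never co-occur (insularity is a function of
region), and `brood_size` and `order` never co-occur (the two-nestling dummy
is exactly the sum of the first- and second-hatched dummies).

Each candidate is a binomial-logit mixed model with crossed Gaussian random
intercepts for year and territory, fitted by Laplace-approximated ML
(`lme4::glmer`); parental-age analyses instead use the age-holder's identity
as the random factor, and age is offered raw and under two categorical
codings (`<6 / 6–15 / >15` and `≤7 / ≥8`). All candidates of a scale are fit
on one dataset — listwise deletion over the union of the scale's variables —
so their AICc values are comparable. Boundary ("singular") variance
estimates are legitimate fits, not convergence failures; genuinely
non-converged models are dropped from the set before ranking. The parameter
count `k` is intercept + fixed effects + variance components (e.g. df 5 for
insularity + brood size with two random terms), which matches the
`logLik` degrees of freedom of the fitted objects.

Model averaging uses the models with `ΔAICc < 2`, weights renormalised
within that set. The default is **full (zero-substitution)** averaging — a
term absent from a model contributes 0 with SE 0 — because it shrinks
weakly supported effects toward zero and is the conservative choice;
conditional averaging is available behind a flag. The unconditional SE is
`Σ wᵢ √(seᵢ² + (bᵢ − b̄)²)`. The verbal support rule is operationalised as:
*strong* = 95% CI excludes 0; *weak* = CI covers 0 but `|estimate| > SE`;
*none* otherwise. Hatching date is centred and scaled per dataset before
fitting (for conditioning) and its coefficient also reported per day.

Post hoc comparisons are pairwise Wald contrasts with p-values multiplied by
the number of pairs (capped at 1); collinearity among continuous covariates
is checked with `VIF = 1/(1−R²)`, infinite under aliasing. Annual-scale
models (`annual_ratio_glm()`) are Gaussian GLMs of the yearly male
proportion on conspecific density (breeding pairs) or on the population
trend `pairs(t) − pairs(t−k)` for lags 1–7 (spanning the typical age at
first breeding), compared by AICc on the common years; a predictor whose
model sits more than 2 AICc above the best is labelled unsupported.

## The synthetic-data generator

`simulate_records()` emulates the monitoring design: six regions with
configurable territory counts, years 1995–2021, annual occupancy 0.7, one
brood per unit-year (the species raises a single annual clutch), trio
probability 0.05 (a placeholder — per-region trio frequencies are not
published), two-nestling broods with probability 0.31 (391 of ~1270
observed broods were doubles), hatching dates uniform over a 60-day spring
window (only the covariate's slope matters to the analyses, so no richer
phenology is modelled), and female identities persisting across years with
10% annual turnover. Sexes are Bernoulli draws from a logistic linear
predictor with effects for insularity, the two later food-availability
periods, hatching order, brood size and scaled hatching date, plus Gaussian
random intercepts for year, territory and breeding-female identity
(pairs/trios inherit the female's effect, the common denominator of the
unit-level analyses). Default effect sizes are anchored to the published
percentages — mainland 47.5% males, Canary 55.1%, and 47.8% / 46.6% / 53.3%
across the three periods — and the default identity SD is 0, consistent
with the near-zero repeatability observed in the field data.

`simulate_study()` fixes the per-region sample sizes (268, 237, 425, 182,
499, 50), double-brood counts and study windows to the published design,
draws sexes at the published regional proportions (or from a two-level
insularity model with a user-chosen true effect, for recovery experiments),
and leaves Balearic hatching dates and orders missing, as in the source
data.

What the generator does **not** emulate: brood reduction and mortality
(analyses concern sexed, banded nestlings only), density dependence,
spatial autocorrelation among territories, observer effort gradients, and
any covariance between covariates (e.g. phenology shifting across periods).
Passing parameter-recovery tests on these data therefore demonstrates the
correctness of the estimators under the stated model, not robustness to
real-data pathologies.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen to balance power against
runtime: variance-component recovery uses 200 groups × 20 observations
(n = 4000); island-effect recovery uses 20 replicates of the 1661-nestling
study-scale dataset; the parity null's super-uniformity uses 400 replicates
of 500-draw randomisations; run-detection is verified exhaustively over all
2¹–2¹² sex strings. Bootstrap examples use 60–200 replicates; for published
inference 1000 (the default) is recommended.

## Known limitations

* No REML, interactions, random slopes or spatial structures; the candidate
  grammar is additive by design.
* The repeatability fitter handles one grouping factor; multi-factor or
  covariate-adjusted repeatability is out of scope.
* Exact binomial tests are reported without mid-p or CI variants.
* Model-set inference inherits lme4's Laplace approximation; for sparse
  random-effect designs the quadrature route of the repeatability module is
  the more accurate reference.
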