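---
title: "Random-parameters logit models for seasonal crash injury severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-parameters logit models for seasonal crash injury severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmlogit)
```

## The model

A casualty $m$ in a motorcycle crash sustains one of three injury severities
$k \in \{\mathrm{MI}, \mathrm{SI}, \mathrm{FI}\}$ (minor, severe, fatal),
treated as unordered alternatives of a discrete-choice problem. Each
severity has a linear utility

$$Y_{km} = \beta_k X_{km} + \varepsilon_{km},$$

with binary indicator covariates $X_{km}$ (crash characteristics, human
factors, roadway features, temporal aspects) and i.i.d. standard Gumbel
errors, which yields multinomial-logit probabilities. One severity level is
the reference with utility normalised to zero (the usual location
normalisation; `MI` by default).

Coefficients that plausibly vary across casualties are declared *random*:

$$\beta_{km} = \beta_k + \delta_{km} Z_{km} +
  \sigma_{km}\, e^{\omega_{km} W_{km}}\, v_{km}, \qquad v_{km} \sim N(0,1),$$

so the coefficient's mean shifts with covariates $Z$ (heterogeneity in
means, coefficients $\delta$) and its standard deviation scales
multiplicatively with covariates $W$ (heterogeneity in variances,
coefficients $\omega$). With empty $Z$ and $W$ this is the ordinary
normally-mixed random parameter; with all coefficients fixed the model
collapses exactly to the MNL. The unconditional choice probability is the
logit kernel integrated over the mixing distribution; the package
approximates it by averaging the kernel over quasi-random draws:

$$P_m(k) \approx \frac{1}{R} \sum_{r=1}^{R}
  \frac{e^{\beta^{(r)}_k X_{km}}}{\sum_{k'} e^{\beta^{(r)}_{k'} X_{k'm}}}.$$

Only the normal mixing distribution is implemented; it is the standard
choice in injury-severity work and the architecture leaves room for
others.

## Halton draws

The mixing integral is simulated with Halton sequences: the radical-inverse
sequence in a prime base (one consecutive prime per random dimension),
mapped through $\Phi^{-1}$. Defaults are $R = 1000$ draws per observation —
the convention in the applied literature this package serves — with a
burn-in of 100 points (at least one point must be discarded so no point
maps to $\pm\infty$), and draws allocated to observations in row-major
blocks. The construction is deterministic, which makes every fit
bit-reproducible; tests use $R$ between 25 and 500 since the toy problems
are small. Halton points cover the unit interval far more evenly than
pseudo-random numbers (their star discrepancy is an order of magnitude
smaller at $n = 1000$), which is why a few hundred draws suffice where
plain Monte Carlo would need thousands.

## Estimation

`mixl_fit()` maximises the simulated log-likelihood by BFGS using the
analytic score of the simulated probability (the mixed-logit score formula,
chained through the mean-shift and variance-scale parameters). An analytic
gradient rather than finite differences keeps a full fit of $n = 4000$
observations at $R = 500$ draws in the tens of seconds on one core, and the
C++ kernel evaluates likelihood and score in a single pass over draws.
Numerical safeguards and conventions:

* **Softmax stability.** All logit kernels subtract the row maximum before
  exponentiating, so utilities of $\pm$ hundreds do not overflow.
* **Starting values.** Means start at the fixed-parameter MNL solution of
  the same utility structure (fitted internally), $\delta$ and $\omega$
  at 0, and $\sigma$ at 0.5. The simulated likelihood is locally flat in
  $\sigma$ at 0 (it is an even function of $\sigma$ there), so a start away
  from the origin avoids stalling on that degenerate stationary point.
* **Convergence.** BFGS runs with a relative function tolerance of
  $10^{-8}$; if the terminal score norm exceeds 0.05 the optimiser is
  restarted once from the terminal point. The convergence flag additionally
  requires a small per-observation score norm.
* **Sign normalisation.** A normal random coefficient is invariant under a
  sign flip of $\sigma$, so $|\sigma|$ is reported.
* **Standard errors.** Inverse of the numerical Hessian (central
  differences of the analytic score). When that matrix is not positive
  definite the BHHH outer product of per-observation scores is used
  instead, and the fit records which method produced the errors.
  Coefficients are screened at the 90% level ($|z| \ge 1.645$), the
  customary threshold in this literature.
* **Log-likelihood at zero.** Two conventions exist: the equal-shares value
  $N\ln(1/J)$ (all parameters zero; the default) and the constants-only
  value $\sum_k n_k \ln(n_k/N)$. Published tables do not always say which
  convention they used, so `ll_zero()` exposes both and the fit records its
  choice.

## Fit statistics and summaries

`FitResult` objects carry $K$, $N$, $LL(0)$, $LL(\mathrm{convergence})$,
$\mathrm{AIC} = 2K - 2LL$, and McFadden's $\rho^2 = 1 - LL/LL(0)$.

Average marginal effects for a binary covariate are computed as the
full-sample counterfactual contrast: predicted probabilities with the
indicator forced to 1 for every record, minus the same with it forced to 0,
averaged over all observations. Reading the average over the full sample
(rather than the subgroup actually observed at 1 or 0) is a deliberate
choice — it answers "what would switching this factor do across the
population of casualties" — and subgroup averaging can be had by passing a
subset as `data`. For random coefficients both counterfactuals reuse the
same Halton array (common random numbers), so simulation noise cancels in
the difference and the effects sum to zero across the three severities to
high accuracy.

For a significant random coefficient, `share_positive(mean, sd)` =
$\Phi(\text{mean}/\text{sd})$ reports the share of casualties whose
realized coefficient is positive — the usual population-level reading of a
normally distributed effect.

## Seasonal partition and stability tests

Records are split into a rainy season (May 1 – November 30) and a dry
season (December 1 – April 30) by calendar month; a non-leap year has
exactly 214 rainy days. A dry season straddles the New Year; records keep
the calendar year of the crash date as their year label, which is the
convention implied by per-calendar-year reporting (the alternative —
labelling December by the following year's season — is not used here and
would change cell counts).

`chi_square_independence()` applies the Pearson test without continuity
correction to season-by-severity tables and reports the confidence level
numerically and as the conventional bracket (">95 %", ">99.99 %", ...).

Transferability and temporal stability between two fitted models use the
likelihood-ratio construction

$$\chi^2 = -2\,[\,LL_{t}(\hat\beta_{s}) - LL_{t}(\hat\beta_{t})\,],
  \qquad df = K,$$

with both log-likelihoods evaluated **on the same target dataset** — the
source model's converged parameters against the natively fitted model.
(The prose definitions in the applied literature sometimes read as if the
two likelihoods were evaluated on different datasets; that cannot yield a
nonnegative statistic and is read here as notational slippage. The
degrees of freedom conventionally attached to these tests match the
same-dataset construction.) `pairwise_test_matrix()` runs all ordered pairs
in both directions, mirroring the reversed-test protocol.

One calibration caveat is worth stating precisely: because the source
parameters are themselves estimates, the statistic is approximately
$(1 + n_t/n_s)\,\chi^2_K$ under equal parameters, not $\chi^2_K$. The
$\chi^2_K$ reference is therefore accurate when the source sample is much
larger than the target and anticonservative for equal splits. The package's
null-calibration study accordingly simulates a 10:1 source:target split
(2000 vs 200 records, $R = 50$, 100 replications), where the empirical
size at the 95% level stays in the low single digits. Applied users
comparing similarly sized seasons should treat borderline confidence
levels with caution; the published applications of this test report
statistics so far in the tail (>99.99%) that the distinction is
immaterial there.

## The synthetic-data generator

Real casualty registries of this kind are confidential, so the package
ships a seeded generator that emulates the *published* structure of such
data: the marginal prevalences of each indicator (the packaged default
reproduces a 2015 rainy-season column of descriptive statistics),
mutually exclusive indicator blocks drawn as single categorical draws
(guaranteeing exclusivity; exhaustive blocks like rider/pillion, sex, age
bands always set exactly one indicator), and independent Bernoulli draws
for the free indicators. Severities are then generated from a declared
RPL-HMV truth by Gumbel-max sampling — add i.i.d. Gumbel noise to the
realized utilities and take the argmax — which is exactly equivalent to
inverse-CDF sampling from the conditional logit probabilities and extends
unchanged to random coefficients.

Two honest limitations. First, blocks are sampled independently of one
another because only marginals are public; real data correlate speeding
with age and sex, road class with area, and so on. A user with access to a
joint structure can supply covariates directly to `simulate_outcomes()`.
Second, the three-level outcome is generated from the model family being
estimated, so recovery tests demonstrate the estimator's correctness, not
the model's adequacy for real crashes. Passing tests show the machinery is
right; they cannot show that a normal-mixing logit describes any
particular registry.

A note on the published descriptive table the default scheme mirrors: its
dispersion column is labelled as a standard deviation but numerically
equals $p(1-p)$, the Bernoulli *variance* (e.g. prevalence 0.444 ↦ 0.247).
The generator's tests check the variance identity and leave the label
discrepancy to this note. The printed age-band shares sum to 0.999;
exhaustive-block probabilities are renormalised to sum exactly to one.

## Validation study sizes

The test suite validates the full pipeline at sizes chosen to exercise the
asymptotics without waste: exact brute-force equivalence on 5–10-record
toys; $\sigma \to 0$ degeneracy to $10^{-10}$ on 200 records; MNL
cross-checks against an independent multinomial fitter at $n = 3000$;
parameter recovery for the heterogeneity-in-means-and-variances DGP at
$n = 4000$, $R = 500$ over 20 seeded replications (truth inside the 95%
Wald interval at least 17 of 20 times per parameter); and the LR-test
size study described above. In the recovery design the random coefficient
sits on a moderate-prevalence indicator (0.44) with mean and variance
shifters of prevalence 0.41 and 0.67 — random-coefficient parameters are
weakly identified when few records carry the indicator, and a design with
a rare indicator would test patience rather than correctness.

## Known limitations

* No panel/repeated-measures correlation across casualties of one crash;
  each record is independent.
* Random coefficients are mutually independent (no correlated mixing), and
  only normal mixing is implemented.
* Marginal effects carry no standard errors (the applied convention this
  package follows reports point effects only).
* Simulated ML at finite $R$ carries the usual small quasi-Monte-Carlo
  bias; at the default $R = 1000$ it is negligible relative to sampling
  error at registry-scale $n$.
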