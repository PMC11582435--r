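# rpmlogit

Random-parameters (mixed) multinomial logit models for casualty-level crash
injury severity, with heterogeneity in both the means and the variances of
the random coefficients, estimated by simulated maximum likelihood with
Halton draws.

The package is aimed at road-safety and injury-epidemiology analysts who
model three-level severity outcomes — minor (MI), severe (SI), fatal (FI) —
from police-report registries, and who need the surrounding workflow as
well as the estimator: seasonal partitioning of records, chi-square
seasonality tests, average marginal effects, random-parameter
distributional summaries, and pairwise likelihood-ratio transferability /
temporal-stability tests between fitted models. Because such registries
are typically confidential, a seeded synthetic-data generator reproducing
their published marginal structure is a first-class component, so the
whole pipeline is testable end to end without any restricted data.

## The model

Severity $k$ for casualty $m$ has utility $Y_{km} = \beta_k X_{km} +
\varepsilon_{km}$ with i.i.d. Gumbel errors (multinomial logit). Selected
coefficients vary across casualties:

$$\beta_{km} = \beta_k + \delta_{km} Z_{km} + \sigma_{km}
  \, e^{\omega_{km} W_{km}} \, v_{km}, \qquad v_{km} \sim N(0,1),$$

where $Z$ shifts the coefficient's mean (heterogeneity in means, via
$\delta$) and $W$ scales its standard deviation (heterogeneity in
variances, via $\omega$). Choice probabilities integrate the logit kernel
over the mixing distribution; the integral is simulated with $R$
standard-normal Halton draws (default $R = 1000$) and the simulated
log-likelihood is maximised by BFGS with an analytic score (C++ kernel).
Transferability between datasets $s$ (source) and $t$ (target) is tested
with $\chi^2 = -2[LL_t(\hat\beta_s) - LL_t(\hat\beta_t)]$ on $K$ degrees
of freedom.

See the vignette `vignettes/seasonal-severity-mixed-logit.Rmd` for the
estimation details, numerical conventions and validation design.

## Worked example

Generate a six-cell (three years x two seasons) synthetic study from the
packaged default covariate scheme and data-generating process, fit the
mixed logit to one cell, and summarise:

```r
library(rpmlogit)

dgp   <- default_dgp()
study <- generate_study(default_scheme(), dgp, study_counts(), seed = 1)
ds    <- study$datasets[["2015 rainy"]]
ds
#> crash_dataset '2015 rainy' : N = 3223 casualties
#>   severity:  MI=1101, SI=973, FI=1149
#>   covariates: 34 binary indicators

fit <- mixl_fit(ds, dgp$spec, R = 200)
summary(fit)
#> Mixed multinomial logit fit (2015 rainy)
#>   N = 3223  K = 12  R = 200 draws
#>   LL(0) = -3540.827  LL(convergence) = -3268.573
#>   AIC = 6561.146  McFadden rho2 = 0.077
#>                                 Estimate  Std.Err       z
#> [SI] constant                   -0.51368  0.08005  -6.417
#> [SI] hit_pedestrian              0.90248  0.11029   8.183
#> [SI] rider                       0.37750  0.09258   4.078
#> [SI] helmet                     -0.24718  0.12073  -2.047
#> [FI] constant                   -1.37847  0.11281 -12.220
#> [FI] hit_pedestrian              1.38128  0.12269  11.259
#> [FI] rider                       1.11697  0.11596   9.632
#> [FI] helmet                     -0.88277  0.15098  -5.847
#> [FI] speeding (mean)             0.46302  0.22966   2.016
#> [FI] speeding : male (het.mean)  1.09256  0.26613   4.105
#> [FI] speeding (sd)               0.42145  1.23204   0.342
#> [FI] speeding : rider (het.sd)   1.44626  2.87661   0.503
```

The coefficient block reads like the standard results tables of this
literature: `[FI] speeding (mean)` is the mean effect of speeding on the
fatal-injury utility, the `het.mean` row says the mean is substantially
higher for male casualties, and the `(sd)` / `het.sd` rows describe the
spread of the effect across casualties (here insignificant — the true
generating values are recovered within sampling error).

Marginal effects are full-sample counterfactual contrasts (switch the
indicator 0 to 1 for everyone, difference the average predicted
probabilities); each row sums to zero by probability conservation:

```r
marginal_effects(fit, covariates = c("hit_pedestrian", "speeding", "helmet"))
#> Average marginal effects (N = 3223 )
#>       covariate      MI      SI      FI
#>  hit_pedestrian -0.2116  0.0395  0.1721
#>        speeding -0.1349 -0.1267  0.2616
#>          helmet  0.1066  0.0203 -0.1268
```

So hitting a pedestrian raises a casualty's fatal-injury probability by
about 17 percentage points, and helmet use lowers it by about 13.
`share_positive(mean, sd)` summarises a random coefficient's
distribution: the share of casualties with a positive realized effect.

Season-by-severity tables and the seasonality chi-square test:

```r
tab <- build_contingency(study$datasets[c("2015 rainy", "2015 dry")])
chi_square_independence(tab)
#> 0.126 (2) [n.s.]
```

(Insignificant here by construction: the synthetic default generates both
seasons from one common process. On real registry counts the same
function reproduces the published seasonal statistics, e.g. 6.210 (2)
[>95 %] for the 2015 table.)

A command-line front end over the same functions lives at
`inst/cli/rpmlogit.R` with `simulate`, `fit`, `effects`, `chi2` and
`transfer` subcommands driven by YAML configs
(see `inst/extdata/example_run.yaml`).

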