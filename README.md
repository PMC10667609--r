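# medakaIPM

Scaling laboratory life-history measurements to population fitness in a
small fish. The package implements the full inference chain for a 2×2
temperature × feeding-frequency experiment on medaka (*Oryzias latipes*):

1. **Hierarchical Bayesian growth** — Von Bertalanffy curves
   *L(t) = L<sub>∞</sub>(1 − e<sup>−K(t − t₀)</sup>)* fitted per treatment
   with correlated tank-level random effects
   ε ~ MVN(0, Σ), vague Normal(0, precision 0.001) priors on the
   treatment-level parameters, Uniform priors on the components of Σ and on
   the residual sd, sampled by an adaptive blockwise Metropolis sampler
   with split-R̂ diagnostics.
2. **Size-based vital rates** — Kaplan–Meier survival from day 60 mapped
   to log body size through the fitted growth curve and smoothed by a
   logistic regression (per-day-step by default); a steep logistic
   reproduction probability at the observed maturity size; Poisson
   fecundity on log length; recruit survival *f_g* and a juvenile size
   distribution *f_d*.
3. **Integral projection model** — midpoint-rule discretization of
   *n(z′, t+1) = ∫ [P(z′,z) + F(z′,z)] n(z,t) dz* on the log-size domain
   (400 meshes from the predicted 30-day size to the maximum observed
   size), with P = s·g and F = f_p·f_n·f_g·ρ·f_d. Outputs are the
   asymptotic per-capita growth rate λ (dominant eigenvalue, interpreted
   as mean fitness), the net reproductive rate R₀ (dominant eigenvalue of
   F(I − P)⁻¹) and the generation time T = log R₀ / log λ.
4. **Uncertainty and sensitivity** — bootstrap CIs for λ and T (posterior
   draws of the growth parameters plus case-resampled vital-rate data,
   1000 replicates by default), treatment comparison by CI overlap, and
   finite-difference sensitivities/elasticities of λ and T to every
   scalar vital-rate parameter.

A synthetic-cohort generator reproduces the statistical structure of the
experiment (four treatments: 20/30 °C × continuous/intermittent feeding,
3/2/3/3 tanks, cross-sectional length measurements at eight ages rounded
to 0.5 mm, daily mortality from day 60, daily clutch counts after
maturity), so the entire pipeline is testable without any external data.
Intended users are population ecologists who want a self-contained,
tested reference implementation of the growth-to-IPM-to-fitness chain.

## Worked example

```r
library(medakaIPM)

cohort <- simulate_experiment(default_config(), seed = 11)
cohort
#> Synthetic cohort data
#>   growth:   1279 length-at-age records
#>   survival: 297 fish
#>   clutch:   2593 clutch observations

result <- run_pipeline(cohort, test_mcmc_config(seed = 3))
result$fit
#> Hierarchical Von Bertalanffy posterior: 2000 draws, 4 chains
#>   treatments: conti_20, inter_20, conti_30, inter_30
#>   max split-Rhat: 1.044 (converged: TRUE)

posterior_growth_bands(result$fit, ages = c(60, 150, 300))
#>   treatment age  mean    lo    hi        (cold-continuous vs warm-continuous)
#>    conti_20  60 16.24 14.51 17.68
#>    conti_20 150 25.60 23.86 27.20
#>    conti_20 300 30.43 29.14 31.90
#>    conti_30  60 17.51 16.28 18.56
#>    conti_30 150 23.59 22.20 24.74
#>    conti_30 300 24.67 23.28 25.80

result
#> Growth-to-fitness pipeline result
#>   conti_20  lambda = 0.99973  R0 = 0.846  T = 609.7 days
#>   inter_20  lambda = 0.99990  R0 = 0.873  T = 1370.7 days
#>   conti_30  lambda = 1.00449  R0 = 2.618  T = 215.0 days
#>   inter_30  lambda = 1.00321  R0 = 2.704  T = 310.6 days
```

Reading the numbers: the credibility bands show the crossed growth
curves — warm fish are larger at day 60 but smaller from mid-experiment
on (the Temperature Size Rule signature). Downstream, warming shortens
the generation time (215 vs 610 days under continuous feeding) and
raises mean fitness (λ = 1.0045 vs 0.9997 per day): the faster life
cycle more than compensates the higher warm mortality. Bootstrap CIs for
λ and T come from `bootstrap_demography()`, treatment contrasts from
`compare_by_ci()`, and vital-rate sensitivities from
`sensitivity_analysis()`.

A thin command-line front end over the same functions is installed at
`inst/cli/medaka-ipm.R` (subcommands `simulate`, `fit-growth`,
`vital-rates`, `ipm`, `bootstrap`, `sensitivity`).

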