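---
title: "From growth curves to population fitness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From growth curves to population fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

medakaIPM turns individual-level life-history measurements from a
temperature × feeding-frequency experiment into population-level fitness
estimates. This vignette explains the models stage by stage, the
assumptions behind them, the tunable parameters, and the design choices
that were genuinely open.

## The growth model

Length at age follows the Von Bertalanffy curve
$L(t) = L_\infty\,(1 - e^{-K (t - t_0)})$, with $L_\infty$ the asymptotic
total length (mm), $K$ the growth-rate coefficient (per day) and $t_0$
the theoretical age at zero length (days, typically negative). The same
curve in one-day-update form,
$L_{t+1} = L_t e^{-K} + L_\infty (1 - e^{-K})$, is used as the mean
displacement of the IPM growth kernel; the two forms are algebraically
identical (a property the test suite sweeps).

The hierarchy has three levels. Treatment-level parameters
$(L_{\infty}, K, t_0)$ per temperature-by-feeding combination carry
vague Normal(0, precision 0.001) priors. Tank-level deviations for the
three parameters are jointly multivariate normal,
$\varepsilon \sim \mathrm{MVN}(0, \Sigma)$, with $\Sigma$ assembled from
three standard deviations (Uniform(0, 10) priors) and three pairwise
correlations (Uniform(−1, 1) priors, jointly truncated to the
positive-definite region — without the truncation the prior would put
mass on invalid covariance matrices). Observed lengths are Normal around
the tank-level curve with residual sd $\sigma \sim$ Uniform(0, 10) mm.
Because the treatment-level priors are unconstrained, negative $L_\infty$
or $K$ draws are possible a priori; the fitter warns when more than 1%
of posterior mass sits on $K \le 0$, and downstream consumers treat such
draws as failures.

Sampling uses an adaptive blockwise random-walk Metropolis sampler
written for this package (the posterior, not the sampler, defines the
model, so the backend is an implementation choice). Blocks: the three
hyper-parameters of each treatment jointly, each tank's deviation vector
jointly, the covariance components, $\sigma$, and — important for
mixing — likelihood-invariant *translation moves* that shift a
treatment's hyper-parameters against its tanks' deviations, which
decorrelates the centered hierarchy. Proposal scales adapt toward
standard acceptance targets during burn-in only, so retained draws form
a valid Markov chain. Convergence is monitored by split-R̂ per parameter;
values above 1.1 set a warning flag rather than an error, because a
flagged posterior is still often usable for point summaries. One test
cross-checks the sampler against JAGS on a single-curve model and
against closed-form conjugate posteriors.

The reference schedule (5 chains, 50,000 burn-in, 400,000 iterations,
thinning 200) retains exactly 10,000 draws. The desk-scale schedule used
throughout the tests (`test_mcmc_config()`: 4 chains × 5,000 iterations,
thinning 10, 2,000 burn-in) retains 2,000 draws and fits the default
synthetic data set in under a minute; posterior means recover the
generating parameters well within posterior uncertainty at that scale.

Treatment curves are compared by pointwise 2.5%/97.5% credibility bands;
ages where two bands are disjoint are flagged significant, with closed
intervals (bands touching at an endpoint overlap). This is a
conservative reading of the non-overlap convention.

## Vital rates on the log-size domain

The IPM state variable is $z = \log$(total length in mm). The time step
is one day: the growth update advances one unit of the $K$ time base,
clutch counts are daily, and the mortality hazard is daily, so a daily
step is the only internally consistent choice.

**Survival s(z).** Kaplan–Meier survival from day 60 (the package
implements the product-limit estimator on a daily risk table; the tests
check it against `survival::survfit` and brute-force counting) is mapped
to size through the fitted growth curve and smoothed by a logistic
regression. Two readings are available. The default, `per_step`, fits a
binomial GLM to daily deaths and numbers at risk, giving the probability
of surviving *one day* at size $z$ — the quantity a daily-step kernel
needs. The `cumulative` flag instead regresses the cumulative KM curve
on size (a literal reading of fitting "the survival probability" as a
function of size); it conflates cumulative and per-step survival and is
retained only for comparison. Fits use numbers-at-risk weights.
Degenerate inputs (no deaths, separation) return a flat curve with a
warning so that bootstrap replicates can proceed and be counted.

**Reproduction probability f_p(z).** All fish are assumed to reproduce
once they reach their treatment's maturity size; implemented as a steep
logistic with midpoint at log maturity length and steepness 50 per
log-length unit (default, configurable). Steepness 50 makes the curve
rise from 0.01 to 0.99 over about ±9% of body length around maturity —
effectively a step, but differentiable, which keeps the sensitivity
analysis well behaved. This steepness makes λ and T highly sensitive to
the reproduction parameters, which the sensitivity analysis makes
explicit.

**Fecundity f_n(z).** Poisson regression of daily clutch counts on log
length (log link), so the expected clutch is $e^{a + b z}$ eggs per
female per day.

**Recruits.** $f_g$ (egg hatching × juvenile survival to the recruit
stage) and the juvenile log-size Normal distribution $f_d$ are external
inputs: they are not identifiable from the three observation tables and
in practice come from separate hatchery observations.

**Residual growth variation.** The kernel sd around the deterministic
growth step is obtained by pushing every posterior draw through the
growth curve at age $t$ and the one-day update to $t+1$, taking the sd
across draws of the log size at $t+1$ per age, and averaging over ages
30–350 (ages below 30 days predate the IPM domain, and near $t_0$ the
log-scale sd diverges). The sd is computed on the log scale so it is
directly the kernel sd on the $z$ domain (a raw-mm option exists). Note
a consequence documented under *Limitations*: this quantity measures
posterior uncertainty about the mean curve, not observed between-fish
variability, so it shrinks as the growth data or chains grow.

## The integral projection model

The domain runs from the predicted log size at 30 days ($L$, the age at
which fish enter rearing tanks) to the maximum observed log size ($U$,
per treatment by default; a pooled table gives a global bound), divided
into 400 uniform meshes (midpoint rule). The kernels are

- $P[i,j] = s(z_j)\, g(z_i \mid z_j)$ with $g$ a Normal density centred
  on the one-day growth update, column-normalized by default so that no
  probability mass is lost at the domain boundaries ("eviction"); each
  column of $P$ then sums to exactly $s(z_j)$. A `truncate` option keeps
  the raw midpoint-rule values instead.
- $F[i,j] = f_p(z_j)\, f_n(z_j)\, f_g\, \rho\, f_d(z_i)\, h$, with
  $f_d$ truncated and renormalized on the domain and $\rho$ the female
  fraction (default 0.5; $\rho = 1$ reproduces an all-female
  accounting). Recruits appear one step after spawning at 30-day-old
  sizes; the egg and larval lag is absorbed into $f_g$.

λ is the dominant eigenvalue of $K = P + F$, computed by power iteration
with an asymptotic-dynamics test (relative change of the growth ratio
below 1e−10 over 50 consecutive steps, both configurable); the tests
cross-check against direct eigendecomposition on random 400×400 kernels
to 1e−8. The stable size distribution $w$ and reproductive value $v$ are
the right/left eigenvectors ($\sum w = 1$, $v \cdot w = 1$). $R_0$ is
the dominant eigenvalue of $F (I - P)^{-1}$ and the generation time is
$T = \log R_0 / \log \lambda$. Exactly at $\lambda = 1$ that ratio is
undefined; the implementation evaluates $T$ with $F$ scaled by
$1 \pm 10^{-6}$ and averages — a documented numerical device, accurate
to the analytic limit on scalar test cases. A spectral radius of $P$ at
or above 1 (an effectively immortal population) is an error, since
$R_0$ has no meaning there. λ is stable to well under 0.1% between 200
and 800 meshes on the default configuration.

## Bootstrap and sensitivity

Uncertainty in λ and T is propagated by, per replicate: sampling one
posterior draw of $(L_\infty, K, t_0)$ with replacement; case-resampling
the survival and clutch tables with replacement at the record level
(tank-level block resampling is available behind a flag — the record
level is the default because the tanks-per-treatment count, two or
three, is too small for a stable block bootstrap); and refitting $s$ and
$f_n$ before solving the IPM. The maturity constant, recruit parameters,
residual growth sd and grid stay fixed — they are not re-estimated from
the resampled tables. 1000 replicates per treatment by default;
replicates whose refits degenerate or whose growth draw is non-positive
are counted as failures and excluded from the percentile intervals
(more than 10% failures aborts). Treatments are compared by overlap of
the closed 95% percentile intervals, matching the growth-curve
convention.

Sensitivities are central finite differences of λ and T under a ±1%
relative perturbation of each scalar vital-rate parameter (survival
intercept/slope, reproduction midpoint/steepness, fecundity a/b, $f_g$,
$\rho$, juvenile size mean/sd, growth residual sd, $L_\infty$, $K$),
with elasticities $(\theta / \lambda)\, \partial\lambda / \partial\theta$
alongside. Perturbations that would push a probability above 1 are
clamped and flagged. The per-kernel-entry adjoint formula
$\partial\lambda / \partial K_{ij} = v_i w_j / (v \cdot w)$ serves as an
independent oracle in the tests, not as the reported sensitivity — the
reported level is the vital-rate parameter, which is the scale on which
the experiment operates.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the design constants of the experiment: four
treatments (20/30 °C × continuous/intermittent feeding), 3 tanks of ~27
fish each (2 tanks for cold-intermittent, 54 fish), lengths measured at
days 30, 45, 60, 100, 150, 200, 300, 350 on 12–17 fish per tank per day
at 0.5 mm precision (rounding after noise, mimicking the instrument),
survival monitored daily from day 60 with right-censoring at day 350,
and daily clutch counts from the treatment's maturity age. Fish are not
individually identified in the growth tables (cross-sectional samples,
as in population-level monitoring); survival records do carry ids
because the product-limit estimator needs event times. Clutch
observations attach to a reference female length read off the treatment
growth curve at the observation day, the same age-to-size device the
analysis itself uses; one observed female per tank-day is the default
layout, with a tank-day aggregate layout behind a flag.

The numeric truths are documented synthetic choices, calibrated once so
the generated populations sit in the canonical regime: maturity ages and
sizes per treatment (67.3 d/16.8 mm, 60 d/17.2 mm, 169.7 d/26.3 mm,
186.5 d/25.7 mm); growth parameters giving crossed curves under warming
(warm: higher $K$, lower $L_\infty$) and nested curves under
intermittent feeding; daily hazards higher under warming and lower under
intermittent feeding (0.002/0.0012/0.004/0.0025 per day); fecundity
intercepts higher in warm treatments; and $f_g = 6\times10^{-4}$ with
$\rho = 0.5$, set by an expected-lifetime-reproduction argument so that
λ lands near 1 per day — warm treatments slightly above, cold-continuous
slightly below, cold-intermittent closest to exactly 1. Tank random
effects use sds (0.8 mm, 0.0008/day, 1.5 d) with correlations 0.2, and
residual length noise 0.9 mm.

Deliberately not emulated: husbandry covariates (water chemistry,
photoperiod), individual longitudinal growth tracks, behavioral feeding
compensation, density dependence, egg-collection dynamics, and any
nonlinearity beyond the 2×2 design. Passing tests therefore show that
the pipeline correctly transmits life-history structure to demographic
estimates under the model's own assumptions — not that those assumptions
hold for any particular real population.

## Numerical choices and degenerate inputs

- Mesh count 400 (λ differs by < 0.1% from 200- and 800-mesh solutions
  on the default configuration); problem sizes in the test suite are
  desk-scale by design: 2,000 retained draws for module tests, 100–1000
  bootstrap replicates, 100–400 meshes.
- Zero growth-kernel sd degenerates to a point mass in the destination
  cell; columns whose Normal mass misses the domain entirely fall back
  to their destination cell before renormalization.
- Ties and boundaries: CI overlap uses closed intervals everywhere
  (touching = overlap = not significant).
- Degenerate GLM fits return flat curves with warnings in the point
  pipeline but count as failures inside the bootstrap.
- All stochastic stages are driven by explicit integer seeds; identical
  (configuration, seed) pairs reproduce byte-identical tables and
  estimates.

## Limitations

- **Residual growth variation couples to posterior width.** The
  propagate-and-average rule makes the growth-kernel sd measure
  *parameter* uncertainty, not individual variability. With desk-scale
  data and short chains it is noticeably larger than with the reference
  schedule, which depresses $R_0$ for long-lived (cold) treatments —
  fish diffuse below the maturity threshold more often. Comparisons
  *between* treatments fitted on the same schedule remain meaningful;
  absolute $R_0$ levels should be read with this in mind.
- **The survival extrapolation is leverage-heavy.** Daily survival
  enters lifetime quantities through powers of ~300, so small changes in
  the fitted logistic translate into large changes in $R_0$ and $T$ for
  long-lived treatments; this is precisely why the bootstrap matters.
- **All-reproduce-at-maturity is steep.** The near-step $f_p$ makes λ
  and T strongly sensitive to the maturity midpoint, visible in the
  sensitivity report; the assumption is shared across treatments, so
  qualitative contrasts are unaffected.
- The generation-time definition is fixed to $\log R_0 / \log \lambda$;
  alternative definitions (mean parent age at offspring production) are
  out of scope, as are density dependence, stochastic environments,
  two-sex structure and energy-budget (DEB) formulations.
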