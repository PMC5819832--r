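---
title: "Statistical models for clustered dauer assays and foraging behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models for clustered dauer assays and foraging behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A plate-based dauer-formation assay scores each animal on a plate as dauer
or non-dauer, so the natural unit of observation is a clustered binomial
count: plate i of strain s on day j contributes `n_dauer` successes out of
`n_total` animals. Treating the per-plate proportions as independent
Gaussian observations — as a t-test or one-way ANOVA does — ignores the
cluster structure, and the data carry substantially more variance than a
binomial law allows. `hidstats` models three extra-binomial sources, all
on the log-odds scale:

* **sD** (`sd_day`) — day-to-day variance, a shift shared by every plate
  assayed on the same day (incubator, food batch, ambient conditions);
* **sP** (`sd_plate`) — plate-to-plate variance, independent per plate;
* **sG** (`sd_history`) — strain culture-history variance, realized per
  strain-by-day cell, so that two strains assayed side by side on one day
  can move in *different* directions. In real assay collections this
  component is not directly estimable (parallel independently cultured
  control replicates are rarely available), but it is retained in the
  model because it is biologically expected.

The generative model used throughout — by the simulator, the frequentist
GLMM and the Bayesian GLMM — is

$$ n_{dauer,ij} \sim \mathrm{Binomial}\!\left(n_{total,ij},\;
   \mathrm{logit}^{-1}(\beta_s + d_j + g_{sj} + e_{ij})\right), $$

with $d_j \sim N(0, s_D^2)$, $g_{sj} \sim N(0, s_G^2)$,
$e_{ij} \sim N(0, s_P^2)$.

## The four analysis routes and the simulation study

`run_comparison()` reproduces a Monte Carlo experiment comparing four ways
of analyzing such data, under the reference design of a control plus two
test genotypes with 6 plates per group collected over 3 days:

1. `welch_prop_test()` — per-contrast Welch t-tests on plate proportions;
2. `anova_prop()` — one-way ANOVA on plate proportions with single-step
   multivariate-t post-hoc contrasts;
3. `fit_binomial_glmm()` — the binomial GLMM above, fitted by maximum
   likelihood with the Laplace approximation (lme4);
4. `fit_bayes_binomial_glmm()` — the same model fitted by MCMC with weak
   priors: Normal(0, 2.5) on group log-odds, half-Normal(0, 1) on each
   random-effect standard deviation.

Two truth scenarios are simulated: all groups equal (type-I error), and
one test group shifted by 1 on the log-odds scale (type-II error /
power). Conditions vary the variance preset, design balance (unbalanced:
the control is run on all days but each test group misses one day), and
systematic day bias (the control's day effect is shifted by one `sd_day`
on a third of the days).

Decisions that were genuinely open, and how they were fixed:

* **Detection rules.** Frequentist methods reject a comparison when its
  raw per-contrast p-value is below alpha; the Bayesian method "detects"
  a difference when the 95% equal-tailed credible interval of the
  contrast excludes zero. Per-comparison (not family-wise) type-I error
  is the primary metric; multiplicity-adjusted p-values are logged
  alongside so family-wise rates can be recomputed from the replicate log
  without refitting (`rates_from_log()`).
* **Variance presets.** The low preset is (0.25, 0.25, 0.25) and the high
  preset (1.0, 0.5, 0.5) logits for (sD, sP, sG). Two considerations fixed
  them: day-to-day variance should dominate plate-to-plate variance, as
  estimated from large wild-type assay collections, and the high preset
  should be strong enough that plate-level tests visibly inflate their
  type-I error. They are config-overridable.
* **Bias convention.** The systematic-bias offset is `+1 * sd_day`
  applied to the control group only, on a random `ceiling(bias_fraction *
  n_days)` subset of days — a deliberately adversarial convention, since
  bias confined to the control cannot be absorbed by a shared day effect.
* **Expected behavior of the Bayesian route.** With 6 plates over 3 days
  the half-Normal priors on three variance components are not overwhelmed
  by the data; the contrast posterior therefore carries prior-induced
  random-effect uncertainty and the credible interval is wider than the
  Wald interval. The practical consequence, visible in
  `run_comparison()` output, is that the Bayesian GLMM is conservative —
  clearly below nominal alpha under zero variance, and by far the lowest
  type-I error under high day/history variance with unbalanced, biased
  designs, where the plate-level tests inflate severely. That
  conservatism is the method's selling point at this design size, not a
  defect, but it does mean the Bayesian route is *not* calibrated to
  alpha in the way the frequentist routes are.

## Bayesian computation

The MCMC engine is JAGS. Two implementation points matter:

* The `glm` module is loaded at package load: with only 3 days, the group
  intercepts and day effects are jointly weakly identified and
  single-site samplers mix an order of magnitude too slowly; the module's
  blocked samplers resolve this.
* Convergence is declared when every *fixed-effect* split-R-hat is at most
  1.05. All reported quantities (contrasts, response-scale intervals)
  are functions of the fixed effects. The variance-component chains
  explore a funnel and their R-hats — reported in `diagnostics$rhat` —
  stabilize much more slowly without affecting the contrast posterior;
  gating on them at desk-scale draws (2 chains of 500) would discard
  most replicates while changing no reported estimate.

Reduced draws (2 chains x 500 post-warmup after 500 burn-in) are used
inside the comparison loop; stand-alone fits default to 4 x 1000.

## Count and intensity assays

Grid-entry exploration scores are approximately Poisson;
`fit_poisson_glmm()` fits `log E[score] = beta_s + b_date + b_plate` with
a per-date random intercept (the `sD` analog) and a per-worm (= plate)
random intercept absorbing plate-level overdispersion, by Laplace ML or
MCMC. Fluorescence intensities show variance increasing with the mean;
`fit_lmm_log10()` applies the standard log10 correction and fits a
Gaussian mixed model with date and plate random intercepts, reporting
back-transformed (geometric-mean) group summaries.

`lrt_nested()` compares nested fits by `2 * (loglik_full -
loglik_reduced)` against a chi-square with the parameter-count
difference. The naive reference (no boundary correction) is the default —
matching the df = 1 convention used for chromosome-substitution
contrasts — with the 50:50 mixture reference available by flag. The
reduced model for a genotype term is formed by collapsing strain labels,
so the nesting check compares random-term names and parameter counts
rather than fixed-effect names.

## Multiplicity adjustment

`adjust_multcomp()` implements single-step Dunnett/Tukey-type adjustment:
adjusted p = Pr(max |T| >= |t|) under the central multivariate t with the
fit's degrees of freedom and the correlation of the contrast estimates.
Probabilities are evaluated by randomized quasi-Monte Carlo (mvtnorm)
under a fixed internal seed, giving reproducibility well below three
decimals; when contrast degrees of freedom differ (Welch), the minimum is
used as a conservative common reference. A one-contrast family is left
unchanged, and the adjusted value is floored at the raw value.

## Track analytics

Locomotion tracks arrive as per-frame positions (mm) at a nominal frame
rate, default 3 fps for 90 minutes. Per frame:

* **speed** = step length / frame interval (mm/s);
* **angular velocity** = the turn angle between successive displacement
  vectors `v12` and `v23`. The normalized dot product
  `v12 . v23 / (|v12| |v23|)` is the *cosine* of that angle; expressing
  the result in degrees per frame requires the arccosine, which is what
  the package computes (cosine clamped to [-1, 1] against rounding; the
  raw cosine is attached for audit). Frames whose displacement falls
  below a stationary threshold (default 1e-4 mm/s) yield an undefined
  angle and are excluded from bin means rather than recorded as zero,
  which would otherwise bias dwelling bins toward artificially low
  turning.

Tracks are summarized in non-overlapping 10-s bins (30 frames at 3 fps; a
90-min track gives exactly 540 complete bins; trailing partial bins are
dropped; bins with more than half their turn angles undefined are labeled
undefined). A bin is **roaming** when its mean speed exceeds `slope = 2`
times its mean angular velocity, **dwelling** otherwise, with
on-the-line bins dwelling by default. Because the speed/angular-velocity
plane's axis units are an assay convention, the classifier exposes unit
multipliers; with the default synthetic state parameters (roaming ~0.15
mm/s with 10 deg/frame turning, dwelling ~0.02 mm/s with 50 deg/frame),
`speed_scale = 1000` — speed in micrometers/s against degrees/frame —
places the slope-2 line cleanly between the two clusters, and is what the
tests and the acceptance script use.

The two-state track generator is a frame-level hidden Markov model
(sticky transition matrix, default total switching intensity 0.01/frame),
with state-specific Gaussian speed and turning draws and radial folding
at the circular arena boundary (3.5 cm plate). It emulates the gross
statistical structure of real foraging tracks — two well-separated
behavioral modes with geometric episode lengths — but not their finer
features: no sinusoidal body-wave residue, no omega turns, no
speed/turning autocorrelation within a state, no food-patch geometry.
Passing recovery tests on these tracks therefore validates the binning,
classification and aggregation arithmetic, not the biological realism of
any particular slope value.

**Grid-entry exploration score**: a square lattice is realized over the
circular arena, keeping cells whose centers fall inside; the cell size is
chosen so the kept-cell count comes closest to the 188-square reference
grid (the realized count is reported — exactly 188 is generally
unattainable on a disk). An entry is a transition into a cell from a
different cell, the starting cell counts as one entry, and per-cell
counts are capped at 10 (further crossings of an already-tracked square
cannot be distinguished); the total is the sum of capped counts.
Collapsing consecutive same-cell frames makes the score invariant to
temporal upsampling of the same geometric path.

## Numerical conventions

* Welch tests floor group variances at 1e-12 instead of failing on
  constant groups (common in small null simulations) and flag the fit
  `degenerate`; an all-equal ANOVA reports F = 0, p = 1.
* Complete separation (a strain with pooled proportion 0 or 1) is
  stabilized in the ML fits by a pseudo-count ridge — one pseudo-plate
  per strain carrying half a success and half a failure (strength
  configurable) — and flagged; the Bayesian fit needs no ridge because
  its proper prior regularizes the posterior.
* All generators take explicit seeds, derive per-replicate sub-streams
  with a mixing function (`derive_seed()`), restore the caller's RNG
  state, and are byte-reproducible.
* Variance estimates are reported as standard deviations and are
  naturally floored at zero by the optimizer's parameterization.

## Problem sizes

The test suite and the acceptance script run the simulator calibration at
10,000 plates; GLMM recovery at 150–200 replicates of the 3-group,
6-plate, 3-day design; Bayesian coverage at 50 replicates with reduced
draws; the method comparison at 150–200 replicates per condition; and
track recovery at 20 worms of 90 minutes. These sizes put Monte Carlo
standard errors comfortably inside the tolerances being asserted (e.g.
~0.011 for a type-I rate at 400 comparisons) while a full run of suite
plus script completes in a few minutes on one core.

## Known limitations

* The GLMM Wald tests are anti-conservative with few clusters (3 days),
  visibly so under the high-variance unbalanced conditions; this is a
  property of the method being studied, reproduced on purpose.
* `sG` cannot be separated from `sD` with a single strain, and with 3
  days all variance estimates are individually noisy; contrasts remain
  well-estimated because day effects are shared across groups.
* The roaming/dwelling partition is a fixed line, not a fitted
  classifier; its accuracy statement holds for the generator's
  well-separated default states and degrades as the states approach the
  line.
* The pipeline orchestrator (`run_pipeline()`/`render_report()`) is a
  reproducibility convenience, not a workflow engine: stages run in a
  fixed dependency order within one R session.
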