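---
title: "Models and design of the codevelop package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the codevelop package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements: the generative model behind the synthetic cohorts, the
harmonization and reliability algebra, the prediction and inference design,
and the numerical and design choices that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scientific setting

Two-visit developmental cohorts measure a parcellated functional connectome
(FC: Pearson correlations between region-averaged resting-state fMRI time
series, stored Fisher-z transformed over the upper triangle) and a battery
of cognitive tests at a baseline visit and a follow-up roughly two years
later, across many acquisition sites. Three questions drive the design:

1. How stable are individual differences in FC and cognition across visits,
   and how large is within-person change?
2. How well do cross-sectional FC, FC measured later, and longitudinal FC
   *change* predict cognition — and how much of any gap is explained by the
   lower test-retest reliability of change scores?
3. Where do cross-sectional and longitudinal brain-cognition couplings
   agree in sign (convergence) and where do they oppose (divergence, the
   multivariate analogue of Simpson's paradox)?

Real cohorts of this kind are access-restricted, so the package is built
around a fully synthetic testbed whose ground truth is known, plus the
estimators one would run on real tables.

## Synthetic cohorts

`generate_cohort()` draws, per participant $i$ at site $s$ and timepoint
$t \in \{0, 2\}$:

- a latent cognitive trait $g_{i0} \sim N(0,1)$,
  $g_{i2} = s_g g_{i0} + \sqrt{1 - s_g^2}\,\eta_i$ with stability $s_g$
  (default 0.8 — cognition ranks are highly preserved across two years);
- observed cognition per measure $m$:
  $y = \lambda_m g_{it} + \gamma_{sm} + \delta_{sm}\varepsilon_{itm}$,
  with loadings $\lambda$ descending from 0.85 to 0.55 over seven measures
  and measure-specific noise (default SD 0.6);
- per-edge FC true scores $a_{ite}$ with variance $\sigma^2_e$, stability
  $s_e$ (default 0.7), plus planted couplings: $w^{cross}_e g_{i0}$ enters
  both visits and $w^{long}_e (g_{i2} - g_{i0})$ enters only the follow-up,
  so the cross-sectional coupling and the change-change coupling are
  independently controllable per network block
  (`plant_block_couplings()`);
- observed edges $a_{ite} + \gamma_{se} + c\,\mathrm{FD}_{it} +
  \delta_{se}\epsilon_{ite}$ with noise variance $\tau^2_e / T$ for $T$
  minutes of usable scan (default 20), linear head-motion leakage
  ($c$ in z-units per mm of framewise displacement), and site effects in
  exactly the longitudinal-ComBat generative form (one additive offset and
  one multiplicative scale per site, shared across visits, scaling the
  noise) so that harmonization recovery is well posed.

Default cohort dimensions mirror the emulated study design (2949
participants, 21 sites, a 400 + 19 region scheme, baseline age 9.93 ± 0.62
years, interval 2.01 ± 0.16 years, sex ≈ 49% coded 1); tests use smaller
schemes and samples with identical structure. Sensorimotor-association
modulation is linear in the mean S-A rank of an edge's regions:
$\sigma^2_e$ grows and $\tau^2_e$ shrinks toward the association end,
reproducing the qualitative stability gradient without claiming empirical
magnitudes. Site sizes follow a gamma-weighted law with a floor of 10
participants (sites below 10 are excluded from the emulated design).

Two generation modes exist because they serve different oracles. In
**direct-edge** mode (default) edges are drawn as true score plus Gaussian
noise of variance $\tau^2/T$, which makes the scan-duration reliability
model below *exact* and gives closed-form expectations for every
reliability test. In **time-series** mode stationary AR(1) runs are
generated whose innovation correlation equals a target FC matrix (a shared
AR coefficient preserves the zero-lag correlation), with a censor mask
marking $\lfloor \text{frac} \cdot n \rfloor$ frames — the input for FC
construction tests. `simulate_split_half_edges()` additionally keeps
per-minute noise increments so that truncating to the first $T$ minutes
yields noise variance exactly $\tau^2/T$, emulating scan truncation.

What the generator does *not* emulate: hemodynamics, scanner physics,
realistic spatial covariance between edges (edges are independent given
the trait), non-Gaussian score distributions, attrition, or the empirical
map of where change-variance concentrates. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
properties of any real cohort.

## FC construction and the change statistic

`build_fc()` computes Pearson correlations per run over uncensored frames
only, Fisher-transforms (`atanh`) with correlations clipped at
$|r| = 0.999999$ so degenerate inputs stay finite, averages z across runs,
and reports `tanh` of the average as the r-scale value. Runs with fewer
than five uncensored frames are skipped with a warning; zero-variance
regions yield zero edges with a warning.

The per-participant change statistic is $z = (r_2 - r_0)/\sqrt{s_2 + s_0}$
with $r_t$ the Fisher-z edge value and $s_t$ its variance. Because fMRI
series are autocorrelated, $s$ uses an effective sample size:
$n_\mathrm{eff} = n / (1 + 2\sum_{l=1}^{L}\rho_x(l)\rho_y(l))$ with lags
truncated at $L = \lfloor\sqrt{n}\rfloor$, the lag sum clipped at $-0.49$
(keeping the denominator positive) and $n_\mathrm{eff}$ clipped to
$[5, n]$; the variance is $1/(n_\mathrm{eff} - 3)$, and a naive
$1/(n - 3)$ mode is retained for analytic tests. This is a deliberately
simple effective-degrees-of-freedom estimator; the truncation and clipping
constants are this package's choices, validated against Monte-Carlo
variances of correlations between AR(1) pairs. Per-timepoint $r$ and $s$
are computed on the concatenated uncensored frames of a visit's runs; z
values are then residualized edge-wise on sex, baseline age, age interval
and both visits' mean framewise displacement.

## Longitudinal harmonization

`fit_longitudinal_combat()` models each feature as
$y_{ist} = \alpha + X\beta + u_i + \gamma_s + \delta_s \varepsilon_{ist}$.
Estimation is deliberately closed-form: covariate effects and site offsets
are estimated jointly by OLS on the stacked two-visit table (offsets
re-centered to a site-size-weighted zero mean, so they satisfy the model's
identifiability constraint); the random intercept $u_i$ is the
participant's mean residual (exactly two observations per participant);
and $\delta_s$ is the ratio of the within-participant residual
root-mean-square in site $s$ to the pooled value. This estimator is
exactly invertible on planted effects and makes
`apply_combat()` — $\hat y = \alpha + X\beta + u_i +
(y - \alpha - X\beta - u_i - \gamma_s)/\delta_s$ — *idempotent to
machine precision* when covariates are participant-level, a property the
tests assert. A full REML mixed-model fit would differ only slightly here
and would make the recovery oracles inexact.

Empirical-Bayes shrinkage of $(\gamma_s, \delta_s^2)$ toward pooled
across-feature moments is available (`use_eb = TRUE`) but off by default:
the unshrunk estimator is the one with exact planted-effect recovery, and
whether the emulated study used EB priors is not stated. Covariate codings
(sex 0/1, ages in years, FD in mm) are exposed, not hard-coded.

## Stability, change, PC1

Stability is Spearman's correlation across participants between the two
visits' features after residualizing each visit on its own covariates;
p-values use the t approximation. Group-level change uses the
two-visit mixed model
$y_{it} = \beta_0 + \beta_1\,\mathrm{age}_{i0} + \beta_2 (\mathrm{age}_{it}
- \mathrm{age}_{i0}) + \beta_3\,\mathrm{sex}_i\ [+ \beta_4 \mathrm{FD}_{it}]
+ u_i + \varepsilon_{it}$, fit by REML (lme4/lmerTest, Satterthwaite df).
The interval coefficient's t statistic is converted to an effect size by
the stated convention $d = 2t/\sqrt{df}$; the conversion function is a
parameter because the convention is not unique. The REML $\beta_2$ agrees
closely — but not to machine precision — with the no-intercept regression
of change scores on the interval, because REML also draws a little
between-participant information; the tests assert agreement at 1%
relative tolerance.

Individual change is the raw difference (follow-up minus baseline),
residualized on sex, baseline age and interval; annualized rates divide by
the individual age interval. PC1 is learned on a held-out reference
sample: measures are z-scored by reference means/SDs, loadings come from
the reference correlation structure, the sign is anchored (default: first
measure, positive loading — the vocabulary-like anchor is configurable
since no sign convention is canonical), and `apply_pc1()` never
re-normalizes on the target sample, preventing leakage. Missing data are
excluded listwise within an operation, never imputed.

## Reliability algebra

`icc_oneway()` is the one-way random-effects ICC
$(\mathrm{MSB} - \mathrm{MSW})/(\mathrm{MSB} + (K-1)\mathrm{MSW})$ with
$K = 2$ repeats. The scan-duration model is
$R_T = \sigma^2 / (\sigma^2 + \tau^2/T) = 1/(1 + k/T)$: only the
noise-to-signal ratio $k = \tau^2/\sigma^2$ (units: minutes) is
identifiable from reliabilities alone, so `fit_scan_time_curve()` fits the
single parameter $k \ge 0$ by least squares *in reliability space*
(matching the reported coefficient-of-determination convention), via a
log-spaced grid bracketing plus golden-section refinement (tolerance
1e-12; the noiseless inversion is exact to ~1e-6 relative). Curves whose
ICCs are all non-positive are flagged unfittable and excluded downstream
with a count. Extrapolation and inversion are
$R_T = 1/(1 + k/T)$ and $T^* = kR/(1 - R)$, exact inverses.

Change-score reliability follows
$R_D = (R_1 V_1 + R_2 V_2 - 2\rho\sqrt{V_1 V_2}) /
(V_1 + V_2 - 2\rho\sqrt{V_1 V_2})$: high between-visit stability $\rho$
destroys change reliability even when both visits are individually
reliable — the quantitative reason FC change predicts worse than baseline
FC. The implementation checks the two analytic limits ($\rho = 0$ gives
the variance-weighted mean of $R_1, R_2$; the symmetric case gives
$(R - \rho)/(1 - \rho)$) and is validated against Monte-Carlo ICCs of
simulated difference scores; the Monte-Carlo oracle averages 10 replicate
simulations of n = 5000 so its own simulation error sits well inside the
0.02 comparison band. `reliability_matched_truncation()` reproduces the
matching experiment: per edge, $T^*$ equates baseline reliability to a
target (e.g. the change reliability); a fixed conservative duration
(default 4 minutes) below the typical $T^*$ is then used to recompute
baseline values. Split halves truncate *both* halves to $T$ minutes over
uncensored data.

## Prediction

Sites are grouped into clusters (default 10, each with at least 280
participants in the emulated design) by greedy bin packing: largest site
first into the currently smallest cluster, round-robin among ties —
sites are never split, so held-out data always comes from unseen sites.
`nested_cv_krr()` enumerates every combination of `n_test_clusters`
(default 3) held-out clusters — $\binom{10}{3} = 120$ folds, each cluster
appearing in exactly $\binom{9}{2} = 36$ test sets. Per fold, covariates
are regressed from the *training* targets and the training coefficients
applied to the test targets (covariates are not regressed from FC, the
target-side-only convention; switchable by passing residualized features).
An inner 10-fold cross-validation on the training participants picks the
ridge penalty from 16 log-spaced values in $[10^{-4}, 10^4]$ by mean inner
Pearson r — the same metric as the outer evaluation; a site-stratified
inner split is available behind a flag. Accuracy is the arithmetic mean
over folds of the test-set Pearson r (no Fisher averaging).

The default kernel is the correlation between participants' edge vectors
(the field's workhorse for connectome-based KRR; linear and Gaussian
kernels are provided). Row standardization makes the correlation kernel
insensitive to each participant's mean and scale — harmless for
high-dimensional FC vectors, but for low-dimensional raw-feature toys the
linear kernel is the right choice, and tests use it there. Kernel systems
are solved by eigendecomposition (inner loop, one decomposition per inner
fold serving the whole penalty grid) or direct solve (final model), with a
diagonal jitter fallback if a centered kernel is numerically indefinite.

`transfer_model()` applies fold models to a later visit without any
refitting: stored covariate coefficients residualize the new targets and
stored dual weights predict through the cross-kernel — the design that
asks whether a brain-cognition mapping learned at baseline transfers
forward. Haufe-transform features (`haufe_pnf()`) are the covariance,
across a fold's *training* participants, between each edge and the model's
prediction for those participants, averaged over folds (the fold handling
is a package choice; the per-fold models are the only honest predictors of
their own training sets). For display a copy normalized to matrix SD 1 is
provided; classification downstream is sign-based and unaffected.

## Inference

All permutation p-values use the strictly valid finite-sample convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$. Prediction
significance shuffles targets *within sites* (preserving site structure)
and re-runs the full pipeline per permutation. Model comparisons use the
corrected resampled t-test,
$t = \bar d / \sqrt{(1/J + n_{test}/n_{train})\, s^2_d}$ with $J - 1$
degrees of freedom — the variance inflation accounts for overlapping
training sets across folds; it equals the classic paired t shrunk by
$\sqrt{(1/J)/(1/J + n_{test}/n_{train})}$. Multiplicity uses
Benjamini-Hochberg FDR via `stats::p.adjust`.

The spin test draws uniform rotations (QR of a Gaussian 3×3 with sign
correction and determinant fixed to +1), applies each rotation to
left-hemisphere centroids and its x-mirrored image to the right
hemisphere (whether a joint-sphere or mirrored scheme is canonical is not
settled; mirrored per-hemisphere is implemented and labelled), and maps
each original parcel to the nearest rotated centroid — duplicates allowed,
with a greedy one-to-one assignment variant behind a flag. Subcortical
regions are never permuted and are excluded from spin statistics.
Calibration tests generate smooth maps whose spatial autocorrelation is
*within-hemisphere* — the structure per-hemisphere rotations preserve;
maps smooth across the 3D midline would need a joint-sphere null.

## Network blocks

`block_average()` averages edge features within unordered network-pair
blocks (diagonal blocks are within-network edges; single-region networks
have empty diagonal blocks and are flagged). `classify_convergence()`
labels a block convergent when its mean feature has the same nonzero sign
in the cross-sectional and longitudinal models, divergent when opposite.
The magnitude threshold defaults to 0 — the faithful pure-sign rule — and
exists because near-zero block means make signs noise; raising it trades
sensitivity for stability. Block averaging is linear, so applying the
SD-1 normalization before or after does not change any label.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are comfortably inside
their tolerances: reliability calibrations at n = 1000 participants
(50 replicates for the split-half oracle), planted-coupling prediction at
n = 800 with a 60-region scheme and 10 site clusters (120 folds),
permutation calibration with 200 permutations × 50 seeds around a reduced
leave-cluster-out pipeline (re-running the full 120-fold nested KRR
thousands of times adds nothing to a statistic-agnostic validity check),
spin calibration with 500 rotations × 100 map pairs on a 100-parcel
sphere, and end-to-end block recovery over 10 seeded cohorts of n = 300.
Seeds are fixed everywhere; identical configuration and seed reproduce
cohorts and pipelines byte-for-byte.

Numerical guards worth knowing: Fisher clipping at $|r| = 0.999999$; the
autocorrelation lag-sum clip at $-0.49$ and $n_\mathrm{eff} \in [5, n]$;
$\delta_s$ floored away from 0 and set to 1 when a feature has no residual
variance; change-reliability denominators below 1e-12 rejected as
degenerate; kernel jitter on indefinite centered kernels; and the
round-robin tie-break in site clustering, which makes clustering
deterministic given the site table.

## Limitations

Two visits cannot identify nonlinear or person-specific trajectories, and
nothing here attempts to. The effective-sample-size variance is an
approximation to full autocorrelation-corrected estimators. The
harmonization estimator is method-of-moments, not REML, by design. The
synthetic generator's independence of edges given the trait makes
multivariate prediction easier than on real connectomes; accuracy numbers
from the testbed characterize the machinery, not any empirical cohort.
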