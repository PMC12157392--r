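# codevelop

Tools for studying how functional brain connectomes and cognition co-develop
across two longitudinal timepoints, written for developmental-neuroimaging
analysts who work with multi-site resting-state fMRI cohorts (two visits,
parcellated connectomes, a battery of cognitive tests) and want to separate
what *stable individual differences* versus *within-person change* in
functional connectivity (FC) say about cognitive outcomes.

## What the package computes

Connectomes are stored as Fisher-z edge vectors over the upper triangle of a
region x region correlation matrix. On top of that representation the
package provides:

- **Synthetic longitudinal cohorts** (`generate_cohort()`) with known ground
  truth: multi-site structure with additive/multiplicative site effects, two
  timepoints with configurable stability, per-edge reliability following a
  true-score + duration-scaled-noise model, a latent cognitive trait g with
  planted multivariate FC couplings, and block-structured couplings
  (`plant_block_couplings()`) for convergence/divergence experiments.
- **FC construction** from censored multi-run time series (`build_fc()`),
  with Fisher-z run averaging, and a per-edge change statistic
  `z = (r2 - r0) / sqrt(s2 + s0)` with an autocorrelation-aware variance
  (`corr_variance()`, `fc_change_z()`).
- **Longitudinal site harmonization** (`fit_longitudinal_combat()`,
  `apply_combat()`): per feature, `y_ist = alpha + X beta + u_i + gamma_s +
  delta_s * eps`, removing additive and multiplicative site effects while
  preserving covariates and the participant random intercept.
- **Stability and change statistics**: Spearman stability of residualized
  features, two-timepoint mixed models with a participant random intercept,
  individual change scores, annualized rates, transferred-loading PC1, and
  cohort summary tables (`spearman_stability()`, `fit_lmm_change()`,
  `change_scores()`, `derive_pc1()`, `cohort_summary()`).
- **Reliability algebra**: one-way random-effects ICC (`icc_oneway()`), the
  scan-duration model `R_T = 1 / (1 + k/T)` with `k = tau^2/sigma^2`
  (`fit_scan_time_curve()`, `extrapolate_reliability()`,
  `matching_duration()`), the change-score reliability
  `R_D = (R1 V1 + R2 V2 - 2 rho sqrt(V1 V2)) / (V1 + V2 - 2 rho sqrt(V1 V2))`
  (`change_reliability()`), and a reliability-matched truncation experiment.
- **Prediction**: site-cluster construction (`make_site_clusters()`), nested
  leave-3-cluster-out kernel ridge regression with training-side covariate
  regression (`nested_cv_krr()`), cross-timepoint model transfer
  (`transfer_model()`), and Haufe-transform predictive network features
  (`haufe_pnf()`), i.e. the covariance between each edge and the predicted
  score.
- **Inference**: within-site permutation tests (`permutation_null()`), the
  corrected resampled t-test for comparing cross-validated models
  (`corrected_resampled_ttest()`), Benjamini-Hochberg FDR (`fdr_bh()`), and
  spherical spin tests for parcellated maps (`build_spin_null()`,
  `spin_pvalue()`).
- **Network-block readout**: block averaging of predictive features and
  convergent/divergent classification across cross-sectional and
  longitudinal models (`block_average()`, `classify_convergence()`,
  `chord_export()`) — the multivariate analogue of Simpson's paradox.

`run_pipeline()` ties the stages into a seeded, manifest-producing
end-to-end run. See `vignette source in vignettes/` for the full model
descriptions and design choices.

## Worked example

```r
library(codevelop)

scheme <- synthetic_parcel_scheme(n_cortical = 40, n_networks = 4,
                                  n_subcortical = 0)
w <- plant_block_couplings(scheme,
                           block_signs_cross = c("net1|net1" = 1,
                                                 "net2|net2" = 1),
                           block_signs_long  = c("net1|net1" = 1,
                                                 "net2|net2" = -1),
                           magnitude = 0.8)
cfg <- cohort_config(n_participants = 300, n_sites = 6,
                     site_size_law = "equal", seed = 1, scheme = scheme,
                     coupling = list(w_cross = w$w_cross,
                                     w_long = w$w_long))
cohort <- generate_cohort(cfg)
cohort
#> synthetic_cohort: 300 participants, 6 sites, 780 edges, 7 cognitive measures

dem <- cohort$demographics
clustering <- make_site_clusters(c(table(dem$site)), n_clusters = 6,
                                 min_size = 30)
pc1 <- derive_pc1(cohort$cognition_y0)
y0 <- apply_pc1(pc1, cohort$cognition_y0)
res <- nested_cv_krr(cohort$fc_y0, y0,
                     covariates = data.frame(sex = dem$sex,
                                             age = dem$age_y0,
                                             fd = dem$fd_y0),
                     site = dem$site, clustering = clustering,
                     config = prediction_config(seed = 1))
res
#> prediction_result: 20 folds, mean r = 0.8856
```

The mean fold r is the average, over held-out site-cluster combinations, of
the Pearson correlation between predicted and observed (covariate-
residualized) PC1 — here large because the planted FC-trait coupling is
strong. Haufe features then localize the model:

```r
blocks <- classify_convergence(
  block_average(haufe_pnf(res), scheme),
  block_average(haufe_pnf(res), scheme))  # cross vs itself: all convergent
```

With the longitudinal model (change in FC predicting change in PC1) in the
second slot, blocks planted with opposite cross-sectional and longitudinal
signs are labelled `divergent` — the package's convergence/divergence
readout.

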