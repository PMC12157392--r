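# Shared fixtures and independent oracles used across test files.

small_scheme <- function(n_cortical = 12, n_networks = 3, n_subcortical = 2) {
  synthetic_parcel_scheme(n_cortical, n_networks, n_subcortical)
}

# Independent one-way ANOVA oracle via lm/anova (different code path from
# the package's closed-form sums of squares).
icc_anova_oracle <- function(test, retest) {
  y <- c(test, retest)
  id <- factor(rep(seq_along(test), 2))
  tab <- stats::anova(stats::lm(y ~ id))
  msb <- tab["id", "Mean Sq"]; msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + msw)
}

# Monte-Carlo change-score reliability: simulate paired measurements with
# the requested reliabilities/variances/correlation, form two replicate
# difference scores sharing true scores, and take the mean split ICC over
# several replicate simulations (averaging reduces Monte-Carlo error of the
# oracle, not the tolerance of the comparison).
mc_change_reliability <- function(r1, r2, v1, v2, rho, n = 5000, reps = 10) {
  mean(replicate(reps, {
    c12 <- rho * sqrt(v1 * v2) / sqrt(r1 * v1 * r2 * v2)
    L <- chol(matrix(c(1, c12, c12, 1), 2))
    TT <- matrix(stats::rnorm(n * 2), n) %*% L
    t1 <- TT[, 1] * sqrt(r1 * v1); t2 <- TT[, 2] * sqrt(r2 * v2)
    mk <- function() (t2 + stats::rnorm(n, 0, sqrt((1 - r2) * v2))) -
      (t1 + stats::rnorm(n, 0, sqrt((1 - r1) * v1)))
    icc_oneway(mk(), mk())$icc
  }))
}

# smooth independent maps on the scheme's sphere, smoothed within
# hemisphere only (matching what per-hemisphere rotations preserve)
smooth_sphere_map <- function(scheme, bandwidth = 0.6) {
  C <- scheme$centroids
  G <- exp(-(acos(pmin(pmax(tcrossprod(C), -1), 1)))^2 / (2 * bandwidth^2))
  G[outer(scheme$hemisphere, scheme$hemisphere, "!=")] <- 0
  as.numeric(G %*% stats::rnorm(nrow(C)))
}

# small null-signal prediction setup reused by permutation calibration
tiny_prediction_setup <- function(n = 96, p = 20, n_sites = 8,
                                  n_clusters = 4) {
  site <- rep(paste0("s", seq_len(n_sites)), each = n / n_sites)
  clustering <- make_site_clusters(c(table(site)), n_clusters = n_clusters,
                                   min_size = n / n_sites)
  config <- prediction_config(lambda_grid = 10^seq(-2, 2, length.out = 4),
                              inner_folds = 3, n_test_clusters = 1, seed = 1)
  list(site = site, clustering = clustering, config = config)
}
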