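test_that("residualize matches normal equations and handles edge cases", {
  # 5-participant hand case against an explicit normal-equations solve
  y <- c(2.0, 3.1, 4.2, 4.9, 6.3)
  x <- c(1, 2, 3, 4, 5)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(as.numeric(residualize(y, data.frame(x = x))),
               as.numeric(y - X %*% beta), tolerance = 1e-12)
  # exact linear dependence -> zero residuals
  age <- rnorm(20, 10)
  expect_equal(max(abs(residualize(2 * age, data.frame(age = age)))), 0,
               tolerance = 1e-10)
  # orthogonal covariate -> centered values
  set.seed(1)
  v <- rnorm(30)
  orth <- as.numeric(residualize(rnorm(30), data.frame(v = v)))
  expect_equal(as.numeric(residualize(v, data.frame(o = orth))),
               v - mean(v), tolerance = 1e-10)
  expect_error(residualize(v[1:10], data.frame(a = 1:10, b = 2 * (1:10))),
               "rank-deficient")
})

test_that("spearman stability: identity, null, and attenuation", {
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  same <- spearman_stability(x, x)
  expect_equal(same$rho, c(1, 1))
  # independent timepoints: mean rho near 0
  n <- 2000
  x0 <- matrix(rnorm(n * 5), n); x2 <- matrix(rnorm(n * 5), n)
  expect_lt(abs(mean(spearman_stability(x0, x2)$rho)), 0.02)
  # attenuation: true stability 0.6, reliabilities 0.7 -> observed ~ 0.42
  stab <- 0.6; rel <- 0.7
  t1 <- rnorm(n); t2 <- stab * t1 + sqrt(1 - stab^2) * rnorm(n)
  noise_var <- (1 - rel) / rel
  o1 <- t1 + rnorm(n, 0, sqrt(noise_var))
  o2 <- t2 + rnorm(n, 0, sqrt(noise_var))
  got <- spearman_stability(cbind(o1), cbind(o2))$rho
  expect_lt(abs(got - stab * rel), 0.05)
  # monotone transform invariance without covariates
  expect_equal(spearman_stability(cbind(exp(o1)), cbind(o2^3))$rho, got,
               tolerance = 1e-12)
})

test_that("mixed-model change recovers planted effects", {
  set.seed(3)
  n <- 500
  age0 <- rnorm(n, 10, 0.6); interval <- rnorm(n, 2, 0.16)
  sex <- rbinom(n, 1, 0.5); u <- rnorm(n, 0, 0.8)
  y0 <- 1 + 0.2 * age0 + 0.3 * sex + u + rnorm(n, 0, 0.4)
  y2 <- 1 + 0.2 * age0 + 1.0 * interval + 0.3 * sex + u + rnorm(n, 0, 0.4)
  fit <- fit_lmm_change(y0, y2, age0, interval, sex)
  expect_lt(abs(fit$coefficients[["tdelta"]] - 1.0), 0.1)
  expect_equal(sign(fit$cohen_d), sign(fit$coefficients[["tdelta"]]))
  expect_equal(fit$cohen_d, 2 * fit$t_interval / sqrt(fit$df_interval))

  # zero planted change, tiny noise
  y2b <- y0 + rnorm(n, 0, 0.01)
  fit0 <- fit_lmm_change(y0, y2b, age0, interval, sex)
  expect_lt(abs(fit0$coefficients[["tdelta"]]), 0.02)

  # near-equivalence with the paired change-score regression
  paired <- summary(lm(I(y2 - y0) ~ 0 + interval))$coefficients
  expect_lt(abs(fit$t_interval / paired[1, "t value"] - 1), 0.01)
})

test_that("change scores subtract, residualize and respect shift invariance", {
  set.seed(4)
  n <- 4
  x0 <- matrix(c(1, 2, 3, 4), n, 1)
  x2 <- matrix(c(2, 2, 5, 3), n, 1)
  covars <- data.frame(z = c(0, 1, 0, 1))
  got <- change_scores(x0, x2, covars)
  d <- x2 - x0
  expect_equal(got$change, residualize(d, covars), tolerance = 1e-12)
  expect_equal(got$change_raw, d)
  # identical timepoints -> zero change
  expect_true(all(change_scores(x0, x0)$change_raw == 0))
  # adding a constant to both timepoints changes nothing
  shifted <- change_scores(x0 + 5, x2 + 5, covars)
  expect_equal(shifted$change, got$change, tolerance = 1e-12)
})

test_that("rate of change is the elementwise ratio", {
  x0 <- matrix(c(0, 1), 2, 2); x2 <- matrix(c(0.14, 1.14), 2, 2)
  got <- rate_of_change(x0, x2, c(10, 10), c(12, 12))
  expect_equal(got, matrix(0.07, 2, 2))
  expect_equal(rate_of_change(x0, x0, c(10, 10), c(12, 12)),
               matrix(0, 2, 2))
  # random table equals a brute-force loop
  set.seed(5)
  a <- matrix(rnorm(12), 4); b <- matrix(rnorm(12), 4)
  age0 <- runif(4, 9, 11); age2 <- age0 + runif(4, 1.5, 2.5)
  got2 <- rate_of_change(a, b, age0, age2)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(got2[i, j], (b[i, j] - a[i, j]) / (age2[i] - age0[i]))
  }
  expect_error(rate_of_change(a, b, age0, age0), "zero or negative")
})

test_that("PC1 transfer uses reference statistics and loadings unchanged", {
  set.seed(6)
  # z-scoring makes PC1 scale-free, so dominance must come from shared
  # correlation: three measures on a common factor and one independent
  n <- 400
  f <- rnorm(n)
  X <- cbind(a = f + 0.1 * rnorm(n), b = f + 0.1 * rnorm(n),
             c = f + 0.1 * rnorm(n), d = rnorm(n))
  m <- derive_pc1(X, anchor = "a")
  expect_gt(m$loadings[["a"]], 0)
  expect_equal(sum(m$loadings^2), 1, tolerance = 1e-12)
  # round trip on the reference equals reference PCA scores
  Z <- scale(X)
  ref_scores <- prcomp(Z, center = FALSE)$x[, 1]
  if (cor(ref_scores, apply_pc1(m, X)) < 0) ref_scores <- -ref_scores
  expect_equal(apply_pc1(m, X), as.numeric(ref_scores), tolerance = 1e-9)
  # equicorrelation: seven measures at pairwise r = 0.4
  rho <- 0.4; p <- 7; n2 <- 5000
  S <- matrix(rho, p, p); diag(S) <- 1
  Y <- matrix(rnorm(n2 * p), n2) %*% chol(S)
  m2 <- derive_pc1(Y)
  expect_lt(abs(m2$explained - (1 + (p - 1) * rho) / p), 0.03)
  expect_error(derive_pc1(cbind(rnorm(10), rep(1, 10))), "zero-variance")
})

test_that("cohort summary change means equal differences of timepoint means", {
  y0 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, dimnames = list(NULL, c("a", "b")))
  y2 <- matrix(c(2, 4, 6, 5, 7, 9), 3, 2, dimnames = list(NULL, c("a", "b")))
  s <- cohort_summary(y0, y2)
  expect_equal(s$mean_change, s$mean_y2 - s$mean_y0, tolerance = 1e-9)
  expect_equal(s$mean_y0, c(2, 5))
  expect_equal(s$sd_y0, c(1, 1))
  const <- matrix(1, 3, 1)
  expect_equal(cohort_summary(const, const)$sd_change, 0)
  y0na <- y0; y0na[1, 1] <- NA
  expect_warning(s2 <- cohort_summary(y0na, y2), "pairwise")
  expect_equal(s2$mean_change[1], mean((y2 - y0)[2:3, 1]))
})
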