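test_that("site clustering follows the greedy rule and its invariants", {
  # ten equal sites, ten clusters: singletons
  s10 <- setNames(rep(300, 10), paste0("s", 1:10))
  cl <- make_site_clusters(s10, 10, 280)
  expect_equal(sort(unname(cl$sizes)), rep(300, 10))
  expect_equal(length(unique(cl$cluster_of)), 10)
  # hand-run of the greedy rule
  sz <- setNames(c(500, 400, 300, 200, 100, 100), paste0("site", 1:6))
  cl2 <- make_site_clusters(sz, 3, 500)
  groups <- split(names(cl2$cluster_of), cl2$cluster_of)
  members <- lapply(groups, function(g) sort(unname(sz[g])))
  expect_true(any(vapply(members, identical, logical(1), y = 500)))
  expect_true(any(vapply(members, identical, logical(1),
                         y = c(100, 400))))
  expect_true(any(vapply(members, identical, logical(1),
                         y = c(100, 200, 300))))
  expect_equal(sort(unname(cl2$sizes)), c(500, 500, 600))
  # infeasibility reports the achievable bound
  expect_error(make_site_clusters(sz, 3, 510), "max achievable")
  expect_error(make_site_clusters(sz, 3, 600), "infeasible")
  # invariant: no site split, all clusters at min size
  set.seed(1)
  rs <- setNames(sample(50:400, 12), paste0("x", 1:12))
  cl3 <- make_site_clusters(rs, 4, min_size = 200)
  expect_true(all(cl3$sizes >= 200))
  expect_equal(sum(cl3$sizes), sum(rs))
})

test_that("fold combinatorics: C(10,3) folds, each cluster in 36 test sets", {
  combos <- utils::combn(10, 3)
  expect_equal(ncol(combos), 120)
  expect_true(all(table(as.vector(combos)) == 36))
  # and the CV driver enumerates exactly those folds
  setup <- tiny_prediction_setup()
  set.seed(2)
  X <- matrix(rnorm(96 * 10), 96)
  res <- nested_cv_krr(X, rnorm(96), NULL, setup$site, setup$clustering,
                       setup$config)
  expect_equal(nrow(res$folds), choose(4, 1))
})

test_that("planted signal is recovered and the ridge limit collapses", {
  set.seed(3)
  n <- 300; p <- 20
  site <- rep(paste0("s", 1:10), each = 30)
  cl <- make_site_clusters(c(table(site)), 5, 30)
  X <- matrix(rnorm(n * p), n)
  w <- c(rep(1, 10), rep(0, p - 10))
  y <- as.numeric(X %*% w) + rnorm(n, 0, 0.5)
  cfg <- prediction_config(kernel = "linear",
                           lambda_grid = 10^seq(-3, 3, length.out = 8),
                           inner_folds = 5, n_test_clusters = 2, seed = 1)
  res <- nested_cv_krr(X, y, NULL, site, cl, cfg)
  expect_gt(res$mean_r, 0.8)
  expect_equal(nrow(res$folds), choose(5, 2))
  # null coupling: mean r near zero across seeds
  rs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    nested_cv_krr(matrix(rnorm(n * p), n), rnorm(n), NULL, site, cl,
                  cfg)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  # huge penalty: predictions collapse to the training mean
  cfg_inf <- prediction_config(kernel = "linear", lambda_grid = 1e8,
                               inner_folds = 3, n_test_clusters = 2,
                               seed = 1)
  res_inf <- nested_cv_krr(X, y, NULL, site, cl, cfg_inf)
  spread <- vapply(res_inf$models,
                   function(m) stats::sd(m$predicted), numeric(1))
  expect_lt(max(spread) / stats::sd(y), 0.01)
  means <- vapply(res_inf$models, function(m) {
    mean(m$predicted) - m$y_mean
  }, numeric(1))
  expect_lt(max(abs(means)) / stats::sd(y), 0.01)
})

test_that("site-stratified inner folds keep each site in one fold", {
  setup <- tiny_prediction_setup()
  set.seed(9)
  X <- matrix(rnorm(96 * 15), 96)
  y <- X[, 1] + rnorm(96, 0, 0.5)
  cfg <- prediction_config(lambda_grid = 10^seq(-2, 2, length.out = 4),
                           inner_folds = 3, n_test_clusters = 1, seed = 1,
                           inner_site_stratified = TRUE)
  res <- nested_cv_krr(X, y, NULL, setup$site, setup$clustering, cfg)
  expect_true(all(is.finite(res$folds$r)))
})

test_that("no leakage: permuting test targets cannot change the models", {
  setup <- tiny_prediction_setup()
  set.seed(4)
  X <- matrix(rnorm(96 * 15), 96)
  y <- as.numeric(X[, 1]) + rnorm(96, 0, 0.5)
  res <- nested_cv_krr(X, y, NULL, setup$site, setup$clustering,
                       setup$config)
  y_perm <- y
  te <- res$models[[1]]$test_idx
  y_perm[te] <- sample(y[te])
  res2 <- nested_cv_krr(X, y_perm, NULL, setup$site, setup$clustering,
                        setup$config)
  expect_identical(res$models[[1]]$alpha, res2$models[[1]]$alpha)
  expect_identical(res$folds$lambda[1], res2$folds$lambda[1])
})

test_that("covariate coefficients come from the training set only", {
  setup <- tiny_prediction_setup()
  set.seed(5)
  X <- matrix(rnorm(96 * 15), 96)
  covars <- data.frame(age = rnorm(96, 10), sex = rbinom(96, 1, 0.5))
  y <- X[, 1] + 0.8 * covars$age + rnorm(96, 0, 0.5)
  res <- nested_cv_krr(X, y, covars, setup$site, setup$clustering,
                       setup$config)
  m <- res$models[[1]]
  D <- cbind(1, as.matrix(covars))[m$train_idx, ]
  oracle <- qr.coef(qr(D), y[m$train_idx])
  expect_equal(unname(m$cov_coef), unname(oracle), tolerance = 1e-10)
})

test_that("model transfer reuses folds and detects broken pairings", {
  setup <- tiny_prediction_setup()
  set.seed(6)
  X <- matrix(rnorm(96 * 15), 96)
  y <- as.numeric(X[, 1] + X[, 2]) + rnorm(96, 0.4)
  res <- nested_cv_krr(X, y, NULL, setup$site, setup$clustering,
                       setup$config)
  # self-transfer reproduces the original accuracies
  self <- transfer_model(res, X, y)
  expect_equal(self$folds$r, res$folds$r, tolerance = 1e-10)
  # permuted targets destroy accuracy
  set.seed(7)
  perm <- transfer_model(res, X, sample(y))
  expect_lt(abs(perm$mean_r), 0.3)
  expect_error(transfer_model(res, X[, 1:10], y), "feature space")
})

test_that("transfer to a cleaner follow-up improves accuracy", {
  # same planted coupling at both timepoints, lower noise at follow-up
  wins <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 150; p <- 20
    site <- rep(paste0("s", 1:6), each = 25)
    cl <- make_site_clusters(c(table(site)), 3, 25)
    cfg <- prediction_config(lambda_grid = 10^seq(-2, 2, length.out = 5),
                             inner_folds = 3, n_test_clusters = 1, seed = s)
    signal <- matrix(rnorm(n * p), n)
    X0 <- signal + matrix(rnorm(n * p), n)
    X2 <- signal + 0.4 * matrix(rnorm(n * p), n)
    truth <- as.numeric(signal %*% c(rep(1, 5), rep(0, p - 5)))
    y0 <- truth + rnorm(n, 0, 2)
    y2 <- truth + rnorm(n, 0, 0.8)
    base <- nested_cv_krr(X0, y0, NULL, site, cl, cfg)
    moved <- transfer_model(base, X2, y2)
    moved$mean_r > base$mean_r
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("Haufe features equal Cov(X) w for linear predictors", {
  set.seed(8)
  X <- matrix(rnorm(50 * 20), 50)
  w <- rnorm(20)
  yhat <- as.numeric(X %*% w)
  pnf <- haufe_pnf(X, yhat)
  expect_equal(pnf$values, as.numeric(cov(X) %*% w), tolerance = 1e-8)
  # single-feature predictor: variance on itself, covariance elsewhere
  p1 <- haufe_pnf(X, X[, 3])
  expect_equal(p1$values[3], var(X[, 3]), tolerance = 1e-12)
  expect_equal(p1$values[1], cov(X[, 1], X[, 3]), tolerance = 1e-12)
  # constant predictions: all-zero features
  expect_true(all(haufe_pnf(X, rep(1, 50))$values == 0))
  expect_equal(sd(pnf$values_normalized), 1, tolerance = 1e-12)
  m <- pnf_matrix(haufe_pnf(matrix(rnorm(40 * 6), 40),
                            rnorm(40)))
  expect_true(isSymmetric(m))
})
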