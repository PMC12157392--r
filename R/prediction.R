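# Site-cluster construction, nested leave-cluster-out kernel ridge
# regression with covariate-coefficient transfer, cross-timepoint model
# transfer, and Haufe-transform predictive network features.

#' Group acquisition sites into cross-validation clusters
#'
#' Greedy bin packing: sites are sorted by size (largest first, ties by
#' label) and each is assigned to the currently smallest cluster; when
#' several clusters tie for smallest, assignment continues round-robin from
#' the previously used cluster. Sites are never split across clusters;
#' every cluster must reach `min_size` participants.
#'
#' @param site_sizes named integer vector of participants per site.
#' @param n_clusters number of clusters (default 10).
#' @param min_size minimum participants per cluster (default 280).
#' @return object of class `site_clustering`: `cluster_of` (named integer
#'   vector site -> cluster), `sizes`, `n_clusters`, `min_size`.
#' @export
make_site_clusters <- function(site_sizes, n_clusters = 10, min_size = 280) {
  if (is.null(names(site_sizes))) names(site_sizes) <- paste0("site", seq_along(site_sizes))
  if (sum(site_sizes) < n_clusters * min_size) {
    stop("infeasible clustering: total ", sum(site_sizes), " < ",
         n_clusters, " x ", min_size)
  }
  ord <- order(-site_sizes, names(site_sizes))
  cluster_of <- integer(length(site_sizes)); names(cluster_of) <- names(site_sizes)
  sizes <- rep(0L, n_clusters)
  last <- 0L
  for (s in ord) {
    cand <- which(sizes == min(sizes))
    k <- cand[which.min((cand - last - 1L) %% n_clusters)]
    cluster_of[s] <- k
    sizes[k] <- sizes[k] + site_sizes[s]
    last <- k
  }
  if (min(sizes) < min_size) {
    stop("infeasible clustering: max achievable minimum cluster size is ",
         min(sizes), " < ", min_size)
  }
  structure(list(cluster_of = cluster_of, sizes = sizes,
                 n_clusters = n_clusters, min_size = min_size),
            class = "site_clustering")
}

#' @export
print.site_clustering <- function(x, ...) {
  cat("site_clustering:", length(x$cluster_of), "sites ->", x$n_clusters,
      "clusters; sizes", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Prediction configuration
#'
#' @param kernel `"correlation"` (default; correlation between participants'
#'   edge vectors), `"linear"` or `"gaussian"`.
#' @param lambda_grid positive regularization grid; default 16 values
#'   log-spaced in `[1e-4, 1e4]`.
#' @param inner_folds inner cross-validation folds for lambda selection.
#' @param n_test_clusters clusters held out per fold (default 3).
#' @param seed seed for the inner-fold assignment.
#' @param inner_site_stratified keep each training site within a single
#'   inner fold (default: plain participant-level folds).
#' @return list of class `prediction_config`.
#' @export
prediction_config <- function(kernel = c("correlation", "linear", "gaussian"),
                              lambda_grid = 10^seq(-4, 4, length.out = 16),
                              inner_folds = 10, n_test_clusters = 3,
                              seed = 1, inner_site_stratified = FALSE) {
  kernel <- match.arg(kernel)
  if (any(lambda_grid <= 0)) stop("lambda_grid must be positive")
  structure(list(kernel = kernel, lambda_grid = sort(lambda_grid),
                 inner_folds = inner_folds,
                 n_test_clusters = n_test_clusters, seed = seed,
                 inner_site_stratified = inner_site_stratified),
            class = "prediction_config")
}

kernel_params <- function(X, kernel) {
  if (kernel == "gaussian") {
    idx <- seq_len(min(nrow(X), 200L))
    d <- stats::dist(X[idx, , drop = FALSE])
    list(h = stats::median(d))
  } else list()
}

kernel_cross <- function(A, B, kernel, params) {
  switch(kernel,
    correlation = {
      za <- t(scale(t(A))); zb <- t(scale(t(B)))
      tcrossprod(za, zb) / (ncol(A) - 1)
    },
    linear = tcrossprod(A, B) / ncol(A),
    gaussian = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      exp(-pmax(d2, 0) / (2 * params$h^2))
    })
}

krr_solve <- function(K_tr, y_c, lambda) {
  m <- nrow(K_tr)
  a <- tryCatch(solve(K_tr + diag(lambda, m), y_c), error = function(e) NULL)
  if (is.null(a)) {   # indefinite after centering: jitter and retry
    message("kernel not positive definite; adding jitter")
    a <- solve(K_tr + diag(lambda + 1e-6 * m, m), y_c)
  }
  a
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

# inner CV over the lambda grid via one eigendecomposition per inner fold
select_lambda <- function(K, y, folds, lambda_grid) {
  scores <- matrix(NA_real_, length(unique(folds)), length(lambda_grid))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); va <- which(folds == f)
    ym <- mean(y[tr]); yc <- y[tr] - ym
    eg <- eigen(K[tr, tr, drop = FALSE], symmetric = TRUE)
    uty <- crossprod(eg$vectors, yc)
    Kva <- K[va, tr, drop = FALSE] %*% eg$vectors
    for (li in seq_along(lambda_grid)) {
      alpha_t <- uty / (pmax(eg$values, 0) + lambda_grid[li])
      pred <- Kva %*% alpha_t + ym
      scores[f, li] <- safe_cor(as.numeric(pred), y[va])
    }
  }
  mean_r <- colMeans(scores, na.rm = TRUE)
  lambda_grid[which.max(mean_r)]
}

#' Nested leave-clusters-out kernel ridge regression
#'
#' For every combination of `n_test_clusters` held-out site clusters (all
#' `choose(n_clusters, n_test_clusters)` of them): covariates are regressed
#' from the training targets by OLS and the training coefficients applied
#' to the test targets; an inner K-fold cross-validation on the training
#' participants selects the ridge penalty by mean inner Pearson r; the
#' final model is fit on the full training set and evaluated as the Pearson
#' correlation between predicted and observed (residualized) test targets.
#' The summary accuracy is the arithmetic mean of the per-fold r.
#'
#' @param X participant x edge feature matrix.
#' @param y target vector.
#' @param covariates per-participant covariate data.frame (regressed from
#'   the target only), or `NULL`.
#' @param site site label per participant.
#' @param clustering a [make_site_clusters()] object.
#' @param config a [prediction_config()].
#' @return object of class `prediction_result`: `folds` (data.frame with
#'   test clusters, chosen lambda, fold r), `mean_r`, per-fold model state
#'   for transfer and Haufe analysis, and the inputs needed to re-apply the
#'   models.
#' @export
nested_cv_krr <- function(X, y, covariates = NULL, site, clustering, config) {
  stopifnot(inherits(clustering, "site_clustering"),
            inherits(config, "prediction_config"))
  X <- as.matrix(X); n <- nrow(X)
  stopifnot(length(y) == n, length(site) == n)
  if (config$n_test_clusters >= clustering$n_clusters) {
    stop("n_test_clusters must be smaller than the number of clusters")
  }
  cluster <- clustering$cluster_of[as.character(site)]
  if (anyNA(cluster)) stop("participant with site outside the clustering")
  params <- kernel_params(X, config$kernel)
  K <- kernel_cross(X, X, config$kernel, params)
  combos <- utils::combn(clustering$n_clusters, config$n_test_clusters)
  C_mat <- if (is.null(covariates)) NULL else as.matrix(covariates)

  models <- vector("list", ncol(combos))
  fold_rows <- vector("list", ncol(combos))
  for (fi in seq_len(ncol(combos))) {
    test_cl <- combos[, fi]
    te <- which(cluster %in% test_cl)
    tr <- which(!(cluster %in% test_cl))
    if (length(unique(site[tr])) < 2) stop("training set spans < 2 sites")
    # covariate regression on train, coefficients transferred to test
    if (is.null(C_mat)) {
      cov_coef <- NULL
      ytr <- y[tr]; yte <- y[te]
    } else {
      D <- cbind(1, C_mat)
      cov_coef <- qr.coef(qr(D[tr, , drop = FALSE]), y[tr])
      ytr <- y[tr] - D[tr, , drop = FALSE] %*% cov_coef
      yte <- y[te] - D[te, , drop = FALSE] %*% cov_coef
    }
    ytr <- as.numeric(ytr); yte <- as.numeric(yte)
    inner <- with_seed(config$seed * 1009L + fi, {
      if (isTRUE(config$inner_site_stratified)) {
        # whole sites assigned to inner folds, largest first into the
        # currently smallest fold
        tr_sites <- table(droplevels(factor(site[tr])))
        fold_of_site <- integer(length(tr_sites))
        names(fold_of_site) <- names(tr_sites)
        fsize <- rep(0L, config$inner_folds)
        for (s in order(-tr_sites, names(tr_sites))) {
          k <- which.min(fsize)
          fold_of_site[s] <- k
          fsize[k] <- fsize[k] + tr_sites[s]
        }
        unname(fold_of_site[as.character(site[tr])])
      } else {
        sample(rep_len(seq_len(config$inner_folds), length(tr)))
      }
    })
    lambda <- select_lambda(K[tr, tr, drop = FALSE], ytr, inner,
                            config$lambda_grid)
    ym <- mean(ytr)
    alpha <- krr_solve(K[tr, tr, drop = FALSE], ytr - ym, lambda)
    pred <- as.numeric(K[te, tr, drop = FALSE] %*% alpha + ym)
    r <- safe_cor(pred, yte)
    if (is.na(r)) warning("fold ", fi, ": undefined accuracy (constant target or prediction)")
    models[[fi]] <- list(train_idx = tr, test_idx = te, alpha = alpha,
                         y_mean = ym, cov_coef = cov_coef, lambda = lambda,
                         predicted = pred, observed = yte)
    fold_rows[[fi]] <- data.frame(fold = fi,
                                  test_clusters = paste(test_cl, collapse = "+"),
                                  lambda = lambda, r = r)
  }
  folds <- do.call(rbind, fold_rows)
  structure(list(folds = folds, mean_r = mean(folds$r, na.rm = TRUE),
                 models = models, X = X, kernel = config$kernel,
                 kernel_params = params, cluster = cluster,
                 config = config),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result:", nrow(x$folds), "folds, mean r =",
      format(x$mean_r, digits = 4), "\n")
  invisible(x)
}

#' Apply trained fold models to new data without refitting
#'
#' Re-uses every fold's trained kernel ridge model and training-derived
#' covariate coefficients on a new feature/target table (e.g. a later
#' timepoint): the stored coefficients residualize the new targets, the
#' stored dual weights predict from the cross-kernel between new test
#' participants and the original training participants, and per-fold test
#' clusters are unchanged.
#'
#' @param result a [nested_cv_krr()] result.
#' @param X_new new feature matrix, same participants and feature space as
#'   the training matrix.
#' @param y_new new target vector.
#' @param covars_new covariates matching the columns used at training.
#' @return `prediction_result` with transferred per-fold accuracies.
#' @export
transfer_model <- function(result, X_new, y_new, covars_new = NULL) {
  stopifnot(inherits(result, "prediction_result"))
  X_new <- as.matrix(X_new)
  if (!identical(dim(X_new), dim(result$X))) {
    stop("feature space mismatch with the trained models")
  }
  C_mat <- if (is.null(covars_new)) NULL else as.matrix(covars_new)
  fold_rows <- vector("list", length(result$models))
  models <- result$models
  for (fi in seq_along(models)) {
    m <- models[[fi]]
    te <- m$test_idx
    yte <- if (is.null(m$cov_coef)) y_new[te] else {
      D <- cbind(1, C_mat)
      as.numeric(y_new[te] - D[te, , drop = FALSE] %*% m$cov_coef)
    }
    Kc <- kernel_cross(X_new[te, , drop = FALSE],
                       result$X[m$train_idx, , drop = FALSE],
                       result$kernel, result$kernel_params)
    pred <- as.numeric(Kc %*% m$alpha + m$y_mean)
    r <- safe_cor(pred, yte)
    models[[fi]]$predicted <- pred
    models[[fi]]$observed <- yte
    fold_rows[[fi]] <- data.frame(fold = fi,
                                  test_clusters = result$folds$test_clusters[fi],
                                  lambda = m$lambda, r = r)
  }
  folds <- do.call(rbind, fold_rows)
  structure(list(folds = folds, mean_r = mean(folds$r, na.rm = TRUE),
                 models = models, X = result$X, kernel = result$kernel,
                 kernel_params = result$kernel_params,
                 cluster = result$cluster, config = result$config),
            class = "prediction_result")
}

#' Haufe-transform predictive network features
#'
#' The predictive network feature (PNF) of an edge is the covariance,
#' across participants, between the edge's value and the model's predicted
#' target. For matrices this is computed directly; for a
#' [nested_cv_krr()] result each fold's model predicts its own training
#' participants and the per-fold PNF vectors are averaged. Positive values
#' mean higher connectivity goes with a higher predicted score.
#'
#' @param x feature matrix (participants x edges) or a `prediction_result`.
#' @param y_predicted predicted target for the same participants (matrix
#'   method only).
#' @return object of class `pnf`: `values` (per-edge covariance),
#'   `norm_constant` (SD of the values), `values_normalized` (SD 1).
#' @export
haufe_pnf <- function(x, y_predicted = NULL) {
  vals <- if (inherits(x, "prediction_result")) {
    per_fold <- lapply(x$models, function(m) {
      tr <- m$train_idx
      if (length(tr) < 2) stop("single-participant fold")
      K <- kernel_cross(x$X[tr, , drop = FALSE], x$X[tr, , drop = FALSE],
                        x$kernel, x$kernel_params)
      yhat <- as.numeric(K %*% m$alpha + m$y_mean)
      as.numeric(stats::cov(x$X[tr, , drop = FALSE], yhat))
    })
    Reduce(`+`, per_fold) / length(per_fold)
  } else {
    if (nrow(as.matrix(x)) < 2) stop("single-participant fold")
    as.numeric(stats::cov(as.matrix(x), as.numeric(y_predicted)))
  }
  nc <- stats::sd(vals)
  structure(list(values = vals,
                 norm_constant = nc,
                 values_normalized = if (nc > 0) vals / nc else vals),
            class = "pnf")
}

#' Fold a PNF edge vector into a symmetric region matrix
#' @param pnf a `pnf` object (or numeric edge vector).
#' @param normalized fold the SD-1 normalized values instead of raw.
#' @return symmetric region x region matrix with zero diagonal.
#' @export
pnf_matrix <- function(pnf, normalized = FALSE) {
  v <- if (inherits(pnf, "pnf")) {
    if (normalized) pnf$values_normalized else pnf$values
  } else pnf
  vec_to_mat(v)
}
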