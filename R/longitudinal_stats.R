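# Stability, group-level change (mixed models), individual change scores,
# transferred-loading PC1, and cohort summary tables.

#' Residualize features on covariates
#'
#' Ordinary least-squares residuals per feature, with an intercept added to
#' the design. Errors on a rank-deficient design.
#'
#' @param values participant x feature matrix (or vector).
#' @param covariates data.frame/matrix of covariates, or `NULL` (centering
#'   only).
#' @return matrix of residuals with the shape of `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  ols_residuals(as.matrix(values), covariates)
}

#' Between-timepoint Spearman stability of residualized features
#'
#' Each timepoint's features are first residualized on that timepoint's
#' covariates (e.g. age and sex at that visit); Spearman's rank correlation
#' across participants between the two residualized timepoints is then the
#' stability of each feature, with a two-sided t-approximation p-value.
#'
#' @param x_y0,x_y2 participant x feature matrices, aligned participants.
#' @param covars_y0,covars_y2 per-timepoint covariates (or `NULL`).
#' @return data.frame with `feature`, `rho`, `p`. Features whose residuals
#'   are constant get `NA` with a warning.
#' @export
spearman_stability <- function(x_y0, x_y2, covars_y0 = NULL,
                               covars_y2 = NULL) {
  x_y0 <- as.matrix(x_y0); x_y2 <- as.matrix(x_y2)
  stopifnot(identical(dim(x_y0), dim(x_y2)))
  n <- nrow(x_y0)
  if (n < 10) stop("need at least 10 participants")
  r0 <- residualize(x_y0, covars_y0)
  r2 <- residualize(x_y2, covars_y2)
  sd0 <- apply(r0, 2, stats::sd); sd2 <- apply(r2, 2, stats::sd)
  bad <- sd0 == 0 | sd2 == 0
  if (any(bad)) warning(sum(bad), " feature(s) with constant residuals: rho = NA")
  rho <- rep(NA_real_, ncol(r0))
  ok <- which(!bad)
  if (length(ok) > 0) {
    rho[ok] <- diag(stats::cor(apply(r0[, ok, drop = FALSE], 2, rank),
                               apply(r2[, ok, drop = FALSE], 2, rank)))
  }
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  data.frame(feature = colnames(x_y0) %||% paste0("f", seq_along(rho)),
             rho = rho, p = p, row.names = NULL)
}

#' Group-level longitudinal change from a linear mixed model
#'
#' Fits, per feature, the two-timepoint mixed model
#' `y_it = b0 + b1 * age_baseline_i + b2 * (age_it - age_i1) + b3 * sex_i
#' [+ b4 * fd_it] + u_i + eps_it` by REML with a participant random
#' intercept. The t-statistic of the age-interval coefficient `b2`
#' (Satterthwaite degrees of freedom) measures group-level change and is
#' converted to an effect size as `d = 2 t / sqrt(df)` (a stated,
#' switchable convention).
#'
#' @param y0,y2 numeric vectors (one feature) or single-column matrices.
#' @param age_y0 baseline age per participant.
#' @param interval age interval (age_y2 - age_y0) per participant.
#' @param sex numeric/factor sex per participant.
#' @param fd optional list of two per-timepoint motion vectors, adding the
#'   time-varying mean-FD covariate.
#' @param d_fun conversion from (t, df) to effect size; default `2t/sqrt(df)`.
#' @return object of class `lmm_result`: `coefficients`, `t_interval`,
#'   `df_interval`, `cohen_d`, `ranef_var`, `resid_var`.
#' @export
fit_lmm_change <- function(y0, y2, age_y0, interval, sex, fd = NULL,
                           d_fun = function(t, df) 2 * t / sqrt(df)) {
  n <- length(y0)
  stopifnot(length(y2) == n, length(age_y0) == n, length(interval) == n)
  dat <- data.frame(
    y = c(y0, y2), id = factor(rep(seq_len(n), 2)),
    age0 = rep(age_y0, 2), tdelta = c(rep(0, n), interval),
    sex = rep(as.numeric(sex), 2))
  form <- y ~ age0 + tdelta + sex + (1 | id)
  if (!is.null(fd)) {
    dat$fd <- c(fd[[1]], fd[[2]])
    form <- y ~ age0 + tdelta + sex + fd + (1 | id)
  }
  fit <- lmerTest::lmer(form, data = dat,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
  co <- summary(fit)$coefficients
  tval <- co["tdelta", "t value"]
  dfv <- co["tdelta", "df"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = co[, "Estimate"],
                 t_interval = tval, df_interval = dfv,
                 cohen_d = d_fun(tval, dfv),
                 ranef_var = vc$vcov[vc$grp == "id"],
                 resid_var = vc$vcov[vc$grp == "Residual"]),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("lmm_result: interval coefficient =",
      format(x$coefficients["tdelta"], digits = 4),
      " t =", format(x$t_interval, digits = 4),
      " df =", format(x$df_interval, digits = 4),
      " d =", format(x$cohen_d, digits = 4), "\n")
  invisible(x)
}

#' Individual change scores with covariate residualization
#'
#' Per-participant difference (follow-up minus baseline) per feature,
#' residualized across participants on the supplied covariates (typically
#' sex, baseline age and age interval).
#'
#' @param x_y0,x_y2 participant x feature matrices.
#' @param covariates data.frame of per-participant covariates or `NULL`
#'   (raw differences are returned unresidualized).
#' @return list with `change` (residualized when covariates given, raw
#'   otherwise), `change_raw`, and `sd` (across-participant SD of the
#'   residualized change per feature).
#' @export
change_scores <- function(x_y0, x_y2, covariates = NULL) {
  x_y0 <- as.matrix(x_y0); x_y2 <- as.matrix(x_y2)
  stopifnot(identical(dim(x_y0), dim(x_y2)))
  d <- x_y2 - x_y0
  dres <- if (is.null(covariates)) d else residualize(d, covariates)
  list(change = dres, change_raw = d, sd = apply(dres, 2, stats::sd))
}

#' Annualized rate of change
#'
#' Elementwise `(x_y2 - x_y0) / (age_y2 - age_y0)` per participant and
#' feature.
#'
#' @param x_y0,x_y2 participant x feature matrices.
#' @param age_y0,age_y2 ages per participant; every interval must be > 0.
#' @return matrix of per-year rates.
#' @export
rate_of_change <- function(x_y0, x_y2, age_y0, age_y2) {
  x_y0 <- as.matrix(x_y0); x_y2 <- as.matrix(x_y2)
  iv <- age_y2 - age_y0
  if (any(iv <= 0)) stop("zero or negative age interval")
  (x_y2 - x_y0) / iv
}

#' Derive a transferred-loading first principal component
#'
#' Learns PC1 on a held-out reference sample: measures are z-scored with
#' the reference means and SDs, PC1 loadings come from the reference
#' covariance, and the sign is oriented so the anchor measure's loading is
#' positive. [apply_pc1()] scores new tables with the reference statistics
#' and loadings unchanged (no re-normalization on the target sample),
#' preventing leakage between reference and analysis samples.
#'
#' @param reference_table participant x measure matrix (no missing values,
#'   more rows than measures).
#' @param anchor measure name (or index) whose loading is forced positive;
#'   default: first measure.
#' @return object of class `pc1_model`: `means`, `sds`, `loadings`
#'   (unit norm), `anchor`, `explained` (PC1 variance fraction).
#' @export
derive_pc1 <- function(reference_table, anchor = 1) {
  X <- as.matrix(reference_table)
  if (anyNA(X)) stop("missing values in reference table")
  if (nrow(X) < ncol(X) + 1) stop("reference needs more rows than measures")
  mu <- colMeans(X); sdev <- apply(X, 2, stats::sd)
  if (any(sdev == 0)) stop("zero-variance measure in reference")
  Z <- scale(X, center = mu, scale = sdev)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  v <- pc$rotation[, 1]
  a_idx <- if (is.character(anchor)) match(anchor, colnames(X)) else anchor
  if (is.na(a_idx)) stop("anchor measure not found")
  if (v[a_idx] < 0) v <- -v
  structure(list(means = mu, sds = sdev, loadings = v,
                 anchor = (colnames(X) %||% seq_len(ncol(X)))[a_idx],
                 explained = pc$sdev[1]^2 / sum(pc$sdev^2)),
            class = "pc1_model")
}

#' @rdname derive_pc1
#' @param model a `pc1_model`.
#' @param table participant x measure matrix with the reference's measures.
#' @return numeric vector of PC1 scores.
#' @export
apply_pc1 <- function(model, table) {
  X <- as.matrix(table)
  stopifnot(inherits(model, "pc1_model"), ncol(X) == length(model$loadings))
  Z <- scale(X, center = model$means, scale = model$sds)
  as.numeric(Z %*% model$loadings)
}

#' Cohort summary of timepoint and change statistics
#'
#' Per measure: mean and SD at baseline, at follow-up, and of the
#' per-participant longitudinal change (follow-up minus baseline). By
#' construction the change mean equals the difference of the timepoint
#' means. Missing values are excluded pairwise with a warning.
#'
#' @param cognition_y0,cognition_y2 participant x measure matrices.
#' @return data.frame with columns `measure`, `mean_y0`, `sd_y0`,
#'   `mean_y2`, `sd_y2`, `mean_change`, `sd_change`.
#' @export
cohort_summary <- function(cognition_y0, cognition_y2) {
  y0 <- as.matrix(cognition_y0); y2 <- as.matrix(cognition_y2)
  stopifnot(identical(dim(y0), dim(y2)))
  if (anyNA(y0) || anyNA(y2)) {
    warning("missing values excluded pairwise")
    drop <- is.na(y0) | is.na(y2)
    y0[drop] <- NA; y2[drop] <- NA
  }
  d <- y2 - y0
  data.frame(
    measure = colnames(y0) %||% paste0("m", seq_len(ncol(y0))),
    mean_y0 = colMeans(y0, na.rm = TRUE),
    sd_y0 = apply(y0, 2, stats::sd, na.rm = TRUE),
    mean_y2 = colMeans(y2, na.rm = TRUE),
    sd_y2 = apply(y2, 2, stats::sd, na.rm = TRUE),
    mean_change = colMeans(d, na.rm = TRUE),
    sd_change = apply(d, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
}
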