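# FC construction from censored multi-run time series, and the
# autocorrelation-aware per-edge change z-statistic.

#' Build a functional-connectivity edge vector from censored runs
#'
#' Per run, Pearson correlations over uncensored frames are computed for
#' every region pair; correlations are Fisher r-to-z transformed, averaged
#' across runs, and also converted back to the r scale after averaging.
#' Runs with fewer than 5 uncensored frames are skipped with a warning;
#' zero-variance regions have their edges set to 0 with a warning.
#'
#' @param runs list of region x frame matrices (>= 1 run).
#' @param masks list of logical censor vectors (`TRUE` = censored), or `NULL`
#'   for no censoring. One mask per run.
#' @return list with `z` and `r` edge vectors in [edge_index()] order, and
#'   `n_frames_used` (total uncensored frames).
#' @export
build_fc <- function(runs, masks = NULL) {
  if (length(runs) < 1) stop("at least one run is required")
  if (is.null(masks)) masks <- lapply(runs, function(r) rep(FALSE, ncol(r)))
  stopifnot(length(masks) == length(runs))
  R <- nrow(runs[[1]])
  zs <- list(); used <- 0L
  for (k in seq_along(runs)) {
    keep <- !masks[[k]]
    if (sum(keep) < 5) {
      warning("run ", k, " has < 5 uncensored frames; skipped")
      next
    }
    x <- t(runs[[k]][, keep, drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance region(s); their edges set to 0")
    }
    cm <- suppressWarnings(stats::cor(x))
    cm[is.na(cm)] <- 0
    zs[[length(zs) + 1L]] <- fisher_z(ut_vec(cm))
    used <- used + sum(keep)
  }
  if (length(zs) == 0) stop("all runs skipped: no run with >= 5 uncensored frames")
  z <- Reduce(`+`, zs) / length(zs)
  list(z = z, r = fisher_r(z), n_frames_used = used)
}

#' Variance of a Fisher-z correlation, optionally autocorrelation-aware
#'
#' `method = "naive"` returns the white-noise value 1/(n-3). For
#' `method = "autocorr"` an effective sample size replaces n:
#' `n_eff = n / (1 + 2 * sum_l rho_x(l) * rho_y(l))`, with sample
#' autocorrelations truncated at lag `L = floor(sqrt(n))`, the lag sum
#' clipped at -0.49 (keeping the denominator positive), and `n_eff` clipped
#' to `[5, n]`. This is a documented effective-degrees-of-freedom
#' approximation to full autocorrelation-corrected correlation variance
#' estimators.
#'
#' @param x,y numeric series of equal length n >= 20.
#' @param method `"naive"` or `"autocorr"`.
#' @return scalar variance estimate for the Fisher-z correlation of x and y.
#' @export
corr_variance <- function(x, y, method = c("naive", "autocorr")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < 20) stop("need n >= 20")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  if (method == "naive") return(1 / (n - 3))
  L <- floor(sqrt(n))
  rx <- stats::acf(x, lag.max = L, plot = FALSE, demean = TRUE)$acf[-1]
  ry <- stats::acf(y, lag.max = L, plot = FALSE, demean = TRUE)$acf[-1]
  s <- max(sum(rx * ry), -0.49)
  n_eff <- min(max(n / (1 + 2 * s), 5), n)
  1 / (n_eff - 3)
}

#' Per-participant FC-change z-statistic with covariate residualization
#'
#' For each edge and participant the change statistic is
#' `z = (r2 - r0) / sqrt(s2 + s0)`, where `r0`, `r2` are Fisher-z FC values
#' at the two timepoints and `s0`, `s2` their variance estimates. The z
#' values are then residualized edge-wise across participants on the
#' supplied covariates (typically sex, baseline age, age interval, and
#' head motion at both timepoints).
#'
#' @param r0,r2 participant x edge matrices of Fisher-z FC.
#' @param s0,s2 matching variance matrices (strictly positive), or scalars.
#' @param covariates data.frame/matrix of per-participant covariates, or
#'   `NULL` to skip residualization.
#' @return list with `z` (raw) and `z_resid` (residualized) participant x
#'   edge matrices.
#' @export
fc_change_z <- function(r0, r2, s0, s2, covariates = NULL) {
  r0 <- as.matrix(r0); r2 <- as.matrix(r2)
  if (!identical(dim(r0), dim(r2))) stop("mismatched edge order or participants")
  if (!is.null(colnames(r0)) && !is.null(colnames(r2)) &&
      !identical(colnames(r0), colnames(r2))) {
    stop("mismatched edge order between timepoints")
  }
  expand <- function(s) if (length(s) == 1) matrix(s, nrow(r0), ncol(r0)) else as.matrix(s)
  s0 <- expand(s0); s2 <- expand(s2)
  if (any(s0 <= 0) || any(s2 <= 0)) stop("variance estimates must be > 0")
  z <- (r2 - r0) / sqrt(s2 + s0)
  z_resid <- if (is.null(covariates)) {
    sweep(z, 2, colMeans(z))
  } else {
    if (anyNA(covariates)) stop("missing covariate values")
    ols_residuals(z, covariates)
  }
  dimnames(z_resid) <- dimnames(z)
  list(z = z, z_resid = z_resid)
}
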