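# Test-retest reliability: one-way random-effects ICC, the scan-duration
# reliability curve R_T = 1/(1 + k/T) with k = tau^2/sigma^2, change-score
# reliability algebra, and the reliability-matched truncation experiment.

#' One-way random-effects intraclass correlation
#'
#' `ICC = (MSB - MSW) / (MSB + (K - 1) MSW)` from a one-way ANOVA with
#' participants as the random factor and K repeated measures (test/retest:
#' K = 2). Accepts vectors (one feature) or matrices (per-feature columns).
#'
#' @param test,retest per-participant values: vectors or participant x
#'   feature matrices with aligned rows.
#' @return for vectors, an object of class `icc_result` (`icc`, `msb`,
#'   `msw`, `k`, `n`); for matrices, a data.frame with one row per feature.
#' @export
icc_oneway <- function(test, retest) {
  if (is.matrix(test) || is.data.frame(test)) {
    test <- as.matrix(test); retest <- as.matrix(retest)
    stopifnot(identical(dim(test), dim(retest)))
    out <- vapply(seq_len(ncol(test)), function(j) {
      r <- icc_oneway(test[, j], retest[, j])
      c(r$icc, r$msb, r$msw)
    }, numeric(3))
    return(data.frame(feature = colnames(test) %||% paste0("f", seq_len(ncol(test))),
                      icc = out[1, ], msb = out[2, ], msw = out[3, ],
                      row.names = NULL))
  }
  n <- length(test)
  stopifnot(length(retest) == n)
  if (n < 5) stop("need at least 5 participants")
  y <- cbind(test, retest); k <- 2L
  grand <- mean(y)
  rowm <- rowMeans(y)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((y - rowm)^2) / (n * (k - 1))
  if (msb + msw == 0) stop("zero total variance")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc = icc, msb = msb, msw = msw, k = k, n = n),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("icc_result: ICC =", format(x$icc, digits = 4), " (MSB =",
      format(x$msb, digits = 4), ", MSW =", format(x$msw, digits = 4),
      ", n =", x$n, ", k =", x$k, ")\n")
  invisible(x)
}

#' Split-half ICC at a scan duration
#'
#' Computes per-edge ICC between the test and retest halves of a
#' split-half simulation (or any pair of half-duration measurements),
#' truncating both halves to the first `minutes` of data.
#'
#' @param sim an [simulate_split_half_edges()] object, or a list with
#'   `test`/`retest` participant x edge matrices (already at the desired
#'   duration, in which case `minutes` is ignored).
#' @param minutes duration each half is truncated to.
#' @return data.frame of per-edge ICCs (see [icc_oneway()]).
#' @export
split_half_icc <- function(sim, minutes = NULL) {
  halves <- if (inherits(sim, "edge_half_sim")) {
    if (is.null(minutes)) stop("minutes required for an edge_half_sim")
    truncate_halves(sim, minutes)
  } else sim
  icc_oneway(halves$test, halves$retest)
}

#' Fit the scan-duration reliability curve
#'
#' Least-squares fit of `R_T = 1 / (1 + k / T)` over `k >= 0`, per feature,
#' minimizing squared error in reliability space. Only the noise-to-signal
#' ratio `k = tau^2 / sigma^2` (in minutes) is identifiable from
#' reliabilities alone; the fit quality is reported as a coefficient of
#' determination in R-space. Features whose ICCs are all <= 0 are flagged
#' unfittable (`k = NA`) and excluded downstream.
#'
#' @param durations numeric vector of scan durations in minutes (>= 3).
#' @param iccs numeric vector (one feature) or durations x feature matrix.
#' @return object of class `reliability_curve`: `k_ratio`, `cod`,
#'   `durations`, `iccs`, `fittable`.
#' @export
fit_scan_time_curve <- function(durations, iccs) {
  iccs <- if (is.null(dim(iccs))) matrix(iccs, ncol = 1) else as.matrix(iccs)
  stopifnot(length(durations) == nrow(iccs))
  if (length(durations) < 3) stop("need at least 3 (duration, ICC) pairs")
  fit_one <- function(r) {
    if (all(r <= 0)) return(c(NA_real_, NA_real_))
    sse <- function(k) sum((r - 1 / (1 + k / durations))^2)
    grid <- c(0, 10^seq(-4, 5, by = 0.1))
    v <- vapply(grid, sse, numeric(1))
    i <- which.min(v)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
    k <- opt$minimum
    sst <- sum((r - mean(r))^2)
    cod <- if (sst > 0) 1 - opt$objective / sst else
      as.numeric(opt$objective < 1e-20)
    c(k, cod)
  }
  res <- apply(iccs, 2, fit_one)
  structure(list(k_ratio = res[1, ], cod = res[2, ], durations = durations,
                 iccs = iccs, fittable = !is.na(res[1, ])),
            class = "reliability_curve")
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat("reliability_curve:", length(x$k_ratio), "feature(s),",
      sum(!x$fittable), "unfittable; median k =",
      format(stats::median(x$k_ratio, na.rm = TRUE), digits = 4),
      " median COD =", format(stats::median(x$cod, na.rm = TRUE),
                              digits = 4), "\n")
  invisible(x)
}

#' Extrapolate reliability to a scan duration
#'
#' `R_T = 1 / (1 + k / T)`: strictly increasing in T, approaching 1 as the
#' scan grows long.
#'
#' @param curve a [fit_scan_time_curve()] object (or a numeric k vector).
#' @param minutes target duration T.
#' @return per-feature reliability at duration T.
#' @export
extrapolate_reliability <- function(curve, minutes) {
  k <- if (inherits(curve, "reliability_curve")) curve$k_ratio else curve
  if (any(minutes <= 0)) stop("duration must be positive")
  1 / (1 + k / minutes)
}

#' Scan duration matching a target reliability
#'
#' Inverts the duration curve: `T* = k R / (1 - R)` satisfies
#' `extrapolate_reliability(curve, T*) = R` exactly.
#'
#' @param curve a [fit_scan_time_curve()] object (or a numeric k vector).
#' @param r_target target reliability per feature, in (0, 1).
#' @return per-feature matching duration T* in minutes.
#' @export
matching_duration <- function(curve, r_target) {
  k <- if (inherits(curve, "reliability_curve")) curve$k_ratio else curve
  if (any(r_target >= 1 | r_target <= 0)) stop("r_target must lie in (0, 1)")
  k * r_target / (1 - r_target)
}

#' Reliability of a change score
#'
#' `R_D = (R1 V1 + R2 V2 - 2 rho sqrt(V1 V2)) /
#'        (V1 + V2 - 2 rho sqrt(V1 V2))`:
#' the reliability of the difference of two measurements with
#' cross-sectional reliabilities R1, R2, observed variances V1, V2, and
#' between-timepoint correlation rho. High stability (large rho) is
#' detrimental to change reliability.
#'
#' @param r1,r2 reliabilities in [0, 1].
#' @param v1,v2 observed variances (> 0).
#' @param rho empirical between-timepoint correlation in (-1, 1).
#' @return change-score reliability R_D (vectorized over features).
#' @export
change_reliability <- function(r1, r2, v1, v2, rho) {
  if (any(r1 < 0 | r1 > 1 | r2 < 0 | r2 > 1)) stop("reliabilities must lie in [0, 1]")
  if (any(v1 <= 0 | v2 <= 0)) stop("variances must be > 0")
  if (any(abs(rho) >= 1)) stop("rho must lie in (-1, 1)")
  cross <- 2 * rho * sqrt(v1 * v2)
  den <- v1 + v2 - cross
  if (any(den <= 1e-12)) {
    stop("degenerate change score: perfectly correlated equal-variance sessions")
  }
  (r1 * v1 + r2 * v2 - cross) / den
}

#' Reliability-matched truncation of baseline measurements
#'
#' Recomputes baseline edge observations at a fixed short duration so that
#' their reliability matches a (lower) target such as the change-score
#' reliability: per edge, the matching duration `T* = k R_target/(1 -
#' R_target)` is reported, and the baseline values are re-estimated from
#' the first `minutes` of data only. Edges with unfittable curves are
#' excluded from the T* summary and counted.
#'
#' @param sim an [simulate_split_half_edges()] object holding the baseline
#'   minute-resolution data.
#' @param curve a [fit_scan_time_curve()] fitted on this data's split-half
#'   ICCs.
#' @param r_target per-edge target reliability (e.g. change reliability).
#' @param minutes fixed conservative duration to truncate to (default 4).
#' @return list: `fc` (participant x edge values at the fixed duration,
#'   test half), `icc_at_t` (per-edge ICC at the fixed duration),
#'   `t_star` (per-edge matching duration, NA where unfittable),
#'   `median_t_star`, `n_unfittable`.
#' @export
reliability_matched_truncation <- function(sim, curve, r_target,
                                           minutes = 4) {
  stopifnot(inherits(sim, "edge_half_sim"),
            inherits(curve, "reliability_curve"))
  if (minutes > sim$minutes) stop("duration T exceeds available data")
  halves <- truncate_halves(sim, minutes)
  icc_t <- icc_oneway(halves$test, halves$retest)
  t_star <- rep(NA_real_, length(curve$k_ratio))
  ok <- curve$fittable & r_target > 0 & r_target < 1
  t_star[ok] <- matching_duration(curve$k_ratio[ok], r_target[ok])
  list(fc = halves$test, icc_at_t = icc_t, t_star = t_star,
       median_t_star = stats::median(t_star, na.rm = TRUE),
       n_unfittable = sum(!curve$fittable))
}
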