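# Longitudinal ComBat-style site harmonization: one additive offset and one
# multiplicative scale per site and feature, shared across the two
# timepoints, with a participant random intercept and preserved covariates.

stack_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.data.frame(covariates) || is.matrix(covariates)) {
    stopifnot(nrow(covariates) == n)
    return(rbind(as.matrix(covariates), as.matrix(covariates)))
  }
  stopifnot(is.list(covariates), length(covariates) == 2)
  rbind(as.matrix(covariates[[1]]), as.matrix(covariates[[2]]))
}

#' Fit a longitudinal ComBat-style harmonization model
#'
#' Models each feature as
#' `y_ist = alpha + X beta + u_i + gamma_s + delta_s * eps_ist`:
#' covariate effects are estimated jointly with per-site additive offsets by
#' ordinary least squares on the stacked two-timepoint table; offsets are
#' centered to a site-size-weighted zero mean; the participant random
#' intercept `u_i` is the participant's mean residual (two observations per
#' participant, closed form); and the multiplicative site scale `delta_s` is
#' the ratio of the within-participant residual root-mean-square in site s
#' to the pooled value. Optional empirical-Bayes shrinkage pools the
#' per-site estimates across features.
#'
#' @param values list of two participant x feature matrices (baseline and
#'   follow-up), same participants in the same order.
#' @param site factor/character of site membership, one value per
#'   participant (a participant keeps one site across both timepoints).
#' @param covariates per-participant data.frame (used for both timepoints)
#'   or a list of two data.frames for time-varying covariates; `NULL` for
#'   none. Typically baseline age, age interval and sex.
#' @param use_eb apply empirical-Bayes shrinkage of (gamma, delta^2) toward
#'   their pooled across-feature moments (default off: the unshrunk
#'   estimator is exactly invertible on planted effects).
#' @return object of class `combat_model`.
#' @export
fit_longitudinal_combat <- function(values, site, covariates = NULL,
                                    use_eb = FALSE) {
  stopifnot(is.list(values), length(values) == 2)
  y0 <- as.matrix(values[[1]]); y2 <- as.matrix(values[[2]])
  stopifnot(identical(dim(y0), dim(y2)))
  n <- nrow(y0); F_ <- ncol(y0)
  site <- factor(site)
  if (length(site) != n) stop("site must have one value per participant")
  if (nlevels(site) < 2) stop("need >= 2 sites")
  tab <- table(site)
  if (any(tab < 3)) {
    stop("site(s) with < 3 participants: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  }
  Y <- rbind(y0, y2)
  site2 <- factor(rep(site, 2), levels = levels(site))
  Xc <- stack_covariates(covariates, n)
  Z <- if (is.null(Xc)) stats::model.matrix(~site2) else
    stats::model.matrix(~ Xc + site2)
  if (qr(Z)$rank < ncol(Z)) stop("singular covariate design")
  qrz <- qr(Z)
  B <- qr.coef(qrz, Y)
  fitted <- Z %*% B
  resid <- Y - fitted

  # site effects: treatment-coded coefficients, recentered to
  # site-size-weighted zero mean; the weighted mean folds into the intercept
  s_cols <- grep("^site2", colnames(Z))
  S <- nlevels(site)
  eff <- matrix(0, S, F_, dimnames = list(levels(site), colnames(Y)))
  if (length(s_cols) > 0) eff[-1, ] <- B[s_cols, , drop = FALSE]
  w <- as.numeric(tab) / n
  wm <- colSums(eff * w)
  gamma <- sweep(eff, 2, wm)

  # covariate-only prediction alpha + X beta; the weighted mean of the raw
  # site effects is part of alpha, not of the centered offsets
  cov_fit <- sweep(fitted - eff[as.integer(site2), , drop = FALSE], 2, wm, "+")

  # resid already excludes alpha + X beta + gamma (fitted includes them all)
  u <- (resid[seq_len(n), , drop = FALSE] +
          resid[n + seq_len(n), , drop = FALSE]) / 2
  e <- resid - rbind(u, u)
  msq_site <- rowsum(e^2, site2) / as.numeric(2 * tab)
  msq_pool <- colMeans(e^2)
  delta <- sqrt(sweep(msq_site, 2, pmax(msq_pool, 1e-300), "/"))
  delta[!is.finite(delta) | delta <= 0] <- 1

  if (use_eb) {
    for (s in seq_len(S)) {
      gbar <- mean(gamma[s, ]); gvar <- stats::var(gamma[s, ])
      svar <- mean(msq_site[s, ]) / (2 * tab[s])   # sampling var of offset
      lam <- if (gvar + svar > 0) gvar / (gvar + svar) else 1
      gamma[s, ] <- lam * gamma[s, ] + (1 - lam) * gbar
      d2 <- delta[s, ]^2
      dbar <- mean(d2); dvar <- stats::var(d2)
      lam_d <- if (dvar > 0) dvar / (dvar + dbar^2 / tab[s]) else 0
      delta[s, ] <- sqrt(lam_d * d2 + (1 - lam_d) * dbar)
    }
  }

  structure(list(beta = B, site_levels = levels(site), gamma = gamma,
                 delta = delta, u = u, cov_fit_y0 = cov_fit[seq_len(n), , drop = FALSE],
                 cov_fit_y2 = cov_fit[n + seq_len(n), , drop = FALSE],
                 site = site, n = n,
                 ranef_var = mean(apply(u, 2, stats::var)),
                 resid_var = mean(msq_pool), use_eb = use_eb),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("combat_model:", length(x$site_levels), "sites,", ncol(x$gamma),
      "features, EB =", x$use_eb, "\n")
  cat("  max |gamma| =", format(max(abs(x$gamma)), digits = 3),
      " delta range =", paste(format(range(x$delta), digits = 3),
                              collapse = " .. "), "\n")
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Reconstructs `yhat = alpha + X beta + u_i + (y - alpha - X beta - u_i -
#' gamma_s) / delta_s`: site offsets removed, site noise scale equalized,
#' covariate effects and participant intercepts restored.
#'
#' @param model a [fit_longitudinal_combat()] model.
#' @param values list of two participant x feature matrices compatible with
#'   the fit (same participants, features, and sites).
#' @return list of two harmonized matrices.
#' @export
apply_combat <- function(model, values) {
  stopifnot(inherits(model, "combat_model"), is.list(values),
            length(values) == 2)
  y0 <- as.matrix(values[[1]]); y2 <- as.matrix(values[[2]])
  if (nrow(y0) != model$n || ncol(y0) != ncol(model$gamma)) {
    stop("values incompatible with fitted model")
  }
  sidx <- as.integer(model$site)
  adj <- function(y, cov_fit) {
    base <- cov_fit + model$u
    g <- model$gamma[sidx, , drop = FALSE]
    d <- model$delta[sidx, , drop = FALSE]
    base + (y - base - g) / d
  }
  out <- list(adj(y0, model$cov_fit_y0), adj(y2, model$cov_fit_y2))
  names(out) <- names(values) %||% c("y0", "y2")
  out
}

#' Fit and apply harmonization in one call
#' @inheritParams fit_longitudinal_combat
#' @return list with `values` (harmonized list) and `model`.
#' @export
harmonize_longitudinal <- function(values, site, covariates = NULL,
                                   use_eb = FALSE) {
  model <- fit_longitudinal_combat(values, site, covariates, use_eb)
  list(values = apply_combat(model, values), model = model)
}
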