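# Seeded synthetic longitudinal cohorts with known ground truth: multi-site
# structure, two timepoints with high between-timepoint stability, per-edge
# true-score + duration-scaled-noise reliability, a latent cognitive trait
# with planted multivariate FC coupling, and block-structured couplings for
# convergence/divergence experiments.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for synthetic cohort generation
#'
#' Default values describe the emulated study design: 2949 participants over
#' 21 acquisition sites, two timepoints (baseline age 9.93 +/- 0.62 y,
#' inter-scan interval 2.01 +/- 0.16 y), seven cognitive measures loading on
#' one latent trait, and a connectome on a 400 + 19 region scheme with 20
#' minutes of usable scan per timepoint. Tests and examples pass much
#' smaller schemes and sample sizes; the statistical structure is identical.
#'
#' @param n_participants cohort size.
#' @param n_sites number of acquisition sites.
#' @param site_size_law `"proportional"` (gamma-weighted site sizes, minimum
#'   10 participants) or `"equal"`.
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @param scheme a [parcel_scheme()]; `NULL` builds the default 419-region
#'   synthetic scheme.
#' @param ages list: `baseline_mean`, `baseline_sd`, `interval_mean`,
#'   `interval_sd` (years).
#' @param motion list of per-timepoint framewise-displacement laws (lognormal
#'   meanlog/sdlog, mm).
#' @param cognition list: `n_measures`, `loadings` (on the latent trait g),
#'   `specific_sd`, `site_sd_add`, `site_sd_scale`, `stability_g`
#'   (between-timepoint correlation of g).
#' @param fc list: `sigma2` (per-edge true-score variance), `tau2` (per-minute
#'   noise scale; noise variance is tau2/T for T minutes), `sa_slope_sigma2`
#'   and `sa_slope_tau2` (linear S-A modulation of the two variances),
#'   `stability` (between-timepoint true-score correlation), `site_sd_add`,
#'   `site_sd_scale`, `motion_coef`, `duration_minutes`.
#' @param coupling list: `w_cross`, `w_long` (per-edge weight vectors, or
#'   `NULL` for no planted coupling; see [plant_block_couplings()]).
#' @param runs list (time-series mode): `n_runs`, `frames_per_run`,
#'   `frame_seconds`, `ar_coef`, `censor_frac`.
#' @param mode `"direct"` (edges drawn as true score + Gaussian noise with
#'   variance tau2/T; exact analytic reliability) or `"timeseries"`
#'   (AR(1) runs emitted for FC-construction tests).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 2949,
                          n_sites = 21,
                          site_size_law = c("proportional", "equal"),
                          seed = 1,
                          scheme = NULL,
                          ages = list(baseline_mean = 9.93, baseline_sd = 0.62,
                                      interval_mean = 2.01, interval_sd = 0.16),
                          motion = list(
                            y0 = list(meanlog = log(0.18), sdlog = 0.35),
                            y2 = list(meanlog = log(0.15), sdlog = 0.35)),
                          cognition = list(n_measures = 7,
                                           loadings = seq(0.85, 0.55,
                                                          length.out = 7),
                                           specific_sd = 0.6,
                                           site_sd_add = 0.15,
                                           site_sd_scale = 0.10,
                                           stability_g = 0.8),
                          fc = list(sigma2 = 0.04, tau2 = 0.12,
                                    sa_slope_sigma2 = 0.8,
                                    sa_slope_tau2 = 0.8,
                                    stability = 0.7,
                                    site_sd_add = 0.05,
                                    site_sd_scale = 0.05,
                                    motion_coef = 0.05,
                                    duration_minutes = 20),
                          coupling = list(w_cross = NULL, w_long = NULL),
                          runs = list(n_runs = 4, frames_per_run = 375,
                                      frame_seconds = 0.8, ar_coef = 0.3,
                                      censor_frac = 0.1),
                          mode = c("direct", "timeseries")) {
  site_size_law <- match.arg(site_size_law)
  mode <- match.arg(mode)
  if (n_sites > n_participants) {
    stop("infeasible site partition: n_sites > n_participants")
  }
  num_fields <- c(cognition$specific_sd, cognition$site_sd_add,
                  fc$sigma2, fc$tau2, fc$site_sd_add)
  if (any(num_fields < 0)) stop("negative variance specification")
  if (abs(cognition$stability_g) > 1 || abs(fc$stability) > 1) {
    stop("stability must lie in [-1, 1]")
  }
  structure(list(n_participants = n_participants, n_sites = n_sites,
                 site_size_law = site_size_law, seed = seed, scheme = scheme,
                 ages = ages, motion = motion, cognition = cognition, fc = fc,
                 coupling = coupling, runs = runs, mode = mode),
            class = "cohort_config")
}

block_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Plant block-structured edge couplings
#'
#' Assigns every edge a coupling weight equal to its network-pair sign times
#' a magnitude, separately for the cross-sectional (baseline trait to
#' baseline FC) and longitudinal (trait change to FC change) couplings.
#' Blocks where the two signs differ are the planted "divergent" ground
#' truth used to validate the convergence classifier.
#'
#' @param scheme a [parcel_scheme()].
#' @param block_signs_cross,block_signs_long named numeric vectors in
#'   \{-1, 0, +1\}; names are unordered network pairs `"netA|netB"`
#'   (alphabetical order). Pairs not listed get sign 0.
#' @param magnitude positive scalar weight magnitude.
#' @return list with per-edge numeric vectors `w_cross` and `w_long` aligned
#'   to [edge_index()] order.
#' @export
plant_block_couplings <- function(scheme, block_signs_cross,
                                  block_signs_long, magnitude = 1) {
  nets <- unique(scheme$network)
  check <- function(signs) {
    if (length(signs) == 0) return(invisible())
    pieces <- unlist(strsplit(names(signs), "|", fixed = TRUE))
    bad <- setdiff(pieces, nets)
    if (length(bad) > 0) stop("unknown network label: ", paste(bad, collapse = ", "))
    if (!all(signs %in% c(-1, 0, 1))) stop("signs must be -1, 0 or +1")
  }
  check(block_signs_cross); check(block_signs_long)
  ei <- edge_index(n_regions(scheme))
  keys <- block_key(scheme$network[ei$i], scheme$network[ei$j])
  weight <- function(signs) {
    s <- rep(0, nrow(ei))
    hit <- keys %in% names(signs)
    s[hit] <- signs[keys[hit]]
    s * magnitude
  }
  list(w_cross = weight(block_signs_cross), w_long = weight(block_signs_long))
}

site_sizes_from_law <- function(n, n_sites, law) {
  if (law == "equal") {
    sizes <- rep(n %/% n_sites, n_sites)
    sizes[seq_len(n %% n_sites)] <- sizes[seq_len(n %% n_sites)] + 1L
    return(sizes)
  }
  w <- stats::rgamma(n_sites, shape = 4)
  sizes <- pmax(10L, as.integer(round(w / sum(w) * n)))
  # repair rounding so sizes sum to n while keeping the minimum of 10
  while (sum(sizes) != n) {
    d <- sum(sizes) - n
    k <- if (d > 0) which.max(sizes) else which.min(sizes)
    sizes[k] <- sizes[k] - sign(d)
    if (sizes[k] < 10L) sizes[k] <- 10L
  }
  sizes
}

centered_site_effects <- function(n_sites, sizes, sd_add, sd_scale, n_feat) {
  gamma <- matrix(stats::rnorm(n_sites * n_feat, 0, sd_add), n_sites, n_feat)
  w <- sizes / sum(sizes)
  gamma <- sweep(gamma, 2, colSums(gamma * w))      # size-weighted zero mean
  delta <- matrix(exp(stats::rnorm(n_sites * n_feat, 0, sd_scale)),
                  n_sites, n_feat)
  list(gamma = gamma, delta = delta)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws a two-timepoint multi-site cohort under the generative model:
#' a latent cognitive trait g with configurable between-timepoint stability;
#' observed cognition `loading * g + site offset + site scale * noise`;
#' per-edge FC true scores with S-A-modulated variance, between-timepoint
#' stability, planted couplings (`w_cross` to baseline g, `w_long` to the
#' change in g), and observation noise with variance `tau2/T` for `T`
#' minutes of scan; linear head-motion leakage; and longitudinal-ComBat-form
#' site effects (one additive offset and one multiplicative scale per site,
#' shared across timepoints, scaling the noise term).
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `demographics` (participant,
#'   site, sex, age_y0, age_y2, fd_y0, fd_y2), `cognition_y0`/`cognition_y2`
#'   (participant x measure matrices), `fc_y0`/`fc_y2` (participant x edge
#'   Fisher-z matrices), `scheme`, `ground_truth` (latent traits, true edge
#'   scores, couplings, site effects, per-edge variances), and in
#'   time-series mode `runs` (per participant/timepoint lists of region x
#'   frame matrices with censor masks).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    scheme <- config$scheme %||%
      synthetic_parcel_scheme(n_cortical = 400, n_networks = 17,
                              n_subcortical = 19)
    n <- config$n_participants
    R <- n_regions(scheme)
    ei <- edge_index(R, scheme$region_ids)
    E <- nrow(ei)

    sizes <- site_sizes_from_law(n, config$n_sites, config$site_size_law)
    site <- factor(rep(seq_len(config$n_sites), times = sizes),
                   levels = seq_len(config$n_sites))

    ages <- config$ages
    age_y0 <- stats::rnorm(n, ages$baseline_mean, ages$baseline_sd)
    interval <- pmax(0.5, stats::rnorm(n, ages$interval_mean, ages$interval_sd))
    sex <- stats::rbinom(n, 1, 0.49)
    fd_y0 <- stats::rlnorm(n, config$motion$y0$meanlog, config$motion$y0$sdlog)
    fd_y2 <- stats::rlnorm(n, config$motion$y2$meanlog, config$motion$y2$sdlog)

    # latent cognitive trait
    sg <- config$cognition$stability_g
    g0 <- stats::rnorm(n)
    g2 <- sg * g0 + sqrt(1 - sg^2) * stats::rnorm(n)
    dg <- g2 - g0

    # cognition: loading * g + site effects
    m <- config$cognition$n_measures
    load <- rep_len(config$cognition$loadings, m)
    cog_site <- centered_site_effects(config$n_sites, sizes,
                                      config$cognition$site_sd_add,
                                      config$cognition$site_sd_scale, m)
    sidx <- as.integer(site)
    cog_one <- function(g) {
      eps <- matrix(stats::rnorm(n * m, 0, config$cognition$specific_sd), n, m)
      outer(g, load) + cog_site$gamma[sidx, , drop = FALSE] +
        cog_site$delta[sidx, , drop = FALSE] * eps
    }
    cog_y0 <- cog_one(g0)
    cog_y2 <- cog_one(g2)
    meas <- paste0("measure", seq_len(m))
    dimnames(cog_y0) <- dimnames(cog_y2) <- list(NULL, meas)

    # per-edge variance components, S-A modulated
    sa_edge <- (scheme$sa_rank[ei$i] + scheme$sa_rank[ei$j]) / 2
    sigma2_e <- config$fc$sigma2 *
      pmax(0.05, 1 + config$fc$sa_slope_sigma2 * (sa_edge - 0.5))
    tau2_e <- config$fc$tau2 *
      pmax(0.05, 1 - config$fc$sa_slope_tau2 * (sa_edge - 0.5))

    w_cross <- config$coupling$w_cross %||% rep(0, E)
    w_long <- config$coupling$w_long %||% rep(0, E)
    stopifnot(length(w_cross) == E, length(w_long) == E)

    st <- config$fc$stability
    b0 <- sweep(matrix(stats::rnorm(n * E), n, E), 2, sqrt(sigma2_e), "*")
    b2 <- st * b0 + sqrt(1 - st^2) *
      sweep(matrix(stats::rnorm(n * E), n, E), 2, sqrt(sigma2_e), "*")
    a0 <- b0 + outer(g0, w_cross)
    a2 <- b2 + outer(g0, w_cross) + outer(dg, w_long)

    Tm <- config$fc$duration_minutes
    fc_site <- centered_site_effects(config$n_sites, sizes,
                                     config$fc$site_sd_add,
                                     config$fc$site_sd_scale, E)
    observe <- function(a, fd) {
      eps <- sweep(matrix(stats::rnorm(n * E), n, E), 2, sqrt(tau2_e / Tm), "*")
      a + fc_site$gamma[sidx, , drop = FALSE] +
        config$fc$motion_coef * fd +
        fc_site$delta[sidx, , drop = FALSE] * eps
    }
    fc_y0 <- observe(a0, fd_y0)
    fc_y2 <- observe(a2, fd_y2)
    dimnames(fc_y0) <- dimnames(fc_y2) <- list(NULL, ei$name)

    runs <- NULL
    if (config$mode == "timeseries") {
      runs <- lapply(seq_len(n), function(i) {
        lapply(list(y0 = a0[i, ], y2 = a2[i, ]), function(a) {
          target <- nearest_psd_corr(vec_to_mat(tanh(a), diag = 1))
          lapply(seq_len(config$runs$n_runs), function(r) {
            generate_run_timeseries(target, config$runs$frames_per_run,
                                    config$runs$ar_coef,
                                    config$runs$censor_frac,
                                    seed = NULL)
          })
        })
      })
    }

    demographics <- data.frame(
      participant = sprintf("sub%05d", seq_len(n)),
      site = paste0("site", sidx), sex = sex,
      age_y0 = age_y0, age_y2 = age_y0 + interval,
      fd_y0 = fd_y0, fd_y2 = fd_y2,
      stringsAsFactors = FALSE)
    rownames(cog_y0) <- rownames(cog_y2) <- demographics$participant
    rownames(fc_y0) <- rownames(fc_y2) <- demographics$participant

    structure(
      list(demographics = demographics,
           cognition_y0 = cog_y0, cognition_y2 = cog_y2,
           fc_y0 = fc_y0, fc_y2 = fc_y2,
           runs = runs, scheme = scheme,
           ground_truth = list(g0 = g0, g2 = g2,
                               true_fc_y0 = a0, true_fc_y2 = a2,
                               w_cross = w_cross, w_long = w_long,
                               sigma2_e = sigma2_e, tau2_e = tau2_e,
                               cog_site = cog_site, fc_site = fc_site,
                               duration_minutes = Tm)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$demographics), "participants,",
      nlevels(factor(x$demographics$site)), "sites,",
      ncol(x$fc_y0), "edges,", ncol(x$cognition_y0), "cognitive measures\n")
  invisible(x)
}

# project a symmetric matrix to the nearest PSD correlation-like matrix
nearest_psd_corr <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= eps) return(m)
  v <- pmax(e$values, eps)
  m2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 / tcrossprod(d)
}

#' Generate a censored AR(1) run time series with a target innovation FC
#'
#' Produces a stationary Gaussian AR(1) series (shared coefficient across
#' regions) whose zero-lag correlation equals `target_fc`, together with a
#' censor mask flagging `floor(censor_frac * n_frames)` random frames. The
#' common AR coefficient preserves the target correlation at lag zero.
#'
#' @param target_fc symmetric positive semi-definite correlation matrix.
#' @param n_frames number of frames.
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param censor_frac fraction of frames to censor, in [0, 1).
#' @param seed optional integer seed (local to this call).
#' @return list with `series` (regions x frames matrix) and `censored`
#'   (logical vector, `TRUE` = frame excluded).
#' @export
generate_run_timeseries <- function(target_fc, n_frames, ar_coef = 0,
                                    censor_frac = 0, seed = NULL) {
  stopifnot(is.matrix(target_fc), nrow(target_fc) == ncol(target_fc))
  if (max(abs(target_fc - t(target_fc))) > 1e-8) stop("target_fc not symmetric")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must lie in [0, 1)")
  if (censor_frac < 0 || censor_frac >= 1) stop("censor_frac must lie in [0, 1)")
  ev <- eigen(target_fc, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("target_fc is not positive semi-definite (smallest eigenvalue ",
         format(min(ev$values)), ")")
  }
  gen <- function() {
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(target_fc))
    R <- nrow(target_fc)
    x <- matrix(0, R, n_frames)
    innov <- L %*% matrix(stats::rnorm(R * n_frames), R, n_frames)
    x[, 1] <- innov[, 1]
    if (n_frames > 1) {
      s <- sqrt(1 - ar_coef^2)
      for (t in 2:n_frames) x[, t] <- ar_coef * x[, t - 1] + s * innov[, t]
    }
    censored <- rep(FALSE, n_frames)
    n_cens <- floor(censor_frac * n_frames)
    if (n_cens > 0) censored[sample.int(n_frames, n_cens)] <- TRUE
    list(series = x, censored = censored)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate split-half edge observations at minute resolution
#'
#' Direct-edge analogue of splitting a participant's runs into test and
#' retest halves: each half observes the same per-participant true edge
#' score plus the average of `minutes` independent per-minute noise draws
#' with variance `tau2`, so an estimate truncated to the first `T` minutes
#' has noise variance `tau2 / T` exactly. Used by the reliability module's
#' duration-curve and matched-truncation experiments.
#'
#' @param n participants.
#' @param sigma2 per-edge true-score variance (scalar or length-E vector).
#' @param tau2 per-minute noise variance (scalar or length-E vector).
#' @param minutes minutes available per half.
#' @param n_edges number of edges E (defaults to length of `sigma2`).
#' @param seed integer seed.
#' @return object of class `edge_half_sim` with fields `truth` (n x E) and
#'   `noise1`, `noise2` (n x E x minutes arrays).
#' @export
simulate_split_half_edges <- function(n, sigma2, tau2, minutes = 10,
                                      n_edges = max(length(sigma2),
                                                    length(tau2)),
                                      seed = 1) {
  sigma2 <- rep_len(sigma2, n_edges)
  tau2 <- rep_len(tau2, n_edges)
  if (any(sigma2 < 0) || any(tau2 < 0)) stop("variances must be >= 0")
  with_seed(seed, {
    truth <- sweep(matrix(stats::rnorm(n * n_edges), n), 2, sqrt(sigma2), "*")
    mk <- function() {
      a <- array(stats::rnorm(n * n_edges * minutes), c(n, n_edges, minutes))
      sweep(a, 2, sqrt(tau2), "*")
    }
    structure(list(truth = truth, noise1 = mk(), noise2 = mk(),
                   minutes = minutes, sigma2 = sigma2, tau2 = tau2),
              class = "edge_half_sim")
  })
}

#' Truncate split-half simulations to a scan duration
#'
#' @param sim an [simulate_split_half_edges()] object.
#' @param minutes duration T to keep (<= `sim$minutes`).
#' @return list with `test` and `retest` participant x edge matrices whose
#'   noise variance is `tau2 / minutes`.
#' @export
truncate_halves <- function(sim, minutes) {
  stopifnot(inherits(sim, "edge_half_sim"))
  if (minutes > sim$minutes) stop("requested duration exceeds available data")
  idx <- seq_len(minutes)
  avg <- function(a) apply(a[, , idx, drop = FALSE], c(1, 2), mean)
  list(test = sim$truth + avg(sim$noise1),
       retest = sim$truth + avg(sim$noise2))
}
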