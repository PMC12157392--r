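test_that("parcel scheme invariants hold and round-trip through CSV", {
  sch <- small_scheme()
  expect_s3_class(sch, "parcel_scheme")
  cortical <- sch$hemisphere != "subcortical"
  expect_true(all(abs(sqrt(rowSums(sch$centroids[cortical, ]^2)) - 1) < 1e-9))
  expect_setequal(unique(sch$network[!cortical]), "subcortex")
  path <- tempfile(fileext = ".csv")
  write_parcel_scheme(sch, path)
  sch2 <- read_parcel_scheme(path)
  expect_equal(sch2$region_ids, sch$region_ids)
  expect_equal(sch2$centroids, sch$centroids, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(parcel_scheme(letters[1:3], rep("a", 3), rep("left", 3),
                             diag(3), rep(0.5, 3)),
               "at least 4")
})

test_that("cohorts are seed-deterministic and reject infeasible configs", {
  sch <- small_scheme()
  cfg <- cohort_config(n_participants = 60, n_sites = 4, seed = 11,
                       scheme = sch)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_participants = 60, n_sites = 4, seed = 12,
                        scheme = sch)
  expect_false(identical(generate_cohort(cfg)$fc_y0,
                         generate_cohort(cfg2)$fc_y0))
  expect_error(cohort_config(n_participants = 5, n_sites = 10),
               "infeasible site partition")
  expect_error(cohort_config(fc = list(sigma2 = -1, tau2 = 0.1,
                                       site_sd_add = 0)),
               "negative variance")
})

test_that("cohort tables share the participant index and ages increase", {
  co <- generate_cohort(cohort_config(n_participants = 80, n_sites = 4,
                                      seed = 2, scheme = small_scheme()))
  ids <- co$demographics$participant
  expect_identical(rownames(co$cognition_y0), ids)
  expect_identical(rownames(co$fc_y2), ids)
  expect_true(all(co$demographics$age_y2 > co$demographics$age_y0))
})

test_that("zero coupling leaves the trait uncorrelated with every edge", {
  n <- 2000
  co <- generate_cohort(cohort_config(n_participants = n, n_sites = 5,
                                      seed = 21,
                                      scheme = synthetic_parcel_scheme(8, 2, 0),
                                      fc = list(sigma2 = 0.04, tau2 = 0.12,
                                                sa_slope_sigma2 = 0,
                                                sa_slope_tau2 = 0,
                                                stability = 0.7,
                                                site_sd_add = 0,
                                                site_sd_scale = 0,
                                                motion_coef = 0,
                                                duration_minutes = 20)))
  r <- abs(cor(co$ground_truth$g0, co$fc_y0))
  expect_lt(max(r), 3 / sqrt(n))
})

test_that("split-half ICC of direct-edge data matches the duration formula", {
  # sigma2 = 0.04, tau2 = 0.12, T = 10 -> ICC = 1/(1 + 3/10)
  target <- 1 / (1 + (0.12 / 0.04) / 10)
  iccs <- vapply(1:50, function(s) {
    sim <- simulate_split_half_edges(1000, 0.04, 0.12, minutes = 10,
                                     n_edges = 1, seed = 100 + s)
    split_half_icc(sim, 10)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - target), 0.03)
})

test_that("between-timepoint stability of true edge scores is calibrated", {
  co <- generate_cohort(cohort_config(n_participants = 1500, n_sites = 5,
                                      seed = 31,
                                      scheme = synthetic_parcel_scheme(8, 2, 0),
                                      fc = list(sigma2 = 0.04, tau2 = 0.12,
                                                sa_slope_sigma2 = 0,
                                                sa_slope_tau2 = 0,
                                                stability = 0.7,
                                                site_sd_add = 0,
                                                site_sd_scale = 0,
                                                motion_coef = 0,
                                                duration_minutes = 20)))
  st <- diag(cor(co$ground_truth$true_fc_y0, co$ground_truth$true_fc_y2))
  expect_lt(abs(mean(st) - 0.7), 0.03)
})

test_that("planted coupling signs are recoverable from edge-trait covariance", {
  sch <- synthetic_parcel_scheme(16, 2, 0)
  cw <- plant_block_couplings(sch, c("net1|net1" = 1, "net2|net2" = -1,
                                     "net1|net2" = 1),
                              c(), magnitude = 1)
  co <- generate_cohort(cohort_config(n_participants = 1500, n_sites = 5,
                                      seed = 41, scheme = sch,
                                      coupling = list(w_cross = cw$w_cross,
                                                      w_long = NULL),
                                      fc = list(sigma2 = 0.01, tau2 = 0.02,
                                                sa_slope_sigma2 = 0,
                                                sa_slope_tau2 = 0,
                                                stability = 0.7,
                                                site_sd_add = 0.01,
                                                site_sd_scale = 0.01,
                                                motion_coef = 0.01,
                                                duration_minutes = 20)))
  nz <- cw$w_cross != 0
  sgn <- sign(cov(co$ground_truth$g0, co$fc_y0[, nz]))
  expect_gte(mean(sgn == sign(cw$w_cross[nz])), 0.99)
})

test_that("block couplings match a brute-force per-edge enumeration", {
  sch <- synthetic_parcel_scheme(12, 3, 0)
  signs_c <- c("net1|net1" = 1, "net1|net2" = -1, "net2|net3" = 1)
  signs_l <- c("net1|net1" = -1, "net3|net3" = 1)
  w <- plant_block_couplings(sch, signs_c, signs_l, magnitude = 0.4)
  ei <- edge_index(n_regions(sch))
  key <- function(i, j) {
    ns <- sort(c(sch$network[i], sch$network[j]))
    paste(ns[1], ns[2], sep = "|")
  }
  expected_c <- expected_l <- numeric(nrow(ei))
  for (e in seq_len(nrow(ei))) {
    k <- key(ei$i[e], ei$j[e])
    if (k %in% names(signs_c)) expected_c[e] <- signs_c[[k]] * 0.4
    if (k %in% names(signs_l)) expected_l[e] <- signs_l[[k]] * 0.4
  }
  expect_equal(w$w_cross, expected_c)
  expect_equal(w$w_long, expected_l)
  z <- plant_block_couplings(sch, c(), c())
  expect_true(all(z$w_cross == 0) && all(z$w_long == 0))
  expect_error(plant_block_couplings(sch, c("netX|net1" = 1), c()),
               "unknown network")
})

test_that("run time series honour the target FC, AR structure and censoring", {
  rt <- generate_run_timeseries(diag(4), 10000, ar_coef = 0, seed = 5)
  cm <- cor(t(rt$series))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.05)

  target <- matrix(c(1, .5, .5, 1), 2)
  rt2 <- generate_run_timeseries(target, 100000, ar_coef = 0, seed = 6)
  expect_lt(abs(cor(rt2$series[1, ], rt2$series[2, ]) - 0.5), 0.01)

  rt3 <- generate_run_timeseries(diag(3), 100, censor_frac = 0.3, seed = 7)
  expect_identical(sum(rt3$censored), 30L)

  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(generate_run_timeseries(bad, 10), "smallest eigenvalue")
})
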