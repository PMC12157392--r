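#' Parcellation scheme with network labels and spherical centroids
#'
#' A parcel scheme describes the regions that index every connectome in the
#' package: ordered region labels, a network assignment (e.g. 17 cortical
#' networks plus "subcortex"), a hemisphere label, a unit-sphere centroid for
#' each cortical region (used by the spin test), and a sensorimotor-to-
#' association rank in [0, 1] (used to modulate synthetic stability/change
#' gradients).
#'
#' @param region_ids character vector of region labels (>= 4 regions).
#' @param network character vector, network label per region. Networks must
#'   partition the regions.
#' @param hemisphere character vector with values `"left"`, `"right"` or
#'   `"subcortical"`.
#' @param centroids numeric matrix (regions x 3) of unit-sphere centroids;
#'   rows for subcortical regions may be `NA`.
#' @param sa_rank numeric in [0, 1]; sensory (0) to association (1) ordering.
#' @return object of class `parcel_scheme`.
#' @export
parcel_scheme <- function(region_ids, network, hemisphere, centroids, sa_rank) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  if (n < 4) stop("a parcel scheme needs at least 4 regions")
  if (anyDuplicated(region_ids)) stop("duplicated region ids")
  stopifnot(length(network) == n, length(hemisphere) == n,
            length(sa_rank) == n, nrow(centroids) == n, ncol(centroids) == 3)
  if (!all(hemisphere %in% c("left", "right", "subcortical"))) {
    stop("hemisphere must be 'left', 'right' or 'subcortical'")
  }
  if (any(sa_rank < 0 | sa_rank > 1, na.rm = TRUE)) {
    stop("sa_rank must lie in [0, 1]")
  }
  cortical <- hemisphere != "subcortical"
  if (any(cortical)) {
    nrm <- sqrt(rowSums(centroids[cortical, , drop = FALSE]^2))
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-9)) {
      stop("every cortical centroid must have unit norm (+/- 1e-9)")
    }
  }
  structure(
    list(region_ids = region_ids,
         network = as.character(network),
         hemisphere = as.character(hemisphere),
         centroids = centroids,
         sa_rank = as.numeric(sa_rank)),
    class = "parcel_scheme")
}

#' @export
print.parcel_scheme <- function(x, ...) {
  cat("parcel_scheme:", length(x$region_ids), "regions,",
      length(unique(x$network)), "networks,",
      sum(x$hemisphere == "subcortical"), "subcortical\n")
  invisible(x)
}

#' Number of regions in a scheme
#' @param scheme a `parcel_scheme`.
#' @return integer region count.
#' @export
n_regions <- function(scheme) length(scheme$region_ids)

#' Generate a synthetic spherical parcellation
#'
#' Builds a parcel scheme with cortical centroids placed on a Fibonacci
#' lattice over each hemisphere's unit sphere, contiguous-on-sphere network
#' assignments, and an S-A rank taken from the polar angle (sensory at the
#' south pole, association at the north). Intended as the testbed analogue of
#' a 400-cortical + 19-subcortical atlas at configurable size.
#'
#' @param n_cortical number of cortical regions (split evenly over
#'   hemispheres).
#' @param n_networks number of cortical networks.
#' @param n_subcortical number of subcortical regions (no centroids).
#' @return a `parcel_scheme`.
#' @export
synthetic_parcel_scheme <- function(n_cortical = 60, n_networks = 6,
                                    n_subcortical = 4) {
  stopifnot(n_cortical >= n_networks, n_cortical %% 2 == 0)
  half <- n_cortical / 2
  fib_sphere <- function(m) {
    k <- seq_len(m) - 0.5
    phi <- acos(1 - 2 * k / m)
    theta <- pi * (1 + sqrt(5)) * k
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  cl <- fib_sphere(half)
  cr <- cl %*% diag(c(-1, 1, 1))   # mirrored right hemisphere
  centroids <- rbind(cl, cr)
  # networks: bands of polar angle, mirrored across hemispheres
  band <- function(z) pmin(n_networks, 1L + floor((z + 1) / 2 * n_networks))
  network <- paste0("net", band(centroids[, 3]))
  sa <- (centroids[, 3] + 1) / 2
  if (n_subcortical > 0) {
    centroids <- rbind(centroids, matrix(NA_real_, n_subcortical, 3))
    network <- c(network, rep("subcortex", n_subcortical))
    sa <- c(sa, rep(NA_real_, n_subcortical))
  }
  ids <- c(sprintf("LH_%03d", seq_len(half)), sprintf("RH_%03d", seq_len(half)),
           if (n_subcortical > 0) sprintf("SC_%02d", seq_len(n_subcortical)))
  hemi <- c(rep("left", half), rep("right", half),
            rep("subcortical", n_subcortical))
  sa[is.na(sa)] <- 0.5  # subcortex: neutral rank
  parcel_scheme(ids, network, hemi, centroids, sa)
}

#' Write / read a parcel scheme as CSV
#'
#' Columns: region, network, hemisphere, x, y, z, sa_rank.
#' @param scheme a `parcel_scheme`.
#' @param path file path.
#' @return `read_parcel_scheme` returns a `parcel_scheme`;
#'   `write_parcel_scheme` returns `path` invisibly.
#' @export
write_parcel_scheme <- function(scheme, path) {
  df <- data.frame(region = scheme$region_ids, network = scheme$network,
                   hemisphere = scheme$hemisphere,
                   x = scheme$centroids[, 1], y = scheme$centroids[, 2],
                   z = scheme$centroids[, 3], sa_rank = scheme$sa_rank)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_scheme
#' @export
read_parcel_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  parcel_scheme(df$region, df$network, df$hemisphere,
                as.matrix(df[, c("x", "y", "z")]), df$sa_rank)
}
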