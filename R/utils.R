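#' @keywords internal
"_PACKAGE"

# Fisher r-to-z with clipping so degenerate inputs (|r| -> 1) stay finite.
R_CLIP <- 0.999999

#' Fisher r-to-z transform with clipping
#'
#' Correlations are clipped at |r| = 0.999999 before `atanh` so that
#' degenerate inputs (duplicated regions, constant series) produce a large
#' but finite z value rather than +/-Inf.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of Fisher-z values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -R_CLIP), R_CLIP))
}

#' Inverse Fisher transform
#' @param z numeric vector of Fisher-z values.
#' @return numeric vector of correlations.
#' @export
fisher_r <- function(z) tanh(z)

#' Upper-triangle edge index in row-major order
#'
#' Edges of an R-region connectome are stored as a fixed-length vector in
#' row-major upper-triangle order: (1,2), (1,3), ..., (1,R), (2,3), ...
#'
#' @param n_regions number of regions R.
#' @param labels optional region labels; if given, edge names
#'   `"regionA|regionB"` are attached.
#' @return data.frame with integer columns `i`, `j` (i < j) and, when labels
#'   are supplied, a character column `name`.
#' @export
edge_index <- function(n_regions, labels = NULL) {
  stopifnot(n_regions >= 2)
  i <- rep(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions),
              use.names = FALSE)
  out <- data.frame(i = i, j = j)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_regions)
    out$name <- paste(labels[i], labels[j], sep = "|")
  }
  out
}

#' Extract the row-major upper triangle of a square matrix
#' @param m square matrix.
#' @return numeric vector of length n(n-1)/2 in `edge_index()` order.
#' @export
ut_vec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

#' Fold an edge vector back into a symmetric matrix
#' @param v edge vector in `edge_index()` order.
#' @param diag value placed on the diagonal (default 0).
#' @return symmetric matrix.
#' @export
vec_to_mat <- function(v, diag = 0) {
  e <- length(v)
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("length ", e, " is not a valid edge count n(n-1)/2")
  }
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v   # lower.tri fills column-major = row-major of t(m)
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag
  m
}

# Residualize columns of a matrix on a covariate design (adds intercept).
# Returns residuals; errors on rank deficiency.
ols_residuals <- function(values, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(sweep(values, 2, colMeans(values)))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  fit <- stats::lm.fit(X, values)
  as.matrix(fit$residuals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
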