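# Significance machinery: within-site permutation nulls, corrected
# resampled t-tests between cross-validated models, FDR control, and
# spatial (spin) permutation tests for parcellated maps.

#' Within-site permutation test of a prediction pipeline
#'
#' Shuffles the target independently within each site (so site structure is
#' preserved), re-runs the full pipeline per permutation, and reports
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`. Sites with a single
#' participant cannot be shuffled and are left fixed.
#'
#' @param pipeline_fn function of a target vector returning a scalar
#'   accuracy; deterministic given the permuted target.
#' @param y target vector.
#' @param site site label per participant.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param two_sided double the smaller tail (default: one-sided, larger
#'   accuracy = more extreme).
#' @return list with `observed`, `null` (length `n_perm`), `p`.
#' @export
permutation_null <- function(pipeline_fn, y, site, n_perm = 1000, seed = 1,
                             two_sided = FALSE) {
  if (n_perm < 100) stop("need n_perm >= 100")
  site <- factor(site)
  singles <- names(which(table(site) < 2))
  if (length(singles) > 0) {
    message(length(singles), " single-participant site(s) left unshuffled")
  }
  observed <- pipeline_fn(y)
  idx_by_site <- split(seq_along(y), site)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- y
    for (ix in idx_by_site) {
      if (length(ix) > 1) yp[ix] <- y[sample(ix)]
    }
    pipeline_fn(yp)
  }, numeric(1)))
  p_up <- (1 + sum(null >= observed)) / (n_perm + 1)
  p <- if (two_sided) {
    p_dn <- (1 + sum(null <= observed)) / (n_perm + 1)
    min(1, 2 * min(p_up, p_dn))
  } else p_up
  list(observed = observed, null = null, p = p)
}

#' Corrected resampled t-test between two cross-validated models
#'
#' Paired t-test on per-fold accuracy differences with the variance
#' inflated by the train/test size ratio to account for overlapping
#' training sets across folds:
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))`, `df = J - 1`,
#' two-sided p.
#'
#' @param acc_a,acc_b per-fold accuracies of the two models (same folds,
#'   J >= 2).
#' @param n_train,n_test training and test set sizes per fold.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
corrected_resampled_ttest <- function(acc_a, acc_b, n_train, n_test) {
  J <- length(acc_a)
  if (length(acc_b) != J) stop("mismatched fold counts")
  if (J < 2) stop("need at least 2 folds")
  d <- acc_a - acc_b
  s2 <- stats::var(d)
  if (s2 == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    if (mean(d) != 0) warning("zero variance with nonzero mean difference")
    return(list(t = t, df = J - 1, p = p, mean_diff = mean(d)))
  }
  t <- mean(d) / sqrt((1 / J + n_test / n_train) * s2)
  list(t = t, df = J - 1, p = 2 * stats::pt(-abs(t), df = J - 1),
       mean_diff = mean(d))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR via `stats::p.adjust(method = "BH")`; returns the rejection
#' mask at level q together with monotone adjusted p-values.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical) and `p_adjusted`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(list(reject = logical(0), p_adjusted = numeric(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj)
}

# uniform random rotation: QR of a Gaussian matrix, sign-corrected, det +1
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Build a spin-test permutation table
#'
#' Per spin, a uniform random 3D rotation is applied to the left-hemisphere
#' centroids and its x-mirrored image to the right hemisphere; each
#' original cortical parcel is then mapped to the parcel whose rotated
#' centroid lies nearest (duplicates allowed; an assignment-based bijective
#' variant is available). Subcortical regions are never permuted and are
#' excluded from spin statistics.
#'
#' @param scheme a [parcel_scheme()] with cortical centroids.
#' @param n_spins number of rotations (warning below 100).
#' @param seed integer seed.
#' @param bijective use a greedy one-to-one assignment instead of
#'   nearest-centroid mapping.
#' @return object of class `spin_null`: `perm` (n_spins x n_cortical index
#'   matrix into the cortical subset), `cortical_idx`, `seed`.
#' @export
build_spin_null <- function(scheme, n_spins = 1000, seed = 1,
                            bijective = FALSE) {
  cortical <- which(scheme$hemisphere != "subcortical")
  if (length(cortical) == 0 || anyNA(scheme$centroids[cortical, ])) {
    stop("missing cortical centroids")
  }
  if (n_spins < 100) warning("n_spins < 100: p-values will be coarse")
  hemi <- scheme$hemisphere[cortical]
  C <- scheme$centroids[cortical, , drop = FALSE]
  M <- diag(c(-1, 1, 1))
  map_hemi <- function(orig, rot) {
    # orig parcel i -> nearest rotated centroid (indices within the subset)
    d2 <- outer(rowSums(orig^2), rowSums(rot^2), "+") - 2 * tcrossprod(orig, rot)
    if (!bijective) return(apply(d2, 1, which.min))
    m <- nrow(d2); out <- integer(m); taken <- rep(FALSE, m)
    for (step in seq_len(m)) {
      j <- arrayInd(which.min(d2), dim(d2))
      out[j[1]] <- j[2]
      d2[j[1], ] <- Inf; d2[, j[2]] <- Inf
    }
    out
  }
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_spins), function(b) {
      R <- random_rotation()
      p <- integer(length(cortical))
      left <- hemi == "left"; right <- hemi == "right"
      if (any(left)) {
        rot <- C[left, , drop = FALSE] %*% t(R)
        p[left] <- which(left)[map_hemi(C[left, , drop = FALSE], rot)]
      }
      if (any(right)) {
        Rr <- M %*% R %*% M
        rot <- C[right, , drop = FALSE] %*% t(Rr)
        p[right] <- which(right)[map_hemi(C[right, , drop = FALSE], rot)]
      }
      p
    }, integer(length(cortical))))
  })
  structure(list(perm = perm, cortical_idx = cortical, seed = seed),
            class = "spin_null")
}

#' Spin-test p-value for map or matrix correlations
#'
#' Correlates two cortical maps (vectors over regions) or two connectomes
#' (region x region matrices, upper triangle of the cortical block). Per
#' spin, the first input is reordered by the rotated parcel mapping and a
#' null correlation collected;
#' `p = (1 + #\{|null| >= |observed|\}) / (n_spins + 1)`.
#'
#' @param map_a,map_b numeric vectors (length = regions or cortical
#'   regions) or symmetric region matrices.
#' @param spin_null a [build_spin_null()] object.
#' @param method correlation type passed to [stats::cor()].
#' @return list with `observed`, `null`, `p`.
#' @export
spin_pvalue <- function(map_a, map_b, spin_null, method = "pearson") {
  stopifnot(inherits(spin_null, "spin_null"))
  ci <- spin_null$cortical_idx
  nc <- length(ci)
  take <- function(m) {
    if (is.matrix(m)) {
      if (nrow(m) != nc) m <- m[ci, ci, drop = FALSE]
      m
    } else {
      if (length(m) != nc) m <- m[ci]
      m
    }
  }
  a <- take(map_a); b <- take(map_b)
  if (is.matrix(a)) {
    obs <- stats::cor(ut_vec(a), ut_vec(b), method = method)
    null <- apply(spin_null$perm, 1, function(p) {
      pl <- match(p, ci)   # indices within the cortical subset
      stats::cor(ut_vec(a[pl, pl, drop = FALSE]), ut_vec(b), method = method)
    })
  } else {
    obs <- stats::cor(a, b, method = method)
    null <- apply(spin_null$perm, 1, function(p) {
      stats::cor(a[match(p, ci)], b, method = method)
    })
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (nrow(spin_null$perm) + 1)
  list(observed = obs, null = null, p = p)
}
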