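# Network-block summarization of predictive network features and the
# convergent/divergent classification across cross-sectional and
# longitudinal models.

#' Average edge features within network blocks
#'
#' Folds a per-edge feature vector to the region matrix and averages it
#' within each unordered network-pair block; diagonal blocks hold
#' within-network edges. Single-region networks have an empty diagonal
#' block and are flagged `NA`.
#'
#' @param pnf a [haufe_pnf()] object or per-edge numeric vector.
#' @param scheme a [parcel_scheme()].
#' @return symmetric network x network matrix of block means, with an
#'   `n_edges` attribute counting edges per block.
#' @export
block_average <- function(pnf, scheme) {
  v <- if (inherits(pnf, "pnf")) pnf$values else as.numeric(pnf)
  ei <- edge_index(n_regions(scheme))
  stopifnot(length(v) == nrow(ei))
  nets <- sort(unique(scheme$network))
  na <- factor(scheme$network[ei$i], levels = nets)
  nb <- factor(scheme$network[ei$j], levels = nets)
  lo <- pmin(as.integer(na), as.integer(nb))
  hi <- pmax(as.integer(na), as.integer(nb))
  key <- (lo - 1L) * length(nets) + hi
  sums <- rowsum(v, key)
  counts <- rowsum(rep(1, length(v)), key)
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  cnt <- matrix(0L, length(nets), length(nets), dimnames = dimnames(out))
  ids <- as.integer(rownames(sums))
  li <- (ids - 1L) %/% length(nets) + 1L
  hj <- (ids - 1L) %% length(nets) + 1L
  for (r in seq_along(ids)) {
    out[li[r], hj[r]] <- out[hj[r], li[r]] <- sums[r] / counts[r]
    cnt[li[r], hj[r]] <- cnt[hj[r], li[r]] <- counts[r]
  }
  attr(out, "n_edges") <- cnt
  out
}

#' Classify network blocks as convergent or divergent across models
#'
#' A block is convergent when its mean feature has the same nonzero sign in
#' the cross-sectional and longitudinal models, divergent when the signs
#' are opposite, and null otherwise. `min_abs` (default 0: a pure sign
#' rule) guards against near-zero sign noise.
#'
#' @param blocks_cross,blocks_long block-mean matrices from
#'   [block_average()] with identical dimnames.
#' @param min_abs magnitude both means must exceed to count as nonzero.
#' @return object of class `block_summary`: data.frame `blocks` with
#'   `network_a`, `network_b` (unordered pairs), `mean_cross`, `mean_long`,
#'   `label`; plus the two input matrices and `min_abs`.
#' @export
classify_convergence <- function(blocks_cross, blocks_long, min_abs = 0) {
  if (!identical(dimnames(blocks_cross), dimnames(blocks_long))) {
    stop("block index sets differ")
  }
  nets <- rownames(blocks_cross)
  pairs <- which(upper.tri(blocks_cross, diag = TRUE), arr.ind = TRUE)
  mc <- blocks_cross[pairs]; ml <- blocks_long[pairs]
  label <- rep("null", nrow(pairs))
  ok <- !is.na(mc) & !is.na(ml) & abs(mc) > min_abs & abs(ml) > min_abs
  label[ok & sign(mc) == sign(ml)] <- "convergent"
  label[ok & sign(mc) != sign(ml)] <- "divergent"
  structure(list(blocks = data.frame(network_a = nets[pairs[, 1]],
                                     network_b = nets[pairs[, 2]],
                                     mean_cross = mc, mean_long = ml,
                                     label = label, row.names = NULL),
                 blocks_cross = blocks_cross, blocks_long = blocks_long,
                 min_abs = min_abs),
            class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat("block_summary:", nrow(x$blocks), "network pairs:",
      sum(x$blocks$label == "convergent"), "convergent,",
      sum(x$blocks$label == "divergent"), "divergent,",
      sum(x$blocks$label == "null"), "null\n")
  invisible(x)
}

#' Export a block summary for external chord plotting
#'
#' Writes `(network_a, network_b, mean_cross, mean_long, label)` rows as
#' CSV, one per unordered network pair.
#'
#' @param summary a [classify_convergence()] summary.
#' @param path output path.
#' @return `path` invisibly.
#' @export
chord_export <- function(summary, path) {
  stopifnot(inherits(summary, "block_summary"))
  utils::write.csv(summary$blocks, path, row.names = FALSE)
  invisible(path)
}
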