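#' @title Classical multidimensional scaling of the network dissimilarity
#' @name embedding
NULL

#' Classical (Torgerson) MDS into k dimensions
#'
#' Double-centers the squared dissimilarities, eigendecomposes, and returns
#' the top-k positive-eigenvalue axes scaled by the square root of their
#' eigenvalues (via [stats::cmdscale()]). Negative eigenvalues (from
#' non-Euclidean dissimilarities such as 1 - adjacency) are truncated to
#' zero for the configuration and reported in the eigenvalue vector. Axis
#' signs are fixed deterministically: the entry of largest magnitude on
#' each axis is made positive.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal and
#'   non-negative entries.
#' @param k number of output dimensions (default 3). If fewer than `k`
#'   eigenvalues are positive, fewer axes are returned with a warning.
#' @return object of class `dom_mds`: `points` (n x <= k coordinates,
#'   centroid at the origin, axes ordered by decreasing eigenvalue),
#'   `eig` (all eigenvalues), `positive_mass` (fraction of the
#'   positive-eigenvalue mass captured by the returned axes).
#' @export
classical_mds <- function(D, k = 3) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(diag(D) > 1e-8)) stop("dissimilarity diagonal must be zero")
  if (any(D < -1e-12)) stop("dissimilarities must be non-negative")
  k <- min(k, nrow(D) - 1L)
  fit <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  P <- as.matrix(fit$points)
  if (ncol(P) < k) {
    warning("only ", ncol(P), " of ", k, " requested axes have positive ",
            "eigenvalues")
  }
  # deterministic axis orientation
  for (j in seq_len(ncol(P))) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  pos <- fit$eig[fit$eig > 0]
  kept <- fit$eig[seq_len(ncol(P))]
  structure(list(points = P, eig = fit$eig,
                 positive_mass = sum(kept[kept > 0]) / sum(pos)),
            class = "dom_mds")
}

#' @export
print.dom_mds <- function(x, ...) {
  cat("Classical MDS embedding:", nrow(x$points), "points in",
      ncol(x$points), "dimensions;", round(100 * x$positive_mass, 1),
      "% of positive eigenvalue mass captured\n")
  invisible(x)
}
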