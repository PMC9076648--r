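#' @title Signed weighted correlation network, modules and eigengenes
#' @name correlation-network
#' @description
#' The network stage: Pearson similarity between all feature pairs, signed
#' soft-threshold adjacency \eqn{A_{ij} = (0.5 (1 + cor))^p} (default
#' p = 9, chosen to approximate scale-free topology), hierarchical
#' clustering of node dissimilarities into modules named by the
#' conventional size-ordered color palette, and per-module eigengenes
#' (first-principal-component sample scores).
NULL

# conventional module color order, by descending module size
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "sienna3",
  "yellowgreen", "skyblue3", "plum1", "orangered4", "mediumpurple3"
)

#' Pearson correlation matrix between features
#'
#' Rows of the feature matrix are features, columns samples. Features with
#' zero variance across samples (undefined correlation) are excluded with a
#' warning.
#'
#' @param X numeric matrix, features x samples (at least 3 samples).
#' @return symmetric correlation matrix over the retained features.
#' @export
correlation_matrix <- function(X) {
  if (ncol(X) < 3L) stop("need at least 3 samples")
  v <- apply(X, 1, stats::sd)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) excluded from the network")
    X <- X[v > 0, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("fewer than 2 features with non-zero variance")
  C <- stats::cor(t(X))
  diag(C) <- 1
  C
}

#' Signed soft-threshold adjacency
#'
#' \eqn{A_{ij} = (0.5 (1 + cor_{ij}))^p}: perfect correlation maps to 1,
#' perfect anticorrelation to 0, zero correlation to \eqn{0.5^p}. The map
#' is strictly increasing in the correlation, so negatively correlated
#' features get near-zero adjacency.
#'
#' @param C correlation matrix with entries in `[-1, 1]`.
#' @param power soft-threshold exponent p > 0 (default 9).
#' @return adjacency matrix with entries in `[0, 1]`, unit diagonal.
#' @export
signed_adjacency <- function(C, power = 9) {
  if (power <= 0) stop("power must be positive")
  if (any(C < -1 - 1e-12 | C > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]")
  }
  (0.5 * (1 + pmin(pmax(C, -1), 1)))^power
}

#' Scale-free topology fit of the connectivity distribution
#'
#' Node connectivity is \eqn{k_i = \sum_{j \ne i} A_{ij}}. Connectivities
#' are binned, and the fit statistic is the R-squared of the linear
#' regression of log10 p(k) on log10 mean(k) over non-empty bins (with the
#' regression slope).
#'
#' @param A adjacency matrix (ignored when `connectivity` is given).
#' @param n_bins number of equal-width connectivity bins (default 10).
#' @param connectivity optional precomputed connectivity vector.
#' @param breaks optional explicit bin breaks.
#' @return list with `r_squared`, `slope`, and the binned `table`.
#' @export
scale_free_fit <- function(A = NULL, n_bins = 10, connectivity = NULL,
                           breaks = NULL) {
  k <- if (is.null(connectivity)) rowSums(A) - diag(A) else connectivity
  if (length(unique(k)) == 1L) {
    stop("all connectivities equal; scale-free fit undefined")
  }
  if (is.null(breaks)) {
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  }
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  kmean <- tapply(k, bin, mean)
  keep <- counts > 0
  if (sum(keep) < 3L) stop("fewer than 3 non-empty connectivity bins")
  tab <- data.frame(k_mean = as.numeric(kmean[keep]),
                    p_k = counts[keep] / length(k))
  fit <- stats::lm(log10(p_k) ~ log10(k_mean), data = tab)
  # summary.lm warns on an exactly collinear (perfect power-law) table
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]),
       table = tab)
}

#' Topological overlap similarity of an adjacency matrix
#'
#' \eqn{TOM_{ij} = (L_{ij} + A_{ij}) / (\min(k_i, k_j) + 1 - A_{ij})} with
#' \eqn{L_{ij} = \sum_{u \ne i,j} A_{iu} A_{uj}}; unit diagonal.
#'
#' @param A adjacency matrix with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(A) {
  k <- rowSums(A) - diag(A)
  L <- A %*% A - 2 * A  # removes the i and j terms (diag(A) = 1)
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  TOM
}

#' Detect network modules by hierarchical clustering of node dissimilarities
#'
#' Dissimilarity is `1 - A` (default) or `1 - TOM`. The dendrogram
#' (average linkage by default) is cut at a constant height, a fraction of
#' the tree maximum; clusters of at least `min_module_size` features become
#' modules, named by color in order of decreasing size; remaining features
#' are `"grey"` (unassigned). With `method = "hybrid"`, grey features are
#' subsequently attached to the module to which their mean adjacency is
#' highest, when that exceeds `reassign_threshold` (a simplified dynamic
#' hybrid cut).
#'
#' @param A adjacency matrix.
#' @param min_module_size minimum features per module (default 30).
#' @param cut_height_frac cut height as a fraction of the maximum merge
#'   height (default 0.995).
#' @param dissimilarity `"adjacency"` (1 - A, default) or `"tom"`.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param method `"height"` (default) or `"hybrid"`.
#' @param reassign_threshold minimum mean adjacency for hybrid
#'   reassignment (default 0.1).
#' @return object of class `module_set`: `colors` (named per-feature
#'   labels), `sizes`, `tree` (the hclust object), and the parameters.
#' @export
detect_modules <- function(A, min_module_size = 30, cut_height_frac = 0.995,
                           dissimilarity = c("adjacency", "tom"),
                           linkage = "average",
                           method = c("height", "hybrid"),
                           reassign_threshold = 0.1) {
  dissimilarity <- match.arg(dissimilarity)
  method <- match.arg(method)
  if (min_module_size < 2) stop("min_module_size must be at least 2")
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("f", seq_len(n))
  if (min_module_size > n) {
    warning("min_module_size exceeds the number of features; all grey")
    colors <- stats::setNames(rep("grey", n), ids)
    return(structure(list(colors = colors, sizes = table(colors),
                          tree = NULL, cut_height = NA_real_,
                          params = list()), class = "module_set"))
  }
  S <- if (dissimilarity == "tom") tom_similarity(A) else A
  D <- 1 - S
  dimnames(D) <- list(ids, ids)
  tree <- stats::hclust(stats::as.dist(D), method = linkage)
  h <- cut_height_frac * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  big <- big[order(-sizes[big], as.integer(big))]  # deterministic size ties
  colors <- rep("grey", n)
  for (i in seq_along(big)) {
    col <- if (i <= length(.module_colors)) .module_colors[i] else
      paste0("module", i)
    colors[cl == as.integer(big[i])] <- col
  }
  names(colors) <- ids
  if (method == "hybrid" && any(colors == "grey") && length(big)) {
    mods <- setdiff(unique(colors), "grey")
    grey_idx <- which(colors == "grey")
    for (g in grey_idx) {
      ma <- vapply(mods, function(m) mean(A[g, colors == m]), numeric(1))
      if (max(ma) > reassign_threshold) colors[g] <- mods[which.max(ma)]
    }
  }
  structure(list(colors = colors,
                 sizes = sort(table(colors), decreasing = TRUE),
                 tree = tree, cut_height = h,
                 params = list(min_module_size = min_module_size,
                               cut_height_frac = cut_height_frac,
                               dissimilarity = dissimilarity,
                               linkage = linkage, method = method)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", sum(names(x$sizes) != "grey"), "modules over",
      length(x$colors), "features\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes: first-principal-component sample scores per module
#'
#' Features of each module are standardized across samples (zero mean,
#' unit variance); the eigengene is the first right singular vector of the
#' standardized block, scaled to unit variance and oriented so that its
#' correlation with the module's mean standardized profile is positive.
#' Grey (unassigned) features are skipped.
#'
#' @param X feature matrix (features x samples).
#' @param modules a `module_set` or a named color vector.
#' @return list with `eigengenes` (module x sample matrix) and
#'   `var_explained` (named vector in `[0, 1]`).
#' @export
module_eigenvalues <- function(X, modules) {
  colors <- if (inherits(modules, "module_set")) modules$colors else modules
  colors <- colors[names(colors) %in% rownames(X)]
  mods <- setdiff(unique(colors), "grey")
  mods <- names(sort(table(colors[colors %in% mods]), decreasing = TRUE))
  if (!length(mods)) stop("no assigned modules")
  E <- matrix(NA_real_, nrow = length(mods), ncol = ncol(X),
              dimnames = list(mods, colnames(X)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    feats <- names(colors)[colors == m]
    M <- X[feats, , drop = FALSE]
    Ms <- t(scale(t(M)))  # rows standardized across samples
    if (nrow(Ms) == 1L) {
      warning("module '", m, "' has a single feature; ",
              "returning its standardized profile")
      E[m, ] <- Ms[1, ]
      ve[m] <- 1
      next
    }
    s <- svd(Ms)
    v <- s$v[, 1]
    v <- v / stats::sd(v)
    mp <- colMeans(Ms)
    orient <- if (stats::sd(mp) > 0) stats::cor(v, mp) else sum(s$u[, 1])
    if (orient < 0) v <- -v
    E[m, ] <- v
    ve[m] <- s$d[1]^2 / sum(s$d^2)
  }
  list(eigengenes = E, var_explained = ve)
}

#' Export the network as a weighted edge list or GraphML
#'
#' Edges with adjacency at or above the threshold are kept (upper
#' triangle, no self loops); node module colors are carried along.
#'
#' @param A adjacency matrix.
#' @param modules optional `module_set` or color vector for node
#'   attributes.
#' @param threshold minimum adjacency for an edge, in `[0, 1]` (default 0).
#' @param file optional output path.
#' @param format `"edgelist"` (TSV: from, to, weight) or `"graphml"`.
#' @return (invisibly) the edge data.frame.
#' @export
export_network <- function(A, modules = NULL, threshold = 0, file = NULL,
                           format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(A)))
  ut <- upper.tri(A)
  sel <- ut & A >= threshold
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = A[cbind(idx[, 1], idx[, 2])],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    if (format == "edgelist") {
      utils::write.table(edges, file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      colors <- if (is.null(modules)) rep("grey", length(ids)) else {
        cc <- if (inherits(modules, "module_set")) modules$colors else modules
        unname(cc[ids])
      }
      g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = ids, module = colors))
      igraph::write_graph(g, file, format = "graphml")
    }
  }
  invisible(edges)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return the Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
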