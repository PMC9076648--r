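#' @title Convergence/divergence statistics across sample groups
#' @name divergence-convergence
#' @description
#' Quantifies whether sample groups (litter types) become more or less
#' similar over the decomposition time series: PCA sample trajectories and
#' between-group Euclidean distance trends with a percent-change summary
#' (positive = divergence, negative = convergence).
NULL

#' PCA sample scores and per-group time-ordered trajectories
#'
#' PCA of the covariance of the (centered, unscaled) sample profiles;
#' returns sample scores, variance-explained fractions, and per-group
#' centroid paths ordered by day.
#'
#' @param X feature matrix (features x samples).
#' @param metadata sample table with `sample_id`, a grouping column and a
#'   `day` column.
#' @param n_comp number of components to keep (default 2); truncated with
#'   a warning if it exceeds the matrix rank.
#' @param group name of the grouping column (default `"litter"`).
#' @return list with `scores` (samples x components), `var_explained`,
#'   `paths` (group, day, per-component centroid), and the `prcomp` fit.
#' @export
pca_trajectories <- function(X, metadata, n_comp = 2, group = "litter") {
  if (n_comp < 2) stop("at least 2 components must be requested")
  fit <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > 1e-12)
  if (n_comp > rank) {
    warning("requested ", n_comp, " components but rank is ", rank,
            "; truncating")
    n_comp <- rank
  }
  scores <- fit$x[, seq_len(n_comp), drop = FALSE]
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  meta <- metadata[match(rownames(scores), metadata$sample_id), ,
                   drop = FALSE]
  agg <- stats::aggregate(scores,
                          by = list(group = meta[[group]], day = meta$day),
                          FUN = mean)
  agg <- agg[order(agg$group, agg$day), , drop = FALSE]
  rownames(agg) <- NULL
  list(scores = scores, var_explained = ve[seq_len(n_comp)],
       var_explained_all = ve, paths = agg, fit = fit)
}

#' Between-group Euclidean distance trend over time
#'
#' At every time point, Euclidean distances between all unordered pairs of
#' groups are computed either between group centroids (`mode =
#' "centroid"`) or as the mean over all cross-group sample pairs (`mode =
#' "full"`, default). The summary percent change is
#' `100 * (d_final - d_initial) / d_initial` on the per-day mean distance;
#' positive values indicate divergence.
#'
#' @param X feature matrix (features x samples).
#' @param metadata sample table with `sample_id`, the grouping column and
#'   `day`.
#' @param group grouping column name (default `"litter"`).
#' @param mode `"full"` (all cross-group sample pairs, default) or
#'   `"centroid"`.
#' @param initial_day,final_day anchor days for the percent change;
#'   default the earliest and latest day present.
#' @return object of class `distance_trend`: `pairwise` (day, group1,
#'   group2, distance), `per_day` (day, mean_distance), `percent_change`.
#' @export
group_distance_trend <- function(X, metadata, group = "litter",
                                 mode = c("full", "centroid"),
                                 initial_day = NULL, final_day = NULL) {
  mode <- match.arg(mode)
  meta <- metadata[match(colnames(X), metadata$sample_id), , drop = FALSE]
  days <- sort(unique(meta$day))
  groups <- sort(unique(meta[[group]]))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(initial_day)) initial_day <- min(days)
  if (is.null(final_day)) final_day <- max(days)
  rows <- list()
  for (d in days) {
    sel_d <- meta$day == d
    for (g in groups) {
      if (!any(sel_d & meta[[group]] == g)) {
        stop("group '", g, "' has no samples at day ", d)
      }
    }
    pairs <- utils::combn(groups, 2)
    for (p in seq_len(ncol(pairs))) {
      g1 <- pairs[1, p]; g2 <- pairs[2, p]
      A <- X[, sel_d & meta[[group]] == g1, drop = FALSE]
      B <- X[, sel_d & meta[[group]] == g2, drop = FALSE]
      dd <- if (mode == "centroid") {
        sqrt(sum((rowMeans(A) - rowMeans(B))^2))
      } else {
        mean(apply(A, 2, function(a) {
          apply(B, 2, function(b) sqrt(sum((a - b)^2)))
        }))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, group1 = g1, group2 = g2, distance = dd,
        stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, rows)
  per_day <- stats::aggregate(distance ~ day, data = pw, FUN = mean)
  names(per_day)[2] <- "mean_distance"
  d0 <- per_day$mean_distance[per_day$day == initial_day]
  d1 <- per_day$mean_distance[per_day$day == final_day]
  if (!length(d0) || !length(d1)) {
    stop("anchor day absent from the data")
  }
  pc <- if (d0 > 0) 100 * (d1 - d0) / d0 else NA_real_
  structure(list(pairwise = pw, per_day = per_day,
                 percent_change = pc, mode = mode,
                 initial_day = initial_day, final_day = final_day),
            class = "distance_trend")
}

#' @export
print.distance_trend <- function(x, ...) {
  cat("Between-group distance trend (", x$mode, " mode): ",
      sprintf("%+.1f%%", x$percent_change), " from day ", x$initial_day,
      " to day ", x$final_day, "\n", sep = "")
  invisible(x)
}
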