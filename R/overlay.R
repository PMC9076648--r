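#' @title Module-by-pathway overlay: concentration vs ubiquity
#' @name module-pathway-overlay
NULL

#' Cross-tabulate pathway-annotated molecules over network modules
#'
#' For every pathway, counts its matched formulas per network module and
#' reports module fractions, a concentration index (the maximum module
#' fraction: 1 when a pathway sits entirely in one module) and a ubiquity
#' flag set when no module fraction exceeds the threshold. Optionally a
#' hypergeometric enrichment p-value per (pathway, module) cell with
#' Benjamini-Hochberg correction across the table (an extension beyond the
#' visual argument it operationalizes; off by default).
#'
#' @param modules a `module_set` or named per-feature color vector (grey
#'   allowed).
#' @param matches a `formula_matches` object or a data.frame with columns
#'   `formula` and `pathway_id`.
#' @param ubiquity_threshold concentration index at or below which a
#'   pathway is flagged ubiquitous (default 0.5).
#' @param enrichment logical; compute hypergeometric enrichment p-values
#'   (default FALSE).
#' @return object of class `overlay_table`: `counts` and `fractions`
#'   (pathway x module matrices), `summary` (pathway_id, n_formulas,
#'   concentration, ubiquitous, top_module), optionally `p_values` and
#'   `p_adjusted` matrices. Pathways with no matched formula in the
#'   network are excluded (listed in `excluded`).
#' @export
module_pathway_overlay <- function(modules, matches,
                                   ubiquity_threshold = 0.5,
                                   enrichment = FALSE) {
  colors <- if (inherits(modules, "module_set")) modules$colors else modules
  recs <- if (inherits(matches, "formula_matches")) matches$records else
    matches
  if (!all(c("formula", "pathway_id") %in% names(recs))) {
    stop("matches must provide formula and pathway_id")
  }
  pairs <- unique(recs[, c("formula", "pathway_id")])
  pairs <- pairs[pairs$formula %in% names(colors), , drop = FALSE]
  all_pw <- sort(unique(recs$pathway_id))
  excluded <- setdiff(all_pw, unique(pairs$pathway_id))
  if (length(excluded)) {
    message(length(excluded),
            " pathway(s) with no matched formula in the network excluded")
  }
  if (!nrow(pairs)) stop("no matched formulas present in the network")
  pairs$module <- colors[pairs$formula]
  counts <- table(pathway = pairs$pathway_id, module = pairs$module)
  counts <- unclass(counts)
  fractions <- counts / rowSums(counts)
  conc <- apply(fractions, 1, max)
  top <- colnames(fractions)[apply(fractions, 1, which.max)]
  out <- list(
    counts = counts, fractions = fractions,
    summary = data.frame(pathway_id = rownames(counts),
                         n_formulas = rowSums(counts),
                         concentration = conc,
                         ubiquitous = conc <= ubiquity_threshold,
                         top_module = top,
                         stringsAsFactors = FALSE, row.names = NULL),
    excluded = excluded)
  if (isTRUE(enrichment)) {
    N <- nrow(unique(pairs[, "formula", drop = FALSE]))
    mod_sizes <- tapply(pairs$formula, pairs$module,
                        function(v) length(unique(v)))
    P <- counts * NA_real_
    for (pw in rownames(counts)) {
      K <- length(unique(pairs$formula[pairs$pathway_id == pw]))
      for (m in colnames(counts)) {
        x <- length(unique(pairs$formula[pairs$pathway_id == pw &
                                           pairs$module == m]))
        P[pw, m] <- stats::phyper(x - 1, mod_sizes[[m]],
                                  N - mod_sizes[[m]], K,
                                  lower.tail = FALSE)
      }
    }
    out$p_values <- P
    out$p_adjusted <- matrix(stats::p.adjust(P, method = "BH"),
                             nrow = nrow(P), dimnames = dimnames(P))
  }
  class(out) <- "overlay_table"
  out
}

#' @export
print.overlay_table <- function(x, ...) {
  cat("Module-pathway overlay:", nrow(x$counts), "pathways x",
      ncol(x$counts), "modules;", sum(x$summary$ubiquitous),
      "flagged ubiquitous\n")
  invisible(x)
}
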