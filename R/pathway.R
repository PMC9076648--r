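#' @title Pathway matching, deduplicated intensities and coverage
#' @name pathway-coverage
#' @description
#' Maps assigned sum formulas onto a compound-to-pathway annotation table
#' (KEGG-style snapshot: `compound_id`, `formula`, `pathway_id`,
#' `pathway_size`) and computes the coverage and intensity statistics of
#' the analysis: match rate, mean isomer multiplicity (structure
#' suggestions per matched formula), per-pathway summed relative intensity
#' with at most one intensity contribution per sum formula per pathway,
#' per-pathway coverage (detected members relative to pathway size), its
#' dispersion across sample groups, and a cross-dataset coverage
#' comparison.
NULL

.check_db <- function(db, need_size = FALSE) {
  need <- c("compound_id", "formula", "pathway_id")
  if (need_size) need <- c(need, "pathway_size")
  if (!all(need %in% names(db))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  }
  db
}

#' Match sum formulas against a compound/pathway annotation table
#'
#' @param formulas character vector of assigned canonical sum formulas.
#' @param db annotation data.frame (`compound_id`, `formula`,
#'   `pathway_id`, optionally `pathway_size`).
#' @return object of class `formula_matches`: `records` (annotation rows
#'   whose formula was assigned), `per_formula` (formula, n_compounds),
#'   `match_rate` (matched / assigned), `mean_multiplicity` (mean distinct
#'   compounds per matched formula; NA when nothing matches), and
#'   `all_pathways` (every pathway id in the table).
#' @export
match_formulas <- function(formulas, db) {
  db <- .check_db(db)
  formulas <- unique(formulas)
  records <- db[db$formula %in% formulas, , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(records)) {
    n_cpd <- tapply(records$compound_id, records$formula,
                    function(v) length(unique(v)))
    per_formula <- data.frame(formula = names(n_cpd),
                              n_compounds = as.integer(n_cpd),
                              stringsAsFactors = FALSE)
  } else {
    per_formula <- data.frame(formula = character(0),
                              n_compounds = integer(0))
  }
  structure(list(
    records = records,
    per_formula = per_formula,
    match_rate = if (length(formulas)) nrow(per_formula) / length(formulas)
                 else 0,
    mean_multiplicity = if (nrow(per_formula))
      mean(per_formula$n_compounds) else NA_real_,
    all_pathways = sort(unique(db$pathway_id))
  ), class = "formula_matches")
}

#' @export
print.formula_matches <- function(x, ...) {
  cat("Formula matches: ", nrow(x$per_formula), " matched formulas (",
      round(100 * x$match_rate, 1), "% match rate), mean ",
      round(x$mean_multiplicity, 2), " structure suggestions\n", sep = "")
  invisible(x)
}

#' Per-pathway summed relative intensity with per-formula deduplication
#'
#' For each pathway, the relative intensities of its matched sum formulas
#' are summed with at most one contribution per formula: a formula
#' matching several isomeric compounds in the same pathway contributes its
#' intensity exactly once, while a formula matching compounds in m
#' different pathways contributes once to each of the m pathways.
#'
#' @param matches a `formula_matches` object (or an annotation record
#'   data.frame restricted to matched formulas).
#' @param intensities named numeric vector of relative intensities, names
#'   are formulas. An intensity missing for a matched formula is an error.
#' @param pathways pathway ids to report (default: all pathways known to
#'   the match object, so unmatched pathways report 0).
#' @return data.frame `pathway_id`, `intensity`, `n_formulas`.
#' @export
pathway_intensity <- function(matches, intensities, pathways = NULL) {
  records <- if (inherits(matches, "formula_matches")) matches$records else
    .check_db(matches)
  if (is.null(pathways)) {
    pathways <- if (inherits(matches, "formula_matches")) matches$all_pathways
                else sort(unique(records$pathway_id))
  }
  pairs <- unique(records[, c("formula", "pathway_id")])
  missing <- setdiff(pairs$formula, names(intensities))
  if (length(missing)) {
    stop("no intensity for matched formula(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(pathway_id = pathways, intensity = 0,
                    n_formulas = 0L, stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    s <- tapply(intensities[pairs$formula], pairs$pathway_id, sum)
    n <- tapply(pairs$formula, pairs$pathway_id, length)
    i <- match(names(s), out$pathway_id)
    keep <- !is.na(i)
    out$intensity[i[keep]] <- as.numeric(s)[keep]
    out$n_formulas[i[keep]] <- as.integer(n)[keep]
  }
  out
}

#' Per-pathway coverage: detected members relative to pathway size
#'
#' Coverage is the number of distinct detected member compounds (default)
#' or distinct matched formulas, divided by the pathway size, clamped to
#' `[0, 1]`. Pathways of size zero are excluded with a warning.
#'
#' @param matches a `formula_matches` object or matched annotation records.
#' @param db the annotation table carrying `pathway_size`.
#' @param counting `"compound"` (default) or `"formula"` numerator.
#' @return data.frame `pathway_id`, `coverage`, `n_detected`,
#'   `pathway_size` over all pathways in `db`.
#' @export
pathway_coverage <- function(matches, db, counting = c("compound", "formula")) {
  counting <- match.arg(counting)
  db <- .check_db(db, need_size = TRUE)
  records <- if (inherits(matches, "formula_matches")) matches$records else
    matches
  sizes <- tapply(db$pathway_size, db$pathway_id, function(v) v[1])
  if (any(sizes == 0)) {
    warning(sum(sizes == 0), " pathway(s) of size zero excluded")
    sizes <- sizes[sizes > 0]
  }
  detected <- if (nrow(records)) {
    key <- if (counting == "compound") records$compound_id else
      records$formula
    tapply(key, records$pathway_id, function(v) length(unique(v)))
  } else numeric(0)
  out <- data.frame(pathway_id = names(sizes),
                    pathway_size = as.integer(sizes),
                    n_detected = 0L, stringsAsFactors = FALSE)
  i <- match(names(detected), out$pathway_id)
  keep <- !is.na(i)
  out$n_detected[i[keep]] <- as.integer(detected)[keep]
  out$coverage <- pmin(out$n_detected / out$pathway_size, 1)
  rownames(out) <- NULL
  out[, c("pathway_id", "coverage", "n_detected", "pathway_size")]
}

#' Dispersion of pathway coverage across sample groups
#'
#' @param coverages either a pathway x group numeric matrix of coverage
#'   fractions, or a named list of coverage data.frames as returned by
#'   [pathway_coverage()] (one per group; joined on `pathway_id`).
#' @return list with `per_pathway` (pathway_id, mean, sd) and `mean_sd`
#'   (mean of the per-pathway standard deviations).
#' @export
coverage_dispersion <- function(coverages) {
  if (is.list(coverages) && !is.matrix(coverages) &&
      !is.data.frame(coverages)) {
    ids <- sort(unique(unlist(lapply(coverages, `[[`, "pathway_id"))))
    M <- sapply(coverages, function(d) {
      d$coverage[match(ids, d$pathway_id)]
    })
    rownames(M) <- ids
    coverages <- M
  }
  coverages <- as.matrix(coverages)
  if (is.null(rownames(coverages))) {
    rownames(coverages) <- paste0("pw", seq_len(nrow(coverages)))
  }
  if (ncol(coverages) < 2L) {
    stop("coverage dispersion requires at least 2 groups")
  }
  per <- data.frame(pathway_id = rownames(coverages),
                    mean = rowMeans(coverages, na.rm = TRUE),
                    sd = apply(coverages, 1, stats::sd, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_pathway = per, mean_sd = mean(per$sd, na.rm = TRUE))
}

#' Compare pathway coverages between two datasets
#'
#' Joins two coverage tables (e.g. DOM HR-MS vs 16S-based functional
#' predictions) on pathway id and classifies shared pathways into
#' quadrants by coverage thresholds. Pathways present in only one table
#' are kept with a missing flag.
#'
#' @param dom,other data.frames with columns `pathway_id` and `coverage`.
#' @param threshold coverage at or above which a pathway counts as "high";
#'   a single value or `c(dom, other)` (default 0.5).
#' @return data.frame `pathway_id`, `coverage_dom`, `coverage_other`,
#'   `quadrant` (`both-high`, `dom-only`, `other-only`, `both-low`, or
#'   `NA` when one side is missing), `missing_in`.
#' @export
compare_coverage <- function(dom, other, threshold = 0.5) {
  threshold <- rep(threshold, length.out = 2)
  ids <- union(dom$pathway_id, other$pathway_id)
  if (!length(intersect(dom$pathway_id, other$pathway_id))) {
    warning("the two coverage tables share no pathways")
  }
  out <- data.frame(
    pathway_id = ids,
    coverage_dom = dom$coverage[match(ids, dom$pathway_id)],
    coverage_other = other$coverage[match(ids, other$pathway_id)],
    stringsAsFactors = FALSE)
  out$missing_in <- ifelse(is.na(out$coverage_dom), "dom",
                    ifelse(is.na(out$coverage_other), "other", ""))
  hd <- out$coverage_dom >= threshold[1]
  ho <- out$coverage_other >= threshold[2]
  out$quadrant <- ifelse(is.na(hd) | is.na(ho), NA_character_,
                  ifelse(hd & ho, "both-high",
                  ifelse(hd & !ho, "dom-only",
                  ifelse(!hd & ho, "other-only", "both-low"))))
  out[order(out$pathway_id), , drop = FALSE]
}
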