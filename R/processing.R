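#' @title Peak-list processing: filtering, formula assignment, feature matrix
#' @name feature-processing
#' @description
#' Turns raw per-sample peak lists (m/z, intensity, signal-to-noise) into a
#' filtered, formula-annotated relative-intensity feature matrix. Filtering
#' keeps peaks with S/N strictly above a threshold (default 4), inside the
#' acquisition window (default m/z 175--1000), and not matching any blank
#' mass within a ppm window. Formula assignment exhaustively enumerates
#' CHNOS compositions within configurable element ranges and a ppm
#' tolerance, applying standard DOM plausibility rules.
NULL

#' Default element count ranges for formula assignment
#'
#' Typical direct-infusion Orbitrap DOM settings; each entry is
#' `c(min, max)`.
#'
#' @return named list of integer ranges for C, H, N, O, S.
#' @export
element_ranges <- function(C = c(1L, 100L), H = c(0L, 200L), N = c(0L, 5L),
                           O = c(0L, 80L), S = c(0L, 2L)) {
  r <- list(C = C, H = H, N = N, O = O, S = S)
  for (el in names(r)) {
    v <- as.integer(r[[el]])
    if (length(v) != 2L || any(is.na(v)) || v[1] < 0L || v[2] < v[1]) {
      stop("invalid range for element ", el)
    }
    r[[el]] <- v
  }
  if (r$C[2] < 1L) stop("carbon range must allow at least one atom")
  r
}

#' Chemical plausibility filters for candidate formulas
#'
#' Standard DOM quality rules, each individually switchable: elemental
#' ratio windows H/C in `[hc_min, hc_max]`, O/C at most `oc_max`, and an
#' even-electron check requiring a non-negative integer count of
#' ring-and-double-bond equivalents.
#'
#' @export
plausibility_filters <- function(hc_min = 0.3, hc_max = 2.5, oc_max = 1.2,
                                 ratio_check = TRUE, even_electron = TRUE) {
  list(hc_min = hc_min, hc_max = hc_max, oc_max = oc_max,
       ratio_check = isTRUE(ratio_check), even_electron = isTRUE(even_electron))
}

.check_peaks <- function(peaks, what = "peaks") {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(data.frame(mz = numeric(0), intensity = numeric(0), sn = numeric(0)))
  }
  need <- c("mz", "intensity", "sn")
  if (!all(need %in% names(peaks))) {
    stop(what, " must have columns mz, intensity, sn")
  }
  if (any(peaks$mz <= 0)) stop(what, ": m/z values must be positive")
  if (any(peaks$intensity < 0)) stop(what, ": negative intensities")
  if (any(peaks$sn < 0)) stop(what, ": negative signal-to-noise ratios")
  peaks
}

#' Filter a peak list by S/N, acquisition window and blank masses
#'
#' Keeps peaks with signal-to-noise strictly greater than `sn_threshold`
#' (a peak at exactly the threshold is removed), m/z inside the window,
#' and no blank peak within `blank_ppm` of their m/z.
#'
#' @param peaks data.frame with columns `mz`, `intensity`, `sn`.
#' @param blanks optional blank-sample peak list (same columns); may be
#'   `NULL` or empty.
#' @param sn_threshold strict lower bound on S/N (default 4).
#' @param mz_window acquisition window, `c(low, high)` (default 175--1000,
#'   inclusive).
#' @param blank_ppm relative mass window (ppm) for blank exclusion.
#' @return the filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, blanks = NULL, sn_threshold = 4,
                         mz_window = c(175, 1000), blank_ppm = 2) {
  peaks <- .check_peaks(peaks)
  if (nrow(peaks) == 0L) return(peaks)
  keep <- peaks$sn > sn_threshold &
    peaks$mz >= mz_window[1] & peaks$mz <= mz_window[2]
  peaks <- peaks[keep, , drop = FALSE]
  if (!is.null(blanks)) {
    blanks <- .check_peaks(blanks, "blanks")
    if (nrow(blanks) > 0L && nrow(peaks) > 0L) {
      bmz <- sort(blanks$mz)
      hit <- vapply(peaks$mz, function(m) {
        any(abs(m - bmz) / bmz * 1e6 <= blank_ppm)
      }, logical(1))
      peaks <- peaks[!hit, , drop = FALSE]
    }
  }
  rownames(peaks) <- NULL
  peaks
}

# enumeration grid over C,N,O,S; H solved from the residual mass
.candidate_grid <- function(ranges) {
  g <- expand.grid(
    C = seq.int(ranges$C[1], ranges$C[2]),
    N = seq.int(ranges$N[1], ranges$N[2]),
    O = seq.int(ranges$O[1], ranges$O[2]),
    S = seq.int(ranges$S[1], ranges$S[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  g$base <- g$C * .element_masses[["C"]] + g$N * .element_masses[["N"]] +
    g$O * .element_masses[["O"]] + g$S * .element_masses[["S"]]
  g
}

.enumerate_candidates <- function(neutral, grid, ranges, ppm_tol, filters) {
  h <- round((neutral - grid$base) / .element_masses[["H"]])
  ok <- h >= ranges$H[1] & h <= ranges$H[2]
  if (!any(ok)) return(NULL)
  cand <- grid[ok, , drop = FALSE]
  cand$H <- h[ok]
  cand$mass <- cand$base + cand$H * .element_masses[["H"]]
  cand$ppm <- 1e6 * (neutral - cand$mass) / cand$mass
  cand <- cand[abs(cand$ppm) <= ppm_tol, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  if (isTRUE(filters$ratio_check)) {
    hc <- cand$H / cand$C
    oc <- cand$O / cand$C
    cand <- cand[hc >= filters$hc_min & hc <= filters$hc_max &
                   oc <= filters$oc_max, , drop = FALSE]
  }
  if (isTRUE(filters$even_electron) && nrow(cand) > 0L) {
    rdbe <- .rdbe(cand$C, cand$H, cand$N)
    cand <- cand[rdbe >= 0 & abs(rdbe - round(rdbe)) < 1e-9, , drop = FALSE]
  }
  if (nrow(cand) == 0L) return(NULL)
  # rank: |ppm| ascending, ties by fewer heteroatoms (N+S), then lower H
  ord <- order(abs(cand$ppm), cand$N + cand$S, cand$H)
  cand <- cand[ord, , drop = FALSE]
  cand$formula <- vapply(seq_len(nrow(cand)), function(i) {
    formula_string(c(C = cand$C[i], H = cand$H[i], N = cand$N[i],
                     O = cand$O[i], S = cand$S[i]))
  }, character(1))
  rownames(cand) <- NULL
  cand[, c("formula", "C", "H", "N", "O", "S", "mass", "ppm")]
}

#' Assign molecular formulas to peaks by exhaustive enumeration
#'
#' Each peak's neutral mass (m/z + proton mass, singly deprotonated ion
#' assumed) is matched against all CHNOS compositions within the element
#' ranges whose relative mass error is within `ppm_tol`
#' (error = 1e6 (observed - candidate) / candidate mass). Candidates are
#' sorted by absolute ppm error; ties broken by fewer heteroatoms (N+S),
#' then lower H. The best surviving candidate is the chosen formula.
#'
#' @param peaks data.frame with column `mz` (and optionally `intensity`,
#'   carried through).
#' @param ranges element ranges, see [element_ranges()].
#' @param ppm_tol assignment tolerance in ppm (default 2).
#' @param filters plausibility filters, see [plausibility_filters()].
#' @return data.frame with one row per peak: `mz`, `intensity` (if given),
#'   `formula` (NA when unassigned), `ppm_error`, `n_candidates`; the full
#'   candidate tables are attached as attribute `"candidates"` (a list).
#' @export
assign_formulas <- function(peaks, ranges = element_ranges(), ppm_tol = 2,
                            filters = plausibility_filters()) {
  if (is.numeric(peaks)) peaks <- data.frame(mz = peaks)
  if (!"mz" %in% names(peaks)) stop("peaks must have an mz column")
  if (nrow(peaks) > 0L && any(peaks$mz <= 0)) stop("m/z values must be positive")
  grid <- .candidate_grid(ranges)
  cands <- vector("list", nrow(peaks))
  formula <- rep(NA_character_, nrow(peaks))
  ppm_error <- rep(NA_real_, nrow(peaks))
  n_cand <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cc <- .enumerate_candidates(neutral_mass(peaks$mz[i]), grid, ranges,
                                ppm_tol, filters)
    if (!is.null(cc)) {
      cands[[i]] <- cc
      formula[i] <- cc$formula[1]
      ppm_error[i] <- cc$ppm[1]
      n_cand[i] <- nrow(cc)
    }
  }
  out <- data.frame(mz = peaks$mz, formula = formula,
                    ppm_error = ppm_error, n_candidates = n_cand,
                    stringsAsFactors = FALSE)
  if ("intensity" %in% names(peaks)) {
    out$intensity <- peaks$intensity
  }
  attr(out, "candidates") <- cands
  out
}

#' Build a relative-intensity feature matrix from per-sample assignments
#'
#' Rows are the union of chosen sum formulas across samples, columns are
#' samples. Duplicate formulas within a sample are summed; formulas absent
#' from a sample get 0. Under the default normalization each column is
#' divided by its total so sample intensities sum to 1.
#'
#' @param assignments named list (one element per sample) of data.frames
#'   with columns `formula` and `intensity` (rows with `NA` formula are
#'   dropped).
#' @param normalize `"sum"` (relative intensities, default) or `"none"`.
#' @return numeric matrix, formulas x samples.
#' @export
build_feature_matrix <- function(assignments, normalize = c("sum", "none")) {
  normalize <- match.arg(normalize)
  if (length(assignments) == 0L) stop("no samples given")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    names(assignments) <- paste0("sample", seq_along(assignments))
  }
  per_sample <- lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    a <- a[!is.na(a$formula), c("formula", "intensity"), drop = FALSE]
    if (nrow(a) == 0L) {
      stop("sample '", s, "' has no retained peaks with an assigned formula")
    }
    stats::aggregate(intensity ~ formula, data = a, FUN = sum)
  })
  formulas <- sort(unique(unlist(lapply(per_sample, `[[`, "formula"))))
  X <- matrix(0, nrow = length(formulas), ncol = length(assignments),
              dimnames = list(formulas, names(assignments)))
  for (j in seq_along(per_sample)) {
    X[per_sample[[j]]$formula, j] <- per_sample[[j]]$intensity
  }
  if (normalize == "sum") {
    X <- sweep(X, 2, colSums(X), "/")
  }
  X
}
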