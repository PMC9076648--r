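#' @title Monoisotopic masses and formula arithmetic
#' @name formula-arithmetic
#' @description
#' Helpers for CHNOS sum formulas as used in negative-mode direct-infusion
#' HR-MS of dissolved organic matter: parsing and printing of Hill-order
#' formula strings, monoisotopic neutral masses, and the deprotonated
#' \eqn{[M-H]^-} m/z convention used throughout the package.
NULL

# IUPAC monoisotopic atomic masses (u); CHNOS covers DOM formula space here.
.element_masses <- c(
  C = 12.000000000,
  H = 1.00782503224,
  N = 14.00307400446,
  O = 15.99491461960,
  S = 31.9720711744
)

#' Mass of the proton (u), used for the [M-H]- deprotonation convention
#' @export
proton_mass <- 1.007276466

.elements <- names(.element_masses)

#' Parse a CHNOS sum-formula string into element counts
#'
#' @param x a formula string such as `"C6H12O6"` (counts of 1 may be
#'   omitted, e.g. `"CH4"`).
#' @return a named integer vector over C, H, N, O, S.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(x)) {
    stop("cannot parse formula string: ", x)
  }
  counts <- stats::setNames(integer(length(.elements)), .elements)
  for (tok in toks) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% .elements) {
      stop("unsupported element '", el, "' in formula ", x)
    }
    counts[el] <- counts[el] + n
  }
  counts
}

#' Canonical Hill-order formula string from element counts
#'
#' Carbon first, hydrogen second, remaining elements alphabetically;
#' counts of one are omitted, zero-count elements dropped.
#'
#' @param counts named numeric vector with (a subset of) names C, H, N, O, S;
#'   counts must be non-negative integers.
#' @return a single canonical formula string.
#' @export
formula_string <- function(counts) {
  full <- stats::setNames(integer(length(.elements)), .elements)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("negative element counts")
  parts <- vapply(.elements, function(el) {
    n <- full[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  out <- paste0(parts, collapse = "")
  if (!nzchar(out)) stop("empty formula")
  out
}

#' Monoisotopic neutral mass of a sum formula
#'
#' @param x a formula string or a named count vector as returned by
#'   [parse_formula()].
#' @return neutral monoisotopic mass in u.
#' @examples
#' formula_mass("C6H12O6")
#' @export
formula_mass <- function(x) {
  if (is.character(x)) x <- parse_formula(x)
  counts <- stats::setNames(numeric(length(.elements)), .elements)
  counts[names(x)] <- x
  if (any(counts < 0)) stop("negative element counts")
  sum(counts * .element_masses)
}

#' m/z of the singly deprotonated ion [M-H]- for a neutral formula
#'
#' @inheritParams formula_mass
#' @return m/z in u (negative mode, z = 1 assumed).
#' @export
mz_from_formula <- function(x) {
  formula_mass(x) - proton_mass
}

#' Neutral mass corresponding to an observed negative-mode m/z
#'
#' @param mz observed m/z of a singly deprotonated ion.
#' @return neutral mass in u.
#' @export
neutral_mass <- function(mz) {
  mz + proton_mass
}

# ring-and-double-bond equivalents for a CHNOS composition (trivalent N,
# divalent O/S); even-electron neutral molecules have integer RDBE >= 0
.rdbe <- function(C, H, N) {
  C - H / 2 + N / 2 + 1
}
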