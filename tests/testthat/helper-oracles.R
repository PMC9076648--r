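# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (own mass constants, own string builder, own
# alignment), so agreement is evidence rather than tautology.

# monoisotopic masses, written out independently of the package source
.orc_masses <- c(C = 12, H = 1.00782503224, N = 14.00307400446,
                 O = 15.9949146196, S = 31.9720711744)
.orc_proton <- 1.007276466

orc_formula_string <- function(C, H, N = 0, O = 0, S = 0) {
  piece <- function(el, n) {
    if (n == 0) "" else if (n == 1) el else paste0(el, n)
  }
  paste0(piece("C", C), piece("H", H), piece("N", N), piece("O", O),
         piece("S", S))
}

# full-grid enumeration over element ranges (H included in the grid),
# relative error measured against the candidate mass
orc_candidates <- function(neutral, ranges, ppm_tol) {
  g <- expand.grid(C = seq(ranges$C[1], ranges$C[2]),
                   H = seq(ranges$H[1], ranges$H[2]),
                   N = seq(ranges$N[1], ranges$N[2]),
                   O = seq(ranges$O[1], ranges$O[2]),
                   S = seq(ranges$S[1], ranges$S[2]))
  mass <- g$C * .orc_masses[["C"]] + g$H * .orc_masses[["H"]] +
    g$N * .orc_masses[["N"]] + g$O * .orc_masses[["O"]] +
    g$S * .orc_masses[["S"]]
  ppm <- 1e6 * (neutral - mass) / mass
  hit <- g[abs(ppm) <= ppm_tol, , drop = FALSE]
  if (nrow(hit) == 0L) return(character(0))
  sort(mapply(orc_formula_string, hit$C, hit$H, hit$N, hit$O, hit$S))
}

# RMS after optimal rigid alignment (rotation + translation, no scaling)
# of configuration Y onto X
orc_procrustes_rms <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(t(Y) %*% X)
  R <- s$u %*% t(s$v)
  sqrt(mean(rowSums((Y %*% R - X)^2)))
}

# hypergeometric upper tail P(X >= x) by direct summation of choose() terms
orc_hyper_tail <- function(x, white, black, drawn) {
  j <- x:min(white, drawn)
  sum(choose(white, j) * choose(black, drawn - j)) / choose(white + black, drawn)
}

# small deterministic sim shared by several tests
tiny_sim <- function(seed = 7) {
  generate_feature_matrix(
    study_design(litter_types = "beech", sites = "S1", replicates = 1L,
                 time_points = c(2, 4, 8), seed = seed),
    planted_structure(blocks = list(block(6, "litter", "beech"),
                                    block(4, "noise")),
                      within_r = 0.8, sigma = 0.2))
}
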