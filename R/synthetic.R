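#' @title Synthetic litter-decomposition HR-MS data with planted structure
#' @name synthetic-data
#' @description
#' Generates feature matrices, peak lists, sample metadata and
#' compound/pathway annotation tables that emulate a lab-scale litter
#' decomposition study: four litter types from two sites, three replicates,
#' leachates sampled on days 2, 4, 8, 15 and 22 (120 leachate samples).
#' Correlated feature blocks are planted with known drivers (litter-specific,
#' time-increasing, convergence among a litter subset, or pure noise) so that
#' every downstream stage -- filtering, network inference, module detection,
#' coverage statistics, trend statistics -- can be checked against ground
#' truth.
NULL

#' Describe the sampling design of the decomposition experiment
#'
#' @param litter_types litter labels; default the four types of the emulated
#'   study.
#' @param sites site labels; default two sites.
#' @param replicates biological replicates per litter x site (default 3).
#' @param time_points sampling days; day 0 denotes the initial litter
#'   sample, positive days are leachate samplings (default
#'   `c(0, 2, 4, 8, 15, 22)`).
#' @param include_day0 logical; whether day-0 initial samples appear in the
#'   generated feature matrix (default `FALSE`: the default design yields
#'   the 4 x 2 x 3 x 5 = 120 leachate samples).
#' @param seed integer seed for all generation from this design.
#' @return an object of class `study_design`.
#' @export
study_design <- function(litter_types = c("beech", "oak", "pine", "grass"),
                         sites = c("Hainich", "Linde"),
                         replicates = 3L,
                         time_points = c(0, 2, 4, 8, 15, 22),
                         include_day0 = FALSE,
                         seed = 1L) {
  stopifnot(length(litter_types) >= 1, length(sites) >= 1,
            replicates >= 1, length(time_points) >= 1)
  leachate <- sort(time_points[time_points > 0])
  if (length(leachate) == 0L) stop("design needs at least one leachate day")
  d <- list(litter_types = litter_types, sites = sites,
            replicates = as.integer(replicates),
            time_points = sort(unique(time_points)),
            leachate_days = leachate,
            include_day0 = isTRUE(include_day0) && any(time_points == 0),
            seed = as.integer(seed))
  d$n_samples <- length(litter_types) * length(sites) * d$replicates *
    length(leachate)
  class(d) <- "study_design"
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$litter_types), "litter types x",
      length(x$sites), "sites x", x$replicates, "replicates x",
      length(x$leachate_days), "leachate days =", x$n_samples,
      "leachate samples\n")
  invisible(x)
}

#' One planted feature block
#'
#' @param n number of features in the block.
#' @param driver `"litter"` (litter-specific temporal ramp),
#'   `"convergence"` (ramp shared by a litter subset), `"time"` (global
#'   ramp) or `"noise"` (no structure).
#' @param litters litter labels the driver applies to (required for
#'   `"litter"` and `"convergence"`).
#' @param trend `"increasing"` (default) or `"decreasing"` temporal ramp;
#'   a decreasing ramp over a litter subset models shared initial
#'   similarity that fades with decomposition.
#' @export
block <- function(n, driver = c("litter", "convergence", "time", "noise"),
                  litters = NULL, trend = c("increasing", "decreasing")) {
  driver <- match.arg(driver)
  trend <- match.arg(trend)
  if (driver %in% c("litter", "convergence") && is.null(litters)) {
    stop("driver '", driver, "' requires litters")
  }
  list(n = as.integer(n), driver = driver, litters = litters, trend = trend)
}

#' Default planted structure: three litter-specific blocks plus noise
#'
#' 3 blocks of 50 features driven by beech, oak and pine respectively,
#' plus 50 unstructured noise features (200 features total).
#'
#' @export
default_blocks <- function() {
  list(
    block(50, "litter", "beech"),
    block(50, "litter", "oak"),
    block(50, "litter", "pine"),
    block(50, "noise")
  )
}

#' A richer block layout emulating the module patterns of the study design
#'
#' Seven litter-specific blocks, two convergence blocks shared by three
#' litters each, one decreasing "initial similarity" block shared by the
#' tree litters, and a noise block.
#'
#' @param n_per_block features per structured block (default 60).
#' @param n_noise unstructured features (default 100).
#' @export
litter_study_blocks <- function(n_per_block = 60L, n_noise = 100L) {
  list(
    block(n_per_block, "litter", "beech"),
    block(n_per_block, "litter", "beech"),
    block(n_per_block, "litter", "oak"),
    block(n_per_block, "litter", "grass"),
    block(n_per_block, "litter", "grass"),
    block(n_per_block, "litter", "pine"),
    block(n_per_block, "litter", "pine"),
    block(n_per_block, "convergence", c("beech", "grass", "pine")),
    block(n_per_block, "convergence", c("beech", "grass", "oak")),
    block(n_per_block, "convergence", c("beech", "oak", "pine"),
          trend = "decreasing"),
    block(n_noise, "noise")
  )
}

#' Planted correlation structure for the generator
#'
#' @param blocks list of [block()] definitions; feature counts sum to the
#'   total number of features.
#' @param within_r target within-block Pearson correlation, in (0, 1].
#' @param sigma lognormal noise sigma on the natural-log scale (default
#'   0.3, i.e. roughly 30\% multiplicative CV).
#' @param baseline_log_sd spread of per-feature baseline log-abundances.
#' @param annotation_fraction fraction of features later given pathway
#'   annotations (default 0.2).
#' @param multiplicity sampler for structure suggestions per annotated
#'   formula: a function of `n` returning positive integers; default
#'   `1 + rpois(n, 1.9)` (mean 2.9).
#' @return an object of class `planted_structure`.
#' @export
planted_structure <- function(blocks = default_blocks(),
                              within_r = 0.9,
                              sigma = 0.3,
                              baseline_log_sd = 1,
                              annotation_fraction = 0.2,
                              multiplicity = function(n) 1L + stats::rpois(n, 1.9)) {
  if (!length(blocks)) stop("at least one block required")
  if (!(within_r > 0 && within_r <= 1)) stop("within_r must be in (0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  if (within_r == 1 && sigma > 0) {
    stop("target correlation 1 is only attainable with sigma = 0")
  }
  if (annotation_fraction < 0 || annotation_fraction > 1) {
    stop("annotation_fraction must be in [0, 1]")
  }
  s <- list(blocks = blocks, within_r = within_r, sigma = sigma,
            baseline_log_sd = baseline_log_sd,
            annotation_fraction = annotation_fraction,
            multiplicity = multiplicity)
  class(s) <- "planted_structure"
  s
}

# sample metadata table for a design
.design_metadata <- function(design) {
  days <- if (design$include_day0) c(0, design$leachate_days) else
    design$leachate_days
  g <- expand.grid(day = days,
                   replicate = seq_len(design$replicates),
                   site = design$sites,
                   litter = design$litter_types,
                   stringsAsFactors = FALSE)
  g <- g[, c("litter", "site", "replicate", "day")]
  g$sample_id <- sprintf("%s_%s_r%d_d%02d", g$litter, g$site, g$replicate,
                         g$day)
  g[, c("sample_id", "litter", "site", "replicate", "day")]
}

# latent driver profile of a block over the samples, standardized
.block_profile <- function(blk, meta, leachate_days) {
  ramp <- (meta$day - min(leachate_days)) /
    (max(leachate_days) - min(leachate_days))
  ramp[meta$day == 0] <- 0
  ramp <- pmax(ramp, 0)
  if (blk$trend == "decreasing") ramp <- 1 - ramp
  z <- switch(blk$driver,
    litter = ,
    convergence = as.numeric(meta$litter %in% blk$litters) * ramp,
    time = ramp,
    noise = rep(0, nrow(meta))
  )
  if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else rep(0, nrow(meta))
}

# random plausible CHNOS formulas with [M-H]- inside the acquisition window
.random_formulas <- function(n) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not generate enough distinct formulas")
    m <- n - length(out) + 10L
    C <- sample(8:40, m, replace = TRUE)
    H <- round(C * stats::runif(m, 0.7, 1.8))
    N <- sample(0:2, m, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    S <- sample(0:1, m, replace = TRUE, prob = c(0.92, 0.08))
    O <- round(C * stats::runif(m, 0.1, 0.9))
    H <- H + (H + N) %% 2  # even-electron parity
    ok <- H / C >= 0.3 & H / C <= 2.5 & O / C <= 1.2 & .rdbe(C, H, N) >= 0
    f <- vapply(which(ok), function(i) {
      formula_string(c(C = C[i], H = H[i], N = N[i], O = O[i], S = S[i]))
    }, character(1))
    mz <- vapply(f, mz_from_formula, numeric(1))
    f <- f[mz > 176 & mz < 999]
    out <- unique(c(out, f))
  }
  out[seq_len(n)]
}

#' Generate a synthetic relative-intensity feature matrix with ground truth
#'
#' Features are organized in planted blocks. Each block has a latent
#' temporal/litter driver profile; per-feature log-intensities are the
#' feature baseline plus `alpha` times the standardized driver plus
#' independent Gaussian noise of sd `sigma`, with
#' `alpha = sigma * sqrt(r / (1 - r))` so the log-scale within-block
#' correlation equals the target `r` (with `sigma = 0`, block features are
#' exact multiples of each other). Intensities are exponentiated and each
#' sample column is normalized to sum 1.
#'
#' @param design a [study_design()].
#' @param structure a [planted_structure()].
#' @param normalize `"sum"` (default, column-stochastic) or `"none"`.
#' @return a list of class `dom_sim` with elements `matrix` (formulas x
#'   samples), `metadata` (sample table), `truth` (feature, block, driver),
#'   `design`, `structure`.
#' @export
generate_feature_matrix <- function(design = study_design(),
                                    structure = planted_structure(),
                                    normalize = c("sum", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(design, "study_design"),
            inherits(structure, "planted_structure"))
  n_feat <- sum(vapply(structure$blocks, `[[`, integer(1), "n"))
  if (n_feat < 1L) stop("structure has zero features")
  meta <- .design_metadata(design)
  if (nrow(meta) < 1L) stop("design has zero samples")
  set.seed(design$seed)

  formulas <- .random_formulas(n_feat)
  sigma <- structure$sigma
  r <- structure$within_r
  alpha <- if (sigma == 0) 1 else sigma * sqrt(r / (1 - r))

  X <- matrix(0, nrow = n_feat, ncol = nrow(meta),
              dimnames = list(formulas, meta$sample_id))
  truth <- data.frame(feature = formulas,
                      block = character(n_feat),
                      driver = character(n_feat),
                      stringsAsFactors = FALSE)
  row0 <- 0L
  for (b in seq_along(structure$blocks)) {
    blk <- structure$blocks[[b]]
    idx <- row0 + seq_len(blk$n)
    row0 <- row0 + blk$n
    z <- .block_profile(blk, meta, design$leachate_days)
    mu <- stats::rnorm(blk$n, 0, structure$baseline_log_sd)
    a <- if (blk$driver == "noise") 0 else alpha
    eps <- matrix(stats::rnorm(blk$n * nrow(meta), 0, sigma),
                  nrow = blk$n)
    X[idx, ] <- exp(mu + a * rep(z, each = blk$n) + eps)
    lab <- if (blk$driver %in% c("litter", "convergence")) {
      paste0("block", b, "_", blk$driver, "_",
             paste(blk$litters, collapse = "+"))
    } else {
      paste0("block", b, "_", blk$driver)
    }
    truth$block[idx] <- lab
    truth$driver[idx] <- blk$driver
  }
  if (normalize == "sum") X <- sweep(X, 2, colSums(X), "/")
  out <- list(matrix = X, metadata = meta, truth = truth,
              design = design, structure = structure)
  class(out) <- "dom_sim"
  out
}

#' @export
print.dom_sim <- function(x, ...) {
  cat("Synthetic DOM feature matrix:", nrow(x$matrix), "features x",
      ncol(x$matrix), "samples;", length(unique(x$truth$block)),
      "planted blocks\n")
  invisible(x)
}

#' Generate per-sample peak lists (and a blank list) from a feature matrix
#'
#' The inverse of the peak-processing stage: each feature becomes a peak at
#' the deprotonated monoisotopic m/z of its sum formula, jittered uniformly
#' within `ppm_jitter`. A configurable fraction of peaks is given S/N <= 4
#' (so the default filter removes them), and blank masses are injected into
#' the blank list and every sample.
#'
#' @param x a `dom_sim` object or a numeric matrix with formula row names.
#' @param formulas formula strings per feature; defaults to row names.
#' @param ppm_jitter maximum absolute mass error in ppm (default 0.5).
#' @param sn_low_frac fraction of sample peaks assigned S/N in (0, 4]
#'   (default 0).
#' @param blank_masses numeric m/z values injected as blank peaks.
#' @param intensity_scale multiplier from relative intensity to arbitrary
#'   counts (default 1e6).
#' @param seed optional seed for jitter and S/N draws.
#' @return list with `samples` (named list of peak data.frames with columns
#'   mz, intensity, sn) and `blank` (a peak data.frame).
#' @export
generate_peak_lists <- function(x, formulas = NULL, ppm_jitter = 0.5,
                                sn_low_frac = 0, blank_masses = numeric(0),
                                intensity_scale = 1e6, seed = NULL) {
  X <- if (inherits(x, "dom_sim")) x$matrix else x
  if (is.null(formulas)) formulas <- rownames(X)
  if (is.null(formulas) || length(formulas) != nrow(X)) {
    stop("need one sum formula per feature")
  }
  if (sn_low_frac < 0 || sn_low_frac > 1) stop("sn_low_frac must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  base_mz <- vapply(formulas, mz_from_formula, numeric(1))
  samples <- stats::setNames(vector("list", ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    n <- nrow(X)
    jit <- stats::runif(n, -ppm_jitter, ppm_jitter)
    low <- stats::runif(n) < sn_low_frac
    sn <- ifelse(low, stats::runif(n, 0, 4), stats::runif(n, 5, 150))
    pk <- data.frame(mz = base_mz * (1 + jit / 1e6),
                     intensity = X[, j] * intensity_scale,
                     sn = sn)
    if (length(blank_masses)) {
      pk <- rbind(pk, data.frame(
        mz = blank_masses,
        intensity = stats::median(pk$intensity),
        sn = stats::runif(length(blank_masses), 5, 150)))
    }
    rownames(pk) <- NULL
    samples[[j]] <- pk
  }
  blank <- data.frame(mz = blank_masses,
                      intensity = rep(intensity_scale * 1e-3,
                                      length(blank_masses)),
                      sn = rep(50, length(blank_masses)))
  list(samples = samples, blank = blank)
}

#' Generate a KEGG-style compound/pathway annotation table
#'
#' A configurable fraction of the supplied formulas is annotated; each
#' annotated formula receives one or more compound records (isomer
#' multiplicity drawn from the structure-suggestion sampler), and each
#' compound is placed in one or more pathways. Pathway sizes are drawn so
#' that detected members cover only part of each pathway.
#'
#' @param formulas character vector of canonical sum formulas.
#' @param annotation_fraction fraction of formulas annotated (default 0.2).
#' @param multiplicity sampler of structure suggestions per formula;
#'   default `1 + rpois(n, 1.9)` (mean 2.9).
#' @param n_pathways number of pathways (default 30).
#' @param seed optional seed.
#' @return data.frame with columns `compound_id`, `formula`, `pathway_id`,
#'   `pathway_size`.
#' @export
generate_pathway_db <- function(formulas, annotation_fraction = 0.2,
                                multiplicity = function(n) 1L + stats::rpois(n, 1.9),
                                n_pathways = 30L, seed = NULL) {
  if (annotation_fraction < 0 || annotation_fraction > 1) {
    stop("annotation_fraction must be in [0, 1]")
  }
  empty <- data.frame(compound_id = character(0), formula = character(0),
                      pathway_id = character(0), pathway_size = integer(0),
                      stringsAsFactors = FALSE)
  if (length(formulas) == 0L) return(empty)
  if (!is.null(seed)) set.seed(seed)
  annotated <- formulas[stats::runif(length(formulas)) < annotation_fraction]
  if (length(annotated) == 0L) return(empty)
  k <- multiplicity(length(annotated))
  if (any(k < 1) || any(k != round(k))) {
    stop("multiplicity sampler must return positive integers")
  }
  pw_ids <- sprintf("path%03d", seq_len(n_pathways))
  recs <- list()
  cpd <- 0L
  for (i in seq_along(annotated)) {
    for (s in seq_len(k[i])) {
      cpd <- cpd + 1L
      n_pw <- 1L + stats::rpois(1, 0.3)
      pws <- sample(pw_ids, min(n_pw, n_pathways))
      recs[[length(recs) + 1L]] <- data.frame(
        compound_id = sprintf("cpd%05d", cpd),
        formula = annotated[i],
        pathway_id = pws,
        stringsAsFactors = FALSE)
    }
  }
  db <- do.call(rbind, recs)
  members <- tapply(db$compound_id, db$pathway_id,
                    function(v) length(unique(v)))
  target_cov <- stats::runif(length(members), 0.05, 0.6)
  size <- pmax(as.integer(members),
               as.integer(round(as.integer(members) / target_cov)))
  names(size) <- names(members)
  db$pathway_size <- size[db$pathway_id]
  rownames(db) <- NULL
  db
}
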