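#' @title Readers, writers, configuration and the end-to-end pipeline
#' @name cli-io
#' @description
#' TSV readers/writers with a fixed header convention (first column = row
#' id), a validated pipeline configuration that round-trips through YAML,
#' and [run_pipeline()], which chains simulation, (optional) peak
#' assignment, network construction, embedding, coverage, trend and
#' overlay stages into a run directory with a machine-readable report.
#' A thin command-line wrapper over these functions ships in
#' `inst/cli/domnet.R`.
NULL

#' Write / read a numeric matrix as TSV (first column = row id)
#'
#' @param X numeric matrix with row and column names.
#' @param file path.
#' @param id name for the row-id column (default `"feature"`).
#' @export
write_matrix_tsv <- function(X, file, id = "feature") {
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  X
}

#' Write / read a data.frame as TSV
#' @param df data.frame.
#' @param file path.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one nested list; unknown keys are
#' rejected by [validate_config()]. The list round-trips losslessly
#' through YAML.
#'
#' @param seed global integer seed.
#' @return a named nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    design = list(
      litter_types = c("beech", "oak", "pine", "grass"),
      sites = c("Hainich", "Linde"),
      replicates = 3L,
      time_points = c(0, 2, 4, 8, 15, 22),
      include_day0 = FALSE
    ),
    structure = list(
      blocks = "default",          # "default" or "study"
      within_r = 0.9,
      sigma = 0.3,
      baseline_log_sd = 1,
      annotation_fraction = 0.2,
      multiplicity_lambda = 1.9,   # suggestions per formula = 1 + Pois
      n_pathways = 30L
    ),
    assign = list(
      from_peaks = FALSE,          # re-derive formulas from peak lists
      ppm_tol = 2,
      ppm_jitter = 0.5,
      sn_low_frac = 0.05,
      sn_threshold = 4,
      mz_window = c(175, 1000),
      blank_masses = numeric(0)
    ),
    network = list(
      power = 9,
      min_module_size = 30L,
      cut_height_frac = 0.995,
      dissimilarity = "adjacency",
      linkage = "average",
      method = "height",
      edge_threshold = 0.1,
      scale_free_bins = 10L
    ),
    embedding = list(k = 3L),
    coverage = list(
      group_by = c("litter", "day"),
      detection_threshold = 1e-4,
      external = NULL,             # path to a pathway_id/coverage TSV
      compare_threshold = 0.5
    ),
    trend = list(group = "litter", mode = "full"),
    overlay = list(ubiquity_threshold = 0.5, enrichment = FALSE)
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.merge_config <- function(template, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(template)) {
      stop("unknown configuration key: ", full)
    }
    if (is.null(user[[key]])) {
      template[key] <- list(NULL)
    } else if (is.list(template[[key]])) {
      if (!is.list(user[[key]])) {
        stop("configuration key ", full, " must be a mapping")
      }
      template[[key]] <- .merge_config(template[[key]], user[[key]], full)
    } else {
      template[[key]] <- user[[key]]
    }
  }
  template
}

#' Validate a (possibly partial) configuration against the defaults
#'
#' Unknown keys are rejected before any stage runs; missing keys take
#' their default values.
#'
#' @param config a named list (e.g. from [read_config()]).
#' @return a complete `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  out <- .merge_config(unclass(pipeline_config()), unclass(config))
  if (!is.null(out$seed)) out$seed <- as.integer(out$seed)
  # YAML reads an empty sequence back as list(); keep the numeric contract
  out$assign$blank_masses <- as.numeric(unlist(out$assign$blank_masses))
  class(out) <- c("pipeline_config", "list")
  out
}

#' Read / write a pipeline configuration as YAML
#' @param file path to a YAML file.
#' @export
read_config <- function(file) {
  validate_config(yaml::read_yaml(file))
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.cfg_blocks <- function(structure_cfg) {
  switch(structure_cfg$blocks,
         default = default_blocks(),
         study = litter_study_blocks(),
         stop("structure$blocks must be 'default' or 'study'"))
}

#' Run the full pipeline into an output directory
#'
#' Executes simulate -> (optional) assign -> network -> embed -> coverage
#' -> trend -> overlay with the given configuration, writing each stage's
#' tables as TSV plus a machine-readable JSON run report (package version,
#' seed, parameters, per-stage row counts). A stage failure halts the run
#' with the stage name; outputs of completed stages are retained.
#'
#' @param config a `pipeline_config` (or partial list; validated first).
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress (default TRUE).
#' @return (invisibly) the run report list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  report <- list(
    package = "domnet",
    version = as.character(utils::packageVersion("domnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = unclass(config),
    stages = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    design <- study_design(
      litter_types = config$design$litter_types,
      sites = config$design$sites,
      replicates = config$design$replicates,
      time_points = config$design$time_points,
      include_day0 = config$design$include_day0,
      seed = config$seed)
    lam <- config$structure$multiplicity_lambda
    structure_ <- planted_structure(
      blocks = .cfg_blocks(config$structure),
      within_r = config$structure$within_r,
      sigma = config$structure$sigma,
      baseline_log_sd = config$structure$baseline_log_sd,
      annotation_fraction = config$structure$annotation_fraction,
      multiplicity = function(n) 1L + stats::rpois(n, lam))
    generate_feature_matrix(design, structure_)
  })
  X <- sim$matrix
  meta <- sim$metadata
  write_matrix_tsv(X, file.path(out_dir, "features.tsv"))
  write_tsv(meta, file.path(out_dir, "metadata.tsv"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  db <- stage("simulate", generate_pathway_db(
    rownames(X),
    annotation_fraction = config$structure$annotation_fraction,
    multiplicity = local({
      lam <- config$structure$multiplicity_lambda
      function(n) 1L + stats::rpois(n, lam)
    }),
    n_pathways = config$structure$n_pathways,
    seed = config$seed + 1L))
  write_tsv(db, file.path(out_dir, "pathway_db.tsv"))
  report$stages$simulate <- list(n_features = nrow(X),
                                 n_samples = ncol(X),
                                 n_blocks = length(unique(sim$truth$block)),
                                 n_db_records = nrow(db))
  say("simulate: ", nrow(X), " features x ", ncol(X), " samples")

  # -- assign (optional re-derivation from synthetic peak lists) --------
  if (isTRUE(config$assign$from_peaks)) {
    X <- stage("assign", {
      pl <- generate_peak_lists(
        sim, ppm_jitter = config$assign$ppm_jitter,
        sn_low_frac = config$assign$sn_low_frac,
        blank_masses = config$assign$blank_masses,
        seed = config$seed + 2L)
      ranges <- element_ranges(C = c(1L, 45L), H = c(0L, 90L),
                               N = c(0L, 3L), O = c(0L, 45L),
                               S = c(0L, 1L))
      assignments <- lapply(pl$samples, function(pk) {
        pk <- filter_peaks(pk, pl$blank,
                           sn_threshold = config$assign$sn_threshold,
                           mz_window = config$assign$mz_window)
        assign_formulas(pk, ranges = ranges,
                        ppm_tol = config$assign$ppm_tol)
      })
      build_feature_matrix(assignments)
    })
    write_matrix_tsv(X, file.path(out_dir, "features_assigned.tsv"))
    report$stages$assign <- list(n_features = nrow(X),
                                 n_samples = ncol(X))
    say("assign: ", nrow(X), " features recovered from peak lists")
  }

  # -- network ----------------------------------------------------------
  net <- stage("network", {
    C <- correlation_matrix(X)
    A <- signed_adjacency(C, power = config$network$power)
    sf <- tryCatch(scale_free_fit(A, n_bins = config$network$scale_free_bins),
                   error = function(e) list(r_squared = NA_real_,
                                            slope = NA_real_))
    mods <- detect_modules(
      A, min_module_size = config$network$min_module_size,
      cut_height_frac = config$network$cut_height_frac,
      dissimilarity = config$network$dissimilarity,
      linkage = config$network$linkage,
      method = config$network$method)
    eig <- module_eigenvalues(X[rownames(A), , drop = FALSE], mods)
    list(C = C, A = A, sf = sf, mods = mods, eig = eig)
  })
  write_tsv(data.frame(feature = names(net$mods$colors),
                       module = unname(net$mods$colors)),
            file.path(out_dir, "modules.tsv"))
  write_matrix_tsv(net$eig$eigengenes,
                   file.path(out_dir, "eigenvalues.tsv"), id = "module")
  export_network(net$A, net$mods,
                 threshold = config$network$edge_threshold,
                 file = file.path(out_dir, "edges.tsv"))
  export_network(net$A, net$mods,
                 threshold = config$network$edge_threshold,
                 file = file.path(out_dir, "network.graphml"),
                 format = "graphml")
  jsonlite::write_json(
    list(r_squared = net$sf$r_squared, slope = net$sf$slope,
         power = config$network$power),
    file.path(out_dir, "scale_free.json"), auto_unbox = TRUE, digits = NA)
  report$stages$network <- list(
    n_nodes = nrow(net$A),
    n_modules = sum(names(net$mods$sizes) != "grey"),
    n_grey = sum(net$mods$colors == "grey"),
    scale_free_r2 = net$sf$r_squared)
  say("network: ", nrow(net$A), " nodes, ",
      sum(names(net$mods$sizes) != "grey"), " modules")

  # -- embed ------------------------------------------------------------
  emb <- stage("embed", classical_mds(1 - net$A, k = config$embedding$k))
  coords <- data.frame(feature = rownames(net$A), emb$points,
                       module = unname(net$mods$colors[rownames(net$A)]),
                       check.names = FALSE)
  names(coords)[2:(1 + ncol(emb$points))] <-
    c("x", "y", "z")[seq_len(ncol(emb$points))]
  write_tsv(coords, file.path(out_dir, "coordinates.tsv"))
  report$stages$embed <- list(k = ncol(emb$points),
                              positive_mass = emb$positive_mass)
  say("embed: ", ncol(emb$points), " axes, ",
      round(100 * emb$positive_mass, 1), "% positive eigenvalue mass")

  # -- coverage ---------------------------------------------------------
  cov <- stage("coverage", {
    matches <- match_formulas(rownames(X), db)
    global_cov <- pathway_coverage(matches, db)
    mean_int <- rowMeans(X)
    intens <- pathway_intensity(matches, mean_int)
    grp <- interaction(meta[, config$coverage$group_by, drop = FALSE],
                       drop = TRUE)
    group_cov <- lapply(levels(grp), function(g) {
      sel <- grp == g
      detected <- rownames(X)[rowMeans(X[, sel, drop = FALSE]) >=
                                config$coverage$detection_threshold]
      pathway_coverage(match_formulas(detected, db), db)
    })
    names(group_cov) <- levels(grp)
    disp <- coverage_dispersion(group_cov)
    list(matches = matches, global = global_cov, intensity = intens,
         group_cov = group_cov, dispersion = disp)
  })
  cov_tab <- merge(cov$global, cov$intensity, by = "pathway_id")
  write_tsv(cov_tab, file.path(out_dir, "coverage.tsv"))
  write_tsv(cov$dispersion$per_pathway,
            file.path(out_dir, "coverage_dispersion.tsv"))
  if (!is.null(config$coverage$external)) {
    other <- read_tsv(config$coverage$external)
    cmp <- compare_coverage(cov$global, other,
                            threshold = config$coverage$compare_threshold)
    write_tsv(cmp, file.path(out_dir, "coverage_compare.tsv"))
    report$stages$coverage$n_compared <- nrow(cmp)
  }
  report$stages$coverage <- c(report$stages$coverage, list(
    match_rate = cov$matches$match_rate,
    mean_multiplicity = cov$matches$mean_multiplicity,
    mean_coverage_sd = cov$dispersion$mean_sd,
    n_pathways = nrow(cov$global)))
  say("coverage: match rate ", round(100 * cov$matches$match_rate, 1),
      "%, mean multiplicity ", round(cov$matches$mean_multiplicity, 2))

  # -- trend ------------------------------------------------------------
  trend <- stage("trend", {
    pca <- pca_trajectories(X, meta, n_comp = 2,
                            group = config$trend$group)
    dt <- group_distance_trend(X, meta, group = config$trend$group,
                               mode = config$trend$mode)
    list(pca = pca, dt = dt)
  })
  write_tsv(data.frame(sample_id = rownames(trend$pca$scores),
                       trend$pca$scores, check.names = FALSE),
            file.path(out_dir, "pca_scores.tsv"))
  write_tsv(trend$dt$pairwise, file.path(out_dir, "trend.tsv"))
  write_tsv(trend$dt$per_day, file.path(out_dir, "trend_per_day.tsv"))
  report$stages$trend <- list(
    percent_change = trend$dt$percent_change,
    pc1_var = trend$pca$var_explained[1])
  say("trend: between-group distance ",
      sprintf("%+.1f%%", trend$dt$percent_change))

  # -- overlay ----------------------------------------------------------
  ov <- stage("overlay", module_pathway_overlay(
    net$mods, cov$matches,
    ubiquity_threshold = config$overlay$ubiquity_threshold,
    enrichment = config$overlay$enrichment))
  write_tsv(ov$summary, file.path(out_dir, "overlay.tsv"))
  write_matrix_tsv(ov$counts, file.path(out_dir, "overlay_counts.tsv"),
                   id = "pathway_id")
  report$stages$overlay <- list(n_pathways = nrow(ov$counts),
                                n_ubiquitous = sum(ov$summary$ubiquitous))
  say("overlay: ", nrow(ov$counts), " pathways across modules")

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
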