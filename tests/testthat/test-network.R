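test_that("correlation matrix matches hand arithmetic and handles edge cases", {
  # 5 features x 4 samples, correlation recomputed from the covariance
  # formula by hand
  X <- rbind(a = c(1, 2, 3, 4),
             b = c(2, 4, 6, 8),
             c = c(4, 3, 2, 1),
             d = c(1, 3, 2, 5),
             e = c(10, 10, 11, 10))
  C <- correlation_matrix(X)
  expect_equal(unname(C["a", "b"]), 1)   # duplicated (scaled) feature
  expect_equal(unname(C["a", "c"]), -1)  # negation around the mean
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in rownames(X)) for (j in rownames(X)) {
    expect_equal(unname(C[i, j]), manual(X[i, ], X[j, ]), tolerance = 1e-12)
  }
  expect_true(isSymmetric(C))
  expect_equal(unname(diag(C)), rep(1, 5))
  # zero-variance feature excluded with a warning
  Xz <- rbind(X, f = c(2, 2, 2, 2))
  expect_warning(Cz <- correlation_matrix(Xz), "zero-variance")
  expect_false("f" %in% rownames(Cz))
  expect_error(correlation_matrix(X[, 1:2]), "3 samples")
})

test_that("signed adjacency obeys the formula endpoints and monotonicity", {
  expect_equal(signed_adjacency(matrix(1), 9)[1], 1)
  expect_equal(signed_adjacency(matrix(-1), 9)[1], 0)
  expect_equal(signed_adjacency(matrix(0), 9)[1], 0.5^9)
  # strictly increasing in cor
  r <- seq(-1, 1, length.out = 101)
  a <- signed_adjacency(matrix(r, 1), 9)
  expect_true(all(diff(as.numeric(a)) > 0))
  expect_true(all(a >= 0 & a <= 1))
  # increasing p never increases adjacency when cor < 1
  r2 <- runif(50, -1, 0.999)
  a6 <- as.numeric(signed_adjacency(matrix(r2, 1), 6))
  a12 <- as.numeric(signed_adjacency(matrix(r2, 1), 12))
  expect_true(all(a12 <= a6))
  expect_error(signed_adjacency(matrix(0.5), 0), "power")
  expect_error(signed_adjacency(matrix(1.5), 9), "\\[-1, 1\\]")
})

test_that("scale-free fit recovers a planted power law and matches lm", {
  # exact power law: connectivity values 2^b with counts 2^(11-b), so
  # log10 p(k) is linear in log10 k
  b <- 1:10
  k <- rep(2^b, times = 2^(11 - b))
  breaks <- c(2^b - 0.5, 2^10 + 0.5)
  fit <- scale_free_fit(connectivity = k, breaks = breaks)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-6)
  expect_equal(fit$slope, -1, tolerance = 1e-6)
  # R^2 equals an independent least-squares computation on the binned table
  set.seed(31)
  A <- signed_adjacency(matrix(runif(400, -1, 1), 20, 20), 3)
  A <- (A + t(A)) / 2; diag(A) <- 1
  f2 <- scale_free_fit(A, n_bins = 5)
  x <- log10(f2$table$k_mean); y <- log10(f2$table$p_k)
  beta <- cov(x, y) / var(x)
  r2 <- cor(x, y)^2
  expect_equal(f2$slope, beta, tolerance = 1e-10)
  expect_equal(f2$r_squared, r2, tolerance = 1e-10)
  expect_error(scale_free_fit(connectivity = rep(3, 10)), "undefined")
  expect_error(scale_free_fit(connectivity = c(1, 2), n_bins = 2),
               "3 non-empty")
})

test_that("modules recover planted blocks exactly in the noise-free limit", {
  sim <- generate_feature_matrix(study_design(seed = 4),
                                 planted_structure(within_r = 1, sigma = 0))
  C <- suppressWarnings(correlation_matrix(sim$matrix))
  A <- signed_adjacency(C, 9)
  mods <- detect_modules(A)
  truth <- setNames(sim$truth$block, sim$truth$feature)
  expect_equal(adjusted_rand_index(mods$colors, truth[names(mods$colors)]),
               1.0)
  # color naming follows size rank with the conventional palette
  cols <- setdiff(names(mods$sizes), "grey")
  expect_setequal(cols, c("turquoise", "blue", "brown", "yellow"))
  sz <- table(mods$colors)[c("turquoise", "blue", "brown", "yellow")]
  expect_true(all(diff(as.integer(sz)) <= 0))
})

test_that("module labels are invariant under feature permutation", {
  sim <- generate_feature_matrix(study_design(seed = 8))
  C <- correlation_matrix(sim$matrix)
  A <- signed_adjacency(C, 9)
  mods <- detect_modules(A)
  set.seed(1)
  p <- sample(nrow(A))
  mods_p <- detect_modules(A[p, p])
  common <- names(mods$colors)
  expect_equal(adjusted_rand_index(mods$colors[common],
                                   mods_p$colors[common]), 1.0)
})

test_that("degenerate module inputs behave as documented", {
  # identical features: one module
  A <- matrix(1, 10, 10, dimnames = list(paste0("f", 1:10), paste0("f", 1:10)))
  mods <- detect_modules(A, min_module_size = 5)
  expect_equal(unname(table(mods$colors)[["turquoise"]]), 10L)
  # min_module_size beyond n: all grey with warning
  expect_warning(g <- detect_modules(A, min_module_size = 50), "all grey")
  expect_true(all(g$colors == "grey"))
  expect_error(detect_modules(A, min_module_size = 1), "at least 2")
})

test_that("in-package ARI agrees with mclust", {
  set.seed(5)
  a <- sample(1:4, 200, replace = TRUE)
  b <- ifelse(runif(200) < 0.8, a, sample(1:4, 200, replace = TRUE))
  expect_equal(adjusted_rand_index(a, b),
               unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, a), 1)
})

test_that("module eigengenes match the PC1 oracle and orientation contract", {
  # rank-1 module: eigengene equals the standardized common profile
  prof <- c(1, 3, 2, 5, 4, 6)
  M <- outer(c(1, 2, 5, 0.5), prof)
  rownames(M) <- paste0("f", 1:4); colnames(M) <- paste0("s", 1:6)
  cols <- setNames(rep("blue", 4), rownames(M))
  eg <- module_eigenvalues(M, cols)
  expect_equal(unname(eg$eigengenes["blue", ]),
               as.numeric(scale(prof)), tolerance = 1e-10)
  expect_equal(unname(eg$var_explained["blue"]), 1.0, tolerance = 1e-12)
  # random 10 x 6 block against an independent eigendecomposition oracle
  set.seed(12)
  R <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  egr <- module_eigenvalues(R, setNames(rep("red", 10), rownames(R)))
  Rs <- t(scale(t(R)))
  ev <- eigen(crossprod(Rs), symmetric = TRUE)
  v <- ev$vectors[, 1] / sd(ev$vectors[, 1])
  if (cor(v, colMeans(Rs)) < 0) v <- -v
  expect_lt(max(abs(egr$eigengenes["red", ] - v)), 1e-8)
  expect_equal(unname(egr$var_explained["red"]),
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  # eigengene maximizes explained variance among unit-norm combinations
  rand_dirs <- matrix(rnorm(10 * 50), 10, 50)
  rand_dirs <- sweep(rand_dirs, 2, sqrt(colSums(rand_dirs^2)), "/")
  best_rand <- max(colSums((t(Rs) %*% rand_dirs)^2))
  expect_gte(ev$values[1] + 1e-9, best_rand)
  # permutation of features within a module leaves the eigengene unchanged
  p <- sample(10)
  egp <- module_eigenvalues(R[p, ], setNames(rep("red", 10), rownames(R)[p]))
  expect_equal(egp$eigengenes["red", ], egr$eigengenes["red", ],
               tolerance = 1e-10)
  # single-feature module warns and returns the standardized profile
  expect_warning(
    eg1 <- module_eigenvalues(M, setNames(c("blue", rep("grey", 3)),
                                          rownames(M))),
    "single feature")
  expect_equal(unname(eg1$eigengenes["blue", ]), as.numeric(scale(M[1, ])),
               tolerance = 1e-10)
})

test_that("eigengene orientation is positive on the default synthetic run", {
  sim <- generate_feature_matrix(study_design(seed = 13))
  C <- correlation_matrix(sim$matrix)
  A <- signed_adjacency(C, 9)
  mods <- detect_modules(A)
  eg <- module_eigenvalues(sim$matrix, mods)
  for (m in rownames(eg$eigengenes)) {
    feats <- names(mods$colors)[mods$colors == m]
    Ms <- t(scale(t(sim$matrix[feats, ])))
    expect_gte(cor(eg$eigengenes[m, ], colMeans(Ms)), 0)
  }
})

test_that("network export thresholds, round-trips and writes GraphML", {
  set.seed(9)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("f", 1:8), NULL))
  A <- signed_adjacency(correlation_matrix(X), 3)
  edges0 <- export_network(A, threshold = 0)
  expect_equal(nrow(edges0), 8 * 7 / 2)
  edges1 <- export_network(A, threshold = 1)
  expect_equal(nrow(edges1), 0L)
  # written file re-read gives the same adjacency on kept edges
  f <- tempfile(fileext = ".tsv")
  export_network(A, threshold = 0.2, file = f)
  back <- read_tsv(f)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$weight[i], A[back$from[i], back$to[i]],
                 tolerance = 1e-12)
  }
  expect_equal(nrow(back), sum(A[upper.tri(A)] >= 0.2))
  # GraphML round-trip preserves node count and weights
  g <- tempfile(fileext = ".graphml")
  cols <- setNames(rep(c("blue", "grey"), 4), rownames(A))
  export_network(A, cols, threshold = 0.2, file = g, format = "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(gr), 8)
  expect_equal(sort(igraph::E(gr)$weight), sort(back$weight),
               tolerance = 1e-9)
  expect_error(export_network(A, threshold = 2), "threshold")
})

test_that("TOM similarity is bounded, symmetric and unit-diagonal", {
  set.seed(10)
  X <- matrix(rnorm(100), 20, 5)
  rownames(X) <- paste0("f", 1:20)
  A <- signed_adjacency(correlation_matrix(X), 6)
  TOM <- tom_similarity(A)
  expect_true(isSymmetric(TOM, tol = 1e-12))
  expect_true(all(TOM >= -1e-12 & TOM <= 1 + 1e-12))
  expect_equal(unname(diag(TOM)), rep(1, 20))
  # TOM-based module detection runs
  mods <- detect_modules(A, min_module_size = 2, dissimilarity = "tom")
  expect_s3_class(mods, "module_set")
})
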