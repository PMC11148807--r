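test_that("whitened correlations match the explicit ZCA and Pearson oracles", {
  set.seed(20)
  for (i in 1:20) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    colnames(X) <- paste0("g", 1:8)
    Xc <- sweep(X, 2, colMeans(X), "-")
    # explicit whitening: (XX')^(-1/2) X on the range of XX'
    G <- Xc %*% t(Xc)
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > 1e-10 * max(eg$values)
    W <- eg$vectors[, pos] %*% ((1 / sqrt(eg$values[pos])) * t(eg$vectors[, pos])) %*% Xc
    expect_lt(max(abs(zca_gene_correlation(X, 0)$C - cor(W))), 1e-8)
    expect_lt(max(abs(zca_gene_correlation(X, 2)$C - cor(X))), 1e-8)
  }
})

test_that("whitened correlation matrices are well-formed", {
  set.seed(21)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[, 10] <- X[, 1]                       # duplicated gene column
  colnames(X) <- paste0("g", 1:10)
  for (P in c(0, 0.5, 1, 2)) {
    zc <- zca_gene_correlation(X, P)
    expect_lt(max(abs(zc$C - t(zc$C))), 1e-10)
    expect_true(all(diag(zc$C) == 1))
    expect_true(all(abs(zc$C) <= 1 + 1e-8))
    expect_equal(zc$C[1, 10], 1)          # identical vectors stay perfectly correlated
  }
  expect_error(zca_gene_correlation(matrix(c(1, NA, 2, 3), 2, 2), 1), "finite")
})

test_that("sparsity z-scores are symmetric, centred and zero on flat strata", {
  set.seed(22)
  C <- cor(matrix(rnorm(200 * 12), 200, 12))
  zeros <- rpois(12, 30)
  z <- sparsity_zscore(C, zeros, n_sparsity_bins = 3)
  expect_identical(dim(z), dim(C))
  expect_lt(max(abs(z - t(z))), 1e-10)
  expect_true(all(diag(z) == 0))
  flat <- matrix(0.5, 6, 6); diag(flat) <- 1
  zf <- suppressWarnings(sparsity_zscore(flat, rep(3, 6), n_sparsity_bins = 2))
  expect_true(all(zf == 0))
  expect_warning(sparsity_zscore(C, zeros, n_sparsity_bins = 50), "fewer genes")
  expect_error(sparsity_zscore(C, zeros[1:5]), "aligned")
})

test_that("planted module pairs exceed the background z tail", {
  cfg <- module_sim_config(n_cells = 5000, n_genes = 200,
                           module_sizes = rep(20, 4), loading = 0.8,
                           mode = "counts", seed = 30)
  sim <- generate_module_dataset(cfg)
  norm <- normalize_log1p(sim$matrix)
  zeros <- colSums(sim$matrix == 0)
  zc <- zca_gene_correlation(norm$values, 1)
  z <- suppressWarnings(sparsity_zscore(zc, zeros))
  truth <- sim$truth$module_of_gene
  same <- outer(truth, truth, "==") & !is.na(outer(truth, truth, "+"))
  ut <- upper.tri(z)
  bg999 <- stats::quantile(z[ut & !same], 0.999, names = FALSE)
  expect_gt(stats::median(z[ut & same]), bg999)
})

test_that("graph thresholding is strict and matches a brute-force scan", {
  z <- matrix(c(0, 4.5, 5.0,
                4.5, 0, 2.0,
                5.0, 2.0, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  g <- threshold_graph(z, 4.5)
  expect_equal(igraph::ecount(g), 1)           # the exact-4.5 entry makes no edge
  expect_equal(igraph::vcount(g), 3)           # isolated genes retained
  expect_equal(igraph::E(g)$weight, 5.0)
  set.seed(23)
  zr <- cor(matrix(rnorm(40 * 15), 40, 15)) * 10
  diag(zr) <- 0
  gr <- threshold_graph(zr, 4.5)
  expect_identical(as.integer(igraph::ecount(gr)),
                   as.integer(sum(zr[upper.tri(zr)] > 4.5)))
  expect_equal(igraph::ecount(threshold_graph(zr, Inf)), 0)
})

test_that("multiplex clustering on identical layers equals single-graph Leiden", {
  g <- two_cliques(6)
  ms <- multigraph_leiden(list(g, g, g), resolution = 1, seed = 1)
  single <- leiden_cluster(g, resolution = 1, seed = 1)
  expect_identical(length(ms$modules), 2L)
  expect_identical(ms$modules[[1]], sort(igraph::V(g)$name[single == single[1]]))
  # two disconnected cliques are exactly the two modules
  expect_identical(lengths(ms$modules), c(6L, 6L))
  g2 <- two_cliques(4)
  expect_error(multigraph_leiden(list(g, g2)), "node set")
})

test_that("module detection recovers planted modules and stays quiet on noise", {
  cfg <- module_sim_config(n_cells = 5000, n_genes = 200,
                           module_sizes = rep(20, 4), loading = 0.8,
                           mode = "counts", seed = 31)
  sim <- generate_module_dataset(cfg)
  norm <- normalize_log1p(sim$matrix)
  ms <- suppressWarnings(detect_modules(norm$values, sim$matrix, seed = 31))
  truth <- ifelse(is.na(sim$truth$module_of_gene), 0L, sim$truth$module_of_gene)
  pred <- ifelse(is.na(ms$module_of_gene), 0L, ms$module_of_gene)
  expect_gte(mclust::adjustedRandIndex(truth, pred), 0.9)
  # determinism of the full recipe
  ms2 <- suppressWarnings(detect_modules(norm$values, sim$matrix, seed = 31))
  expect_identical(ms$modules, ms2$modules)
  expect_identical(ms$module_of_gene, ms2$module_of_gene)

  cfg0 <- module_sim_config(n_cells = 4000, n_genes = 160,
                            module_sizes = integer(0), mode = "counts",
                            seed = 32)
  sim0 <- generate_module_dataset(cfg0)
  norm0 <- normalize_log1p(sim0$matrix)
  ms0 <- suppressWarnings(detect_modules(norm0$values, sim0$matrix, seed = 32))
  expect_lte(mean(!is.na(ms0$module_of_gene)), 0.05)
})

test_that("module detection is equivariant under gene permutation", {
  cfg <- module_sim_config(n_cells = 2000, n_genes = 100,
                           module_sizes = rep(12, 3), loading = 0.8,
                           mode = "counts", seed = 33)
  sim <- generate_module_dataset(cfg)
  norm <- normalize_log1p(sim$matrix)
  ms <- suppressWarnings(detect_modules(norm$values, sim$matrix, seed = 33))
  perm <- withr::with_seed(1, sample(ncol(norm$values)))
  msp <- suppressWarnings(detect_modules(norm$values[, perm], sim$matrix[, perm],
                                         seed = 33))
  canon <- function(m) sort(vapply(m$modules, paste, "", collapse = "+"))
  expect_identical(canon(ms), canon(msp))
})

test_that("recovered-module agreement increases with the planted loading", {
  ari_at <- function(l, s) {
    cfg <- module_sim_config(n_cells = 2000, n_genes = 100,
                             module_sizes = rep(12, 3), loading = l,
                             mode = "counts", seed = s)
    sim <- generate_module_dataset(cfg)
    norm <- normalize_log1p(sim$matrix)
    ms <- suppressWarnings(detect_modules(norm$values, sim$matrix, seed = s))
    truth <- ifelse(is.na(sim$truth$module_of_gene), 0L, sim$truth$module_of_gene)
    pred <- ifelse(is.na(ms$module_of_gene), 0L, ms$module_of_gene)
    mclust::adjustedRandIndex(truth, pred)
  }
  avg <- vapply(c(0.2, 0.4, 0.6, 0.8),
                function(l) mean(vapply(1:3, function(s) ari_at(l, s), 1.0)), 1.0)
  expect_true(all(diff(avg) >= 0))
})

test_that("module scores separate the planted factor and stay null otherwise", {
  cfg <- module_sim_config(n_cells = 5000, n_genes = 200,
                           module_sizes = rep(20, 4), loading = 0.8,
                           mode = "counts", seed = 34)
  sim <- generate_module_dataset(cfg)
  norm <- normalize_log1p(sim$matrix)
  # score the planted modules themselves: the scorer, not detection, is on test
  planted <- lapply(1:4, function(m) {
    sort(colnames(sim$matrix)[which(sim$truth$module_of_gene == m)])
  })
  ms <- structure(list(modules = planted), class = "module_set")
  sc <- score_modules(norm, ms, seed = 1)
  expect_identical(sc, score_modules(norm, ms, seed = 1))
  # factor-on cells (top quintile) rank above factor-off cells (bottom quintile)
  f <- sim$truth$factors[match(rownames(norm$values), rownames(sim$matrix)), 1]
  extreme <- f > stats::quantile(f, 0.8) | f < stats::quantile(f, 0.2)
  expect_gte(auroc(sc[extreme, 1], (f > stats::quantile(f, 0.8))[extreme]), 0.9)
  expect_error(score_modules(norm, list(modules = list())), "empty")
})

test_that("hypergeometric module enrichment matches the combinatorial oracle", {
  universe <- sprintf("u%03d", 1:100)
  ms <- list(modules = list(universe[1:5]),
             module_of_gene = NULL, parameters = list())
  class(ms) <- "module_set"
  enr <- enrich_modules(ms, list(hit = universe[1:5], all = universe), universe)
  expect_equal(enr$pvalue[enr$set == "hit"], 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(enr$pvalue[enr$set == "all"], 1)
  none <- enrich_modules(ms, list(miss = universe[6:10]), universe)
  expect_identical(none$overlap, 0L)
  expect_lte(none$pvalue, 1)
  expect_error(enrich_modules(ms, list(a = "x"), character(0)), "universe")
})
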