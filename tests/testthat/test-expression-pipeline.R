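test_that("rare-gene filter applies the detection threshold", {
  set.seed(1)
  counts <- named_counts(matrix(0, 20, 3))
  counts[1:9, 1] <- 1    # detected in 9 cells
  counts[1:10, 2] <- 1   # detected in 10 cells
  counts[, 3] <- 2
  kept <- filter_rare_genes(counts, min_cells = 10)
  expect_identical(colnames(kept), c("g2", "g3"))
  expect_identical(filter_rare_genes(counts, min_cells = 0), counts)
  expect_error(filter_rare_genes(counts, min_cells = 21), "no genes")
})

test_that("CP10K log normalisation matches direct arithmetic", {
  counts <- named_counts(rbind(c(1, 9999), c(5, 5)))
  norm <- normalize_log1p(counts, target = 10000)
  expect_equal(norm$values[1, 1], log(2))
  expect_equal(norm$values[2, ], c(g1 = log(5001), g2 = log(5001)))
  counts2 <- named_counts(matrix(rpois(300, 3), 20, 15))
  norm2 <- suppressWarnings(normalize_log1p(counts2))
  expect_lt(max(abs(rowSums(expm1(norm2$values)) - 10000)), 1e-6)
  kept <- counts2[rownames(norm2$values), ]
  expect_true(all(norm2$values[kept == 0] == 0))
  expect_error(normalize_log1p(named_counts(matrix(-1, 2, 2))), "negative")
})

test_that("HVG selection enforces mean window and handles singleton bins", {
  set.seed(2)
  n <- 400
  low <- rbinom(n, 1, 0.01)                        # mean statistic ~0.01
  high <- rpois(n, 100)                            # mean statistic ~4.6
  mid <- matrix(rpois(n * 30, 2), n, 30)
  bursty <- rpois(n, 2) * rbinom(n, 1, 0.2) * 4    # overdispersed mid gene
  counts <- cbind(low, mid, bursty, high)
  # filler gene tops every cell up to exactly the CP10K target, so the
  # normalisation is the identity and the default cutoffs act on raw means
  counts <- cbind(counts, filler = 10000 - rowSums(counts))
  dimnames(counts) <- list(sprintf("c%d", seq_len(n)),
                           c("low", sprintf("m%02d", 1:30), "bursty", "high",
                             "filler"))
  norm <- normalize_log1p(counts)
  mask <- select_hvg(norm, n_bins = 5)
  expect_false(mask[["low"]])      # mean 0.01 sits below the 0.0125 floor
  expect_false(mask[["high"]])     # mean above the ceiling of 3
  expect_true(mask[["bursty"]])
  expect_identical(length(mask), ncol(counts))
  # far more bins than genes: merged bins still score every gene
  mask2 <- select_hvg(norm, n_bins = 200)
  expect_identical(length(mask2), ncol(counts))
  expect_false(anyNA(attr(mask2, "gene_stats")$dispersion_norm))
})

test_that("covariate regression returns orthogonal residuals", {
  set.seed(3)
  n <- 100
  total <- runif(n, 500, 5000)
  y <- named_counts(cbind(2 + 0.001 * total, matrix(rnorm(n * 5), n, 5)))
  pm <- processed_matrix(y, "normalized_log")
  res <- regress_covariates(pm, list(total = total))
  expect_lt(max(abs(res$values[, 1])), 1e-8)   # exactly linear gene vanishes
  for (j in 2:6) {
    r <- res$values[, j]
    expect_lt(abs(sum(r * total)), 1e-6 * sqrt(sum(r^2) * sum(total^2)))
  }
  expect_warning(regress_covariates(pm, list(total = total, k = rep(1, n))),
                 "constant")
  expect_error(regress_covariates(pm, list(a = total, b = 2 * total)),
               "rank-deficient")
})

test_that("scaling standardises, zeroes constants and clips above", {
  set.seed(4)
  x <- named_counts(cbind(rep(5, 400), rnorm(400), c(rep(0, 399), 25)))
  pm <- processed_matrix(x, "residual")
  sc <- scale_clip(pm, max_value = 10)
  expect_true(all(sc$values[, 1] == 0))
  expect_lt(max(abs(colMeans(sc$values[, 1:2]))), 1e-10)
  # the lone 25 sits ~20 SD above its column mean: clipped to the max
  expect_equal(max(sc$values[, 3]), 10)
  expect_error(scale_clip(sc), "backwards")  # stage can only move forward
})

test_that("PCA embedding is rank-aware, invertible and sign-stable", {
  set.seed(5)
  base <- matrix(rnorm(60 * 2), 60, 2) %*% matrix(rnorm(2 * 8), 2, 8)
  colnames(base) <- paste0("g", 1:8)
  expect_warning(pca_embed(base, n_pcs = 10), "clamped")
  p <- suppressWarnings(pca_embed(base, n_pcs = 10))
  expect_lt(sum(p$sdev[3:8]^2), 1e-10)
  full <- pca_embed(base, n_pcs = 8)
  recon <- full$embedding %*% t(full$loadings)
  centred <- sweep(base, 2, colMeans(base), "-")
  expect_lt(max(abs(recon - centred)), 1e-8)
  expect_identical(pca_embed(base, 4), pca_embed(base, 4))
  for (j in 1:2) {
    v <- full$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("kNN graph matches the brute-force distance ranking", {
  set.seed(6)
  emb <- matrix(rnorm(50 * 3), 50, 3)
  g <- knn_graph(emb, k = 4)
  d <- as.matrix(dist(emb))
  for (i in sample(50, 10)) {
    ord <- order(d[i, ])
    nn <- setdiff(ord, i)[1:4]
    expect_true(all(nn %in% as.integer(igraph::neighbors(g, i))))
  }
  # 3 collinear equidistant points, k = 1: union edges are 1-2 and 2-3
  line <- cbind(c(0, 1, 2), 0)
  gl <- knn_graph(line, k = 1)
  el <- igraph::as_edgelist(gl)
  expect_identical(nrow(el), 2L)
  expect_false(any(el[, 1] == 1 & el[, 2] == 3))
  # k clamps to n - 1 and yields a complete graph
  expect_warning(knn_graph(emb[1:5, ], k = 10), "clamped")
  gc <- suppressWarnings(knn_graph(emb[1:5, ], k = 10))
  expect_equal(igraph::ecount(gc), 10)
})

test_that("Leiden clustering respects graph structure and seeds", {
  g <- two_cliques(6)
  lab <- leiden_cluster(g, resolution = 1, seed = 1)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:6])), 1L)
  con <- igraph::make_full_graph(10)
  igraph::E(con)$weight <- 1
  expect_identical(length(unique(leiden_cluster(con, resolution = 1e-4, seed = 1))), 1L)
  expect_identical(leiden_cluster(g, seed = 9), leiden_cluster(g, seed = 9))
  expect_error(leiden_cluster(igraph::make_empty_graph(0, directed = FALSE)), "empty")
})

test_that("gene-set scorer is null-calibrated and separates planted markers", {
  set.seed(7)
  x <- named_counts(matrix(rpois(1000 * 40, 2), 1000, 40))
  norm <- suppressWarnings(normalize_log1p(x))
  s <- score_gene_set(norm, paste0("g", 1:5), seed = 1)
  expect_lt(abs(mean(s)), 0.05)
  expect_identical(s, score_gene_set(norm, paste0("g", 1:5), seed = 1))

  ds <- generate_droplet_dataset(droplet_sim_config(seed = 2))
  normd <- suppressWarnings(normalize_log1p(ds$spliced + ds$unspliced))
  cls <- ds$truth$droplet_class[match(rownames(normd$values), rownames(ds$spliced))]
  sc <- score_gene_set(normd, ds$gene_sets$CM, seed = 1)
  expect_gte(auroc(sc, cls == "nucleus_CM"), 0.95)
  expect_error(score_gene_set(norm, "not_a_gene"), "empty")
})

test_that("marker ranking finds constructed markers and reproduces BH", {
  set.seed(8)
  n <- 60
  x <- named_counts(matrix(rpois(n * 30, 2), n, 30))
  labs <- rep(c(1, 2), each = n / 2)
  x[labs == 1, 5] <- x[labs == 1, 5] + 20    # exclusive marker of cluster 1
  norm <- suppressWarnings(normalize_log1p(x))
  rm <- rank_markers(norm, labs)
  expect_identical(rm[["1"]]$table$gene[1], "g5")
  expect_true(rm[["1"]]$table$significant[1])
  # dual-route FDR: package column vs hand-rolled BH step-up
  tab <- rm[["2"]]$table
  expect_equal(tab$fdr, oracle_bh(tab$pvalue))
  expect_true(all(tab$fdr >= tab$pvalue))
  w <- capture_warnings(rank_markers(norm, c(1, rep(2, n - 1))))
  expect_match(w, "fewer than 2", all = TRUE)
})

test_that("null labels keep the BH discovery fraction at the nominal level", {
  set.seed(9)
  fdp <- replicate(40, {
    x <- named_counts(matrix(rpois(50 * 60, 2), 50, 60))
    labs <- rep(1:2, each = 25)
    rm <- suppressWarnings(rank_markers(processed_matrix(log1p(x), "normalized_log"), labs))
    mean(rm[["1"]]$table$significant)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / (40 * 60)))
})

test_that("cluster annotation assigns types and flags mixed clusters", {
  set.seed(10)
  n <- 300
  genes <- c(paste0("a", 1:5), paste0("b", 1:5), paste0("f", 1:20))
  x <- matrix(rpois(n * 30, 1), n, 30, dimnames = list(NULL, genes))
  labs <- rep(1:3, each = n / 3)
  x[labs == 1, 1:5] <- x[labs == 1, 1:5] + 6
  x[labs == 2, 6:10] <- x[labs == 2, 6:10] + 6
  x[labs == 3, 1:10] <- x[labs == 3, 1:10] + 6    # 50/50 doublet profile
  norm <- suppressWarnings(normalize_log1p(x))
  refs <- list(typeA = paste0("a", 1:5), typeB = paste0("b", 1:5))
  ann <- annotate_clusters(norm, labs, refs, high_quantile = 0.5, seed = 1)
  expect_identical(ann$type[1], "typeA")
  expect_identical(ann$type[2], "typeB")
  expect_true(ann$doublet_cluster[3])
  expect_false(any(ann$doublet_cluster[1:2]))
  one <- annotate_clusters(norm, labs, refs["typeA"], seed = 1)
  expect_false(any(one$doublet_cluster))
  expect_error(annotate_clusters(norm, labs, list()), "no reference")
})

test_that("per-sample proportions conserve mass and summarise groups", {
  labels <- c(rep("CM", 3), rep("FB", 7), rep("CM", 5), rep("FB", 5))
  samples <- rep(c("s1", "s2"), each = 10)
  pr <- compute_proportions(labels, samples)
  expect_equal(pr$proportion[pr$sample == "s1" & pr$label == "CM"], 30)
  expect_equal(pr$proportion[pr$sample == "s1" & pr$label == "FB"], 70)
  sums <- tapply(pr$proportion, pr$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  gr <- compute_proportions(labels, samples, groups = c(s1 = "ctrl", s2 = "hf"))
  expect_s3_class(attr(gr, "group_summaries"), "data.frame")
  expect_error(compute_proportions(labels, samples[1:3]), "length")
})

test_that("the processing chain is deterministic end to end", {
  run_chain <- function() {
    set.seed(42)
    counts <- named_counts(matrix(rpois(200 * 80, 2), 200, 80))
    counts[1:100, 1:10] <- counts[1:100, 1:10] + 4
    norm <- suppressWarnings(normalize_log1p(counts))
    res <- regress_covariates(norm, list(total = norm$cell_meta$total_counts))
    sc <- scale_clip(res)
    emb <- pca_embed(sc, n_pcs = 10)$embedding
    leiden_cluster(knn_graph(emb, k = 10), resolution = 1, seed = 5)
  }
  expect_identical(run_chain(), run_chain())
})
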