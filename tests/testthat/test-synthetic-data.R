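test_that("droplet simulator respects degenerate configurations", {
  cfg <- droplet_sim_config(n_droplets = 50,
                            class_fractions = c(nucleus_CM = 1.0),
                            n_genes = 120, markers_per_type = 20, seed = 3)
  ds <- generate_droplet_dataset(cfg)
  expect_true(all(ds$truth$droplet_class == "nucleus_CM"))

  # near-delta Beta at 1 for the empty class forces splicing fraction 1
  sp <- list(nucleus_CM = c(6, 18), empty = c(1, 1e-300), contaminated = c(12, 8))
  cfg2 <- droplet_sim_config(n_droplets = 200,
                             class_fractions = c(nucleus_CM = 0.5, empty = 0.4,
                                                 contaminated = 0.1),
                             n_genes = 120, markers_per_type = 20,
                             spliced_fraction_params = sp, seed = 4)
  ds2 <- generate_droplet_dataset(cfg2)
  empty <- ds2$truth$droplet_class == "empty"
  spl <- Matrix::rowSums(ds2$spliced)
  tot <- spl + Matrix::rowSums(ds2$unspliced)
  expect_true(all(spl[empty] == tot[empty]))
})

test_that("droplet simulator is seed-reproducible and count-consistent", {
  cfg <- droplet_sim_config(n_droplets = 150, n_genes = 150,
                            markers_per_type = 15, seed = 7)
  a <- generate_droplet_dataset(cfg)
  b <- generate_droplet_dataset(cfg)
  expect_identical(as.matrix(a$spliced), as.matrix(b$spliced))
  expect_identical(a$truth$droplet_class, b$truth$droplet_class)
  expect_true(all(a$spliced@x >= 0))
  expect_true(all(a$unspliced@x >= 0))
  expect_true(all(as.matrix(a$spliced) == floor(as.matrix(a$spliced))))
})

test_that("droplet simulator validates its configuration", {
  expect_error(droplet_sim_config(class_fractions = c(nucleus_CM = 0.5, empty = 0.4)),
               "sum to 1")
  expect_error(generate_droplet_dataset(droplet_sim_config(n_droplets = 0)),
               "nothing to generate")
  expect_error(droplet_sim_config(n_genes = 10), "exceed")
})

test_that("empty-droplet splicing rises with the ambient spliced Beta mean", {
  mean_spl <- function(target, seed) {
    conc <- 30
    sp <- list(nucleus_CM = c(6, 18),
               empty = c(target * conc, (1 - target) * conc),
               contaminated = c(12, 8))
    cfg <- droplet_sim_config(n_droplets = 300,
                              class_fractions = c(nucleus_CM = 0.6, empty = 0.3,
                                                  contaminated = 0.1),
                              n_genes = 120, markers_per_type = 20,
                              spliced_fraction_params = sp, seed = seed)
    ds <- generate_droplet_dataset(cfg)
    empty <- ds$truth$droplet_class == "empty"
    spl <- Matrix::rowSums(ds$spliced)
    tot <- spl + Matrix::rowSums(ds$unspliced)
    mean((spl / tot)[empty])
  }
  levels <- c(0.4, 0.6, 0.8, 0.95)
  avg <- vapply(levels, function(tg) mean(vapply(1:3, function(s) mean_spl(tg, s), 1.0)), 1.0)
  expect_true(all(diff(avg) > 0))
})

test_that("planted factor modules reproduce the closed-form correlation", {
  # population correlation between two genes of a module is loading^2
  cfg <- module_sim_config(n_cells = 5000, n_genes = 40,
                           module_sizes = 10, loading = 0.8,
                           mode = "gaussian", seed = 11)
  sim <- generate_module_dataset(cfg)
  idx <- which(sim$truth$module_of_gene == 1)
  cm <- cor(sim$matrix[, idx])
  expect_lt(max(abs(cm[upper.tri(cm)] - 0.64)), 0.05)

  # independence limit: near-zero loading gives near-zero correlation
  cfg0 <- module_sim_config(n_cells = 10000, n_genes = 20, module_sizes = 10,
                            loading = 1e-6, mode = "gaussian", seed = 12)
  sim0 <- generate_module_dataset(cfg0)
  cm0 <- cor(sim0$matrix[, 1:10])
  expect_lt(max(abs(cm0[upper.tri(cm0)])), 0.04)

  expect_identical(generate_module_dataset(cfg)$matrix, sim$matrix)
})

test_that("counts mode emits integer counts near the sparsity target", {
  cfg <- module_sim_config(n_cells = 2000, n_genes = 100,
                           module_sizes = rep(10, 2), mode = "counts",
                           sparsity_target = 0.6, seed = 5)
  sim <- generate_module_dataset(cfg)
  expect_true(all(sim$matrix >= 0))
  expect_true(all(sim$matrix == floor(sim$matrix)))
  expect_lt(abs(mean(sim$matrix == 0) - 0.6), 0.02)
  expect_error(module_sim_config(n_genes = 10, module_sizes = c(6, 6)), "exceed")
})

test_that("molecule generator places genes by domain construction", {
  one <- generate_molecule_table(100, 100,
    list(list(type = "rect", xlim = c(0, 100), ylim = c(0, 100),
              profile = c(GENE1 = 1))), 500, seed = 1)
  expect_true(all(one$molecules$gene == "GENE1"))
  expect_true(all(one$molecules$x >= 0 & one$molecules$x <= 100))

  none <- generate_molecule_table(100, 100,
    list(list(type = "rect", xlim = c(0, 100), ylim = c(0, 100),
              profile = c(GENE1 = 1))), 0, seed = 1)
  expect_identical(nrow(none$molecules), 0L)
  expect_named(none$molecules, c("x", "y", "gene", "section"))

  two <- two_domain_slide(2000, seed = 2)
  is_a <- two$sim$molecules$gene %in% two$genes_a
  expect_identical(unname(is_a), unname(two$sim$truth$domain_of_molecule == 1))
  expect_error(generate_molecule_table(100, 100, list(), 10), "domain")
  expect_error(generate_molecule_table(100, 100,
    list(list(type = "disc", center = c(95, 50), radius = 10, profile = c(A = 1))),
    10), "beyond the slide")
})

test_that("DE-comparison fixture delivers requested overlap and correlation", {
  # |A n B| = 50, |A u B| = 100 by construction
  de <- generate_de_comparison(n_genes = 200, shared_fraction = 2 / 3,
                               logfc_correlation = 0.9, seed = 1, n_sig = 75)
  expect_equal(de$expected_jaccard, 0.5)
  sig_a <- de$table_a$gene[de$table_a$significant]
  sig_b <- de$table_b$gene[de$table_b$significant]
  expect_identical(length(intersect(sig_a, sig_b)), 50L)
  expect_identical(length(union(sig_a, sig_b)), 100L)

  # perfectly correlated shared logFCs
  de1 <- generate_de_comparison(400, 0.5, 1, seed = 2)
  shared <- intersect(de1$table_a$gene[de1$table_a$significant],
                      de1$table_b$gene[de1$table_b$significant])
  a <- de1$table_a$logFC[match(shared, de1$table_a$gene)]
  b <- de1$table_b$logFC[match(shared, de1$table_b$gene)]
  expect_equal(cor(a, b), 1, tolerance = 1e-12)

  # independent shared logFCs: sampling error bound 1/sqrt(n)
  de0 <- generate_de_comparison(4000, 2 / 3, 0, seed = 3, n_sig = 1500)
  shared0 <- intersect(de0$table_a$gene[de0$table_a$significant],
                       de0$table_b$gene[de0$table_b$significant])
  expect_gte(length(shared0), 1000)
  a0 <- de0$table_a$logFC[match(shared0, de0$table_a$gene)]
  b0 <- de0$table_b$logFC[match(shared0, de0$table_b$gene)]
  expect_lt(abs(cor(a0, b0)), 0.08)
})
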