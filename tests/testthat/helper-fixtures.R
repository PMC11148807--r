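# Shared fixture builders. Everything is generated in code; no files.

# minimal gene-set collection matching a hand-built 6-gene panel
tiny_panel <- function() {
  genes <- c("MT-01", "NUC-001", "MKCM-01", "MKFB-01", "BG-001", "BG-002")
  sets <- list(mito = "MT-01", nuclear = "NUC-001",
               CM = "MKCM-01", FB = "MKFB-01")
  list(genes = genes, sets = sets)
}

# cells x genes count matrix with named dims
named_counts <- function(m, prefix_cell = "c", prefix_gene = "g") {
  dimnames(m) <- list(sprintf("%s%d", prefix_cell, seq_len(nrow(m))),
                      sprintf("%s%d", prefix_gene, seq_len(ncol(m))))
  m
}

# two disconnected k-cliques as an igraph graph with unit weights
two_cliques <- function(k = 5) {
  g <- igraph::make_full_graph(k) + igraph::make_full_graph(k)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- sprintf("n%02d", seq_len(2 * k))
  g
}

# brute-force hexagon assignment: nearest center, ties to lowest index
oracle_hex_assign <- function(x, y, grid) {
  ctr <- grid$centers
  vapply(seq_along(x), function(i) {
    d <- (ctr$x - x[i])^2 + (ctr$y - y[i])^2
    ctr$index[which.min(d)]
  }, 1L)
}

# hand-rolled BH step-up for the dual-route FDR checks
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# planted two-domain molecule slide shared by spatial tests
two_domain_slide <- function(n_molecules = 10000, seed = 1L) {
  genes_a <- paste0("ga", 1:8)
  genes_b <- paste0("gb", 1:8)
  domains <- list(
    list(type = "disc", center = c(300, 400), radius = 250,
         profile = stats::setNames(rep(1, 8), genes_a)),
    list(type = "disc", center = c(900, 400), radius = 250,
         profile = stats::setNames(rep(1, 8), genes_b)))
  sim <- generate_molecule_table(1200, 800, domains, n_molecules, seed = seed)
  list(sim = sim, genes_a = genes_a, genes_b = genes_b,
       bbox = c(0, 1200, 0, 800))
}
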