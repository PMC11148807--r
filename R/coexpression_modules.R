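## Gene co-expression module discovery from whitened correlation graphs.
##
## The cells x genes matrix X is column-centred and decomposed as
## X = U S V'. The gene-gene association matrix at whitening resolution P is
## M = V S^P V', normalised to correlation scale. P interpolates between the
## fully ZCA-whitened structure (P = 0: the gene correlations of
## (XX')^(-1/2) X, which removes cell-cell correlation structure that biases
## module recovery) and the ordinary Pearson correlations (P = 2, since
## X'X = V S^2 V'). Correlations are z-scored within sparsity strata, the
## graphs thresholded at z > z_min, and modules found by multiplex
## Leiden-style community detection over the per-resolution graph ensemble.

#' ZCA-adjusted gene-gene correlation at a whitening resolution
#'
#' @param X Cells x genes numeric matrix; column-centred internally.
#' @param P Whitening resolution exponent in \[0, 2\]: 0 gives the gene
#'   correlations of the explicitly ZCA-whitened matrix, 2 the ordinary
#'   Pearson correlation matrix.
#' @return A `zca_correlation` list: `C` (genes x genes, unit diagonal where
#'   defined, entries in \[-1, 1\]), `P`, `undefined` (genes with zero
#'   diagonal, whose correlations are set to 0), and the singular values `d`.
#' @export
zca_gene_correlation <- function(X, P) {
  if (any(!is.finite(X))) stop("non-finite values in the expression matrix")
  if (min(dim(X)) < 2L) stop("need at least 2 cells and 2 genes")
  if (P < 0 || P > 2) stop("P must lie in [0, 2]")
  X <- sweep(X, 2L, colMeans(X), "-")
  sv <- svd(X)
  d <- sv$d
  tol <- 1e-12 * max(d, 0)
  # 0^0 := 0 for the numerical null space: directions carrying no signal are
  # not amplified at P = 0
  dp <- ifelse(d <= tol, 0, d^P)
  M <- sv$v %*% (dp * t(sv$v))
  diag_m <- diag(M)
  defined <- diag_m > 1e-12 * max(diag_m, 0)
  scale_vec <- ifelse(defined, 1 / sqrt(diag_m), 0)
  C <- M * tcrossprod(scale_vec)
  C <- (C + t(C)) / 2
  diag(C)[defined] <- 1
  C[abs(C) > 1] <- sign(C[abs(C) > 1])
  dimnames(C) <- list(colnames(X), colnames(X))
  structure(list(C = C, P = P, undefined = !defined, d = d),
            class = "zca_correlation")
}

#' Sparsity-stratified z-scoring of gene-gene correlations
#'
#' Genes are assigned to equal-frequency bins of their zero fraction in the
#' *raw* count matrix; for every unordered bin pair the null mean and SD are
#' estimated from all off-diagonal correlations between the two bins, and
#' each correlation is z-scored against its stratum. This controls for the
#' inflated correlation estimates that sparse genes produce. The null
#' parameters are estimated robustly (median and 1.4826 x MAD) so that the
#' co-expressed pairs the procedure is meant to find do not inflate their
#' own null.
#'
#' @param zca A `zca_correlation` (or a plain symmetric matrix).
#' @param zeros_per_gene Number of zero entries per gene in the raw counts,
#'   aligned with the correlation matrix's gene axis.
#' @param n_sparsity_bins Number of sparsity strata; reduced with a warning
#'   when there are fewer genes than bins.
#' @return Symmetric genes x genes z matrix with zero diagonal.
#' @export
sparsity_zscore <- function(zca, zeros_per_gene, n_sparsity_bins = 10) {
  C <- if (inherits(zca, "zca_correlation")) zca$C else zca
  g <- ncol(C)
  if (length(zeros_per_gene) != g) stop("zeros_per_gene not aligned with the gene axis")
  if (n_sparsity_bins > g) {
    warning("fewer genes than sparsity bins; using ", g, " bins")
    n_sparsity_bins <- g
  }
  bins <- equal_freq_bins(zeros_per_gene, n_sparsity_bins)
  z <- matrix(0, g, g, dimnames = dimnames(C))
  ids <- sort(unique(bins))
  for (ai in seq_along(ids)) {
    for (bi in ai:length(ids)) {
      ia <- which(bins == ids[ai])
      ib <- which(bins == ids[bi])
      block <- C[ia, ib, drop = FALSE]
      if (ai == bi) {
        off <- block[upper.tri(block)]
      } else {
        off <- as.vector(block)
      }
      if (length(off) < 2L) next
      mu <- stats::median(off)
      sdv <- stats::mad(off, constant = 1.4826)
      if (sdv < 1e-12) {
        warning("zero-spread stratum (bins ", ids[ai], ",", ids[bi], "); z set to 0")
        next
      }
      zb <- (block - mu) / sdv
      z[ia, ib] <- zb
      z[ib, ia] <- t(zb)
    }
  }
  diag(z) <- 0
  z
}

#' Threshold a z matrix into a weighted gene graph
#'
#' @param z Symmetric z matrix.
#' @param z_min Strict threshold: an undirected edge is created iff
#'   `z > z_min`, with the z value as weight. Isolated genes are retained as
#'   nodes.
#' @return An undirected weighted `igraph` graph over all genes.
#' @export
threshold_graph <- function(z, z_min = 4.5) {
  g <- ncol(z)
  adj <- z
  adj[!(z > z_min)] <- 0
  adj[lower.tri(adj, diag = TRUE)] <- 0
  idx <- which(adj > 0, arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n = g, directed = FALSE)
  if (!is.null(colnames(z))) igraph::V(gr)$name <- colnames(z)
  if (nrow(idx) > 0L) {
    gr <- igraph::add_edges(gr, t(idx), weight = adj[idx])
  }
  gr
}

## ---- multiplex Leiden-style community detection ---------------------------
## Optimises the equally-weighted sum over layers of the RB-configuration
## quality  Q_l = sum_ij (A_ij - gamma k_i k_j / 2m_l) d(c_i, c_j)
## by multilevel local moving with aggregation, followed by a refinement
## pass that splits communities into connected components of the multiplex
## union (the connectivity guarantee Leiden adds over Louvain) and a final
## move pass.

# one local-moving sweep cycle over a list of dense adjacency matrices;
# returns converged membership (integers 1..K, compacted)
multiplex_local_moving <- function(A_list, gamma, membership) {
  n <- nrow(A_list[[1L]])
  L <- length(A_list)
  k <- lapply(A_list, rowSums)               # strengths per layer
  two_m <- vapply(k, sum, 1.0)               # 2m per layer
  active <- two_m > 0
  comm_k <- lapply(seq_len(L), function(l) {
    vapply(split(k[[l]], membership), sum, 1.0)[as.character(seq_len(max(membership)))]
  })
  # represent community strength as named-by-id numeric vectors
  comm_ids <- sort(unique(membership))
  K <- lapply(seq_len(L), function(l) {
    out <- numeric(max(comm_ids))
    s <- vapply(split(k[[l]], membership), sum, 1.0)
    out[as.integer(names(s))] <- s
    out
  })
  improved_any <- TRUE
  while (improved_any) {
    improved_any <- FALSE
    for (v in sample.int(n)) {
      cur <- membership[v]
      # edge weight from v to each community, per layer
      w_to <- vector("list", L)
      cand <- integer(0)
      for (l in seq_len(L)) {
        row <- A_list[[l]][v, ]
        row[v] <- 0  # self-loops are invariant under any move
        nz <- which(row > 0)
        if (length(nz) > 0L) {
          w <- vapply(split(row[nz], membership[nz]), sum, 1.0)
          w_to[[l]] <- w
          cand <- c(cand, as.integer(names(w)))
        } else {
          w_to[[l]] <- numeric(0)
        }
      }
      cand <- unique(c(cand, cur))
      # quality change of assigning v to community c (v removed first)
      gain <- vapply(cand, function(cc) {
        gsum <- 0
        for (l in seq_len(L)) {
          if (!active[l]) next
          w <- w_to[[l]]
          wc <- if (as.character(cc) %in% names(w)) w[[as.character(cc)]] else 0
          Kc <- K[[l]][cc] - if (cc == cur) k[[l]][v] else 0
          gsum <- gsum + wc - gamma * k[[l]][v] * Kc / two_m[l]
        }
        gsum
      }, 1.0)
      best <- cand[which.max(gain)]
      # strict improvement required; ties keep the current community
      if (best != cur && gain[which.max(gain)] > gain[match(cur, cand)] + 1e-12) {
        membership[v] <- best
        for (l in seq_len(L)) {
          K[[l]][cur] <- K[[l]][cur] - k[[l]][v]
          K[[l]][best] <- K[[l]][best] + k[[l]][v]
        }
        improved_any <- TRUE
      }
    }
  }
  match(membership, sort(unique(membership)))
}

# collapse layers by community membership
aggregate_layers <- function(A_list, membership) {
  K <- max(membership)
  M <- matrix(0, length(membership), K)
  M[cbind(seq_along(membership), membership)] <- 1
  lapply(A_list, function(A) t(M) %*% A %*% M)
}

#' Multiplex Leiden-style module detection over a graph ensemble
#'
#' Finds gene communities maximising the equally-weighted sum of
#' RB-configuration qualities across graph layers sharing one node set:
#' multilevel local moving with aggregation, then a refinement pass that
#' splits each community into connected components of the multiplex union
#' graph and a final move pass, so every reported module is connected in at
#' least the union of layers. Communities below `min_module_size` are
#' discarded and their genes left unassigned.
#'
#' @param graphs List of undirected weighted `igraph` graphs over the same
#'   (ordered) node set.
#' @param resolution Resolution parameter gamma; default 2.
#' @param seed Integer seed (node visiting order is randomised).
#' @param min_module_size Minimum genes per reported module; default 2.
#' @return A `module_set` list: `modules` (gene-name lists, size-descending,
#'   each sorted), `module_of_gene` (integer or `NA`, named by gene),
#'   `parameters`, `edges_per_layer`.
#' @export
multigraph_leiden <- function(graphs, resolution = 2, seed = 1L,
                              min_module_size = 2) {
  if (length(graphs) == 0L) stop("no graphs supplied")
  n <- igraph::vcount(graphs[[1L]])
  nodes <- igraph::V(graphs[[1L]])$name
  for (g in graphs) {
    if (igraph::vcount(g) != n || !identical(igraph::V(g)$name, nodes)) {
      stop("all layers must share one node set")
    }
  }
  A_list <- lapply(graphs, function(g) {
    as.matrix(igraph::as_adjacency_matrix(g, attr = if (!is.null(igraph::E(g)$weight) &&
                                                        igraph::ecount(g) > 0) "weight" else NULL,
                                          sparse = TRUE))
  })
  membership <- with_seed(seed, {
    memb <- seq_len(n)
    layers <- A_list
    repeat {
      new_memb <- multiplex_local_moving(layers, resolution, seq_len(nrow(layers[[1L]])))
      memb <- new_memb[memb]
      if (max(new_memb) == nrow(layers[[1L]])) break  # no merge happened
      layers <- aggregate_layers(layers, new_memb)
      if (max(new_memb) == 1L) break
    }
    # refinement: enforce connectivity in the multiplex union
    union_adj <- Reduce(`+`, A_list)
    memb <- split_disconnected(memb, union_adj)
    memb <- multiplex_local_moving(A_list, resolution, memb)
    split_disconnected(memb, union_adj)
  })
  module_set(membership, nodes, graphs, min_module_size,
             parameters = list(resolution = resolution, seed = seed,
                               min_module_size = min_module_size))
}

# split communities into connected components of the union adjacency
split_disconnected <- function(membership, union_adj) {
  g <- igraph::graph_from_adjacency_matrix(union_adj > 0, mode = "undirected",
                                           diag = FALSE)
  out <- membership
  next_id <- max(membership) + 1L
  for (cc in unique(membership)) {
    idx <- which(membership == cc)
    if (length(idx) < 2L) next
    sub <- igraph::induced_subgraph(g, idx)
    comp <- igraph::components(sub)$membership
    if (max(comp) > 1L) {
      for (piece in 2:max(comp)) {
        out[idx[comp == piece]] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  match(out, sort(unique(out)))
}

# package a membership vector into the module_set structure
module_set <- function(membership, nodes, graphs, min_module_size, parameters) {
  if (is.null(nodes)) nodes <- as.character(seq_along(membership))
  sizes <- table(membership)
  keep_ids <- as.integer(names(sizes)[sizes >= min_module_size])
  modules <- lapply(keep_ids, function(id) sort(nodes[membership == id]))
  ord <- order(-lengths(modules), vapply(modules, `[`, "", 1L))
  modules <- modules[ord]
  module_of_gene <- rep(NA_integer_, length(nodes))
  names(module_of_gene) <- nodes
  for (m in seq_along(modules)) {
    module_of_gene[modules[[m]]] <- m
  }
  edges_per_layer <- vapply(graphs, function(g) as.integer(igraph::ecount(g)), 1L)
  structure(list(modules = modules, module_of_gene = module_of_gene,
                 parameters = parameters, edges_per_layer = edges_per_layer),
            class = "module_set")
}

#' Detect gene co-expression modules from an expression matrix
#'
#' Full recipe: for each whitening resolution in `P_list`, compute the
#' ZCA-adjusted gene-gene correlations, z-score them within sparsity strata
#' of the raw counts, and threshold at `z > z_min`; then run multiplex
#' Leiden-style clustering over the per-resolution graph ensemble.
#'
#' @param X Cells x genes log-normalised expression matrix (rare genes
#'   already filtered).
#' @param raw_counts Matching raw count matrix, used only for the per-gene
#'   zero counts of the sparsity strata.
#' @param P_list Whitening resolutions; default `c(0, 0.5, 1)`.
#' @param z_min Edge threshold; default 4.5 (strict).
#' @param resolution Community-detection resolution; default 2.
#' @param seed Integer seed.
#' @param min_module_size Minimum module size; default 2.
#' @param n_sparsity_bins Sparsity strata; default 10.
#' @return A `module_set` (see [multigraph_leiden()]) whose `parameters`
#'   record the full recipe and which additionally carries `edge_lists`, a
#'   per-resolution data frame of thresholded edges (gene_i, gene_j, P, z).
#' @export
detect_modules <- function(X, raw_counts, P_list = c(0, 0.5, 1), z_min = 4.5,
                           resolution = 2, seed = 1L, min_module_size = 2,
                           n_sparsity_bins = 10) {
  stopifnot(ncol(X) == ncol(raw_counts))
  zeros <- as.numeric(Matrix::colSums(raw_counts == 0))
  graphs <- list()
  edge_lists <- list()
  for (P in P_list) {
    zc <- zca_gene_correlation(X, P)
    z <- sparsity_zscore(zc, zeros, n_sparsity_bins)
    gr <- threshold_graph(z, z_min)
    graphs[[length(graphs) + 1L]] <- gr
    el <- igraph::as_data_frame(gr, what = "edges")
    if (nrow(el) > 0L) {
      edge_lists[[length(edge_lists) + 1L]] <-
        data.frame(gene_i = el$from, gene_j = el$to, P = P, z = el$weight,
                   stringsAsFactors = FALSE)
    }
  }
  ms <- multigraph_leiden(graphs, resolution = resolution, seed = seed,
                          min_module_size = min_module_size)
  ms$parameters <- c(ms$parameters,
                     list(P_list = P_list, z_min = z_min,
                          n_sparsity_bins = n_sparsity_bins))
  ms$edge_lists <- if (length(edge_lists) > 0L) {
    do.call(rbind, edge_lists)
  } else {
    data.frame(gene_i = character(0), gene_j = character(0),
               P = numeric(0), z = numeric(0))
  }
  ms
}

#' Score cells for every module
#'
#' @param norm `processed_matrix` (log-normalised) or plain matrix with gene
#'   column names.
#' @param modules A `module_set`.
#' @param seed Seed forwarded to [score_gene_set()].
#' @return Cells x modules numeric matrix.
#' @export
score_modules <- function(norm, modules, seed = 1L) {
  if (length(modules$modules) == 0L) stop("empty module set")
  scores <- vapply(modules$modules, function(genes) {
    score_gene_set(norm, genes, seed = seed)
  }, numeric(nrow(if (inherits(norm, "processed_matrix")) norm$values else norm)))
  colnames(scores) <- paste0("module_", seq_along(modules$modules))
  scores
}

#' Hypergeometric gene-set enrichment of modules
#'
#' One-sided upper-tail hypergeometric test of each module's overlap with
#' each annotation set (sets intersected with the universe first), BH
#' corrected across all module x set pairs.
#'
#' @param modules A `module_set`.
#' @param sets Named list of annotation gene sets (e.g. GWAS-prioritised
#'   gene lists).
#' @param universe Character vector of testable genes.
#' @return Data frame: `module`, `set`, `overlap`, `module_size`, `set_size`,
#'   `universe_size`, `pvalue`, `fdr`, `genes` (comma-separated overlap).
#' @export
enrich_modules <- function(modules, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  rows <- list()
  for (m in seq_along(modules$modules)) {
    mod_genes <- intersect(modules$modules[[m]], universe)
    for (s in names(sets)) {
      set_genes <- intersect(sets[[s]], universe)
      ov <- intersect(mod_genes, set_genes)
      # P(X >= |ov|) drawing |module| genes from the universe
      p <- stats::phyper(length(ov) - 1L, length(set_genes),
                         length(universe) - length(set_genes),
                         length(mod_genes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = length(ov),
        module_size = length(mod_genes), set_size = length(set_genes),
        universe_size = length(universe), pvalue = p,
        genes = paste(sort(ov), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, "BH")
  out[, c("module", "set", "overlap", "module_size", "set_size",
          "universe_size", "pvalue", "fdr", "genes")]
}
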