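## Deterministic expression-processing chain: filtering, CP10K log
## normalisation, dispersion-based HVG selection, covariate regression,
## scaling, PCA, kNN graph, Leiden clustering, marker scoring/ranking,
## annotation and per-sample proportions.

stage_order <- c(raw = 1L, normalized_log = 2L, residual = 3L, scaled = 4L)

#' Construct a processed-matrix container
#'
#' Light container tracking the processing stage of a cells x genes matrix.
#' Stages advance only forward through raw, normalized_log, residual, scaled.
#'
#' @param values Cells x genes numeric matrix.
#' @param stage One of `"raw"`, `"normalized_log"`, `"residual"`, `"scaled"`.
#' @param cell_meta,gene_meta Optional data frames aligned with rows/columns.
#' @return A `processed_matrix`.
#' @export
processed_matrix <- function(values, stage,
                             cell_meta = NULL, gene_meta = NULL) {
  stage <- match.arg(stage, names(stage_order))
  structure(list(values = values, stage = stage,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "processed_matrix")
}

advance_stage <- function(pm, to) {
  if (stage_order[[to]] <= stage_order[[pm$stage]]) {
    stop("stage transition ", pm$stage, " -> ", to, " goes backwards")
  }
  to
}

#' Remove genes detected in too few cells
#'
#' @param counts Cells x genes count matrix (dense or `Matrix`).
#' @param min_cells Minimum number of cells a gene must be detected in
#'   (nonzero count) to be kept. Default 10.
#' @return The column-subset count matrix.
#' @export
filter_rare_genes <- function(counts, min_cells = 10) {
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty count matrix")
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= min_cells
  if (!any(keep)) stop("no genes survive the min_cells filter")
  counts[, keep, drop = FALSE]
}

#' Library-size normalise and log-transform counts
#'
#' Computes `ln(count * target / cell_total + 1)` per entry (counts per
#' `target`, natural-log transformed). Cells with zero total counts are
#' dropped with a warning.
#'
#' @param counts Cells x genes count matrix.
#' @param target Library-size target; default 10000 (CP10K).
#' @param cell_meta Optional per-cell data frame carried along.
#' @return A `processed_matrix` at stage `normalized_log` whose `cell_meta`
#'   gains `total_counts` (the pre-normalisation totals).
#' @export
normalize_log1p <- function(counts, target = 10000, cell_meta = NULL) {
  if (any(counts < 0)) stop("negative counts")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    warning(sum(totals == 0), " all-zero cells dropped before normalisation")
    keep <- totals > 0
    counts <- counts[keep, , drop = FALSE]
    if (!is.null(cell_meta)) cell_meta <- cell_meta[keep, , drop = FALSE]
    totals <- totals[keep]
  }
  if (nrow(counts) == 0L) stop("no cells left to normalise")
  values <- log1p(as_dense(counts) * (target / totals))
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = rownames(counts) %||% seq_len(nrow(counts)))
  }
  cell_meta$total_counts <- totals
  processed_matrix(values, "normalized_log", cell_meta = cell_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select highly variable genes by binned normalised dispersion
#'
#' Means and dispersions (variance/mean) are computed on the back-transformed
#' scale (`expm1` of the log-normalised values); the mean statistic is
#' `log1p(mean)` and the dispersion statistic `log(dispersion)`, the classic
#' dispersion-based recipe. Dispersions are z-scored within equal-frequency
#' mean bins; bins left with fewer than two genes are merged with their lower
#' neighbour so no gene is silently dropped.
#'
#' @param norm `processed_matrix` at stage `normalized_log`.
#' @param min_mean,max_mean Open interval the mean statistic must fall in.
#' @param min_disp Minimum normalised dispersion.
#' @param n_bins Number of equal-frequency mean bins.
#' @param mean_scale `"log1p"` (default) applies the cutoffs to
#'   `log1p(mean)`; `"raw"` applies them to the back-transformed mean.
#' @return Logical gene mask, with the per-gene statistics attached as
#'   attribute `"gene_stats"`.
#' @export
select_hvg <- function(norm, min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                       n_bins = 20, mean_scale = c("log1p", "raw")) {
  stopifnot(inherits(norm, "processed_matrix"), norm$stage == "normalized_log")
  mean_scale <- match.arg(mean_scale)
  x <- expm1(norm$values)
  if (ncol(x) < 2L) stop("need at least 2 genes for HVG selection")
  mu <- colMeans(x)
  v <- col_vars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  mean_stat <- if (mean_scale == "log1p") log1p(mu) else mu
  disp_stat <- ifelse(disp > 0, log(disp), NA_real_)
  bins <- equal_freq_bins(mean_stat, n_bins)
  # merge singleton bins downward so every bin has >= 2 genes
  repeat {
    tab <- table(bins)
    small <- as.integer(names(tab)[tab < 2L])
    if (length(small) == 0L || length(tab) == 1L) break
    b <- small[1L]
    ids <- sort(unique(bins))
    nb <- if (b == min(ids)) min(ids[ids > b]) else max(ids[ids < b])
    bins[bins == b] <- nb
  }
  z <- rep(NA_real_, length(disp_stat))
  for (b in unique(bins)) {
    idx <- which(bins == b)
    ds <- disp_stat[idx]
    m <- mean(ds, na.rm = TRUE)
    s <- stats::sd(ds, na.rm = TRUE)
    z[idx] <- if (is.na(s) || s < 1e-12) 0 else (ds - m) / s
  }
  z[is.na(z)] <- -Inf  # zero-dispersion genes can never be variable
  keep <- mean_stat > min_mean & mean_stat < max_mean & z >= min_disp
  names(keep) <- colnames(norm$values)
  stats_df <- data.frame(mean = mean_stat, dispersion = disp_stat,
                         dispersion_norm = z, hvg = keep)
  rownames(stats_df) <- colnames(norm$values)
  attr(keep, "gene_stats") <- stats_df
  keep
}

#' Regress per-cell covariates out of every gene
#'
#' Ordinary least squares of each gene on the supplied covariates (intercept
#' always included); the residual matrix is returned. Constant covariates are
#' dropped with a warning; any remaining rank deficiency is an error.
#'
#' @param norm `processed_matrix` at stage `normalized_log`.
#' @param covariates Named list or data frame of per-cell numeric vectors.
#' @return A `processed_matrix` at stage `residual`.
#' @export
regress_covariates <- function(norm, covariates) {
  stopifnot(inherits(norm, "processed_matrix"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(norm$values)) stop("covariate length mismatch")
  if (any(!vapply(covariates, is.numeric, TRUE))) stop("covariates must be numeric")
  if (any(!is.finite(as.matrix(covariates)))) stop("covariates must be finite")
  const <- vapply(covariates, function(v) stats::var(v) < 1e-24, TRUE)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("rank-deficient covariate design")
  res <- qr.resid(qr_d, norm$values)
  dimnames(res) <- dimnames(norm$values)
  processed_matrix(res, advance_stage(norm, "residual"),
                   cell_meta = norm$cell_meta, gene_meta = norm$gene_meta)
}

#' Standard-scale genes with an upper clip
#'
#' Per gene: zero mean, unit variance (zero-variance genes become all zeros),
#' then values clipped from above at `max_value`.
#'
#' @param pm `processed_matrix` at stage `normalized_log` or `residual`.
#' @param max_value Upper clip; default 10.
#' @return A `processed_matrix` at stage `scaled`.
#' @export
scale_clip <- function(pm, max_value = 10) {
  stopifnot(inherits(pm, "processed_matrix"))
  v <- col_vars(pm$values)
  sdv <- sqrt(pmax(v, 0))
  mu <- colMeans(pm$values)
  out <- sweep(pm$values, 2L, mu, "-")
  nz <- sdv > 1e-12
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdv[nz], "/")
  out[, !nz] <- 0
  out[out > max_value] <- max_value
  processed_matrix(out, advance_stage(pm, "scaled"),
                   cell_meta = pm$cell_meta, gene_meta = pm$gene_meta)
}

#' Principal-component embedding
#'
#' Thin SVD of the (re-centred) scaled matrix; components are made
#' reproducible by fixing each loading vector's sign so its largest-magnitude
#' entry is positive.
#'
#' @param scaled `processed_matrix` at stage `scaled` (a plain matrix is also
#'   accepted).
#' @param n_pcs Number of components; clamped to `min(dim) ` with a warning.
#' @return List with `embedding` (cells x n_pcs), `loadings` (genes x n_pcs)
#'   and `sdev`.
#' @export
pca_embed <- function(scaled, n_pcs = 40) {
  x <- if (inherits(scaled, "processed_matrix")) scaled$values else scaled
  x <- sweep(x, 2L, colMeans(x), "-")
  max_pcs <- min(dim(x))
  if (n_pcs > max_pcs) {
    warning("n_pcs clamped from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  sv <- svd(x, nu = n_pcs, nv = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 1.0)
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2L, flip, "*")
  v <- sweep(sv$v, 2L, flip, "*")
  emb <- sweep(u, 2L, sv$d[seq_len(n_pcs)], "*")
  rownames(emb) <- rownames(x)
  rownames(v) <- colnames(x)
  list(embedding = emb, loadings = v,
       sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, nrow(x) - 1)))
}

#' Exact k-nearest-neighbour graph
#'
#' All-pairs Euclidean distances with ties broken toward the lower cell
#' index; the graph is union-symmetrised (an undirected edge when either
#' endpoint lists the other among its k nearest).
#'
#' @param embedding Cells x dims matrix.
#' @param k Neighbours per cell; clamped to `n - 1` with a warning.
#' @return An undirected `igraph` graph with unit connectivity weights.
#' @export
knn_graph <- function(embedding, k = 10) {
  n <- nrow(embedding)
  if (n < 2L) stop("need at least 2 cells for a kNN graph")
  if (k >= n) {
    warning("k clamped from ", k, " to ", n - 1L)
    k <- n - 1L
  }
  d2 <- as.matrix(stats::dist(embedding))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])        # stable: ties resolved toward lower index
    ord <- ord[ord != i][seq_len(k)]
    edges[[i]] <- cbind(i, ord)
  }
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- 1
  if (!is.null(rownames(embedding))) igraph::V(g)$name <- rownames(embedding)
  g
}

#' Leiden clustering of a cell graph
#'
#' Runs the Leiden algorithm with the RB-configuration (resolution-scaled
#' modularity) objective, seeded, and relabels communities by descending
#' size (ties toward the lower original label). Labels are 1-based integers.
#'
#' @param graph An `igraph` graph.
#' @param resolution Resolution parameter; default 1.
#' @param seed Integer seed.
#' @param n_iterations Leiden iterations; default 10 (runs to convergence at
#'   these sizes).
#' @return Integer cluster labels, one per vertex.
#' @export
leiden_cluster <- function(graph, resolution = 1, seed = 1L, n_iterations = 10) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = n_iterations,
      weights = igraph::E(graph)$weight
    ))
  })
  relabel_by_size(as.integer(memb))
}

# relabel integer communities to 1..K by descending size, ties toward the
# lower original label
relabel_by_size <- function(labels) {
  tab <- table(labels)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- stats::setNames(seq_along(ord), names(tab)[ord])
  as.integer(map[as.character(labels)])
}

#' Score cells for a gene set against expression-matched controls
#'
#' Genes are binned by mean expression into `n_bins` equal-frequency bins;
#' for each set gene, `n_ctrl` control genes are sampled (seeded) from its
#' bin, and the score is the per-cell mean over set genes minus the mean
#' over the pooled control genes.
#'
#' @param norm `processed_matrix` at stage `normalized_log` (any real-valued
#'   stage is accepted).
#' @param gene_set Character vector of gene names.
#' @param n_bins Expression bins; default 25.
#' @param n_ctrl Controls sampled per set gene; default 50.
#' @param seed Integer seed.
#' @return Numeric per-cell score vector.
#' @export
score_gene_set <- function(norm, gene_set, n_bins = 25, n_ctrl = 50, seed = 1L) {
  x <- if (inherits(norm, "processed_matrix")) norm$values else norm
  genes <- colnames(x)
  if (is.null(genes)) stop("matrix must carry gene column names")
  set_idx <- which(genes %in% gene_set)
  if (length(set_idx) == 0L) stop("gene set is empty after intersection with the matrix")
  if (length(set_idx) < length(unique(gene_set))) {
    warning(length(unique(gene_set)) - length(set_idx),
            " gene-set member(s) absent from the matrix were dropped")
  }
  mu <- colMeans(x)
  bins <- equal_freq_bins(mu, n_bins)
  ctrl <- with_seed(seed, {
    unlist(lapply(set_idx, function(g) {
      pool <- setdiff(which(bins == bins[g]), g)
      if (length(pool) == 0L) return(integer(0))
      pool[sample.int(length(pool), n_ctrl, replace = length(pool) < n_ctrl)]
    }))
  })
  ctrl <- unique(ctrl)
  set_mean <- rowMeans(x[, set_idx, drop = FALSE])
  ctrl_mean <- if (length(ctrl) > 0L) rowMeans(x[, ctrl, drop = FALSE]) else 0
  unname(set_mean - ctrl_mean)
}

#' Rank cluster marker genes by Wilcoxon rank-sum test
#'
#' Per cluster, each gene is tested cluster vs rest with a two-sided Wilcoxon
#' rank-sum test (exact when both groups have fewer than 25 cells and no
#' ties, normal approximation with tie correction otherwise), p-values are
#' BH-adjusted across genes within the cluster, and the ranked list is
#' truncated to the top `n_top` significant genes. The logFC is the
#' difference of mean log-normalised expression (cluster minus rest).
#'
#' @param norm `processed_matrix` at stage `normalized_log`.
#' @param labels Per-cell cluster labels.
#' @param n_top Ranked significant genes retained per cluster; default 500.
#' @param alpha BH FDR significance threshold; default 0.05.
#' @return Named list per cluster, each with `table` (all genes, sorted by
#'   p-value then |logFC| descending) and `top` (truncated significant list).
#' @export
rank_markers <- function(norm, labels, n_top = 500, alpha = 0.05) {
  x <- if (inherits(norm, "processed_matrix")) norm$values else norm
  stopifnot(length(labels) == nrow(x))
  out <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    n1 <- sum(in_cl); n0 <- sum(!in_cl)
    if (n1 < 2L || n0 < 2L) {
      warning("cluster ", cl, " has fewer than 2 cells on one side; skipped")
      next
    }
    exact <- n1 < 25 && n0 < 25
    p <- vapply(seq_len(ncol(x)), function(j) {
      suppressWarnings(stats::wilcox.test(x[in_cl, j], x[!in_cl, j],
                                          exact = exact)$p.value)
    }, 1.0)
    p[is.na(p)] <- 1  # constant genes: no evidence either way
    lfc <- colMeans(x[in_cl, , drop = FALSE]) - colMeans(x[!in_cl, , drop = FALSE])
    fdr <- stats::p.adjust(p, "BH")
    tab <- data.frame(gene = colnames(x) %||% as.character(seq_len(ncol(x))),
                      logFC = lfc, pvalue = p, fdr = fdr,
                      significant = fdr < alpha,
                      stringsAsFactors = FALSE, row.names = NULL)
    tab <- tab[order(tab$pvalue, -abs(tab$logFC)), ]
    top <- tab[tab$significant, ]
    top <- utils::head(top, n_top)
    out[[as.character(cl)]] <- list(table = tab, top = top)
  }
  out
}

#' Annotate clusters against reference marker sets
#'
#' Each cluster is assigned the reference type whose marker-set score (mean
#' of [score_gene_set()] over the cluster's cells) is highest. Clusters whose
#' mean score exceeds the `high_quantile` quantile of per-cluster scores for
#' two or more distinct types are flagged as doublet clusters.
#'
#' @param norm `processed_matrix` at stage `normalized_log`.
#' @param labels Per-cell cluster labels.
#' @param reference_markers Named list of marker gene sets.
#' @param high_quantile Quantile (over clusters, per type) above which a
#'   score counts as "high"; default 0.9.
#' @param seed Seed forwarded to the scorer.
#' @return Data frame per cluster: `cluster`, `type`, `doublet_cluster`, and
#'   the per-type mean score matrix as attribute `"score_matrix"`.
#' @export
annotate_clusters <- function(norm, labels, reference_markers,
                              high_quantile = 0.9, seed = 1L) {
  if (length(reference_markers) == 0L) stop("no reference marker sets supplied")
  clusters <- sort(unique(labels))
  scores <- sapply(names(reference_markers), function(nm) {
    s <- score_gene_set(norm, reference_markers[[nm]], seed = seed)
    vapply(clusters, function(cl) mean(s[labels == cl]), 1.0)
  })
  scores <- matrix(scores, nrow = length(clusters),
                   dimnames = list(as.character(clusters), names(reference_markers)))
  type <- colnames(scores)[max.col(scores, ties.method = "first")]
  doublet <- rep(FALSE, length(clusters))
  if (ncol(scores) >= 2L && length(clusters) >= 2L) {
    thr <- apply(scores, 2L, stats::quantile, probs = high_quantile, type = 7)
    high <- sweep(scores, 2L, thr, ">=")
    doublet <- rowSums(high) >= 2L
  }
  out <- data.frame(cluster = clusters, type = type,
                    doublet_cluster = doublet, stringsAsFactors = FALSE)
  attr(out, "score_matrix") <- scores
  out
}

#' Per-sample label proportions with group summaries
#'
#' @param labels Per-cell labels (cluster or cell type).
#' @param sample_ids Per-cell sample ids.
#' @param groups Optional named vector mapping sample id to group.
#' @return Data frame `sample`, `label`, `n`, `proportion` (percent); when
#'   `groups` is given, per group x label [boxplot_summary()] rows are
#'   attached as attribute `"group_summaries"`.
#' @export
compute_proportions <- function(labels, sample_ids, groups = NULL) {
  if (length(labels) != length(sample_ids)) stop("labels and sample_ids differ in length")
  tab <- table(sample = sample_ids, label = labels)
  n_per_sample <- rowSums(tab)
  if (any(n_per_sample == 0)) {
    warning("empty sample(s) excluded: ",
            paste(rownames(tab)[n_per_sample == 0], collapse = ", "))
    tab <- tab[n_per_sample > 0, , drop = FALSE]
    n_per_sample <- n_per_sample[n_per_sample > 0]
  }
  prop <- sweep(tab, 1L, n_per_sample, "/") * 100
  out <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(out) <- c("sample", "label", "n")
  out$proportion <- as.data.frame(as.table(prop))$Freq
  if (!is.null(groups)) {
    out$group <- unname(groups[out$sample])
    summaries <- do.call(rbind, lapply(split(out, list(out$group, out$label), drop = TRUE),
      function(df) {
        bs <- boxplot_summary(df$proportion)
        data.frame(group = df$group[1], label = df$label[1],
                   median = bs$median, q1 = bs$q1, q3 = bs$q3,
                   whisker_low = bs$whisker_low, whisker_high = bs$whisker_high,
                   n = bs$n, stringsAsFactors = FALSE)
      }))
    rownames(summaries) <- NULL
    attr(out, "group_summaries") <- summaries
  }
  out
}
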