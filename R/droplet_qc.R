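## Quality-space droplet filtering for single-nuclei RNA-seq: per-droplet
## contamination metrics, k-means clustering in the standardised metric
## space, cluster-level empty/contaminated flagging, and per-sample MAD
## outlier filtering.

#' Default droplet-QC configuration
#'
#' Thresholds are this package's documented defaults, all configurable:
#' `k = 4` quality-space clusters, cluster flagged empty when its mean
#' spliced fraction exceeds `splicing_max = 0.7` while its mean nuclear score
#' sits below the `nuclear_quantile = 0.5` quantile of cluster means, flagged
#' contaminated when its mean mitochondrial fraction exceeds
#' `mito_max = 0.3`; per-sample outlier filtering at `n_mads = 4`.
#'
#' @param k Number of quality-space clusters.
#' @param splicing_max,mito_max,nuclear_quantile Cluster flagging rules.
#' @param n_mads Per-sample MAD multiplier.
#' @param seed Seed for metric scoring and clustering.
#' @return A `qc_config` list.
#' @export
qc_config <- function(k = 4, splicing_max = 0.7, mito_max = 0.3,
                      nuclear_quantile = 0.5, n_mads = 4, seed = 1L) {
  rules <- list(splicing_max = splicing_max, mito_max = mito_max,
                nuclear_quantile = nuclear_quantile)
  for (nm in names(rules)) {
    if (rules[[nm]] < 0 || rules[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  structure(list(k = as.integer(k), rules = rules, n_mads = n_mads,
                 seed = as.integer(seed)),
            class = "qc_config")
}

#' Compute per-droplet contamination and quality metrics
#'
#' From spliced/unspliced count layers and a gene-set collection, computes
#' total counts, detected genes, splicing fraction (spliced share of total
#' counts), mitochondrial fraction, and binned-control enrichment scores
#' ([score_gene_set()] on the log-normalised totals) for the nuclear gene
#' set, the cardiomyocyte marker set and every non-cardiomyocyte marker set.
#'
#' @param spliced,unspliced Cells x genes count matrices sharing dimnames.
#' @param gene_sets Named list that must contain `mito`, `nuclear`, a
#'   cardiomyocyte set (named `CM` or given by `cm_set`) and at least one
#'   other marker set.
#' @param cm_set Name of the cardiomyocyte marker set within `gene_sets`.
#' @param seed Seed for control-gene sampling in the scorer.
#' @return A `qc_metrics` data frame, rows in the barcode order of the input:
#'   `total_counts`, `n_genes`, `splicing_fraction`, `mito_fraction`,
#'   `nuclear_score`, `cm_score`, one `score_<set>` column per
#'   non-cardiomyocyte set, and `max_noncm_score`.
#' @export
compute_qc_metrics <- function(spliced, unspliced, gene_sets,
                               cm_set = "CM", seed = 1L) {
  if (is.null(spliced) || is.null(unspliced)) {
    stop("both spliced and unspliced layers are required")
  }
  stopifnot(identical(dim(spliced), dim(unspliced)))
  total <- spliced + unspliced
  if (is.null(rownames(total))) {
    rownames(total) <- sprintf("BC%05d", seq_len(nrow(total)))
  }
  genes <- colnames(total)
  required <- c("mito", "nuclear", cm_set)
  if (!all(required %in% names(gene_sets))) {
    stop("gene_sets must provide: ", paste(required, collapse = ", "))
  }
  noncm <- setdiff(names(gene_sets), c("mito", "nuclear", cm_set))
  if (length(noncm) == 0L) stop("at least one non-cardiomyocyte marker set is required")
  present <- lapply(gene_sets, function(s) {
    kept <- intersect(s, genes)
    if (length(kept) < length(unique(s))) {
      warning(length(unique(s)) - length(kept), " gene-set member(s) missing from features dropped")
    }
    if (length(kept) == 0L) stop("a gene set is empty after intersecting with the features")
    kept
  })
  total_counts <- Matrix::rowSums(total)
  spliced_counts <- Matrix::rowSums(spliced)
  splicing_fraction <- ifelse(total_counts > 0, spliced_counts / total_counts, 0)
  if (any(total_counts == 0)) {
    warning(sum(total_counts == 0), " zero-count droplet(s): splicing fraction set to 0")
  }
  mito_fraction <- ifelse(total_counts > 0,
                          Matrix::rowSums(total[, present$mito, drop = FALSE]) / total_counts,
                          0)
  norm <- normalize_log1p(pmax_matrix(total))
  # normalisation may drop zero-count droplets; score on kept rows, pad zeros
  kept_rows <- rownames(norm$values)
  pad <- function(score) {
    out <- numeric(nrow(total))
    names(out) <- rownames(total)
    out[kept_rows] <- score
    unname(out)
  }
  metrics <- data.frame(
    total_counts = as.numeric(total_counts),
    n_genes = as.integer(Matrix::rowSums(total > 0)),
    splicing_fraction = splicing_fraction,
    mito_fraction = mito_fraction,
    nuclear_score = pad(score_gene_set(norm, present$nuclear, seed = seed)),
    cm_score = pad(score_gene_set(norm, present[[cm_set]], seed = seed)),
    row.names = rownames(total), stringsAsFactors = FALSE
  )
  for (nm in noncm) {
    metrics[[paste0("score_", nm)]] <- pad(score_gene_set(norm, present[[nm]], seed = seed))
  }
  metrics$max_noncm_score <- do.call(pmax, metrics[paste0("score_", noncm)])
  class(metrics) <- c("qc_metrics", "data.frame")
  metrics
}

# suppress all-zero-cell warnings from normalisation: zero droplets are
# legitimate here and handled by padding
pmax_matrix <- function(m) {
  keep <- Matrix::rowSums(m) > 0
  if (all(keep)) return(m)
  m[keep, , drop = FALSE]
}

# the metric columns spanning the contamination/quality space
quality_space_columns <- function(metrics) {
  intersect(c("splicing_fraction", "mito_fraction", "nuclear_score",
              "cm_score", "max_noncm_score"),
            names(metrics))
}

#' Cluster droplets in the standardised quality space
#'
#' Standardises the contamination metric columns (zero mean, unit variance;
#' zero-variance columns dropped with a warning) and partitions the droplets
#' with seeded k-means (25 restarts).
#'
#' @param metrics A `qc_metrics` data frame.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param columns Metric columns to use; defaults to splicing fraction,
#'   mitochondrial fraction, nuclear score, cardiomyocyte score and the max
#'   non-cardiomyocyte score.
#' @return Integer per-droplet cluster labels.
#' @export
cluster_quality_space <- function(metrics, k = 4, seed = 1L,
                                  columns = quality_space_columns(metrics)) {
  if (k < 2L) stop("k must be at least 2")
  x <- as.matrix(metrics[, columns, drop = FALSE])
  if (nrow(x) < k) stop("fewer droplets than clusters")
  v <- col_vars(x)
  if (any(v < 1e-24)) {
    warning("dropping zero-variance metric column(s): ",
            paste(columns[v < 1e-24], collapse = ", "))
    x <- x[, v >= 1e-24, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("degenerate input: all metric columns constant")
  x <- scale(x)
  with_seed(seed, {
    km <- stats::kmeans(x, centers = k, nstart = 25, iter.max = 100)
    as.integer(km$cluster)
  })
}

#' Flag empty/contaminated quality-space clusters
#'
#' A cluster is proposed as *empty* when its mean splicing fraction exceeds
#' `rules$splicing_max` while its mean nuclear score lies below the
#' `rules$nuclear_quantile` quantile of the per-cluster mean nuclear scores;
#' it is proposed as *contaminated* when its mean mitochondrial fraction
#' exceeds `rules$mito_max`. The empty rule takes precedence when both fire.
#'
#' @param labels Integer labels from [cluster_quality_space()].
#' @param metrics The matching `qc_metrics`.
#' @param rules List with `splicing_max`, `mito_max`, `nuclear_quantile`.
#' @return Character per-droplet proposal: `"kept"`, `"empty_cluster"` or
#'   `"contaminated_cluster"`.
#' @export
flag_contaminated_clusters <- function(labels, metrics,
                                       rules = qc_config()$rules) {
  for (nm in c("splicing_max", "mito_max", "nuclear_quantile")) {
    if (rules[[nm]] < 0 || rules[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  clusters <- sort(unique(labels))
  mean_by <- function(col) {
    vapply(clusters, function(cl) mean(metrics[[col]][labels == cl]), 1.0)
  }
  m_spl <- mean_by("splicing_fraction")
  m_mito <- mean_by("mito_fraction")
  m_nuc <- mean_by("nuclear_score")
  nuc_thr <- stats::quantile(m_nuc, rules$nuclear_quantile, type = 7, names = FALSE)
  empty <- m_spl > rules$splicing_max & m_nuc < nuc_thr
  contaminated <- m_mito > rules$mito_max
  proposal <- rep("kept", length(clusters))
  proposal[contaminated] <- "contaminated_cluster"
  proposal[empty] <- "empty_cluster"  # empty rule wins when both fire
  names(proposal) <- as.character(clusters)
  unname(proposal[as.character(labels)])
}

#' Per-sample MAD outlier filtering
#'
#' Within each sample, among the currently kept droplets, drops droplets
#' whose splicing or mitochondrial fraction exceeds the sample median plus
#' `n_mads` MADs (MAD scaled by 1.4826; one-sided, high side only). A zero
#' MAD reduces the threshold to the median, dropping only strictly greater
#' values. Samples with fewer than 3 kept droplets are skipped with a
#' warning.
#'
#' @param metrics A `qc_metrics` data frame.
#' @param sample_ids Per-droplet sample ids.
#' @param keep_mask Logical vector of currently kept droplets.
#' @param n_mads MAD multiplier; `Inf` disables the filter.
#' @return Updated logical keep mask.
#' @export
sample_outlier_filter <- function(metrics, sample_ids, keep_mask, n_mads = 4) {
  stopifnot(length(sample_ids) == nrow(metrics),
            length(keep_mask) == nrow(metrics))
  out <- keep_mask
  for (s in unique(sample_ids)) {
    idx <- which(sample_ids == s & keep_mask)
    if (length(idx) < 3L) {
      warning("sample ", s, " has fewer than 3 kept droplets; skipped")
      next
    }
    for (col in c("splicing_fraction", "mito_fraction")) {
      v <- metrics[[col]][idx]
      thr <- stats::median(v) + n_mads * stats::mad(v, constant = 1.4826)
      if (is.finite(thr)) out[idx[v > thr]] <- FALSE
    }
  }
  out
}

#' Run the full droplet-QC workflow
#'
#' Composes metric computation, quality-space clustering, cluster flagging,
#' per-sample MAD filtering and an optional external doublet mask, and
#' summarises retained droplets per sample.
#'
#' @param spliced,unspliced Cells x genes count layers.
#' @param gene_sets Gene-set collection (see [compute_qc_metrics()]).
#' @param config A [qc_config()].
#' @param sample_ids Per-droplet sample ids; default a single sample.
#' @param doublet_mask Optional logical vector, `TRUE` for droplets flagged
#'   as doublets by an external tool.
#' @param cm_set Name of the cardiomyocyte set in `gene_sets`.
#' @return A `qc_filter_result` list: `keep_mask`, `cluster_label`,
#'   `removal_reason` (kept / empty_cluster / contaminated_cluster /
#'   sample_outlier / doublet), `metrics`, and `per_sample_summary` with the
#'   retained count per sample plus its median and mean across samples.
#' @export
run_droplet_qc <- function(spliced, unspliced, gene_sets,
                           config = qc_config(), sample_ids = NULL,
                           doublet_mask = NULL, cm_set = "CM") {
  if (nrow(spliced) == 0L || ncol(spliced) == 0L) stop("empty count matrix")
  n <- nrow(spliced)
  if (is.null(sample_ids)) sample_ids <- rep("sample1", n)
  metrics <- compute_qc_metrics(spliced, unspliced, gene_sets,
                                cm_set = cm_set, seed = config$seed)
  labels <- cluster_quality_space(metrics, k = config$k, seed = config$seed)
  proposal <- flag_contaminated_clusters(labels, metrics, config$rules)
  reason <- proposal
  keep <- reason == "kept"
  kept_after_clusters <- keep
  keep <- sample_outlier_filter(metrics, sample_ids, keep, config$n_mads)
  reason[kept_after_clusters & !keep] <- "sample_outlier"
  if (!is.null(doublet_mask)) {
    stopifnot(length(doublet_mask) == n)
    reason[keep & doublet_mask] <- "doublet"
    keep <- keep & !doublet_mask
  }
  retained <- vapply(split(keep, sample_ids), sum, 1L)
  structure(list(
    keep_mask = keep,
    cluster_label = labels,
    removal_reason = reason,
    metrics = metrics,
    per_sample_summary = list(retained = retained,
                              median = stats::median(retained),
                              mean = mean(retained))
  ), class = "qc_filter_result")
}
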