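## Small comparison statistics used for figure-level dataset comparisons:
## Jaccard similarity of DEG sets, logFC correlations, min-max scaling and
## 1.5xIQR boxplot summaries. Quantiles use the linear-interpolation
## convention (type 7) throughout.

#' Jaccard similarity of two sets
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return `|A n B| / |A u B|`; two empty sets give 0 with a warning.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) {
    warning("both sets empty; Jaccard index defined as 0")
    return(0)
  }
  length(intersect(set_a, set_b)) / u
}

#' Pearson correlation of log fold changes between two DE tables
#'
#' In `overlap_significant` mode the correlation is computed over genes
#' significant in both tables; in `all_genes` mode over the union of genes
#' significant in either table, pairwise-complete (genes missing a logFC in
#' one table are dropped).
#'
#' @param table_a,table_b Data frames with columns `gene`, `logFC`,
#'   `significant`.
#' @param mode `"overlap_significant"` or `"all_genes"`.
#' @return List with `r` (Pearson correlation) and `n` (genes used).
#' @export
logfc_correlation <- function(table_a, table_b,
                              mode = c("overlap_significant", "all_genes")) {
  mode <- match.arg(mode)
  sig_a <- table_a$gene[table_a$significant]
  sig_b <- table_b$gene[table_b$significant]
  genes <- if (mode == "overlap_significant") {
    intersect(sig_a, sig_b)
  } else {
    union(sig_a, sig_b)
  }
  a <- table_a$logFC[match(genes, table_a$gene)]
  b <- table_b$logFC[match(genes, table_b$gene)]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) stop("fewer than 3 matched genes; correlation undefined")
  list(r = stats::cor(a[ok], b[ok]), n = sum(ok))
}

#' Min-max scale values to \[0, 1\]
#'
#' @param values Numeric vector.
#' @return `(v - min) / (max - min)`; a constant vector maps to all zeros
#'   with a warning.
#' @export
minmax_scale <- function(values) {
  if (length(values) == 0L) stop("empty input")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant input; min-max scale returns zeros")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Boxplot summary with the 1.5xIQR outlier rule
#'
#' Quartiles use linear-interpolation quantiles; a value is an outlier when
#' it lies below `q1 - 1.5 IQR` or above `q3 + 1.5 IQR`, and whiskers extend
#' to the most extreme non-outlier values.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inliers <- values[values >= lo & values <= hi]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inliers), whisker_high = max(inliers),
       outliers = sort(out), n = length(values))
}
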