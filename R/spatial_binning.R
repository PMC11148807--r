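## Hexagonal pseudo-spot binning of single-molecule spatial transcriptomics,
## plus the Resolve-style (no library-size normalisation) and Visium-style
## (CP10K) spot processing recipes.
##
## Hexagon convention: pointy-top hexagons; "width" is the center-to-center
## horizontal spacing within a row (so hexagon size = width / sqrt(3)), rows
## are width * sqrt(3) / 2 apart vertically and offset horizontally by half a
## width. The grid anchor sits at the bounding-box minimum corner.

#' Build a hexagonal grid covering a bounding box
#'
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param width Center-to-center horizontal spacing of the pointy-top
#'   hexagons, in pixels; default 80.
#' @return A `hex_grid` list: `width`, `size`, `origin`, `centers` (data
#'   frame `index`, `q`, `r`, `x`, `y` in axial coordinates), `bbox`. The
#'   grid extends at least one hexagon beyond the box on every side.
#' @export
build_hex_grid <- function(bbox, width = 80) {
  if (width <= 0) stop("width must be positive")
  if (length(bbox) != 4L || bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate bounding box")
  }
  size <- width / sqrt(3)
  origin <- c(bbox[1], bbox[3])
  vstep <- width * sqrt(3) / 2          # = 1.5 * size
  r_min <- floor((bbox[3] - origin[2]) / vstep) - 1L
  r_max <- ceiling((bbox[4] - origin[2]) / vstep) + 1L
  rows <- list()
  for (r in r_min:r_max) {
    # center x = origin_x + width * (q + r/2)
    q_min <- floor((bbox[1] - origin[1]) / width - r / 2) - 1L
    q_max <- ceiling((bbox[2] - origin[1]) / width - r / 2) + 1L
    q <- q_min:q_max
    rows[[length(rows) + 1L]] <- data.frame(
      q = q, r = r,
      x = origin[1] + width * (q + r / 2),
      y = origin[2] + vstep * r)
  }
  centers <- do.call(rbind, rows)
  centers$index <- seq_len(nrow(centers))
  centers <- centers[, c("index", "q", "r", "x", "y")]
  structure(list(width = width, size = size, origin = origin,
                 centers = centers, bbox = bbox),
            class = "hex_grid")
}

# fractional axial coordinates of points, then cube rounding
hex_round <- function(x, y, grid) {
  xp <- x - grid$origin[1]
  yp <- y - grid$origin[2]
  s <- grid$size
  qf <- (sqrt(3) / 3 * xp - yp / 3) / s
  rf <- (2 / 3 * yp) / s
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); ss <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(ss - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - ss[fix_q]
  r[fix_r] <- -q[fix_r] - ss[fix_r]
  cbind(q = q, r = r)
}

#' Assign molecules to hexagonal pseudo-spots
#'
#' Each molecule is assigned to the hexagon containing it via axial
#' cube rounding (equivalent to nearest hexagon center; exact boundary ties
#' resolve by nearest center, residual ties by lowest hexagon index). Empty
#' hexagons are dropped; total counts are conserved.
#'
#' @param molecules Data frame `x`, `y`, `gene` (and optionally `section`).
#' @param grid A [build_hex_grid()] grid.
#' @return A `spot_matrix` list: `counts` (spots x genes `dgCMatrix`),
#'   `centers` (spot center coordinates), `spot_of_molecule` (row index into
#'   `centers` per molecule), `section`, `platform = "hexbin"`.
#' @export
assign_molecules <- function(molecules, grid) {
  stopifnot(inherits(grid, "hex_grid"))
  section <- if (!is.null(molecules$section)) unique(molecules$section) else "S1"
  if (nrow(molecules) == 0L) {
    counts <- Matrix::Matrix(0, 0, 0, sparse = TRUE)
    return(structure(list(counts = counts,
                          centers = grid$centers[0, ],
                          spot_of_molecule = integer(0),
                          section = section, platform = "hexbin"),
                     class = "spot_matrix"))
  }
  qr_pts <- hex_round(molecules$x, molecules$y, grid)
  key <- paste(qr_pts[, "q"], qr_pts[, "r"])
  grid_key <- paste(grid$centers$q, grid$centers$r)
  hex_id <- match(key, grid_key)
  if (anyNA(hex_id)) {
    bad <- utils::head(which(is.na(hex_id)), 5L)
    stop("molecule(s) outside the padded grid, e.g. rows: ",
         paste(bad, collapse = ", "))
  }
  occupied <- sort(unique(hex_id))
  spot <- match(hex_id, occupied)
  genes <- sort(unique(molecules$gene))
  counts <- Matrix::sparseMatrix(
    i = spot, j = match(molecules$gene, genes), x = 1,
    dims = c(length(occupied), length(genes)),
    dimnames = list(sprintf("hex_%d", occupied), genes))
  counts <- methods::as(counts, "CsparseMatrix")
  centers <- grid$centers[occupied, ]
  rownames(centers) <- rownames(counts)
  structure(list(counts = counts, centers = centers,
                 spot_of_molecule = spot, section = section,
                 platform = "hexbin"),
            class = "spot_matrix")
}

#' Process hexbin pseudo-spots with the Resolve-style recipe
#'
#' Counts are log1p-transformed *without* library-size normalisation (small
#' targeted panels make per-spot rescaling an artifact source); per-gene OLS
#' regression removes the per-spot total count and detected-gene count;
#' then standard scaling (clip 10), PCA, kNN graph and seeded Leiden
#' clustering — all via the shared expression-pipeline operations.
#'
#' Pseudo-spots with very few molecules (partial tissue coverage at domain
#' or slide edges) are removed first, the usual spot-level QC step.
#'
#' @param spots A `spot_matrix` (or plain spots x genes count matrix).
#' @param n_pcs PCs for the embedding; default 15 (clamped with a warning on
#'   small panels).
#' @param resolution Leiden resolution; default 1.
#' @param k Neighbours for the kNN graph; default 10.
#' @param seed Integer seed.
#' @param min_counts Minimum molecules per pseudo-spot; default 20.
#' @param batch_hook Optional function `embedding -> embedding` applied
#'   between PCA and the kNN graph (integration hook); default identity.
#' @return List: `embedding`, `labels`, `log_values`, `kept_spots` (logical
#'   over the input spots).
#' @export
process_resolve_spots <- function(spots, n_pcs = 15, resolution = 1, k = 10,
                                  seed = 1L, min_counts = 20,
                                  batch_hook = identity) {
  counts <- if (inherits(spots, "spot_matrix")) spots$counts else spots
  if (ncol(counts) < 2L) stop("degenerate input: need at least 2 genes")
  kept_spots <- Matrix::rowSums(counts) >= min_counts
  counts <- counts[kept_spots, , drop = FALSE]
  if (nrow(counts) < 3L) stop("too few spots to process")
  x <- log1p(as_dense(counts))
  pm <- processed_matrix(x, "normalized_log")
  covars <- data.frame(total_counts = as.numeric(Matrix::rowSums(counts)),
                       n_genes = as.numeric(Matrix::rowSums(counts > 0)))
  res <- regress_covariates(pm, covars)
  sc <- scale_clip(res, max_value = 10)
  pca <- pca_embed(sc, n_pcs = n_pcs)
  emb <- batch_hook(pca$embedding)
  g <- knn_graph(emb, k = k)
  labels <- leiden_cluster(g, resolution = resolution, seed = seed)
  list(embedding = emb, labels = labels, log_values = x,
       kept_spots = kept_spots)
}

#' Process Visium-style spots with the CP10K recipe
#'
#' Normalise to `target` counts per spot, log1p, HVG selection (same cutoffs
#' as the single-nuclei pipeline), regression of total counts and
#' mitochondrial percentage, scaling (clip 10), PCA, kNN graph and seeded
#' Leiden clustering; optionally scores marker gene sets per spot.
#'
#' @param spots A `spot_matrix` or plain spots x genes count matrix.
#' @param target Per-spot library-size target; default 10000.
#' @param n_pcs,resolution,k,seed,batch_hook As in [process_resolve_spots()].
#' @param marker_sets Optional named list of marker sets scored with
#'   [score_gene_set()] on the normalised data.
#' @param mito_genes Optional character vector defining the mitochondrial
#'   percentage covariate (omitted from the regression when absent).
#' @param hvg Logical: apply HVG selection; disable for small panels.
#' @return List: `embedding`, `labels`, `scores` (spots x sets, or NULL),
#'   `norm` (the normalised `processed_matrix`).
#' @export
process_visium_spots <- function(spots, target = 10000, n_pcs = 40,
                                 resolution = 1, k = 10, seed = 1L,
                                 batch_hook = identity, marker_sets = NULL,
                                 mito_genes = NULL, hvg = TRUE) {
  counts <- if (inherits(spots, "spot_matrix")) spots$counts else spots
  if (ncol(counts) < 2L) stop("degenerate input: need at least 2 genes")
  norm <- normalize_log1p(counts, target = target)
  covars <- data.frame(total_counts = norm$cell_meta$total_counts)
  if (!is.null(mito_genes)) {
    mito <- intersect(mito_genes, colnames(counts))
    totals <- Matrix::rowSums(counts)
    pct <- as.numeric(100 * Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(totals, 1))
    covars$pct_mito <- pct[match(rownames(norm$values), rownames(counts))]
  }
  work <- norm
  if (hvg) {
    mask <- select_hvg(norm)
    if (sum(mask) < 2L) {
      warning("fewer than 2 HVGs; keeping all genes")
    } else {
      work <- processed_matrix(norm$values[, mask, drop = FALSE],
                               "normalized_log", cell_meta = norm$cell_meta)
    }
  }
  res <- regress_covariates(work, covars)
  sc <- scale_clip(res, max_value = 10)
  pca <- pca_embed(sc, n_pcs = n_pcs)
  emb <- batch_hook(pca$embedding)
  g <- knn_graph(emb, k = k)
  labels <- leiden_cluster(g, resolution = resolution, seed = seed)
  scores <- NULL
  if (!is.null(marker_sets)) {
    scores <- vapply(marker_sets, function(s) score_gene_set(norm, s, seed = seed),
                     numeric(nrow(norm$values)))
    rownames(scores) <- rownames(norm$values)
  }
  list(embedding = emb, labels = labels, scores = scores, norm = norm)
}

#' Summarise a gene's expression across sections
#'
#' Per section the gene's per-spot log1p expression is summarised with
#' [boxplot_summary()] (1.5xIQR whisker rule); sections whose panel lacks
#' the gene are reported as missing, not as zero.
#'
#' @param sections Named list of `spot_matrix` objects (or count matrices).
#' @param gene Gene symbol.
#' @param groups Optional named vector mapping section name to group.
#' @return Data frame: one row per section with `section`, `group`,
#'   `missing` and the boxplot-summary fields (`NA` when missing).
#' @export
quantify_gene_by_section <- function(sections, gene, groups = NULL) {
  if (is.null(names(sections))) names(sections) <- sprintf("S%d", seq_along(sections))
  rows <- lapply(names(sections), function(nm) {
    counts <- sections[[nm]]
    if (inherits(counts, "spot_matrix")) counts <- counts$counts
    if (!(gene %in% colnames(counts))) {
      return(data.frame(section = nm, missing = TRUE, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
                        whisker_high = NA_real_, n_outliers = NA_integer_,
                        n = 0L, stringsAsFactors = FALSE))
    }
    v <- log1p(as.numeric(counts[, gene]))
    bs <- boxplot_summary(v)
    data.frame(section = nm, missing = FALSE, median = bs$median, q1 = bs$q1,
               q3 = bs$q3, whisker_low = bs$whisker_low,
               whisker_high = bs$whisker_high,
               n_outliers = length(bs$outliers), n = bs$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- if (!is.null(groups)) unname(groups[out$section]) else NA_character_
  out
}

#' Export a per-molecule dot map
#'
#' One point per molecule at its exact coordinates, coloured by gene through
#' the palette (unmapped genes receive the default colour). Optionally
#' written as CSV and/or rendered to PNG.
#'
#' @param molecules Data frame `x`, `y`, `gene`.
#' @param palette Named character vector gene -> colour; may be empty.
#' @param default_color Colour for unmapped genes.
#' @param csv,png Optional output paths.
#' @param point_cex Point size for the PNG render.
#' @return Data frame `x`, `y`, `gene`, `color` (invisibly when writing).
#' @export
export_molecule_map <- function(molecules, palette = character(0),
                                default_color = "grey50", csv = NULL,
                                png = NULL, point_cex = 0.3) {
  color <- unname(palette[molecules$gene])
  color[is.na(color)] <- default_color
  out <- data.frame(x = molecules$x, y = molecules$y, gene = molecules$gene,
                    color = color, stringsAsFactors = FALSE)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 1200, height = 1200)
    on.exit(grDevices::dev.off())
    graphics::plot(out$x, out$y, col = out$color, pch = 16, cex = point_cex,
                   asp = 1, xlab = "x (px)", ylab = "y (px)")
  }
  if (is.null(csv) && is.null(png)) out else invisible(out)
}
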