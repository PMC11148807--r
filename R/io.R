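#' Write a count matrix as a Matrix Market triplet directory
#'
#' Writes `matrix.mtx` (or `<layer>.mtx` for each layer of a layered matrix),
#' `barcodes.tsv` and `features.tsv` in the Cell Ranger-style layout. Matrices
#' are stored genes x cells on disk (the usual convention); in memory this
#' package keeps cells x genes.
#'
#' @param counts A cells x genes matrix, or a named list of such matrices
#'   (e.g. `list(spliced = ..., unspliced = ...)`) sharing dimnames.
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(counts, dir) {
  if (!is.list(counts)) counts <- list(matrix = counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  first <- counts[[1L]]
  barcodes <- rownames(first)
  features <- colnames(first)
  if (is.null(barcodes) || is.null(features)) {
    stop("count matrices must carry barcode rownames and feature colnames")
  }
  for (nm in names(counts)) {
    m <- counts[[nm]]
    stopifnot(identical(rownames(m), barcodes), identical(colnames(m), features))
    m_t <- Matrix::t(Matrix::Matrix(m, sparse = TRUE))
    Matrix::writeMM(methods::as(m_t, "generalMatrix"),
                    file.path(dir, paste0(nm, ".mtx")))
  }
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(features, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a Matrix Market triplet directory
#'
#' @param dir Directory holding `barcodes.tsv`, `features.tsv` and one or more
#'   `.mtx` files (genes x cells on disk).
#' @return A named list of cells x genes `dgCMatrix` objects, one per `.mtx`
#'   file found.
#' @export
read_mtx_dir <- function(dir) {
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  mtx_files <- list.files(dir, pattern = "\\.mtx$", full.names = TRUE)
  if (length(mtx_files) == 0L) stop("no .mtx files in ", dir)
  out <- lapply(mtx_files, function(f) {
    m <- Matrix::t(Matrix::readMM(f))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(barcodes, features)
    m
  })
  names(out) <- sub("\\.mtx$", "", basename(mtx_files))
  out
}

#' Read a gene-set collection from a two-column TSV
#'
#' Expects columns `set_name` and `gene` (header required). Returns a named
#' list of unique gene vectors.
#'
#' @param path TSV path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene") %in% names(df))) {
    stop("gene-set TSV needs columns 'set_name' and 'gene'")
  }
  lapply(split(df$gene, df$set_name), unique)
}

#' Write a gene-set collection to a two-column TSV
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(
    set_name = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a molecule table as CSV
#'
#' @param molecules Data frame with columns `x`, `y`, `gene` and optionally
#'   `section`.
#' @param path Output path.
#' @export
write_molecule_csv <- function(molecules, path) {
  utils::write.csv(molecules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a molecule table CSV
#'
#' @param path CSV with columns `x`, `y`, `gene` and optionally `section`.
#' @return Data frame; a missing `section` column is filled with `"S1"`.
#' @export
read_molecule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "gene") %in% names(df))) {
    stop("molecule CSV needs columns x, y, gene")
  }
  if (is.null(df$section)) df$section <- "S1"
  df
}

#' Write a module set to JSON
#'
#' Serialises modules, per-gene assignment, parameters and per-layer edge
#' counts.
#'
#' @param modules A `module_set` from [multigraph_leiden()] / [detect_modules()].
#' @param path Output path.
#' @export
write_module_set_json <- function(modules, path) {
  payload <- list(
    modules = modules$modules,
    module_of_gene = modules$module_of_gene,
    parameters = modules$parameters,
    edges_per_layer = modules$edges_per_layer
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
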