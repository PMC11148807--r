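#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Area under the ROC curve by the rank-sum formula
#'
#' @param score Numeric vector of scores.
#' @param positive Logical vector, `TRUE` for positive cases.
#' @return AUROC in \[0, 1\]; ties handled by midranks.
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("auroc() needs at least one positive and one negative case")
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Equal-frequency bin assignment
#'
#' Assigns each value to one of `n_bins` bins of (as near as possible) equal
#' occupancy, by rank. Ties are broken by first occurrence so the assignment
#' is deterministic.
#'
#' Ties share a midrank, so equal values always land in the same bin (a
#' constant vector yields a single occupied bin).
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins; reduced to `length(x)` when larger.
#' @return Integer bin ids in `1:n_bins`, ordered with `x`.
#' @keywords internal
equal_freq_bins <- function(x, n_bins) {
  n <- length(x)
  n_bins <- max(1L, min(as.integer(n_bins), n))
  r <- rank(x, ties.method = "average")
  pmin(as.integer(ceiling(r * n_bins / n)), n_bins)
}

#' @keywords internal
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# column variance without forming a full apply() copy per gene
#' @keywords internal
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
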