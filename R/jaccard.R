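#' Binarize a non-negative count matrix
#'
#' Converts a features-by-cells count matrix into a presence/absence
#' indicator: an entry becomes 1 exactly when the count is positive.
#' Binarization is standard practice for sparse single-cell epigenomics
#' data (scATAC-seq peak or tile matrices, scChIP-seq bin matrices) and is
#' the expected input form for all scoring functions in this package.
#'
#' @param counts Features-by-cells matrix (base matrix or sparse
#'   [Matrix::Matrix]) with non-negative, finite entries.
#' @return A matrix of the same class and dimnames with entries in `{0,1}`.
#' @examples
#' binarize(matrix(c(0, 3, 1, 0), 2, 2))
#' @export
binarize <- function(counts) {
  .assert(is.matrix(counts) || is(counts, "sparseMatrix"),
          "counts must be a matrix or sparse Matrix")
  if (is(counts, "sparseMatrix")) {
    counts <- as(counts, "CsparseMatrix")
    .assert(all(is.finite(counts@x)) && all(counts@x >= 0),
            "counts must be finite and non-negative")
    counts@x <- as.numeric(counts@x > 0)
    return(Matrix::drop0(counts))
  }
  .assert(all(is.finite(counts)) && all(counts >= 0),
          "counts must be finite and non-negative")
  out <- (counts > 0) + 0L
  dimnames(out) <- dimnames(counts)
  out
}

#' Chance-centered Jaccard similarity of two binary vectors
#'
#' The Jaccard index `J = |x & y| / |x | y|` of two presence/absence
#' profiles is inflated for dense cells and deflated for sparse ones.
#' Centering by the expectation of `J` under independence of the two
#' vectors given their densities `p1 = sum(x)/n`, `p2 = sum(y)/n`,
#' `E = p1 p2 / (p1 + p2 - p1 p2)`, yields a similarity that is 0 for
#' chance-level overlap regardless of sparsity.  When both vectors are
#' empty, `J`, `E` and the centered value are defined as 0 (an empty cell
#' carries no signal) and a warning is raised.
#'
#' @param x,y Binary (0/1) vectors of equal positive length.
#' @return List with elements `jaccard`, `expected` and
#'   `centered = jaccard - expected`.
#' @examples
#' centered_jaccard_pair(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
centered_jaccard_pair <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  .assert(n >= 1L, "vectors must be non-empty")
  .assert(all(x %in% c(0, 1)) && all(y %in% c(0, 1)), "x and y must be binary")
  s1 <- sum(x)
  s2 <- sum(y)
  if (s1 + s2 == 0) {
    warning("both vectors empty; similarity defined as 0")
    return(list(jaccard = 0, expected = 0, centered = 0))
  }
  a <- sum(x * y)
  J <- a / (s1 + s2 - a)
  p1 <- s1 / n
  p2 <- s2 / n
  E <- (p1 * p2) / (p1 + p2 - p1 * p2)
  list(jaccard = J, expected = E, centered = J - E)
}

# Dense k x k matrix of centered Jaccard similarities for one cell group.
# mg: features x cells indicator (base or sparse).  Vectorized through one
# crossproduct; the diagonal is meaningless and ignored by callers.
.pairwise_centered <- function(mg) {
  n <- nrow(mg)
  S <- as.matrix(Matrix::crossprod(mg))
  s <- Matrix::colSums(mg)
  dj <- outer(s, s, "+") - S
  J <- ifelse(dj > 0, S / dj, 0)
  p <- s / n
  P <- outer(p, p)
  de <- outer(p, p, "+") - P
  E <- ifelse(de > 0, P / de, 0)
  list(centered = J - E, counts = s)
}

# Pairwise-complete variant for matrices with missing values (methylation):
# each pair is evaluated on its co-observed features only; pairs with fewer
# than min_obs co-observed features are excluded from the group mean.
.pairwise_centered_na <- function(mg, min_obs = 20L) {
  k <- ncol(mg)
  C <- matrix(NA_real_, k, k)
  obs <- !is.na(mg)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      keep <- obs[, i] & obs[, j]
      if (sum(keep) < min_obs) next
      cj <- suppressWarnings(centered_jaccard_pair(mg[keep, i], mg[keep, j]))
      C[i, j] <- C[j, i] <- cj$centered
    }
  }
  list(centered = C, counts = colSums(mg == 1, na.rm = TRUE))
}

#' Raw heterogeneity score of one cell group
#'
#' Computes the mean of all pairwise chance-centered Jaccard similarities
#' between the cells of a group, together with the mean per-cell number of
#' detected features (the covariate later used for sparsity adjustment).
#' Note the raw value is on the *similarity* scale: homogeneous groups
#' score high, heterogeneous groups low; the inversion to a heterogeneity
#' score happens in [finalize_scores()].
#'
#' @param m Features-by-cells binary matrix with cell ids as colnames.
#' @param cells Character vector of cell ids (or integer column indices)
#'   defining the group; at least 2 cells.
#' @param pairwise_min_obs Minimum co-observed features per pair when `m`
#'   contains missing values (pairwise-complete mode).
#' @return List with `raw` (mean centered similarity), `mean_count`
#'   (mean per-cell 1-count), `n_cells`, and `n_empty_cells`.
#' @export
raw_group_score <- function(m, cells, pairwise_min_obs = 20L) {
  if (is.character(cells)) {
    .check_ids(colnames(m), "cell ids")
    missing <- setdiff(cells, colnames(m))
    .assert(length(missing) == 0L,
            "cells absent from matrix: ", paste(head(missing, 3L), collapse = ", "))
  }
  mg <- m[, cells, drop = FALSE]
  k <- ncol(mg)
  .assert(k >= 2L, "a group needs at least 2 cells to be scored")
  has_na <- anyNA(if (is(mg, "sparseMatrix")) mg@x else mg)
  pc <- if (has_na) .pairwise_centered_na(as.matrix(mg), pairwise_min_obs)
        else .pairwise_centered(mg)
  vals <- pc$centered[upper.tri(pc$centered)]
  vals <- vals[!is.na(vals)]
  .assert(length(vals) >= 1L, "no scorable cell pair in group")
  list(raw = mean(vals),
       mean_count = mean(pc$counts),
       n_cells = k,
       n_empty_cells = sum(pc$counts == 0))
}
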