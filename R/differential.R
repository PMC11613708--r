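#' Permutation test for differential heterogeneity between two cell groups
#'
#' For each region set, the observed difference in heterogeneity between
#' groups A and B is compared with differences between pseudo-groups of
#' the same sizes drawn at random from the pooled cells.  The statistic is
#' computed on adjusted-but-unscaled scores: with exactly two groups the
#' count regression degenerates to mean-centering, so the difference
#' equals the difference of raw mean centered-Jaccard similarities,
#' expressed on the heterogeneity scale
#' (`delta = raw(B) - raw(A)`, positive when A is more heterogeneous).
#' Min-max scaling is deliberately not applied: over two groups it would
#' force the scores to 0 and 1.
#'
#' One shared permutation stream is used for all region sets of a run
#' (paired permutations), and p-values use add-one smoothing:
#' `p = (1 + #(|d_perm| >= |d_obs|)) / (n_perm + 1)`, so `p >= 1/(n_perm+1)`
#' and a zero observed difference gives `p = 1`.  The permutation stream
#' is anchored to the alphabetical order of the two group labels, so
#' swapping A and B flips the sign of `delta` and leaves `p` unchanged.
#'
#' @param m Features-by-cells binary matrix.
#' @param features Feature table aligned with rows of `m`, or `NULL` when
#'   `region_sets` is `NULL`.
#' @param grouping Data frame with columns `cell_id`, `group`.
#' @param group_a,group_b Two distinct group labels, each with >= 2 cells.
#' @param region_sets Named list of region sets; `NULL` scores the whole
#'   matrix as a single `"global"` set.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation stream.
#' @param min_features Minimum overlapping features per region set.
#' @param alternative `"two.sided"` (default, on `|delta|`), `"greater"`
#'   (A more heterogeneous) or `"less"`.
#' @return Data frame with columns `region_set`, `delta`, `p_value`,
#'   `n_features`, `n_perm`.
#' @export
differential_heterogeneity <- function(m, features = NULL, grouping,
                                       group_a, group_b, region_sets = NULL,
                                       n_perm = 1000L, seed = 1L,
                                       min_features = 20L,
                                       alternative = c("two.sided", "greater",
                                                       "less")) {
  alternative <- match.arg(alternative)
  m <- .as_indicator(m)
  .check_ids(colnames(m), "cell ids")
  grouping <- .check_grouping(grouping)
  .assert(group_a != group_b, "group_a and group_b must differ")
  cells_a <- grouping$cell_id[grouping$group == group_a]
  cells_b <- grouping$cell_id[grouping$group == group_b]
  .assert(length(cells_a) >= 2L && length(cells_b) >= 2L,
          "both groups need at least 2 cells")
  .assert(length(intersect(cells_a, cells_b)) == 0L,
          "groups must be disjoint")
  .assert(n_perm >= 1L, "n_perm must be positive")
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value grid")

  if (is.null(region_sets)) {
    idx_list <- list(global = seq_len(nrow(m)))
  } else {
    features <- .check_features(features, nrow(m))
    idx_list <- lapply(region_sets, function(rs) overlap_indices(features, rs))
    idx_list <- idx_list[lengths(idx_list) >= min_features]
    .assert(length(idx_list) >= 1L, "no region set with >= ", min_features,
            " overlapping features")
  }

  # canonical orientation: pseudo-group sizes follow the alphabetical order
  # of the labels so the test is invariant under swapping A and B
  flip <- group_b < group_a
  first <- if (flip) cells_b else cells_a
  second <- if (flip) cells_a else cells_b
  pool <- c(first, second)
  n1 <- length(first)
  n_pool <- length(pool)

  perm_idx <- .with_seed(seed, lapply(seq_len(n_perm), function(i)
    sample.int(n_pool)))

  # mean centered similarity over the unordered cell pairs of a subset,
  # read off a precomputed pool-level similarity matrix
  pair_mean <- function(C, I) {
    k <- length(I)
    (sum(C[I, I]) - sum(diag(C)[I])) / (k * (k - 1))
  }

  out <- lapply(names(idx_list), function(nmset) {
    sub <- m[idx_list[[nmset]], pool, drop = FALSE]
    C <- suppressWarnings(.pairwise_centered(sub))$centered
    i1 <- seq_len(n1)
    i2 <- (n1 + 1L):n_pool
    # heterogeneity-scale difference: second-label group minus first-label
    d_canon <- pair_mean(C, i2) - pair_mean(C, i1)
    d_perm <- vapply(perm_idx, function(px)
      pair_mean(C, px[i2]) - pair_mean(C, px[i1]), numeric(1))
    # d_canon = raw(second) - raw(first); on the heterogeneity scale the
    # required delta is het(A) - het(B) = raw(B) - raw(A)
    delta <- if (flip) -d_canon else d_canon
    p <- switch(alternative,
      two.sided = (1 + sum(abs(d_perm) >= abs(d_canon))) / (n_perm + 1),
      greater = {
        dd <- if (flip) -d_perm else d_perm
        (1 + sum(dd >= delta)) / (n_perm + 1)
      },
      less = {
        dd <- if (flip) -d_perm else d_perm
        (1 + sum(dd <= delta)) / (n_perm + 1)
      })
    data.frame(region_set = nmset, delta = delta, p_value = p,
               n_features = length(idx_list[[nmset]]),
               n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
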