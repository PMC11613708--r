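#' Sparsity adjustment of raw group scores
#'
#' Fits ordinary least squares of the raw mean centered-Jaccard scores
#' against the mean per-cell detected-feature count across all score
#' observations of one run, and returns the residuals as adjusted scores.
#' The regression removes residual coverage effects (sequencing depth,
#' quiescence, genome-wide accessibility shifts) that survive the
#' chance-centering of individual pairs.
#'
#' With fewer than 3 observations the fit is exact and residuals would be
#' identically zero, erasing all signal; the same happens when the
#' covariate is constant.  In both degenerate cases the function falls
#' back to mean-centering (`raw - mean(raw)`), recorded in the
#' `"method"` attribute (`"ols"` or `"centering"`).
#'
#' @param raw Numeric vector of raw scores (one per group/replicate).
#' @param mean_count Numeric vector of mean per-cell 1-counts, same length.
#' @return Numeric vector of adjusted scores (residuals), with attribute
#'   `"method"`.
#' @export
adjust_scores <- function(raw, mean_count) {
  .assert(length(raw) >= 1L, "need at least one observation")
  .assert(length(raw) == length(mean_count), "raw and mean_count lengths differ")
  .assert(all(is.finite(raw)) && all(is.finite(mean_count)),
          "raw and mean_count must be finite")
  degenerate <- length(raw) < 3L ||
    diff(range(mean_count)) <= 1e-10 * max(1, max(abs(mean_count)))
  if (degenerate) {
    out <- raw - mean(raw)
    attr(out, "method") <- "centering"
  } else {
    fit <- lm.fit(cbind(intercept = 1, mean_count = mean_count), raw)
    out <- unname(fit$residuals)
    # snap floating-point dust to zero so exact fits and duplicated
    # observations tie instead of being blown up by the later min-max
    out[abs(out) < 1e-12 * max(1, diff(range(raw)))] <- 0
    attr(out, "method") <- "ols"
  }
  out
}

#' Transform adjusted scores into final 0-1 heterogeneity scores
#'
#' Min-max scales the adjusted (similarity-scale) scores to `[0,1]` and
#' subtracts from 1, so that within one run the most heterogeneous
#' observation scores 1 and the most homogeneous scores 0.  Scores are
#' therefore *relative to the run*; cross-run comparisons should use the
#' `raw`/`adjusted` columns.  If all adjusted scores are equal no ordering
#' exists and every score is set to 0.5 with a warning.
#'
#' @param adjusted Numeric vector of adjusted scores.
#' @return Numeric vector of final scores in `[0,1]`.
#' @examples
#' finalize_scores(c(-0.2, 0, 0.3))  # 1.0, 0.6, 0.0
#' @export
finalize_scores <- function(adjusted) {
  .assert(length(adjusted) >= 1L && all(is.finite(adjusted)),
          "adjusted scores must be finite and non-empty")
  rng <- range(adjusted)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2L]))) {
    warning("all adjusted scores equal; returning 0.5 for every group")
    return(rep(0.5, length(adjusted)))
  }
  1 - (adjusted - rng[1L]) / diff(rng)
}

#' Expand a cell grouping into subsample replicates
#'
#' For robust between-group comparison, scores are computed on several
#' random subsamples of fixed size from each group.  Groups with at least
#' `size` cells yield `n_subsamples` replicates of exactly `size` cells,
#' sampled without replacement within each replicate (independently across
#' replicates); smaller groups are scored once on all their cells.
#' Groups with fewer than 2 cells cannot be scored and are dropped with a
#' warning (names recorded in the `"skipped"` attribute).
#'
#' @param grouping Data frame with columns `cell_id` and `group`.
#' @param n_subsamples Number of replicates per large group (default 5).
#' @param size Subsample size (default 100 cells).
#' @param seed Integer seed; the expansion is a pure function of
#'   `(grouping, n_subsamples, size, seed)`.
#' @return Data frame with columns `cell_id`, `group`, `replicate`.
#' @export
subsample_groups <- function(grouping, n_subsamples = 5L, size = 100L, seed = 1L) {
  grouping <- .check_grouping(grouping)
  .assert(size >= 2L, "subsample size must be at least 2")
  .assert(n_subsamples >= 1L, "n_subsamples must be at least 1")
  groups <- sort(unique(grouping$group))
  skipped <- character()
  pieces <- list()
  .with_seed(seed, {
    for (g in groups) {
      cells <- grouping$cell_id[grouping$group == g]
      if (length(cells) < 2L) {
        skipped <- c(skipped, g)
        next
      }
      if (length(cells) >= size) {
        for (r in seq_len(n_subsamples)) {
          take <- cells[sample.int(length(cells), size)]
          pieces[[length(pieces) + 1L]] <-
            data.frame(cell_id = take, group = g, replicate = r,
                       stringsAsFactors = FALSE)
        }
      } else {
        pieces[[length(pieces) + 1L]] <-
          data.frame(cell_id = cells, group = g, replicate = 1L,
                     stringsAsFactors = FALSE)
      }
    }
  })
  if (length(skipped))
    warning("skipped groups with < 2 cells: ", paste(skipped, collapse = ", "))
  .assert(length(pieces) > 0L, "no group with at least 2 cells")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

.check_grouping <- function(grouping) {
  .assert(is.data.frame(grouping) &&
            all(c("cell_id", "group") %in% names(grouping)),
          "grouping must be a data frame with columns cell_id and group")
  grouping$cell_id <- as.character(grouping$cell_id)
  grouping$group <- as.character(grouping$group)
  .assert(!anyDuplicated(grouping[c("cell_id", "group", "replicate")[
    c(TRUE, TRUE, "replicate" %in% names(grouping))]]),
    "duplicate cell assignments in grouping")
  grouping
}

# Apply the missing-value policy before scoring.  "drop": remove features
# missing in more than na_drop_frac of cells, then treat remaining missing
# entries as 0 (absent).  "pairwise": keep missing values; every pair is
# scored on co-observed features (slow path).
.apply_na_policy <- function(m, na_policy, na_drop_frac) {
  has_na <- anyNA(if (is(m, "sparseMatrix")) m@x else m)
  if (!has_na) return(list(m = .as_indicator(m), dropped = 0L))
  .assert(is.matrix(m), "matrices with missing values must be dense")
  if (na_policy == "drop") {
    keep <- rowMeans(is.na(m)) <= na_drop_frac
    m <- m[keep, , drop = FALSE]
    m[is.na(m)] <- 0
    .assert(nrow(m) > 0L, "all features removed by the missing-value filter")
    list(m = .as_indicator(m), dropped = sum(!keep))
  } else {
    .as_indicator(m, allow_na = TRUE)
    list(m = m, dropped = 0L)
  }
}

#' Compute epiCHAOS heterogeneity scores per group of cells
#'
#' The main entry point of the package.  For every group (optionally
#' expanded into subsample replicates) the mean pairwise chance-centered
#' Jaccard similarity and the mean per-cell detected-feature count are
#' computed; adjusted scores are the residuals of one regression fitted
#' across *all* observations of the run ([adjust_scores()]); final scores
#' min-max invert the adjusted scores into relative 0-1 heterogeneity
#' values ([finalize_scores()]).
#'
#' @param m Features-by-cells binary matrix (use [binarize()] first for
#'   counts).  May contain missing values (dense only) if a missing-value
#'   policy is set.
#' @param grouping Data frame with columns `cell_id`, `group`; a
#'   pre-expanded replicate column is honoured as-is.
#' @param subsample Expand groups into subsample replicates
#'   (default `TRUE`)?
#' @param n_subsamples,subsample_size Replication parameters, see
#'   [subsample_groups()].
#' @param seed Integer seed controlling all randomness of the run.
#' @param adjust Apply the count regression (default `TRUE`).  With
#'   `FALSE` the final scores invert the raw scores directly
#'   ("uncorrected" scores, useful for diagnosing coverage artifacts).
#' @param na_policy `"drop"` (filter features missing in more than
#'   `na_drop_frac` of cells, impute the rest as 0) or `"pairwise"`
#'   (pairwise-complete scoring with at least `pairwise_min_obs`
#'   co-observed features per pair).
#' @param na_drop_frac,pairwise_min_obs Missing-value policy parameters.
#' @return Data frame with one row per (group, replicate):
#'   `group`, `replicate`, `n_cells`, `mean_count`, `raw`, `adjusted`,
#'   `epichaos`, `flags`.  Attributes: `"skipped"` (unscorable groups),
#'   `"adjust_method"`, `"dropped_features"`.
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(600, 1, 0.3), 30, 20,
#'             dimnames = list(NULL, paste0("c", 1:20)))
#' g <- data.frame(cell_id = colnames(m), group = rep(c("a", "b"), each = 10))
#' compute_epichaos(m, g, subsample = FALSE)
#' @export
compute_epichaos <- function(m, grouping, subsample = TRUE, n_subsamples = 5L,
                             subsample_size = 100L, seed = 1L, adjust = TRUE,
                             na_policy = c("drop", "pairwise"),
                             na_drop_frac = 0.05, pairwise_min_obs = 20L) {
  na_policy <- match.arg(na_policy)
  prep <- .apply_na_policy(m, na_policy, na_drop_frac)
  m <- prep$m
  .check_ids(colnames(m), "cell ids")
  grouping <- .check_grouping(grouping)
  missing <- setdiff(grouping$cell_id, colnames(m))
  .assert(length(missing) == 0L, "grouping cells absent from matrix: ",
          paste(head(missing, 3L), collapse = ", "))

  if ("replicate" %in% names(grouping)) {
    reps <- grouping
    skipped <- character()
  } else if (subsample) {
    reps <- subsample_groups(grouping, n_subsamples, subsample_size, seed)
    skipped <- attr(reps, "skipped")
  } else {
    small <- names(which(table(grouping$group) < 2L))
    skipped <- as.character(small)
    if (length(skipped))
      warning("skipped groups with < 2 cells: ", paste(skipped, collapse = ", "))
    reps <- grouping[!grouping$group %in% skipped, , drop = FALSE]
    .assert(nrow(reps) > 0L, "no group with at least 2 cells")
    reps$replicate <- 1L
  }

  key <- paste(reps$group, reps$replicate, sep = "\r")
  units <- split(reps$cell_id, factor(key, levels = unique(key)))
  scores <- lapply(units, function(cells)
    raw_group_score(m, cells, pairwise_min_obs = pairwise_min_obs))

  out <- data.frame(
    group = sub("\r.*$", "", names(units)),
    replicate = as.integer(sub("^.*\r", "", names(units))),
    n_cells = vapply(scores, `[[`, integer(1), "n_cells"),
    mean_count = vapply(scores, `[[`, numeric(1), "mean_count"),
    raw = vapply(scores, `[[`, numeric(1), "raw"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  n_empty <- vapply(scores, `[[`, numeric(1), "n_empty_cells")
  if (any(n_empty > 0))
    warning("empty cells (no detected features) in ",
            sum(n_empty > 0), " scored unit(s)")

  if (adjust) {
    adjusted <- adjust_scores(out$raw, out$mean_count)
    method <- attr(adjusted, "method")
  } else {
    adjusted <- out$raw
    method <- "none"
  }
  out$adjusted <- as.numeric(adjusted)
  out$epichaos <- finalize_scores(out$adjusted)
  full <- vapply(split(grouping$cell_id, grouping$group)[out$group],
                 length, integer(1)) >= subsample_size
  out$flags <- ifelse(n_empty > 0, "empty_cells",
                      ifelse(!subsample | full | "replicate" %in% names(grouping),
                             ".", "all_cells"))
  attr(out, "skipped") <- skipped
  attr(out, "adjust_method") <- method
  attr(out, "dropped_features") <- prep$dropped
  out
}

#' Per-chromosome, copy-number robust heterogeneity scores
#'
#' Whole-chromosome gains or deletions shift both coverage and apparent
#' similarity on the affected chromosome and can leak into a global score.
#' This variant stratifies scoring by chromosome: for every chromosome
#' with at least `min_features` features, raw scores and chromosome-wise
#' mean counts are computed per (group, replicate) and adjusted by a
#' regression fitted *within that chromosome* across all observations;
#' the corrected score of an observation is the mean of its per-chromosome
#' residuals, min-max inverted across the run.
#'
#' @inheritParams compute_epichaos
#' @param features Data frame aligned with the rows of `m`, with at least
#'   a `chrom` column (see [feature_table()]).
#' @param min_features Minimum features for a chromosome to qualify
#'   (default 20).
#' @return Data frame with one row per (group, replicate): `group`,
#'   `replicate`, `n_cells`, `n_chromosomes`, `adjusted` (mean
#'   per-chromosome residual) and `epichaos`.  The per-chromosome residual
#'   matrix is attached as attribute `"per_chromosome"`.
#' @export
per_chromosome_scores <- function(m, features, grouping, min_features = 20L,
                                  subsample = TRUE, n_subsamples = 5L,
                                  subsample_size = 100L, seed = 1L) {
  m <- .as_indicator(m)
  .check_ids(colnames(m), "cell ids")
  features <- .check_features(features, nrow(m))
  grouping <- .check_grouping(grouping)

  chrom_rows <- split(seq_len(nrow(m)), features$chrom)
  chrom_rows <- chrom_rows[lengths(chrom_rows) >= min_features]
  .assert(length(chrom_rows) >= 1L,
          "no chromosome with at least ", min_features, " features")

  if ("replicate" %in% names(grouping)) {
    reps <- grouping
  } else if (subsample) {
    reps <- subsample_groups(grouping, n_subsamples, subsample_size, seed)
  } else {
    small <- names(which(table(grouping$group) < 2L))
    if (length(small))
      warning("skipped groups with < 2 cells: ", paste(small, collapse = ", "))
    reps <- grouping[!grouping$group %in% small, , drop = FALSE]
    .assert(nrow(reps) > 0L, "no group with at least 2 cells")
    reps$replicate <- 1L
  }
  key <- paste(reps$group, reps$replicate, sep = "\r")
  units <- split(reps$cell_id, factor(key, levels = unique(key)))

  resid <- sapply(names(chrom_rows), function(chr) {
    idx <- chrom_rows[[chr]]
    sc <- lapply(units, function(cells)
      suppressWarnings(raw_group_score(m[idx, , drop = FALSE], cells)))
    raw <- vapply(sc, `[[`, numeric(1), "raw")
    cnt <- vapply(sc, `[[`, numeric(1), "mean_count")
    as.numeric(adjust_scores(raw, cnt))
  })
  resid <- matrix(resid, nrow = length(units),
                  dimnames = list(NULL, names(chrom_rows)))

  corrected <- rowMeans(resid)
  out <- data.frame(
    group = sub("\r.*$", "", names(units)),
    replicate = as.integer(sub("^.*\r", "", names(units))),
    n_cells = vapply(units, length, integer(1)),
    n_chromosomes = length(chrom_rows),
    adjusted = corrected,
    epichaos = finalize_scores(corrected),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "per_chromosome") <- resid
  out
}
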