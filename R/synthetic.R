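#' @name synthetic-generators
#' @title Synthetic binary-matrix generators
#' @description
#' Generators for every synthetic input class used to validate the score:
#' a controlled-heterogeneity series with constant total count, add/remove
#' perturbation series, a sparsity ladder, in-silico cell-type mixtures,
#' a sequencing-depth thinning series, copy-number altered groups, and
#' generic flip noise.  All generators are pure functions of their
#' parameters and `seed`.
NULL

.series <- function(matrices, truth, params) {
  structure(list(matrices = matrices, truth = truth, params = params),
            class = "epichaos_series")
}

#' @export
print.epichaos_series <- function(x, ...) {
  cat("epichaos synthetic series:", length(x$matrices), "matrices of",
      nrow(x$matrices[[1]]), "features x", ncol(x$matrices[[1]]), "cells\n")
  invisible(x)
}

#' Combine a list of matrices into one scoring run
#'
#' Column-binds matrices that share a feature space and builds the
#' matching grouping table (one group per matrix, named after the list
#' element), ready for [compute_epichaos()].
#'
#' @param mats Named list of features-by-cells matrices with identical
#'   row counts; a series object's `$matrices` works directly.
#' @return List with `matrix` and `grouping` (`cell_id`, `group`).
#' @export
combine_matrices <- function(mats) {
  if (inherits(mats, "epichaos_series")) mats <- mats$matrices
  .assert(is.list(mats) && length(mats) >= 1L && !is.null(names(mats)),
          "mats must be a named list of matrices")
  nf <- vapply(mats, nrow, integer(1))
  .assert(length(unique(nf)) == 1L, "matrices differ in feature count")
  cells <- unlist(lapply(names(mats), function(g)
    sprintf("%s|c%04d", g, seq_len(ncol(mats[[g]])))), use.names = FALSE)
  combined <- do.call(cbind, unname(mats))
  colnames(combined) <- cells
  rownames(combined) <- rownames(mats[[1]])
  grouping <- data.frame(cell_id = cells,
                         group = rep(names(mats), vapply(mats, ncol, integer(1))),
                         stringsAsFactors = FALSE)
  list(matrix = combined, grouping = grouping)
}

.name_matrix <- function(m, prefix) {
  dimnames(m) <- list(sprintf("f%05d", seq_len(nrow(m))),
                      sprintf("%s_c%04d", prefix, seq_len(ncol(m))))
  m
}

#' Matrix of identical cells (homogeneous base)
#'
#' Every cell carries the same random presence/absence profile: the most
#' homogeneous group possible, used as the base for perturbation
#' experiments.
#'
#' @param n_features,n_cells Matrix dimensions.
#' @param density Fraction of features present in the shared profile.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix.
#' @export
gen_homogeneous_matrix <- function(n_features = 2000L, n_cells = 100L,
                                   density = 0.5, seed = 1L) {
  .assert(density > 0 && density < 1, "density must be in (0,1)")
  .with_seed(seed, {
    profile <- rbinom(n_features, 1L, density)
    m <- matrix(rep(profile, n_cells), n_features, n_cells)
    .name_matrix(m, "base")
  })
}

#' Controlled-heterogeneity series with constant total count
#'
#' Generates `n_steps` matrices of identical dimensions and identical
#' total 1-count.  Matrix 0 is i.i.d. Bernoulli(`density`) — maximal
#' disorder.  Matrix `i` homogenizes `i * rows_per_step` donor rows (all
#' their 1's removed) and `i * rows_per_step` recipient rows (filled to
#' saturation with the displaced 1's); donor/recipient rows are drawn
#' fresh for each step.  Homogenized rows are constant across cells and
#' contribute no cell-to-cell variation, so the true heterogeneity level
#' declines linearly: `truth_i = (n_steps - i) / n_steps`.  If the
#' displaced 1's exceed the recipients' capacity, additional recipient
#' rows are drawn from the untouched rows.
#'
#' @param n_steps Number of matrices in the series (default 100).
#' @param n_features,n_cells Matrix dimensions (defaults 2000 x 100).
#' @param density Bernoulli density of the base matrix (default 0.5).
#' @param rows_per_step Rows homogenized per step and side (default 10);
#'   requires `rows_per_step * n_steps * 2 <= n_features`.
#' @param seed Integer seed.
#' @return `epichaos_series` with `matrices` (named `d000`, `d001`, ...),
#'   `truth`, and `params`.
#' @export
gen_controlled_series <- function(n_steps = 100L, n_features = 2000L,
                                  n_cells = 100L, density = 0.5,
                                  rows_per_step = 10L, seed = 1L) {
  .assert(rows_per_step * n_steps * 2L <= n_features,
          "rows_per_step * n_steps * 2 must not exceed n_features")
  params <- list(generator = "controlled", n_steps = n_steps,
                 n_features = n_features, n_cells = n_cells,
                 density = density, rows_per_step = rows_per_step, seed = seed)
  .with_seed(seed, {
    base <- matrix(rbinom(n_features * n_cells, 1L, density),
                   n_features, n_cells)
    total <- sum(base)
    fill_rows <- function(m, rows, budget) {
      for (r in rows) {
        if (budget <= 0L) break
        zeros <- which(m[r, ] == 0L)
        add <- min(length(zeros), budget)
        if (add > 0L) {
          pick <- if (add == length(zeros)) zeros
                  else zeros[sample.int(length(zeros), add)]
          m[r, pick] <- 1L
          budget <- budget - add
        }
      }
      list(m = m, budget = budget)
    }
    mats <- vector("list", n_steps)
    for (i in 0:(n_steps - 1L)) {
      m <- base
      if (i > 0L) {
        n_rows <- i * rows_per_step
        sel <- sample.int(n_features, 2L * n_rows)
        donors <- sel[seq_len(n_rows)]
        recips <- sel[(n_rows + 1L):(2L * n_rows)]
        budget <- sum(m[donors, ])
        m[donors, ] <- 0L
        res <- fill_rows(m, recips, budget)
        if (res$budget > 0L) {
          extra <- setdiff(seq_len(n_features), sel)
          extra <- if (length(extra) > 1L) extra[sample.int(length(extra))] else extra
          res <- fill_rows(res$m, extra, res$budget)
          .assert(res$budget == 0L, "cannot place displaced 1's: matrix saturated")
        }
        m <- res$m
        .assert(sum(m) == total, "internal error: total count drifted")
      }
      mats[[i + 1L]] <- .name_matrix(m, sprintf("d%03d", i))
    }
    names(mats) <- sprintf("d%03d", 0:(n_steps - 1L))
    .series(mats, truth = (n_steps - 0:(n_steps - 1L)) / n_steps, params)
  })
}

#' Perturbation series: random addition or removal of 1's
#'
#' Starting from a base matrix, a fraction `f` of the 1's is selected at
#' random and set to 0 (`mode = "remove"`), or an equal number of 0's is
#' selected at random and set to 1 (`mode = "add"`).  Either perturbation
#' randomizes previously shared structure, so heterogeneity grows with
#' `f` while the total count moves down (remove) or up (add) — the
#' scenario the count regression must not mistake for heterogeneity.
#'
#' @param base Binary features-by-cells matrix.
#' @param fractions Perturbation fractions in `[0, 1)` (default
#'   `0.1 ... 0.5`); truth equals the fraction.
#' @param mode `"add"` or `"remove"`.
#' @param seed Integer seed.
#' @return `epichaos_series`; matrices named `add10`, `remove30`, ...
#' @export
gen_perturbation_series <- function(base, fractions = seq(0.1, 0.5, by = 0.1),
                                    mode = c("add", "remove"), seed = 1L) {
  mode <- match.arg(mode)
  base <- .as_indicator(base)
  .assert(is.matrix(base), "base must be a dense binary matrix")
  .assert(all(fractions >= 0 & fractions < 1), "fractions must lie in [0,1)")
  .assert(sum(base) > 0, "base matrix has no 1's")
  params <- list(generator = "perturbation", mode = mode,
                 fractions = fractions, seed = seed)
  .with_seed(seed, {
    ones <- which(base == 1L)
    zeros <- which(base == 0L)
    mats <- lapply(fractions, function(f) {
      k <- floor(f * length(ones))
      m <- base
      if (k > 0L) {
        if (mode == "remove") {
          m[ones[sample.int(length(ones), k)]] <- 0L
        } else {
          .assert(k <= length(zeros),
                  "not enough 0 entries to add ", k, " 1's")
          m[zeros[sample.int(length(zeros), k)]] <- 1L
        }
      }
      .name_matrix(m, sprintf("%s%02d", mode, round(100 * f)))
    })
    names(mats) <- sprintf("%s%02d", mode, round(100 * fractions))
    .series(mats, truth = fractions, params)
  })
}

#' Sparsity series: random matrices of increasing density
#'
#' Pure-noise matrices of identical dimensions whose Bernoulli density
#' rises linearly over `density_range`; every matrix is equally (un-)
#' structured, so a sparsity-invariant score should not track the total
#' 1-count across the series.
#'
#' @param n_datasets Number of matrices (default 100).
#' @param n_features,n_cells Dimensions (defaults 2000 x 100).
#' @param density_range Increasing density limits (default 0.05-0.5).
#' @param seed Integer seed.
#' @return `epichaos_series`; `truth` is constant 1 (pure noise).
#' @export
gen_sparsity_series <- function(n_datasets = 100L, n_features = 2000L,
                                n_cells = 100L, density_range = c(0.05, 0.5),
                                seed = 1L) {
  .assert(length(density_range) == 2L && density_range[1] < density_range[2] &&
            density_range[1] > 0 && density_range[2] < 1,
          "density_range must be increasing within (0,1)")
  dens <- seq(density_range[1], density_range[2], length.out = n_datasets)
  params <- list(generator = "sparsity", n_datasets = n_datasets,
                 n_features = n_features, n_cells = n_cells,
                 density_range = density_range, seed = seed)
  .with_seed(seed, {
    mats <- lapply(seq_len(n_datasets), function(i)
      .name_matrix(matrix(rbinom(n_features * n_cells, 1L, dens[i]),
                          n_features, n_cells), sprintf("s%03d", i - 1L)))
    names(mats) <- sprintf("s%03d", seq_len(n_datasets) - 1L)
    .series(mats, truth = rep(1, n_datasets), params)
  })
}

#' In-silico cell-type mixtures
#'
#' Emulates mixing sorted cell types on their most differentially
#' accessible peaks: archetype `t` is Bernoulli(`p_on_marker`) on its own
#' block of `markers_per_type` marker features and Bernoulli(`p_off`)
#' elsewhere.  For every subset of 1..`n_types` types a mixture matrix is
#' built with `cells_per_type` cells split as evenly as possible among
#' the member types.  Heterogeneity should grow with the number of mixed
#' types.
#'
#' @param n_types Number of archetypes (default 5).
#' @param cells_per_type Cells per mixture matrix (default 100).
#' @param markers_per_type Marker features per archetype (default 500).
#' @param p_on_marker,p_off Accessibility probability on own markers
#'   versus elsewhere (defaults 0.6 / 0.05).
#' @param seed Integer seed.
#' @return `epichaos_series` with one matrix per type combination
#'   (names like `T1`, `T2+T4`, ...); `truth` is the number of mixed
#'   types scaled to `[0,1]` (`k / n_types`); `params$k` holds `k` per
#'   matrix.
#' @export
gen_celltype_mixtures <- function(n_types = 5L, cells_per_type = 100L,
                                  markers_per_type = 500L, p_on_marker = 0.6,
                                  p_off = 0.05, seed = 1L) {
  .assert(n_types >= 2L, "need at least 2 cell types")
  n_features <- n_types * markers_per_type
  probs <- matrix(p_off, n_features, n_types)
  for (t in seq_len(n_types))
    probs[(t - 1L) * markers_per_type + seq_len(markers_per_type), t] <- p_on_marker
  combos <- unlist(lapply(seq_len(n_types), function(k)
    combn(n_types, k, simplify = FALSE)), recursive = FALSE)
  nm <- vapply(combos, function(cc) paste0("T", cc, collapse = "+"), character(1))
  params <- list(generator = "mixture", n_types = n_types,
                 cells_per_type = cells_per_type,
                 markers_per_type = markers_per_type,
                 p_on_marker = p_on_marker, p_off = p_off, seed = seed,
                 k = setNames(lengths(combos), nm))
  .with_seed(seed, {
    mats <- lapply(seq_along(combos), function(ci) {
      cc <- combos[[ci]]
      sizes <- diff(round(seq(0, cells_per_type, length.out = length(cc) + 1L)))
      cols <- lapply(seq_along(cc), function(j)
        matrix(rbinom(n_features * sizes[j], 1L, probs[, cc[j]]),
               n_features, sizes[j]))
      .name_matrix(do.call(cbind, cols), nm[ci])
    })
    names(mats) <- nm
    .series(mats, truth = lengths(combos) / n_types, params)
  })
}

#' Synthetic base counts matrix for depth experiments
#'
#' Features-by-cells counts with gamma-distributed peak propensities and
#' uniform per-cell size factors, multinomially allocated to a fixed
#' total — a minimal stand-in for a real scATAC-seq counts matrix.
#'
#' @param n_features,n_cells Dimensions (defaults 2000 x 500).
#' @param total Total count (default 200000).
#' @param seed Integer seed.
#' @return Integer counts matrix.
#' @export
gen_counts_matrix <- function(n_features = 2000L, n_cells = 500L,
                              total = 200000L, seed = 1L) {
  .with_seed(seed, {
    w <- rgamma(n_features, shape = 1)
    u <- runif(n_cells, 0.5, 1.5)
    prob <- as.vector(outer(w, u))
    m <- matrix(as.integer(rmultinom(1L, total, prob)), n_features, n_cells)
    .name_matrix(m, "cnt")
  })
}

#' Sequencing-depth series by exact thinning of a counts matrix
#'
#' For each target depth `D`, exactly `D` of the base matrix's reads are
#' retained (sampling without replacement across all matrix entries —
#' multivariate hypergeometric thinning) and the thinned counts are
#' binarized.  `D` equal to the base total returns the binarized base
#' itself.  This is an internal, documented stand-in for read-level
#' simulators: it reproduces the depth gradient, not read-level realism.
#'
#' @param base_counts Non-negative integer features-by-cells matrix whose
#'   total is at least `max(depths)`.
#' @param depths Target totals (default 50000 to 100000 by 10000).
#' @param seed Integer seed.
#' @return `epichaos_series` of binary matrices named `depth50000`, ...;
#'   `params$depths` holds the depths.
#' @export
gen_depth_series <- function(base_counts,
                             depths = seq(50000L, 100000L, by = 10000L),
                             seed = 1L) {
  .assert(is.matrix(base_counts) && all(base_counts >= 0) &&
            all(.is_wholenumber(base_counts)),
          "base_counts must be a non-negative integer matrix")
  total <- sum(base_counts)
  .assert(all(depths >= 1) && all(depths <= total),
          "each depth must lie in [1, total(base_counts) = ", total, "]")
  nm <- paste0("depth", depths)
  params <- list(generator = "depth", depths = setNames(as.integer(depths), nm),
                 base_total = total, seed = seed)
  reads <- rep(seq_along(base_counts), as.integer(base_counts))
  .with_seed(seed, {
    mats <- lapply(seq_along(depths), function(i) {
      D <- as.integer(depths[i])
      kept <- if (D == total) reads else reads[sample.int(total, D)]
      cnt <- tabulate(kept, nbins = length(base_counts))
      m <- (matrix(cnt, nrow(base_counts), ncol(base_counts)) > 0) + 0L
      .name_matrix(m, nm[i])
    })
    names(mats) <- nm
    .series(mats, truth = rep(1, length(depths)), params)
  })
}

#' Cell groups with a whole-chromosome copy-number alteration
#'
#' Draws `n_groups` groups of cells from one archetype (per-feature
#' accessibility probabilities uniform on `prob_range`); in the last
#' group ("CNA") the features of `target_chrom` are zeroed (`"deletion"`)
#' or their probability is doubled, capped at 1 (`"gain"`).  Features are
#' laid out on `chrom_labels` with `features_per_chrom` features each,
#' with coordinates suitable for [per_chromosome_scores()].
#'
#' @param n_groups Number of groups including the CNA group (default 6).
#' @param cells_per_group Cells per group (default 100).
#' @param chrom_labels Chromosome names (default chr1..chr13).
#' @param features_per_chrom Features per chromosome (default 150).
#' @param prob_range Range of per-feature accessibility probabilities.
#' @param cna_type `"deletion"` or `"gain"`.
#' @param target_chrom Altered chromosome (default last label).
#' @param seed Integer seed.
#' @return List with `matrix`, `features` (feature table), `grouping`
#'   (groups `G1..G<n-1>` and `CNA`), and `params`.
#' @export
gen_cna_groups <- function(n_groups = 6L, cells_per_group = 100L,
                           chrom_labels = paste0("chr", 1:13),
                           features_per_chrom = 150L,
                           prob_range = c(0.1, 0.6),
                           cna_type = c("deletion", "gain"),
                           target_chrom = NULL, seed = 1L) {
  cna_type <- match.arg(cna_type)
  if (is.null(target_chrom)) target_chrom <- chrom_labels[length(chrom_labels)]
  .assert(target_chrom %in% chrom_labels, "target_chrom not in chrom_labels")
  n_features <- length(chrom_labels) * features_per_chrom
  features <- feature_table(
    chrom = rep(chrom_labels, each = features_per_chrom),
    start = rep((seq_len(features_per_chrom) - 1L) * 1000L, length(chrom_labels)),
    end = rep((seq_len(features_per_chrom) - 1L) * 1000L + 500L, length(chrom_labels)))
  groups <- c(paste0("G", seq_len(n_groups - 1L)), "CNA")
  params <- list(generator = "cna", n_groups = n_groups,
                 cells_per_group = cells_per_group, cna_type = cna_type,
                 target_chrom = target_chrom, prob_range = prob_range,
                 seed = seed)
  .with_seed(seed, {
    p <- runif(n_features, prob_range[1], prob_range[2])
    on_target <- features$chrom == target_chrom
    mats <- lapply(groups, function(g) {
      pg <- p
      if (g == "CNA") {
        pg[on_target] <- if (cna_type == "deletion") 0 else pmin(2 * p[on_target], 1)
      }
      matrix(rbinom(n_features * cells_per_group, 1L, pg),
             n_features, cells_per_group)
    })
    names(mats) <- groups
    run <- combine_matrices(mats)
    rownames(run$matrix) <- features$id
    list(matrix = run$matrix, features = features, grouping = run$grouping,
         params = params)
  })
}

#' Flip noise: independent random bit flips
#'
#' Each entry of the base matrix is flipped with probability `rate`,
#' a generic model for symmetric technical noise.  Note that two passes
#' at rate `r` are not equivalent to one pass at `2r` (flips can cancel).
#'
#' @param base Binary matrix.
#' @param rate Flip probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Matrix of the same shape and dimnames.
#' @export
gen_flip_noise <- function(base, rate, seed = 1L) {
  base <- .as_indicator(base)
  .assert(is.matrix(base), "base must be a dense binary matrix")
  .assert(length(rate) == 1L && rate >= 0 && rate < 1, "rate must be in [0,1)")
  .with_seed(seed, {
    flips <- matrix(rbinom(length(base), 1L, rate), nrow(base), ncol(base))
    out <- (base + flips) %% 2L
    dimnames(out) <- dimnames(base)
    out
  })
}
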