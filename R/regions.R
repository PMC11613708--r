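#' Construct a feature coordinate table
#'
#' Genomic coordinates for the rows of a features-by-cells matrix, using
#' the BED convention throughout: 0-based, half-open `[start, end)`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors with `start < end`.
#' @param id Optional feature ids (default `chrom:start-end`).
#' @return Data frame with columns `chrom`, `start`, `end`, `id`.
#' @export
feature_table <- function(chrom, start, end, id = NULL) {
  .assert(length(chrom) == length(start) && length(start) == length(end),
          "chrom, start, end must have equal length")
  .assert(all(.is_wholenumber(start)) && all(.is_wholenumber(end)),
          "start and end must be integers")
  .assert(all(start >= 0) && all(start < end),
          "intervals must satisfy 0 <= start < end")
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), id = as.character(id),
             stringsAsFactors = FALSE)
}

.check_features <- function(features, n_rows) {
  .assert(is.data.frame(features) && "chrom" %in% names(features),
          "features must be a data frame with at least a chrom column")
  .assert(nrow(features) == n_rows,
          "features table (", nrow(features), " rows) does not match matrix (",
          n_rows, " rows)")
  if (all(c("start", "end") %in% names(features)))
    .assert(all(features$start < features$end), "features must have start < end")
  features
}

.check_region_set <- function(rs, name = "region set") {
  .assert(is.data.frame(rs) && all(c("chrom", "start", "end") %in% names(rs)),
          name, " must be a data frame with chrom, start, end")
  .assert(all(rs$start >= 0) && all(rs$start < rs$end),
          name, " has invalid intervals (need 0 <= start < end)")
  rs
}

# GRanges live in 1-based closed coordinates; BED is 0-based half-open,
# so start shifts by +1 and end stays.  With this conversion, abutting
# BED intervals do not overlap and a single shared base pair does.
.to_granges <- function(tab) {
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end))
}

#' Row indices of features overlapping a region set
#'
#' A feature is retained when it shares at least 1 bp with any interval of
#' the region set (half-open BED arithmetic, strand ignored).
#'
#' @param features Feature table with `chrom`, `start`, `end` columns.
#' @param regions Region set: data frame with `chrom`, `start`, `end`.
#' @return Sorted integer vector of feature row indices (possibly empty).
#' @export
overlap_indices <- function(features, regions) {
  .assert(all(c("start", "end") %in% names(features)),
          "features need start/end coordinates for overlap")
  .check_region_set(regions)
  hits <- GenomicRanges::findOverlaps(.to_granges(features),
                                      .to_granges(regions))
  sort(unique(S4Vectors_queryHits(hits)))
}

# thin wrapper so the S4Vectors generic is resolved without Importing the
# whole package namespace
S4Vectors_queryHits <- function(hits) {
  as.integer(as.data.frame(hits)$queryHits)
}

#' Subset a matrix to features overlapping a region set
#'
#' @param m Features-by-cells binary matrix.
#' @param features Feature table aligned with the rows of `m`.
#' @param regions Region set (data frame with `chrom`, `start`, `end`).
#' @return The row-subsetted matrix (cells unchanged); zero overlapping
#'   features yield a 0-row matrix, which callers treat as an
#'   empty-subset signal.
#' @export
overlap_subset <- function(m, features, regions) {
  features <- .check_features(features, nrow(m))
  idx <- overlap_indices(features, regions)
  m[idx, , drop = FALSE]
}

#' Score a collection of region sets within one cell group
#'
#' Subsets the matrix to each region set, computes the raw group score on
#' each qualifying subset (at least `min_features` overlapping features),
#' adjusts across region sets (covariate: mean per-cell 1-count within the
#' subset), min-max inverts, and assigns dense ranks (1 = most
#' heterogeneous).  Region sets below `min_features` are flagged and kept
#' out of scaling and ranking.
#'
#' @param m Features-by-cells binary matrix.
#' @param features Feature table aligned with the rows of `m`.
#' @param cells Cell ids of one group (at least 2).
#' @param region_sets Named list of region sets (data frames with
#'   `chrom`, `start`, `end`), e.g. from [read_regions()] or
#'   [promoters_for_gene_sets()].
#' @param min_features Minimum overlapping features (default 20).
#' @param adjust Apply the across-region-set count regression
#'   (default `TRUE`).
#' @return Data frame with one row per region set: `region_set`,
#'   `n_features`, `mean_count`, `raw`, `adjusted`, `epichaos`, `rank`,
#'   `flags`; ordered by decreasing score then name, flagged sets last.
#' @export
score_region_sets <- function(m, features, cells, region_sets,
                              min_features = 20L, adjust = TRUE) {
  m <- .as_indicator(m)
  features <- .check_features(features, nrow(m))
  .assert(is.list(region_sets) && length(region_sets) >= 1L &&
            !is.null(names(region_sets)) && !anyDuplicated(names(region_sets)),
          "region_sets must be a uniquely named list")
  nm <- names(region_sets)
  idx_list <- lapply(region_sets, function(rs) overlap_indices(features, rs))
  n_feat <- lengths(idx_list)
  ok <- n_feat >= min_features
  .assert(sum(ok) >= 2L, "need at least 2 region sets with >= ",
          min_features, " overlapping features (", sum(ok), " qualify)")

  sc <- lapply(idx_list[ok], function(idx)
    raw_group_score(m[idx, , drop = FALSE], cells))
  raw <- vapply(sc, `[[`, numeric(1), "raw")
  cnt <- vapply(sc, `[[`, numeric(1), "mean_count")
  adjusted <- if (adjust) as.numeric(adjust_scores(raw, cnt)) else raw
  final <- finalize_scores(adjusted)
  # dense ranks over distinct score values (rounded so numerically equal
  # scores tie); row order breaks residual ties by name
  fr <- round(final, 10L)
  rank <- match(fr, sort(unique(fr), decreasing = TRUE))

  scored <- data.frame(region_set = nm[ok], n_features = n_feat[ok],
                       mean_count = cnt, raw = raw, adjusted = adjusted,
                       epichaos = final, rank = rank, flags = ".",
                       stringsAsFactors = FALSE)
  scored <- scored[order(-scored$epichaos, scored$region_set), , drop = FALSE]
  if (any(!ok)) {
    flagged <- data.frame(region_set = nm[!ok], n_features = n_feat[!ok],
                          mean_count = NA_real_, raw = NA_real_,
                          adjusted = NA_real_, epichaos = NA_real_,
                          rank = NA_integer_, flags = "below_min_features",
                          stringsAsFactors = FALSE)
    scored <- rbind(scored, flagged)
  }
  rownames(scored) <- NULL
  scored
}

#' Build promoter region sets from gene sets
#'
#' Maps each gene set to the promoter intervals of its member genes.
#' Genes without a promoter entry are dropped and counted; duplicate
#' genes within a set contribute one interval.
#'
#' @param promoters Data frame with columns `chrom`, `start`, `end`,
#'   `gene` (one interval per gene id).
#' @param gene_sets Named list of character vectors of gene ids, e.g.
#'   from [read_gmt()].
#' @return Named list of region sets (one per gene set, possibly with 0
#'   rows); attribute `"n_missing"` holds the per-set count of genes
#'   without a promoter.
#' @export
promoters_for_gene_sets <- function(promoters, gene_sets) {
  .assert(is.data.frame(promoters) &&
            all(c("chrom", "start", "end", "gene") %in% names(promoters)),
          "promoters must have columns chrom, start, end, gene")
  .assert(!anyDuplicated(promoters$gene), "promoter table has duplicate genes")
  .assert(is.list(gene_sets) && !is.null(names(gene_sets)),
          "gene_sets must be a named list")
  n_missing <- integer(length(gene_sets))
  names(n_missing) <- names(gene_sets)
  out <- lapply(seq_along(gene_sets), function(i) {
    genes <- unique(as.character(gene_sets[[i]]))
    hit <- genes %in% promoters$gene
    n_missing[[i]] <<- sum(!hit)
    rows <- promoters[match(genes[hit], promoters$gene), , drop = FALSE]
    rs <- rows[c("chrom", "start", "end")]
    rownames(rs) <- NULL
    rs
  })
  names(out) <- names(gene_sets)
  total_missing <- sum(n_missing)
  if (total_missing > 0)
    message(total_missing, " gene(s) without promoter entry across ",
            sum(n_missing > 0), " gene set(s)")
  attr(out, "n_missing") <- n_missing
  out
}

#' Rank of one region set across cell groups
#'
#' Extracts the dense rank (1 = most heterogeneous) of a target region
#' set from per-group region score tables, e.g. to ask whether a gene
#' set's promoters are preferentially heterogeneous in stem versus
#' differentiated cells.
#'
#' @param tables Named list of tables from [score_region_sets()], one per
#'   cell group.
#' @param target_set Region set name; must qualify in every table.
#' @return Named integer vector of ranks, one per group.
#' @export
rank_across_celltypes <- function(tables, target_set) {
  .assert(is.list(tables) && !is.null(names(tables)),
          "tables must be a named list of region score tables")
  vapply(names(tables), function(g) {
    tab <- tables[[g]]
    row <- tab[tab$region_set == target_set & tab$flags == ".", , drop = FALSE]
    .assert(nrow(row) == 1L, "target set '", target_set,
            "' missing or flagged in group '", g, "'")
    as.integer(row$rank)
  }, integer(1))
}
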