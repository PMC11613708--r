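#' Per-gene transcriptional noise (coefficient of variation)
#'
#' Companion heterogeneity measure on the transcriptional level: for each
#' gene, the coefficient of variation `CV = sd / mean` across cells
#' (sample standard deviation, `n - 1` denominator).  Genes with zero
#' mean have an undefined CV and are returned as `NA`.
#'
#' @param expr Genes-by-cells non-negative expression matrix with at
#'   least 2 cells.
#' @return Named numeric vector of per-gene CVs.
#' @examples
#' transcriptional_noise_cv(rbind(g1 = c(1, 3), g2 = c(2, 2)))
#' @export
transcriptional_noise_cv <- function(expr) {
  .assert(is.matrix(expr) || is(expr, "sparseMatrix"),
          "expr must be a matrix")
  .assert(ncol(expr) >= 2L, "need at least 2 cells")
  vals <- if (is(expr, "sparseMatrix")) expr@x else expr
  .assert(all(is.finite(vals)) && all(vals >= 0),
          "expr must be finite and non-negative")
  mu <- Matrix::rowMeans(expr)
  n <- ncol(expr)
  # sample sd via E[x^2]; exact and avoids a per-gene apply
  ssd <- sqrt(pmax(Matrix::rowSums((expr - mu)^2), 0) / (n - 1L))
  cv <- ifelse(mu > 0, ssd / mu, NA_real_)
  names(cv) <- rownames(expr)
  cv
}

#' DNA methylation variability aggregated over region sets
#'
#' Computes the per-CpG-site variance of methylation levels across
#' samples and averages it over the sites overlapping each region set —
#' an orthogonal, methylation-based readout of regional epigenetic
#' heterogeneity.  Sparse coverage is handled by a missingness filter:
#' sites whose per-site missing fraction exceeds the `missing_quantile`
#' quantile of the per-site missingness distribution are removed (with
#' fully observed data the filter removes nothing).  Variances use the
#' sample (`n - 1`) convention over the available (non-missing) values.
#'
#' @param meth List as returned by [read_methylation()], or a data frame
#'   with columns `chrom`, `pos` (0-based site position) followed by one
#'   numeric column per sample (values in `[0,1]`, `NA` = missing).
#' @param region_sets Named list of region sets (`chrom`, `start`, `end`;
#'   half-open).  A site overlaps when `start <= pos < end`.
#' @param missing_quantile Quantile of the missingness distribution used
#'   as removal threshold (default 0.005).
#' @param scale01 Min-max scale the returned vector to `[0,1]`
#'   (display convention; default `FALSE`).
#' @return Named numeric vector: mean per-site variance per region set
#'   (`NA` when no surviving site overlaps).
#' @export
methylation_region_variability <- function(meth, region_sets,
                                           missing_quantile = 0.005,
                                           scale01 = FALSE) {
  if (is.list(meth) && !is.data.frame(meth) && all(c("sites", "values") %in% names(meth))) {
    sites <- meth$sites
    values <- meth$values
  } else {
    .assert(is.data.frame(meth) && all(c("chrom", "pos") %in% names(meth)),
            "meth must have chrom and pos columns")
    sites <- meth[c("chrom", "pos")]
    values <- as.matrix(meth[setdiff(names(meth), c("chrom", "pos"))])
  }
  .assert(ncol(values) >= 2L, "need at least 2 samples")
  ok <- is.na(values) | (values >= 0 & values <= 1)
  .assert(all(ok), "methylation values must lie in [0,1] or be missing")
  .assert(is.list(region_sets) && !is.null(names(region_sets)),
          "region_sets must be a named list")

  miss_frac <- rowMeans(is.na(values))
  thr <- quantile(miss_frac, probs = missing_quantile, names = FALSE)
  keep <- miss_frac <= thr
  sites <- sites[keep, , drop = FALSE]
  values <- values[keep, , drop = FALSE]
  n_obs <- rowSums(!is.na(values))
  site_var <- ifelse(n_obs >= 2L,
                     apply(values, 1L, var, na.rm = TRUE), NA_real_)

  site_tab <- data.frame(chrom = sites$chrom, start = sites$pos,
                         end = sites$pos + 1L)
  out <- vapply(region_sets, function(rs) {
    idx <- overlap_indices(site_tab, .check_region_set(rs))
    v <- site_var[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (scale01) {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  }
  out
}
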