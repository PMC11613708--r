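# shared fixtures: tiny matrices with known structure, built in code

# random binary matrix with named dims
rand_bin <- function(n_features, n_cells, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_features * n_cells, 1L, density), n_features, n_cells)
    dimnames(m) <- list(sprintf("f%03d", seq_len(n_features)),
                        sprintf("c%03d", seq_len(n_cells)))
    m
  })
}

one_group <- function(m, label = "g") {
  data.frame(cell_id = colnames(m), group = label, stringsAsFactors = FALSE)
}

# independent oracle: mean pairwise centered Jaccard by explicit enumeration
brute_raw <- function(m, cells) {
  mg <- as.matrix(m)[, cells, drop = FALSE]
  pairs <- combn(ncol(mg), 2)
  vals <- apply(pairs, 2, function(ij)
    suppressWarnings(centered_jaccard_pair(mg[, ij[1]], mg[, ij[2]])$centered))
  list(raw = mean(vals), mean_count = mean(colSums(mg)))
}

# independent oracle: OLS residuals via the normal equations
brute_ols_resid <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# independent oracle: all-pairs half-open interval overlap scan
brute_overlap <- function(features, regions) {
  hit <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(regions))) {
      if (features$chrom[i] == regions$chrom[j] &&
          features$start[i] < regions$end[j] &&
          regions$start[j] < features$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  which(hit)
}
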