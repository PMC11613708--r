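#' @importFrom methods as is
#' @importFrom stats lm.fit quantile rbinom rgamma rmultinom runif sd var cor setNames
#' @importFrom utils write.table head combn packageVersion
NULL

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

.is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Validate a features-by-cells indicator matrix.  Accepts a base matrix or any
# Matrix::sparseMatrix; the input is returned untouched (dense stays dense so
# the 50%-density synthetic benchmarks avoid a pointless sparse blow-up).
.as_indicator <- function(m, allow_na = FALSE, what = "matrix") {
  .assert(is.matrix(m) || is(m, "sparseMatrix"),
          what, " must be a base matrix or a sparse Matrix")
  vals <- if (is(m, "sparseMatrix")) as(m, "CsparseMatrix")@x else as.vector(m)
  if (allow_na) vals <- vals[!is.na(vals)]
  .assert(!anyNA(vals), what, " contains missing values; ",
          "set a missing-value policy to score methylation-style input")
  .assert(all(vals == 0 | vals == 1),
          what, " must be binary (0/1); run binarize() on count matrices")
  m
}

.check_ids <- function(ids, what) {
  .assert(!is.null(ids), what, " must be named (dimnames required)")
  .assert(!anyDuplicated(ids), "duplicate ", what, ": ",
          paste(head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
  invisible(ids)
}

.check_seed <- function(seed) {
  .assert(length(seed) == 1L && .is_wholenumber(seed), "seed must be one integer")
  as.integer(seed)
}

# All exported entry points funnel randomness through here so the global RNG
# state of the caller is never disturbed.
.with_seed <- function(seed, code) {
  withr::with_seed(.check_seed(seed), code)
}

# FNV-1a over the serialized configuration; used to stamp outputs so a run can
# be matched to the exact configuration that produced it (no digest dep).
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, kept exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.format_num <- function(x) {
  ifelse(is.na(x), ".", formatC(x, digits = 6L, format = "g"))
}
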