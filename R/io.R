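#' Parse `chrom:start-end` feature ids into a feature table
#'
#' @param ids Character vector like `"chr1:100-200"` (0-based half-open).
#' @return Feature table (see [feature_table()]).
#' @export
parse_feature_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  .assert(!any(bad), "malformed feature id(s): ",
          paste(head(ids[bad], 3L), collapse = ", "))
  feature_table(chrom = vapply(m, `[`, character(1), 2L),
                start = as.integer(vapply(m, `[`, character(1), 3L)),
                end = as.integer(vapply(m, `[`, character(1), 4L)),
                id = ids)
}

.read_tsv <- function(path, header = TRUE) {
  .assert(file.exists(path), "file not found: ", path)
  as.data.frame(data.table::fread(path, header = header, sep = "\t",
                                  na.strings = c("", "."),
                                  data.table = FALSE, showProgress = FALSE))
}

#' Read a features-by-cells matrix
#'
#' Two layouts are supported: a MatrixMarket triplet (`matrix.mtx` plus a
#' features file and a barcodes file) or a dense TSV with feature ids in
#' the first column and one column per cell.  Feature coordinates are
#' taken from BED-like feature files (`chrom  start  end  [id]`) or
#' parsed from `chrom:start-end` ids; plain ids give `features = NULL`.
#'
#' @param path Path to `.mtx` file or dense TSV.
#' @param features,barcodes Companion files for the MTX layout.
#' @param binarize Binarize counts on read (default `FALSE`)?
#' @return List with `matrix` (dimnames set), `features` (feature table
#'   or `NULL`), `cell_ids`.
#' @export
read_matrix <- function(path, features = NULL, barcodes = NULL,
                        binarize = FALSE) {
  .assert(file.exists(path), "file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    .assert(!is.null(features) && !is.null(barcodes),
            "the MTX layout needs features and barcodes files")
    m <- Matrix::readMM(path)
    # pattern/logical MTX files come back without numeric entries
    if (!is(m, "dMatrix")) m <- as(m, "dMatrix")
    m <- as(m, "CsparseMatrix")
    ftab <- .read_features_file(features, nrow(m))
    bc <- .read_tsv(barcodes, header = FALSE)[[1L]]
    dup <- unique(bc[duplicated(bc)])
    .assert(length(dup) == 0L, "duplicate barcode(s): ",
            paste(head(dup, 3L), collapse = ", "))
    .assert(length(bc) == ncol(m), "barcodes file (", length(bc),
            ") does not match matrix columns (", ncol(m), ")")
    dimnames(m) <- list(if (is.null(ftab)) NULL else ftab$id, bc)
  } else {
    tab <- .read_tsv(path, header = TRUE)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[-1L])
    rownames(m) <- ids
    bc <- colnames(m)
    dup <- unique(bc[duplicated(bc)])
    .assert(length(dup) == 0L, "duplicate barcode(s): ",
            paste(head(dup, 3L), collapse = ", "))
    ftab <- tryCatch(parse_feature_ids(ids), error = function(e) NULL)
  }
  .assert(all(is.finite(if (is(m, "sparseMatrix")) m@x else m)),
          "matrix has non-finite entries")
  if (binarize) m <- binarize(m)
  list(matrix = m, features = ftab, cell_ids = colnames(m))
}

.read_features_file <- function(path, n_rows) {
  tab <- .read_tsv(path, header = FALSE)
  .assert(nrow(tab) == n_rows, "features file (", nrow(tab),
          " rows) does not match matrix (", n_rows, " rows)")
  if (ncol(tab) >= 3L && is.numeric(tab[[2L]]) && is.numeric(tab[[3L]])) {
    id <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else NULL
    feature_table(tab[[1L]], tab[[2L]], tab[[3L]], id = id)
  } else {
    ids <- as.character(tab[[1L]])
    tryCatch(parse_feature_ids(ids), error = function(e) {
      # plain identifiers without coordinates
      data.frame(chrom = NA_character_, start = NA_integer_,
                 end = NA_integer_, id = ids, stringsAsFactors = FALSE)
    })
  }
}

#' Read a cell-to-group assignment table
#'
#' @param path TSV with header columns `cell_id` and `group`.
#' @return Data frame with character `cell_id`, `group`.
#' @export
read_grouping <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("cell_id", "group") %in% names(tab)),
          "grouping file needs columns cell_id and group")
  .check_grouping(tab[c("cell_id", "group")])
}

.read_bed <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  .assert(length(rows) > 0L, "no intervals in BED file: ", path)
  fields <- strsplit(trimws(lines[rows]), "[ \t]+")
  out <- lapply(seq_along(rows), function(i) {
    f <- fields[[i]]
    .assert(length(f) >= 3L, "BED line ", rows[i], " of ", basename(path),
            ": fewer than 3 columns")
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    .assert(!is.na(start) && !is.na(end) && start >= 0 && start < end,
            "BED line ", rows[i], " of ", basename(path),
            ": invalid interval [", f[2L], ", ", f[3L], ")")
    data.frame(chrom = f[1L], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read region sets from BED files
#'
#' Accepts one BED file or a directory of `.bed` files; each file becomes
#' one region set named after the file stem.  Coordinates are 0-based
#' half-open; `track`/`browser`/comment lines are skipped; malformed
#' lines raise an error naming the line.
#'
#' @param path BED file or directory.
#' @return Named list of region sets.
#' @export
read_regions <- function(path) {
  .assert(file.exists(path), "path not found: ", path)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.bed$", full.names = TRUE))
  } else path
  .assert(length(files) > 0L, "no .bed files under ", path)
  out <- lapply(files, .read_bed)
  names(out) <- sub("\\.bed$", "", basename(files))
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  .assert(length(bad) == 0L, "GMT line ", if (length(bad)) bad[1L] else 0L,
          ": fewer than 3 fields")
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[`, character(1), 1L)
  .assert(!anyDuplicated(names(out)), "duplicate gene set names in GMT")
  out
}

#' Read a methylation matrix
#'
#' TSV with header `chrom`, `pos`, then one numeric column per sample;
#' empty fields or `.` denote missing values.
#'
#' @param path TSV file.
#' @return List with `sites` (data frame `chrom`, `pos`) and `values`
#'   (sites-by-samples numeric matrix in `[0,1]` with `NA`s).
#' @export
read_methylation <- function(path) {
  tab <- .read_tsv(path)
  .assert(all(c("chrom", "pos") %in% names(tab)),
          "methylation file needs chrom and pos columns")
  values <- as.matrix(tab[setdiff(names(tab), c("chrom", "pos"))])
  storage.mode(values) <- "double"
  ok <- is.na(values) | (values >= 0 & values <= 1)
  .assert(all(ok), "methylation values must lie in [0,1] or be missing")
  list(sites = tab[c("chrom", "pos")], values = values)
}

#' Write a score table as TSV
#'
#' Tab-separated, UTF-8, header row, floats with 6 significant digits,
#' `.` for missing values.
#'
#' @param tab Data frame (e.g. from [compute_epichaos()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tab, path) {
  out <- tab
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .format_num(out[[j]])
    if (is.character(out[[j]]) || is.factor(out[[j]]))
      out[[j]][is.na(out[[j]])] <- "."
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

.write_metadata <- function(path, params) {
  meta <- list(package = "epichaos",
               version = as.character(packageVersion("epichaos")),
               params = params)
  meta$config_hash <- .config_hash(params)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a matrix with companion files
#'
#' Emits a MatrixMarket triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`) plus optional `grouping.tsv`, `truth.tsv` and a
#' `metadata.json` echoing the generating parameters and their hash.
#'
#' @param m Features-by-cells matrix (dense or sparse).
#' @param dir Output directory (created if needed).
#' @param features Optional feature table written as BED-like columns.
#' @param grouping Optional grouping data frame.
#' @param truth Optional data frame (e.g. `group`, `truth`).
#' @param params Parameter list recorded in the metadata.
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(m, dir, features = NULL, grouping = NULL,
                             truth = NULL, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- if (is(m, "sparseMatrix")) as(m, "CsparseMatrix")
        else Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  if (is.null(features)) {
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("f%05d", seq_len(nrow(m)))
    ftab <- data.frame(id = ids)
  } else {
    ftab <- .check_features(features, nrow(m))[c("chrom", "start", "end", "id")]
  }
  write.table(ftab, file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bc <- colnames(m)
  if (is.null(bc)) bc <- sprintf("c%05d", seq_len(ncol(m)))
  writeLines(bc, file.path(dir, "barcodes.tsv"))
  if (!is.null(grouping))
    write.table(grouping, file.path(dir, "grouping.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  .write_metadata(file.path(dir, "metadata.json"), params)
  invisible(dir)
}
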