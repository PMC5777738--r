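# Reading/writing of count matrices, sample sheets and GMT gene sets.
# Files are UTF-8, tab-separated, LF on write; CRLF is accepted on read.

.read_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Read a gene-by-sample count matrix
#'
#' Expects a tab-separated file whose header row names the samples and whose
#' first column holds gene identifiers (treated as opaque strings). Cells
#' must be non-negative integers; identifiers must be unique. RSEM-style
#' fractional expected counts are rejected unless `fractional = "round"`,
#' which rounds half-to-even and reports how many cells were rounded.
#'
#' @param path file path.
#' @param fractional `"error"` (default) or `"round"`.
#' @return an integer-valued numeric matrix with gene rownames and sample
#'   colnames, in file order.
#' @export
read_counts <- function(path, fractional = c("error", "round")) {
  fractional <- match.arg(fractional)
  lines <- .read_lines(path)
  if (length(lines) < 2L) stopf("count file needs a header and >= 1 gene row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  # the header may or may not carry a label over the gene-id column; pick
  # the reading consistent with more data rows
  row_len <- lengths(cells[-1L])
  labeled <- sum(row_len == length(header))
  unlabeled <- sum(row_len == length(header) + 1L)
  if (labeled == 0L && unlabeled == 0L)
    stopf("row 2 has %d fields, expected %d", row_len[1L],
          length(header))
  samples <- if (unlabeled > labeled) header else header[-1L]
  ncol_data <- length(samples)
  if (anyDuplicated(samples))
    stopf("duplicate sample id: %s",
          samples[duplicated(samples)][1L])
  n <- length(lines) - 1L
  genes <- character(n)
  mat <- matrix(NA_real_, n, ncol_data)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != ncol_data + 1L)
      stopf("row %d has %d fields, expected %d", i + 1L, length(row),
            ncol_data + 1L)
    genes[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stopf("non-numeric value '%s' at row %d (gene '%s'), column %d (sample '%s')",
            row[j + 1L], i + 1L, genes[i], j, samples[j])
    }
    mat[i, ] <- v
  }
  if (anyDuplicated(genes))
    stopf("duplicate gene id: %s", genes[duplicated(genes)][1L])
  bad <- which(mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("negative count at gene '%s', sample '%s'",
          genes[bad[1L, 1L]], samples[bad[1L, 2L]])
  frac <- which(mat != round(mat), arr.ind = TRUE)
  if (nrow(frac) > 0L) {
    if (fractional == "error")
      stopf("non-integer count %g at gene '%s', sample '%s' (use fractional = \"round\" for expected counts)",
            mat[frac[1L, , drop = FALSE]], genes[frac[1L, 1L]],
            samples[frac[1L, 2L]])
    mat <- round(mat)  # round() is half-to-even
    message(sprintf("read_counts: rounded %d fractional cells half-to-even",
                    nrow(frac)))
  }
  dimnames(mat) <- list(genes, samples)
  mat
}

#' Write a count matrix as tab-separated text
#'
#' @param counts matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param id_column header label for the gene-id column.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path, id_column = "gene_id") {
  validate_counts(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate an in-memory count matrix
#'
#' @param counts candidate matrix.
#' @return invisibly, `counts`.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene id: %s",
          rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1L])
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts contain negative values")
  if (any(counts != round(counts))) stopf("counts contain non-integer values")
  invisible(counts)
}

#' Read a count matrix from an MTX triplet
#'
#' MatrixMarket sparse matrix plus one-id-per-line row (gene) and column
#' (sample) files, as written by common quantification tools.
#'
#' @param mtx_path MatrixMarket file.
#' @param genes_path,samples_path plain-text id files.
#' @return a dense validated count matrix.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- .read_lines(genes_path)
  samples <- .read_lines(samples_path)
  if (nrow(m) != length(genes))
    stopf("matrix has %d rows but %d gene ids", nrow(m), length(genes))
  if (ncol(m) != length(samples))
    stopf("matrix has %d columns but %d sample ids", ncol(m), length(samples))
  dimnames(m) <- list(genes, samples)
  validate_counts(m)
  m
}

.POOLS <- c("T", "P")

#' Read a sample sheet
#'
#' Tab-separated with required columns `sample_id`, `cell_line`, `treatment`,
#' `pool` (one of `T` = total, `P` = polysomal) and `replicate`.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
read_design <- function(path) {
  lines <- .read_lines(path)
  if (length(lines) < 2L) stopf("design file needs a header and >= 1 sample")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  need <- c("sample_id", "cell_line", "treatment", "pool", "replicate")
  miss <- setdiff(need, header)
  if (length(miss) > 0L)
    stopf("design is missing required column(s): %s",
          paste(miss, collapse = ", "))
  idx <- match(need, header)
  rows <- lapply(seq_along(cells)[-1L], function(i) {
    row <- cells[[i]]
    if (length(row) != length(header))
      stopf("design row %d has %d fields, expected %d", i, length(row),
            length(header))
    row[idx]
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- need
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  validate_design(df)
}

#' Validate an in-memory sample sheet
#'
#' @param design data.frame with the [read_design()] columns.
#' @return invisibly, `design` with `replicate` as integer.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "cell_line", "treatment", "pool", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0L)
    stopf("design is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stopf("duplicate sample_id: %s",
          design$sample_id[duplicated(design$sample_id)][1L])
  bad <- setdiff(unique(design$pool), .POOLS)
  if (length(bad) > 0L)
    stopf("unknown pool value '%s'; allowed values are {T, P}", bad[1L])
  if (anyNA(design$replicate)) stopf("non-integer replicate index in design")
  key <- do.call(paste, c(design[c("cell_line", "treatment", "pool",
                                   "replicate")], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- design[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate (cell_line, treatment, pool, replicate) tuple: (%s, %s, %s, %d)",
          d$cell_line, d$treatment, d$pool, d$replicate)
  }
  invisible(design)
}

#' Write a sample sheet
#' @param design validated design data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

# Pair a count matrix with a design, enforcing exact sample agreement.
match_design <- function(counts, design) {
  validate_design(design)
  if (!setequal(colnames(counts), design$sample_id) ||
      ncol(counts) != nrow(design))
    stopf("design sample_ids do not match count matrix columns")
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#' Members are de-duplicated per set; set names must be unique. An empty file
#' yields an empty collection.
#'
#' @param path GMT file path.
#' @return a named list of character vectors of class
#'   `"gene_set_collection"`, with a `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT line %d has %d field(s); need name, description, >= 1 member",
            i, length(f))
    nm <- f[1L]
    if (nm %in% names(sets)) stopf("GMT line %d: duplicate set name '%s'",
                                   i, nm)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stopf("GMT line %d: set '%s' has no members", i, nm)
    sets[[nm]] <- members
    desc[nm] <- f[2L]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors (optionally with a
#'   `"descriptions"` attribute).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[nm] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
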