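#' Expression matrix container
#'
#' An `ExpressionMatrix` is a plain numeric matrix (genes in rows, chips /
#' hybridizations in columns) carrying unique gene and sample identifiers in
#' its dimnames.  Values are assumed already normalized (e.g. RMA);
#' normalization itself is out of scope.  Validation enforces the container
#' invariants relied on by every downstream stage: unique identifiers, at
#' least 2 genes and 3 samples, and no missing or non-finite entries (the
#' rank/MI machinery assumes complete rows).
#'
#' @param values Numeric matrix, genes x samples.
#' @param gene_ids Character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param sample_ids Character vector of unique chip names
#'   (default: `colnames(values)`).
#' @return A validated `ExpressionMatrix`.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("c", 1:4))))
#' n_genes(x); n_samples(x)
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    data_error("`values` must be a numeric matrix (genes x samples)")
  if (is.null(gene_ids) || is.null(sample_ids))
    data_error("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    data_error("identifier lengths do not match matrix dimensions")
  if (nrow(values) < 2L)
    data_error("an ExpressionMatrix needs at least 2 genes")
  if (ncol(values) < 3L)
    data_error("an ExpressionMatrix needs at least 3 samples (chips)")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    data_error(sprintf("duplicate gene identifier(s): %s",
                       paste(unique(dup), collapse = ", ")))
  dups <- sample_ids[duplicated(sample_ids)]
  if (length(dups))
    data_error(sprintf("duplicate sample name(s): %s",
                       paste(unique(dups), collapse = ", ")))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    data_error(sprintf(
      "non-finite expression value at gene '%s', sample '%s'",
      gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
n_genes <- function(x) nrow(x)

#' @rdname expression_matrix
#' @export
n_samples <- function(x) ncol(x)

#' @rdname expression_matrix
#' @export
gene_ids <- function(x) rownames(x)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  genes:   %s%s\n", paste(utils::head(rownames(x), 4L),
                                         collapse = ", "),
              if (nrow(x) > 4L) ", ..." else ""))
  cat(sprintf("  samples: %s%s\n", paste(utils::head(colnames(x), 4L),
                                         collapse = ", "),
              if (ncol(x) > 4L) ", ..." else ""))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Parses the standard exchange format: first row is a header whose first
#' cell is an ignored label and remaining cells are chip names; every
#' subsequent row is a gene identifier followed by one numeric value per
#' chip.  UTF-8, Unix or Windows line endings; a `.gz` path is
#' transparently decompressed.  Parsing is locale-independent (decimal
#' point only).  Malformed rows fail with the offending line number, and
#' non-numeric cells fail with their coordinates; missing values are
#' rejected at load.
#'
#' @param path Path to a tab-delimited text file (optionally gzipped).
#' @return A validated [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    data_error(sprintf("input file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    parse_error(sprintf("%s: need a header line and at least one gene row",
                        path))
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    parse_error(sprintf("%s: header has no sample columns", path))
  samples <- header[-1L]
  m <- length(samples)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(body)
  bad <- which(nf != m + 1L)
  if (length(bad))
    parse_error(sprintf(
      "%s: line %d has %d fields, expected %d (gene id + %d values)",
      path, bad[1L] + 1L, nf[bad[1L]], m + 1L, m))
  ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(body), m)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    nb <- which(is.na(v) | !is.finite(v))
    if (length(nb))
      parse_error(sprintf(
        "%s: non-numeric or non-finite value '%s' at line %d, column '%s'",
        path, body[[i]][nb[1L] + 1L], i + 1L, samples[nb[1L]]))
    vals[i, ] <- v
  }
  expression_matrix(vals, ids, samples)
}

#' Write an expression matrix in the tab-delimited exchange format
#'
#' Inverse of [read_expression()] up to floating-point formatting (values
#' are written with 15 significant digits, so a round trip preserves at
#' least 12).  Identifiers containing tabs or newlines are rejected before
#' anything is written.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param path Output path; `"\n"` line endings, tab separated.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  ids <- c(rownames(matrix), colnames(matrix))
  if (any(grepl("[\t\n\r]", ids)))
    data_error("identifiers must not contain tab or newline characters")
  con <- tryCatch(file(path, "wb"), error = function(e)
    data_error(sprintf("cannot open '%s' for writing: %s", path,
                       conditionMessage(e))))
  on.exit(close(con))
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  out <- c(paste(c("id", colnames(matrix)), collapse = "\t"),
           vapply(seq_len(nrow(matrix)), function(i)
             paste(c(rownames(matrix)[i], fmt(matrix[i, ])), collapse = "\t"),
             ""))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
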