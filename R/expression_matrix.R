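#' Expression matrix container
#'
#' A light container for a genes x samples expression matrix carrying the
#' data modality (bulk or single-cell) and the normalization state. The
#' value matrix always has genes in rows and samples (or cell barcodes) in
#' columns, with identifiers as dimnames.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). All values must
#'   be finite and non-negative.
#' @param modality Either `"bulk"` or `"single_cell"`.
#' @param transform_state One of `"raw"`, `"per_million"`, `"log"`.
#'   Transitions are one-way raw -> per_million -> log.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, modality = c("bulk", "single_cell"),
                              transform_state = c("raw", "per_million", "log")) {
  modality <- match.arg(modality)
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicated gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (any(values < 0))
    stop("expression values must be non-negative")
  structure(
    list(values = values, modality = modality, transform_state = transform_state),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [%s, %s], zero fraction %.3f\n",
    nrow(x$values), ncol(x$values), x$modality, x$transform_state,
    mean(x$values == 0)
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of sample / cell ids.
#' @export
sample_ids <- function(x) colnames(x$values)

.infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a dense expression matrix
#'
#' Reads a delimited text file (TSV or CSV, decided by extension) with one
#' header row of identifiers and one leading identifier column, and returns
#' it as an [expression_matrix()] in genes x samples layout.
#'
#' @param path Path to the delimited file.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`;
#'   the output is always genes x samples.
#' @param modality `"bulk"` or `"single_cell"`.
#' @return An `ExpressionMatrix` with `transform_state = "raw"`.
#' @export
read_dense_matrix <- function(path, orientation = c("genes_in_rows", "genes_in_columns"),
                              modality = c("bulk", "single_cell")) {
  orientation <- match.arg(orientation)
  modality <- match.arg(modality)
  sep <- .infer_sep(path)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected at least one identifier column and one value column")
  row_ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = list(row_ids, colnames(body))))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d ('%s'), column %d ('%s')",
                 body[bad[1, 1], bad[1, 2]], bad[1, 1], row_ids[bad[1, 1]],
                 bad[1, 2], colnames(body)[bad[1, 2]]))
  }
  if (anyNA(num)) stop("missing values are not allowed in an expression matrix")
  if (orientation == "genes_in_columns") num <- t(num)
  em <- expression_matrix(num, modality = modality, transform_state = "raw")
  message(sprintf("read %d genes x %d samples from %s (zero fraction %.3f)",
                  nrow(num), ncol(num), basename(path), mean(num == 0)))
  em
}

#' Write a dense expression matrix
#'
#' Inverse of [read_dense_matrix()]: writes the value matrix as TSV with a
#' `gene_id` header column. Values are written at full precision so a
#' write/read round trip reproduces them exactly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dense_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse triplet (MatrixMarket) single-cell matrix
#'
#' Reads the common single-cell exchange convention: a MatrixMarket
#' coordinate file (1-based indices) with two one-column sidecar files
#' listing gene ids (rows) and cell barcodes (columns). Missing entries
#' are zeros.
#'
#' @param matrix_path MatrixMarket `.mtx` coordinate file.
#' @param genes_path One gene id per line, length = declared row count.
#' @param barcodes_path One barcode per line, length = declared column count.
#' @return An `ExpressionMatrix` with `modality = "single_cell"`.
#' @export
read_sparse_triplet <- function(matrix_path, genes_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("failed to read sparse matrix: ",
                                         conditionMessage(e)))
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (length(genes) != nrow(m))
    stop(sprintf("gene sidecar has %d entries but matrix declares %d rows",
                 length(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcode sidecar has %d entries but matrix declares %d columns",
                 length(barcodes), ncol(m)))
  dense <- as.matrix(m)
  dimnames(dense) <- list(genes, barcodes)
  em <- expression_matrix(dense, modality = "single_cell", transform_state = "raw")
  message(sprintf("read %d genes x %d cells from %s (zero fraction %.3f)",
                  nrow(dense), ncol(dense), basename(matrix_path), mean(dense == 0)))
  em
}

#' Write a sparse triplet (MatrixMarket) single-cell matrix
#'
#' @param x An `ExpressionMatrix`.
#' @param matrix_path,genes_path,barcodes_path Output paths for the
#'   coordinate file and the two sidecars.
#' @return `matrix_path`, invisibly.
#' @export
write_sparse_triplet <- function(x, matrix_path, genes_path, barcodes_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  sm <- Matrix::Matrix(x$values, sparse = TRUE)
  Matrix::writeMM(sm, matrix_path)
  writeLines(rownames(x$values), genes_path)
  writeLines(colnames(x$values), barcodes_path)
  invisible(matrix_path)
}

#' Per-million normalization (TPM / CPM)
#'
#' With gene lengths, computes transcripts per million:
#' `1e6 * (c/l) / sum(c/l)` per sample. Without lengths, computes counts
#' per million, appropriate for UMI data. Every non-zero sample column
#' sums to 1e6 afterwards; all-zero columns are left at zero with a
#' warning.
#'
#' @param x An `ExpressionMatrix` in `raw` state.
#' @param gene_lengths Optional named numeric vector of positive lengths
#'   covering every gene in `x`.
#' @return An `ExpressionMatrix` with `transform_state = "per_million"`.
#' @export
normalize_per_million <- function(x, gene_lengths = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$transform_state != "raw")
    stop("normalize_per_million requires transform_state 'raw', got '",
         x$transform_state, "'")
  v <- x$values
  if (!is.null(gene_lengths)) {
    missing <- setdiff(rownames(v), names(gene_lengths))
    if (length(missing))
      stop("gene length missing for: ", paste(utils::head(missing, 5), collapse = ", "))
    len <- gene_lengths[rownames(v)]
    if (any(len <= 0) || anyNA(len)) stop("gene lengths must be positive")
    v <- v / len
  }
  totals <- colSums(v)
  zero_cols <- totals == 0
  if (any(zero_cols)) {
    warning(sum(zero_cols), " all-zero sample column(s) left at zero")
    totals[zero_cols] <- 1 # keep 0/1 = 0
  }
  v <- sweep(v, 2, totals, "/") * 1e6
  out <- x
  out$values <- v
  out$transform_state <- "per_million"
  out
}

#' Log-transform expression values
#'
#' Applies `log_base(value + pseudocount)` entrywise. The default base-10
#' log with pseudocount 1 maps zeros to zero and compresses the heavy
#' right tail typical of TPM and UMI-count data.
#'
#' @param x An `ExpressionMatrix` in `raw` or `per_million` state.
#' @param base Logarithm base, > 1.
#' @param pseudocount Non-negative offset; must be positive if any value
#'   is zero.
#' @return An `ExpressionMatrix` with `transform_state = "log"`.
#' @export
log_transform <- function(x, base = 10, pseudocount = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!x$transform_state %in% c("raw", "per_million"))
    stop("log_transform requires transform_state 'raw' or 'per_million'")
  if (base <= 1) stop("'base' must be > 1")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  if (pseudocount == 0 && any(x$values == 0))
    stop("pseudocount 0 with zero values would produce -Inf")
  out <- x
  out$values <- log(x$values + pseudocount, base = base)
  out$transform_state <- "log"
  out
}

#' Restrict paired matrices to a shared gene universe
#'
#' Intersects the gene sets of a bulk and a single-cell matrix, drops
#' genes with no expression in either modality (a silent gene yields an
#' uninformative joint histogram and no usable prediction), and returns
#' both matrices with identically ordered rows.
#'
#' @param bulk,sc `ExpressionMatrix` objects.
#' @return A list with elements `bulk`, `sc` and `shared_genes`.
#' @export
align_gene_universe <- function(bulk, sc) {
  stopifnot(inherits(bulk, "ExpressionMatrix"), inherits(sc, "ExpressionMatrix"))
  shared <- intersect(gene_ids(bulk), gene_ids(sc))
  if (!length(shared)) stop("bulk and single-cell matrices share no gene ids")
  bv <- bulk$values[shared, , drop = FALSE]
  sv <- sc$values[shared, , drop = FALSE]
  keep <- rowSums(bv) > 0 & rowSums(sv) > 0
  shared <- shared[keep]
  if (!length(shared))
    stop("no shared gene has non-zero expression in both modalities")
  out_bulk <- bulk
  out_bulk$values <- bv[shared, , drop = FALSE]
  out_sc <- sc
  out_sc$values <- sv[shared, , drop = FALSE]
  list(bulk = out_bulk, sc = out_sc, shared_genes = shared)
}
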