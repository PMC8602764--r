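#' Read a genes-by-cells expression matrix
#'
#' Reads a nonnegative expression matrix (counts, FPKM, TPM, ...) from either
#' a dense delimited file (genes as rows, cells as columns, header row of cell
#' ids, first column of gene ids) or a Matrix Market `.mtx` file with sidecar
#' `genes.txt` / `cells.txt` files (one identifier per line) next to it.
#'
#' @param path Path to the file (`.csv`/`.tsv`/`.txt` for dense, `.mtx` for
#'   Matrix Market).
#' @param format One of `"auto"`, `"dense"`, `"mtx"`. With `"auto"` the format
#'   is inferred from the file extension.
#' @param transpose If `TRUE`, a dense file is read as cells-by-genes and
#'   transposed. Ignored for Matrix Market input.
#' @param sep Field separator for dense input; inferred from the extension
#'   when `NULL` (`,` for `.csv`, tab otherwise).
#' @return A numeric matrix with genes as rows and cells as columns; `rownames`
#'   carry gene identifiers and `colnames` cell identifiers.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(matrix(0:5, 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2"))), tf)
#' X <- read_expression(tf)
#' dim(X)
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"),
                            transpose = FALSE, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt")
    cf <- file.path(dir, "cells.txt")
    rownames(m) <- if (file.exists(gf)) readLines(gf) else paste0("gene", seq_len(nrow(m)))
    colnames(m) <- if (file.exists(cf)) readLines(cf) else paste0("cell", seq_len(ncol(m)))
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error reading ", path, ": ", conditionMessage(e))
    )
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      num <- suppressWarnings(matrix(as.numeric(m), nrow(m)))
      bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
      stop("parse error: non-numeric entry near line ",
           if (nrow(bad)) bad[1, 1] + 1 else "?", " of ", path)
    }
    if (transpose) m <- t(m)
  }
  validate_expression(m)
  m
}

#' Validate an expression matrix
#'
#' Checks the invariants assumed throughout the package: a numeric matrix with
#' finite nonnegative entries and unique gene/cell identifiers.
#'
#' @param X Numeric matrix, genes in rows and cells in columns.
#' @return `X`, invisibly, after validation.
#' @export
validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("expression data must be a numeric matrix")
  if (anyNA(X) || any(!is.finite(X))) stop("expression matrix contains NA or non-finite entries")
  if (any(X < 0)) {
    ij <- which(X < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at gene row ", ij[1], ", cell column ", ij[2])
  }
  if (!is.null(rownames(X)) && anyDuplicated(rownames(X)))
    stop("duplicate gene ids: ", paste(utils::head(unique(
      rownames(X)[duplicated(rownames(X))]), 3), collapse = ", "))
  if (!is.null(colnames(X)) && anyDuplicated(colnames(X)))
    stop("duplicate cell ids")
  invisible(X)
}

#' Remove genes with zero expression in all cells
#'
#' Drops every gene whose expression is zero across all cells; gene order is
#' otherwise preserved.
#'
#' @param X Numeric genes-by-cells matrix.
#' @return The filtered matrix.
#' @export
filter_zero_genes <- function(X) {
  validate_expression(X)
  keep <- rowSums(X != 0) > 0
  if (!any(keep)) stop("empty matrix after filtering: all genes are zero")
  X[keep, , drop = FALSE]
}

#' L2-normalize each cell
#'
#' Scales every cell (column) to unit Euclidean norm, removing per-cell
#' expression-scale differences so that inner products between cells are
#' cosine similarities.
#'
#' @param X Numeric genes-by-cells matrix; every column must have a nonzero
#'   entry.
#' @return Matrix with unit-norm columns.
#' @export
l2_normalize_cells <- function(X) {
  validate_expression(X)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop("cell ", nm, " has zero total expression; cannot L2-normalize")
  }
  sweep(X, 2, nrm, "/")
}

#' Read a label vector aligned to cells
#'
#' Reads cluster or cell-type labels from a delimited text file: either a
#' single column, or a table with a column named `cluster`, `label`, or
#' `group` (as written by [write_pipeline_result()]). A header line is
#' detected automatically when `header = NA`: if every field of the first
#' line parses as a number the file is taken to be headerless.
#'
#' @param path Path to the file.
#' @param header Logical, or `NA` to auto-detect.
#' @return Integer vector of labels.
#' @export
read_labels <- function(path, header = NA) {
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1), ",")[[1]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.csv(path, header = header)
  pick <- intersect(c("cluster", "label", "group"), names(df))
  v <- if (length(pick)) df[[pick[1]]] else df[[ncol(df)]]
  as_label_vector(v)
}

#' Coerce to an integer label vector
#'
#' @param labels Vector of group assignments (factor, character, or numeric).
#' @return Integer codes starting at 1 (order of first appearance for
#'   character input, factor level order for factors).
#' @export
as_label_vector <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels))
  if (is.character(labels)) return(match(labels, unique(labels)))
  if (!all(labels == round(labels))) stop("labels must be integer-valued")
  as.integer(labels)
}

#' Write an expression matrix as Matrix Market plus sidecar id files
#'
#' @param X Genes-by-cells matrix.
#' @param dir Output directory (created if absent). Writes `matrix.mtx`,
#'   `genes.txt`, `cells.txt`.
#' @return The directory path, invisibly.
#' @export
write_expression_mtx <- function(X, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE, doDiag = FALSE),
                  file.path(dir, "matrix.mtx"))
  writeLines(if (is.null(rownames(X))) paste0("gene", seq_len(nrow(X))) else rownames(X),
             file.path(dir, "genes.txt"))
  writeLines(if (is.null(colnames(X))) paste0("cell", seq_len(ncol(X))) else colnames(X),
             file.path(dir, "cells.txt"))
  invisible(dir)
}
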