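#' Construct a count matrix container
#'
#' Raw integer gene x cell counts plus gene/cell identifiers and a per-gene
#' ERCC spike-in flag. The entry point of the pipeline.
#'
#' @param values gene x cell matrix of nonnegative integer counts (dense or
#'   \code{Matrix} sparse).
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param is_spikein logical per-gene flag; defaults to the \code{"ERCC-"}
#'   id-prefix rule.
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{values} (a \code{dgCMatrix}), \code{gene_ids}, \code{cell_ids},
#'   \code{is_spikein}.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values),
                         is_spikein = startsWith(gene_ids, "ERCC-")) {
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("count_matrix: gene_ids and cell_ids are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop("count_matrix: duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("count_matrix: duplicate cell ids")
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(cell_ids))
    stop("count_matrix: dimension mismatch between values and ids")
  v <- values@x
  if (any(v < 0) || any(v != round(v)))
    stop("count_matrix: counts must be nonnegative integers")
  stopifnot(length(is_spikein) == length(gene_ids))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 is_spikein = as.logical(is_spikein)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d spike-ins) x %d cells\n",
              length(x$gene_ids), sum(x$is_spikein), length(x$cell_ids)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a count matrix from disk
#'
#' Reads either a MatrixMarket sparse triplet directory (\code{matrix.mtx} +
#' \code{genes.tsv} + \code{cells.tsv}, one id per line) or a single delimited
#' text file with gene rows and cell columns. Genes whose id starts with
#' \code{"ERCC-"} are flagged as spike-ins.
#'
#' @param path directory (sparse format) or file (delimited format).
#' @param format \code{"mtx"} or \code{"delim"}.
#' @param sep field separator for delimited input.
#' @return A \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path, format = c("mtx", "delim"), sep = "\t") {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    cf <- file.path(path, "cells.tsv")
    if (!all(file.exists(c(mtx, gf, cf))))
      stop("read_count_matrix: expected matrix.mtx, genes.tsv, cells.tsv in ", path)
    m <- Matrix::readMM(mtx)
    genes <- readLines(gf)
    cells <- readLines(cf)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("read_count_matrix: matrix dimensions do not match annotation files")
    count_matrix(m, gene_ids = genes, cell_ids = cells)
  } else {
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (any(m != round(m))) stop("read_count_matrix: non-integer entries")
    count_matrix(m, gene_ids = rownames(df), cell_ids = colnames(df))
  }
}

#' Write a count matrix to disk
#'
#' Inverse of \code{\link{read_count_matrix}}; sparse MatrixMarket triplet
#' plus one-id-per-line gene and cell tables.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param path output directory (created if missing).
#' @return \code{path}, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts$values, file.path(path, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(path, "genes.tsv"))
  writeLines(counts$cell_ids, file.path(path, "cells.tsv"))
  invisible(path)
}

#' Construct a cell annotation table
#'
#' @param cell_id character vector, one entry per cell of the matrix.
#' @param timepoint categorical timepoint (e.g. \code{"E10.5"}).
#' @param tracing_line optional categorical lineage-tracing label.
#' @param cluster_label optional categorical cluster label.
#' @return data.frame of class \code{cell_annotation}.
#' @export
cell_annotation <- function(cell_id, timepoint,
                            tracing_line = NA_character_,
                            cluster_label = NA_character_) {
  df <- data.frame(cell_id = as.character(cell_id),
                   timepoint = as.character(timepoint),
                   tracing_line = tracing_line,
                   cluster_label = cluster_label,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$cell_id)) stop("cell_annotation: duplicate cell ids")
  class(df) <- c("cell_annotation", "data.frame")
  df
}
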