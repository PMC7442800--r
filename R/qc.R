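#' QC thresholds for Smart-seq2 cells
#'
#' Defaults follow the filtering used for deep Smart-seq2 data: cells with
#' fewer than 5e4 transcripts, fewer than 2500 detected genes, or more than
#' 25% ERCC spike-in reads are removed (boundary values are kept, i.e. the
#' removal inequalities are strict).
#'
#' @param min_transcripts minimum total transcript count.
#' @param min_genes minimum number of detected (count > 0) non-spike-in genes.
#' @param max_spikein_fraction maximum tolerated ERCC read fraction.
#' @return A \code{qc_params} list.
#' @export
qc_params <- function(min_transcripts = 5e4, min_genes = 2500,
                      max_spikein_fraction = 0.25) {
  stopifnot(min_transcripts > 0, min_genes > 0,
            max_spikein_fraction > 0, max_spikein_fraction <= 1)
  structure(list(min_transcripts = min_transcripts, min_genes = min_genes,
                 max_spikein_fraction = max_spikein_fraction),
            class = "qc_params")
}

#' Filter cells on transcript count, detected genes and spike-in fraction
#'
#' Keeps exactly the cells with total transcripts >= \code{min_transcripts},
#' detected genes >= \code{min_genes} and ERCC fraction <=
#' \code{max_spikein_fraction}. Totals and the ERCC fraction are computed
#' over all rows (spike-ins included); detected genes count non-spike-in
#' rows with count > 0.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param params a \code{\link{qc_params}}.
#' @return list with the filtered \code{counts} and a \code{report}
#'   data.frame (cell_id, total_counts, n_genes, spikein_fraction, pass,
#'   reason).
#' @export
qc_filter_cells <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(params, "qc_params"))
  v <- counts$values
  total <- Matrix::colSums(v)
  spike <- if (any(counts$is_spikein))
    Matrix::colSums(v[counts$is_spikein, , drop = FALSE]) else
      numeric(ncol(v))
  frac <- ifelse(total > 0, spike / total, 0)
  n_genes <- Matrix::colSums(v[!counts$is_spikein, , drop = FALSE] > 0)

  ok_total <- total >= params$min_transcripts
  ok_genes <- n_genes >= params$min_genes
  ok_frac <- frac <= params$max_spikein_fraction
  pass <- ok_total & ok_genes & ok_frac
  reason <- rep("", length(pass))
  reason[!ok_total] <- paste0(reason[!ok_total], "low_transcripts;")
  reason[!ok_genes] <- paste0(reason[!ok_genes], "low_genes;")
  reason[!ok_frac] <- paste0(reason[!ok_frac], "high_spikein;")
  report <- data.frame(cell_id = counts$cell_ids,
                       total_counts = as.numeric(total),
                       n_genes = as.numeric(n_genes),
                       spikein_fraction = as.numeric(frac),
                       pass = pass, reason = sub(";$", "", reason),
                       stringsAsFactors = FALSE)
  if (!any(pass))
    warning("qc_filter_cells: all cells removed by QC")
  filtered <- count_matrix(v[, pass, drop = FALSE],
                           gene_ids = counts$gene_ids,
                           cell_ids = counts$cell_ids[pass],
                           is_spikein = counts$is_spikein)
  list(counts = filtered, report = report)
}

#' Normalize counts to the median library size and log-transform
#'
#' Spike-in rows are dropped, each cell is scaled to the median post-QC
#' library size (size factor = depth / median depth, computed on non
#' spike-in genes), and values are natural-log transformed as
#' \code{log(1 + x)}.
#'
#' @param counts a post-QC \code{\link{count_matrix}}.
#' @return list of class \code{expression_matrix}: \code{values} (dense
#'   gene x cell matrix of log expression), \code{size_factors},
#'   \code{normalization} record.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  v <- counts$values[!counts$is_spikein, , drop = FALSE]
  depth <- Matrix::colSums(v)
  if (any(depth == 0))
    stop("normalize_counts: zero-depth cell present (should be removed by QC)")
  m <- stats::median(depth)
  sf <- depth / m
  vals <- log1p(as.matrix(v) %*% diag(1 / sf, length(sf)))
  dimnames(vals) <- dimnames(v)
  structure(list(values = vals,
                 size_factors = stats::setNames(as.numeric(sf),
                                                counts$cell_ids),
                 normalization = list(method = "median-depth log1p",
                                      median_depth = m)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d cells\n",
              x$normalization$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Rank genes by excess variance over the mean-variance trend
#'
#' Fits a smoothed regression of log variance on log mean across genes and
#' ranks genes by their positive residual from the trend; the top
#' \code{n_top} gene ids are returned. Zero-variance genes are never
#' selected.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param n_top number of genes to return (clipped with a warning if it
#'   exceeds the number of rankable genes).
#' @return character vector of gene ids, most overdispersed first.
#' @export
select_overdispersed_genes <- function(expr, n_top) {
  stopifnot(inherits(expr, "expression_matrix"), n_top >= 0)
  v <- expr$values
  if (ncol(v) < 2) stop("select_overdispersed_genes: need >= 2 cells")
  if (n_top == 0) return(character())
  mu <- rowMeans(v)
  va <- apply(v, 1, stats::var)
  ok <- va > 0
  if (!any(ok)) stop("select_overdispersed_genes: all genes have zero variance")
  lm_ <- log(mu[ok] + 1e-9)
  lv <- log(va[ok])
  fit <- if (sum(ok) >= 10) {
    stats::predict(stats::loess(lv ~ lm_, span = 0.75, degree = 1))
  } else {
    stats::fitted(stats::lm(lv ~ lm_))
  }
  resid <- lv - fit
  ids <- rownames(v)[ok][order(resid, decreasing = TRUE)]
  if (n_top > length(ids)) {
    warning("select_overdispersed_genes: n_top exceeds rankable genes; clipped")
    n_top <- length(ids)
  }
  ids[seq_len(n_top)]
}
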