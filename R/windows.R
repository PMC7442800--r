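#' Sliding windows of cells along pseudotime
#'
#' Cells are sorted by pseudotime; window i contains the cells at ranks
#' [1 + (i-1)*s, (i-1)*s + w]. After the last full window one trailing
#' partial window is kept if it still holds at least \code{min_cells}
#' cells.
#'
#' @param projections projection table (one path) with \code{cell_id} and
#'   \code{pseudotime}.
#' @param w window size in cells (default 40).
#' @param s step in cells (default 10).
#' @param min_cells minimum cells for the trailing partial window
#'   (default 10).
#' @return list of class \code{window_set}: \code{windows} (list of
#'   cell-id vectors), \code{centers} (mean pseudotime), \code{full}
#'   (logical), \code{w}, \code{s}.
#' @export
build_windows <- function(projections, w = 40, s = 10, min_cells = 10) {
  if (w < min_cells) stop("build_windows: w must be >= min_cells")
  ord <- order(projections$pseudotime, projections$cell_id)
  ids <- projections$cell_id[ord]
  pt <- projections$pseudotime[ord]
  n <- length(ids)
  if (n < w) stop("build_windows: need >= w cells on the path")
  starts <- seq(1, n - w + 1, by = s)
  windows <- lapply(starts, function(i) ids[i:(i + w - 1)])
  centers <- vapply(starts, function(i) mean(pt[i:(i + w - 1)]), numeric(1))
  full <- rep(TRUE, length(starts))
  tail_start <- starts[length(starts)] + s
  if (tail_start <= n && n - tail_start + 1 >= min_cells) {
    windows <- c(windows, list(ids[tail_start:n]))
    centers <- c(centers, mean(pt[tail_start:n]))
    full <- c(full, FALSE)
  }
  structure(list(windows = windows, centers = centers, full = full,
                 w = w, s = s), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows (%d full), w = %d, s = %d\n",
              length(x$windows), sum(x$full), x$w, x$s))
  invisible(x)
}

#' Mean local correlation of a gene with a module
#'
#' Pearson correlation of gene \code{g} with each gene of the module
#' (excluding \code{g} itself) over the window's cells; zero-variance
#' pairs are excluded; the mean of the remaining correlations is returned
#' (NA if all pairs are excluded).
#'
#' @param expr \code{expression_matrix} or gene x cell matrix.
#' @param cells character vector of window cell ids (>= 3).
#' @param gene gene id.
#' @param module character vector of module gene ids.
#' @return numeric scalar (NA when undefined).
#' @export
local_gene_correlation <- function(expr, cells, gene, module) {
  y <- .expr_values(expr)
  if (length(cells) < 3)
    stop("local_gene_correlation: window must have >= 3 cells")
  others <- setdiff(module, gene)
  g <- y[gene, cells]
  if (stats::sd(g) == 0) return(NA_real_)
  cors <- vapply(others, function(m) {
    v <- y[m, cells]
    if (stats::sd(v) == 0) NA_real_ else stats::cor(g, v)
  }, numeric(1))
  if (all(is.na(cors))) NA_real_ else mean(cors, na.rm = TRUE)
}

#' Intra- and inter-module correlation track with repulsion
#'
#' Per window: \code{intra_A} (mean Pearson correlation over all unordered
#' within-A gene pairs), \code{intra_B} likewise, \code{inter} (mean over
#' all A x B pairs), and the repulsion statistic
#' \code{|mean(intra_A, intra_B) - inter|}. Zero-variance pairs are
#' excluded from the means and exclusion counts are reported.
#'
#' @param expr \code{expression_matrix} or gene x cell matrix.
#' @param windows a \code{\link{build_windows}} result.
#' @param module_a,module_b disjoint gene-id sets (each >= 2 genes).
#' @return data.frame of class \code{module_track}: one row per window
#'   with \code{center}, \code{intra_A}, \code{intra_B}, \code{inter},
#'   \code{repulsion} and used-pair counts.
#' @export
module_correlation_track <- function(expr, windows, module_a, module_b) {
  stopifnot(inherits(windows, "window_set"))
  if (length(intersect(module_a, module_b)))
    stop("module_correlation_track: modules must be disjoint")
  if (length(module_a) < 2 || length(module_b) < 2)
    stop("module_correlation_track: each module needs >= 2 genes")
  y <- .expr_values(expr)
  genes <- c(module_a, module_b)
  ia <- seq_along(module_a)
  ib <- length(module_a) + seq_along(module_b)
  rows <- lapply(seq_along(windows$windows), function(i) {
    cells <- windows$windows[[i]]
    m <- t(y[genes, cells, drop = FALSE])
    sds <- apply(m, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(m))
    cc[sds == 0, ] <- NA
    cc[, sds == 0] <- NA
    ca <- cc[ia, ia][upper.tri(diag(length(ia)))]
    cb <- cc[ib, ib][upper.tri(diag(length(ib)))]
    ci <- as.vector(cc[ia, ib])
    intra_a <- if (all(is.na(ca))) NA_real_ else mean(ca, na.rm = TRUE)
    intra_b <- if (all(is.na(cb))) NA_real_ else mean(cb, na.rm = TRUE)
    inter <- if (all(is.na(ci))) NA_real_ else mean(ci, na.rm = TRUE)
    data.frame(center = windows$centers[i], intra_A = intra_a,
               intra_B = intra_b, inter = inter,
               repulsion = abs(mean(c(intra_a, intra_b)) - inter),
               n_pairs_A = sum(!is.na(ca)), n_pairs_B = sum(!is.na(cb)),
               n_pairs_inter = sum(!is.na(ci)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("module_track", "data.frame")
  out
}
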