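# gene x cell matrix out of an expression_matrix or plain matrix
.expr_values <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
}

#' Cells lying on a set of segments
#'
#' @param projections projection table with \code{segment} and
#'   \code{pseudotime} columns.
#' @param segments character vector of segment labels forming a path.
#' @return the matching projection rows, ordered by pseudotime.
#' @export
path_cells <- function(projections, segments) {
  out <- projections[projections$segment %in% segments, , drop = FALSE]
  out[order(out$pseudotime, out$cell_id), , drop = FALSE]
}

#' Test genes for association with the tree
#'
#' Per gene, a penalized cubic-spline fit of log expression on pseudotime
#' is compared against the constant model by an F-test on residual sums of
#' squares pooled over all root-to-leaf paths (spline effective degrees of
#' freedom pooled likewise). P-values are Benjamini-Hochberg adjusted
#' across genes; a gene is called associated when its q-value is below
#' \code{alpha} and its fitted profile amplitude (max - min over the grid,
#' any path) is at least \code{A_min} natural-log units.
#'
#' @param expr \code{expression_matrix} or gene x cell matrix of log
#'   expression.
#' @param projections projection table (see
#'   \code{\link{compute_pseudotime}} or \code{\link{truth_projections}}).
#' @param paths list of segment-label vectors, one per root-to-leaf path
#'   (see \code{\link{tree_paths}} / \code{\link{segment_paths}}).
#' @param alpha FDR level (default 0.05).
#' @param A_min minimum fitted amplitude in natural-log units (default 0.5).
#' @param gamma smoothing penalty (default 5).
#' @param n_grid grid points per path for the amplitude (default 100).
#' @return data.frame with \code{gene_id}, \code{f_statistic},
#'   \code{p_value}, \code{q_value}, \code{amplitude}, \code{associated}.
#' @export
test_associated_genes <- function(expr, projections, paths, alpha = 0.05,
                                  A_min = 0.5, gamma = 5, n_grid = 100) {
  y <- .expr_values(expr)
  all_cells <- unique(unlist(lapply(paths, function(p)
    path_cells(projections, p)$cell_id)))
  if (length(all_cells) < 20)
    stop("test_associated_genes: need >= 20 cells on the tested subtree")
  genes <- rownames(y)
  rss1 <- rss0 <- rep(0, length(genes))
  edf1 <- n_tot <- 0
  amp <- rep(0, length(genes))
  n_paths_used <- 0
  for (p in paths) {
    pc <- path_cells(projections, p)
    idx <- match(pc$cell_id, colnames(y))
    if (length(idx) < 8) next
    sm <- .pspline_smoother(pc$pseudotime, gamma)
    if (length(idx) <= sm$edf + 1)
      stop("test_associated_genes: fewer cells than spline df on a path")
    yp <- t(y[, idx, drop = FALSE])           # cells x genes
    coefs <- sm$v %*% yp
    fitted <- sm$b %*% coefs
    rss1 <- rss1 + colSums((yp - fitted)^2)
    rss0 <- rss0 + colSums(sweep(yp, 2, colMeans(yp))^2)
    edf1 <- edf1 + sm$edf
    n_tot <- n_tot + length(idx)
    n_paths_used <- n_paths_used + 1
    grid <- seq(sm$range[1], sm$range[2], length.out = n_grid)
    bg <- splines::splineDesign(sm$knots, grid, ord = 4, outer.ok = TRUE)
    prof <- bg %*% coefs
    amp <- pmax(amp, apply(prof, 2, max) - apply(prof, 2, min))
  }
  if (n_paths_used == 0) stop("test_associated_genes: no usable path")
  df_num <- edf1 - n_paths_used
  df_den <- n_tot - edf1
  fstat <- ((rss0 - rss1) / df_num) / (rss1 / df_den)
  fstat[rss1 == 0 & rss0 == 0] <- 0
  p <- stats::pf(fstat, df_num, df_den, lower.tail = FALSE)
  p[!is.finite(fstat)] <- 0  # perfect fit of a non-constant gene
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = genes, f_statistic = as.numeric(fstat),
             p_value = as.numeric(p), q_value = as.numeric(q),
             amplitude = as.numeric(amp),
             associated = q < alpha & amp >= A_min,
             stringsAsFactors = FALSE)
}

#' Fit smoothed pseudotime profiles per root-to-leaf path
#'
#' Penalized cubic-spline fits of log expression on pseudotime, evaluated
#' on a uniform grid per path. Paths with fewer than 4 cells are marked
#' unavailable (NULL entry) rather than extrapolated.
#'
#' @inheritParams test_associated_genes
#' @param genes gene ids to fit (default: all rows of \code{expr}).
#' @param n_grid grid points per path (>= 100 by default).
#' @return object of class \code{fitted_profiles}: list with \code{paths}
#'   (per path: \code{grid}, \code{values} gene x grid matrix,
#'   \code{segments}), \code{genes}, \code{gamma}.
#' @export
fit_gene_profiles <- function(expr, projections, paths,
                              genes = NULL, gamma = 5, n_grid = 100) {
  y <- .expr_values(expr)
  if (is.null(genes)) genes <- rownames(y)
  y <- y[genes, , drop = FALSE]
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    pc <- path_cells(projections, paths[[i]])
    idx <- match(pc$cell_id, colnames(y))
    if (length(idx) < 4) {
      warning("fit_gene_profiles: path ", i,
              " has < 4 cells; profile unavailable")
      next  # element stays NULL
    }
    sm <- .pspline_smoother(pc$pseudotime, gamma)
    coefs <- sm$v %*% t(y[, idx, drop = FALSE])
    grid <- seq(sm$range[1], sm$range[2], length.out = n_grid)
    bg <- splines::splineDesign(sm$knots, grid, ord = 4, outer.ok = TRUE)
    vals <- t(bg %*% coefs)
    rownames(vals) <- genes
    out[[i]] <- list(grid = grid, values = vals, segments = paths[[i]])
  }
  structure(list(paths = out, genes = genes, gamma = gamma),
            class = "fitted_profiles")
}

#' @export
print.fitted_profiles <- function(x, ...) {
  cat(sprintf("fitted_profiles: %d genes, %d paths (gamma = %g)\n",
              length(x$genes), length(x$paths), x$gamma))
  invisible(x)
}

#' Cluster fitted profiles into expression patterns
#'
#' Gene profiles (concatenated over paths) are z-scored per gene and
#' clustered by agglomerative hierarchical clustering with Ward linkage on
#' Euclidean distances, cut at \code{n_patterns} clusters.
#'
#' @param profiles a \code{\link{fit_gene_profiles}} result.
#' @param n_patterns number of patterns (default 30).
#' @return list of class \code{profile_clustering}: \code{pattern} (named
#'   integer per gene), \code{n_patterns}, \code{linkage}, \code{metric}.
#' @export
cluster_profiles <- function(profiles, n_patterns = 30) {
  stopifnot(inherits(profiles, "fitted_profiles"))
  mats <- Filter(Negate(is.null), profiles$paths)
  if (!length(mats)) stop("cluster_profiles: no available profiles")
  m <- do.call(cbind, lapply(mats, `[[`, "values"))
  if (n_patterns > nrow(m))
    stop("cluster_profiles: n_patterns exceeds gene count")
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- (m - mu) / sd_
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  pattern <- stats::cutree(hc, k = n_patterns)
  names(pattern) <- rownames(m)
  structure(list(pattern = pattern, n_patterns = n_patterns,
                 linkage = "ward.D2", metric = "euclidean"),
            class = "profile_clustering")
}
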