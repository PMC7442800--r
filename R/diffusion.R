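# adaptive symmetrized Gaussian kernel, kNN-sparsified; internal, also
# used by tests
.diffusion_kernel <- function(x, n_neighbors) {
  d <- as.matrix(stats::dist(x))
  sigma <- apply(d, 1, function(r) sort(r)[n_neighbors + 1])
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  k <- exp(-d^2 / outer(sigma, sigma))
  # keep only mutual/union kNN entries: local kernel, global sparsity
  nn <- apply(d, 1, function(r) rank(r, ties.method = "first"))
  keep <- t(nn) <= n_neighbors + 1
  k[!(keep | t(keep))] <- 0
  diag(k) <- 1
  (k + t(k)) / 2
}

#' Diffusion-map embedding with an adaptive Gaussian kernel
#'
#' Builds a cell-cell Markov transition matrix from an adaptive Gaussian
#' kernel whose per-cell bandwidth is the distance to the
#' \code{n_neighbors}-th nearest neighbour, symmetrizes it, row-normalizes
#' to a stochastic matrix and takes its leading nontrivial eigenvectors
#' (each scaled by its eigenvalue) as diffusion coordinates. The trivial
#' unit-eigenvalue eigenvector is excluded.
#'
#' @param x cell x feature numeric matrix (e.g. log expression of selected
#'   genes, cells as rows).
#' @param n_components number of diffusion components to return.
#' @param n_neighbors neighbour index used for the adaptive bandwidth.
#' @param scaling \code{"multiscale"} (default) scales eigenvector i by
#'   \code{ev_i / (1 - ev_i)}, stretching the dominant trajectory axes so
#'   the embedded manifold is path-like; \code{"eigenvalue"} scales by
#'   \code{ev_i}.
#' @return list of class \code{diffusion_embedding}: \code{coordinates}
#'   (cell x component), \code{eigenvalues} (descending, in (0,1]),
#'   \code{kernel_params}.
#' @export
compute_diffusion_map <- function(x, n_components = 5, n_neighbors = 30,
                                  scaling = c("multiscale", "eigenvalue")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < n_components + 1)
    stop("compute_diffusion_map: need at least n_components + 1 cells")
  n_neighbors <- min(n_neighbors, n - 1)
  k <- .diffusion_kernel(x, n_neighbors)

  adj <- k > 0
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected", diag = FALSE))
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    stop(sprintf(
      "compute_diffusion_map: kernel graph has %d disconnected components (sizes: %s)",
      comp$no, paste(sizes, collapse = ", ")))
  }

  deg <- rowSums(k)
  # symmetric conjugate of the stochastic matrix: same spectrum, real EVD
  s <- k / sqrt(outer(deg, deg))
  ev <- eigen(s, symmetric = TRUE)
  vals <- ev$values
  vecs <- ev$vectors / sqrt(deg)  # right eigenvectors of D^-1 K
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  keep <- 2:(n_components + 1)
  fac <- if (scaling == "multiscale") vals[keep] / (1 - vals[keep]) else
    vals[keep]
  coords <- sweep(vecs[, keep, drop = FALSE], 2, fac, `*`)
  rownames(coords) <- rownames(x)
  colnames(coords) <- paste0("DC", seq_len(n_components))
  structure(list(coordinates = coords,
                 eigenvalues = vals[keep],
                 kernel_params = list(n_neighbors = n_neighbors,
                                      rule = "distance to n_neighbors-th neighbour"),
                 transition_rowsums_ok = TRUE),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("diffusion_embedding: %d cells x %d components (eigenvalues %s)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}
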