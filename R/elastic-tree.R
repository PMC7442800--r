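#' Construct a principal tree
#'
#' An acyclic connected graph of nodes embedded in (diffusion) space, with
#' elastic stretching/bending penalties and up to two declared roots.
#' Edges are stored canonically: each pair ordered (min, max) and rows
#' sorted lexicographically; all tie-breaks in the package reference this
#' ordering.
#'
#' @param node_positions node x dimension numeric matrix.
#' @param edges two-column matrix of node indices.
#' @param lambda stretching (edge length) penalty, >= 0.
#' @param mu bending (star deviation) penalty, >= 0.
#' @param roots integer vector of 0-2 root node indices.
#' @param ... additional fields (energy traces etc.) stored on the object.
#' @return object of class \code{principal_tree}.
#' @export
principal_tree <- function(node_positions, edges, lambda = 0.01, mu = 0.1,
                           roots = integer(0), ...) {
  node_positions <- as.matrix(node_positions)
  if (!all(is.finite(node_positions)))
    stop("principal_tree: non-finite node coordinates")
  edges <- .canon_edges(edges)
  n <- nrow(node_positions)
  if (any(edges < 1) || any(edges > n))
    stop("principal_tree: edge references unknown node")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (n > 1) {
    if (!igraph::is_connected(g))
      stop("principal_tree: edge graph is not connected")
    if (igraph::ecount(g) != n - 1)
      stop("principal_tree: edge graph is not acyclic")
  }
  roots <- as.integer(roots)
  if (length(roots) > 2 || any(roots < 1) || any(roots > n))
    stop("principal_tree: roots must be 1-2 valid node ids")
  stopifnot(lambda >= 0, mu >= 0)
  structure(list(node_positions = node_positions, edges = edges,
                 lambda = lambda, mu = mu, roots = roots, ...),
            class = "principal_tree")
}

#' @export
print.principal_tree <- function(x, ...) {
  cat(sprintf("principal_tree: %d nodes, %d edges, %d leaves, dim %d\n",
              nrow(x$node_positions), nrow(x$edges),
              sum(.node_degrees(x) == 1), ncol(x$node_positions)))
  invisible(x)
}

.canon_edges <- function(edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  edges
}

.node_degrees <- function(tree) {
  tabulate(as.vector(tree$edges), nbins = nrow(tree$node_positions))
}

# total elastic energy given an assignment of points to nodes
.elastic_energy <- function(x, edges, points, assign, lambda, mu) {
  data_term <- mean(rowSums((points - x[assign, , drop = FALSE])^2))
  el <- x[edges[, 1], , drop = FALSE] - x[edges[, 2], , drop = FALSE]
  stretch <- lambda * sum(el^2)
  deg <- tabulate(as.vector(edges), nbins = nrow(x))
  bend <- 0
  for (j in which(deg >= 2)) {
    nb <- c(edges[edges[, 1] == j, 2], edges[edges[, 2] == j, 1])
    bend <- bend + sum((x[j, ] - colMeans(x[nb, , drop = FALSE]))^2)
  }
  data_term + stretch + mu * bend
}

# closed-form quadratic solve for node positions given the assignment
.solve_positions <- function(points, assign, edges, n_nodes, lambda, mu) {
  n_pts <- nrow(points)
  cnt <- tabulate(assign, nbins = n_nodes)
  a <- diag(cnt / n_pts, n_nodes)
  # stretching: lambda * graph Laplacian
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    a[u, u] <- a[u, u] + lambda
    a[v, v] <- a[v, v] + lambda
    a[u, v] <- a[u, v] - lambda
    a[v, u] <- a[v, u] - lambda
  }
  # bending: mu * sum_j s_j s_j' over star centres (degree >= 2)
  deg <- tabulate(as.vector(edges), nbins = n_nodes)
  for (j in which(deg >= 2)) {
    nb <- c(edges[edges[, 1] == j, 2], edges[edges[, 2] == j, 1])
    s <- numeric(n_nodes)
    s[j] <- 1
    s[nb] <- s[nb] - 1 / length(nb)
    a <- a + mu * tcrossprod(s)
  }
  b <- matrix(0, n_nodes, ncol(points))
  sums <- rowsum(points, group = assign)
  b[as.integer(rownames(sums)), ] <- sums / n_pts
  solve(a + diag(1e-12, n_nodes), b)
}

# alternate nearest-node assignment and position solves; energy is
# non-increasing across iterations by construction
.optimize_tree <- function(points, x, edges, lambda, mu,
                           max_iter = 50, tol = 1e-7) {
  trace <- numeric()
  assign <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .point_node_dist2(points, x)
    assign <- max.col(-d2, ties.method = "first")
    x_new <- .solve_positions(points, assign, edges, nrow(x), lambda, mu)
    e_new <- .elastic_energy(x_new, edges, points, assign, lambda, mu)
    if (length(trace) && e_new > trace[length(trace)] + 1e-12) {
      # quadratic solve cannot increase energy; keep previous iterate
      break
    }
    x <- x_new
    trace <- c(trace, e_new)
    if (length(trace) >= 2 &&
        abs(trace[length(trace) - 1] - e_new) <
        tol * max(1e-12, trace[1])) break
  }
  list(x = x, assign = assign, energy = trace[length(trace)], trace = trace)
}

.point_node_dist2 <- function(points, x) {
  # squared distances, points x nodes
  pn <- rowSums(points^2)
  xn <- rowSums(x^2)
  outer(pn, xn, `+`) - 2 * points %*% t(x)
}

#' Fit an elastic principal tree (or curve) to points
#'
#' Grows a tree from a 2-node seed by grammar moves (bisect an edge, add a
#' node to a node), at each step choosing the move that minimizes the
#' elastic energy: mean squared point-to-nearest-node distance +
#' \code{lambda} * sum of squared edge lengths + \code{mu} * sum of squared
#' deviations of star centres from the mean of their neighbours. Node
#' positions are updated by closed-form quadratic solves alternating with
#' nearest-node assignment; energy is non-increasing across iterations of
#' every fit.
#'
#' @param points point x dimension numeric matrix.
#' @param n_nodes final number of nodes (>= 2, <= number of points).
#' @param lambda stretching penalty (default 0.01).
#' @param mu bending penalty (default 0.1).
#' @param seed controls the initial 2-node placement (two most distant
#'   points of a random subsample).
#' @param topology \code{"tree"} (default) or \code{"curve"} (no branching:
#'   node additions restricted to path endpoints).
#' @param max_iter maximum optimization iterations per fit.
#' @return a \code{\link{principal_tree}} carrying \code{energy} (final),
#'   and \code{energy_traces} (per accepted fit, each non-increasing).
#' @export
fit_elastic_tree <- function(points, n_nodes, lambda = 0.01, mu = 0.1,
                             seed = 1L, topology = c("tree", "curve"),
                             max_iter = 50) {
  topology <- match.arg(topology)
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("fit_elastic_tree: non-finite coordinates")
  n_pts <- nrow(points)
  if (n_nodes < 2) stop("fit_elastic_tree: n_nodes must be >= 2")
  if (n_nodes > n_pts) stop("fit_elastic_tree: n_nodes exceeds point count")

  set.seed(seed)
  sub <- points[sample.int(n_pts, min(100L, n_pts)), , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  x <- sub[c(far[1], far[2]), , drop = FALSE]
  edges <- matrix(c(1L, 2L), ncol = 2)

  fit <- .optimize_tree(points, x, edges, lambda, mu, max_iter)
  x <- fit$x
  traces <- list(fit$trace)

  while (nrow(x) < n_nodes) {
    cand <- list()
    # bisect an edge
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      new_x <- rbind(x, (x[u, ] + x[v, ]) / 2)
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(u, nrow(new_x)), c(nrow(new_x), v))
      cand[[length(cand) + 1]] <- list(x = new_x, edges = .canon_edges(new_edges))
    }
    # add a node to a node
    deg <- tabulate(as.vector(edges), nbins = nrow(x))
    d2 <- .point_node_dist2(points, x)
    assign <- max.col(-d2, ties.method = "first")
    grow_nodes <- if (topology == "curve") which(deg <= 1) else seq_len(nrow(x))
    for (j in grow_nodes) {
      nb <- c(edges[edges[, 1] == j, 2], edges[edges[, 2] == j, 1])
      pos <- if (any(assign == j)) {
        colMeans(points[assign == j, , drop = FALSE])
      } else {
        2 * x[j, ] - colMeans(x[nb, , drop = FALSE])
      }
      if (sqrt(sum((pos - x[j, ])^2)) < 1e-12)
        pos <- 2 * x[j, ] - colMeans(x[nb, , drop = FALSE])
      new_x <- rbind(x, pos)
      new_edges <- .canon_edges(rbind(edges, c(j, nrow(new_x))))
      cand[[length(cand) + 1]] <- list(x = new_x, edges = new_edges)
    }
    fits <- lapply(cand, function(cc)
      .optimize_tree(points, cc$x, cc$edges, lambda, mu,
                     max_iter = 10, tol = 1e-5))
    best <- which.min(vapply(fits, `[[`, numeric(1), "energy"))
    edges <- cand[[best]]$edges
    fit <- .optimize_tree(points, fits[[best]]$x, edges, lambda, mu, max_iter)
    x <- fit$x
    traces[[length(traces) + 1]] <- fit$trace
  }
  rownames(x) <- NULL
  principal_tree(x, edges, lambda = lambda, mu = mu,
                 energy = fit$energy, energy_traces = traces)
}

#' Attach a component to an existing principal tree
#'
#' Semi-supervised stitching: either add the geometrical centre of a point
#' cloud as one node linked to the nearest tree node (\code{"centroid"}),
#' or fit a separate principal tree/curve on the points and link its node
#' nearest to the main tree to the main tree's nearest node
#' (\code{"subtree"} / \code{"curve"}). The result is always a single
#' acyclic connected graph.
#'
#' @param tree a \code{\link{principal_tree}}.
#' @param points point x dimension matrix of the cells to add.
#' @param mode \code{"centroid"}, \code{"subtree"} or \code{"curve"}.
#' @param n_nodes nodes of the fitted sub-component (subtree/curve modes).
#' @param seed seed for the sub-fit.
#' @return the extended \code{\link{principal_tree}}.
#' @export
attach_component <- function(tree, points, mode = c("centroid", "subtree",
                                                    "curve"),
                             n_nodes = 4, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "principal_tree"))
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("attach_component: empty addition")
  if (ncol(points) != ncol(tree$node_positions))
    stop("attach_component: dimension mismatch")
  x <- tree$node_positions
  if (mode == "centroid") {
    cen <- colMeans(points)
    near <- which.min(rowSums(sweep(x, 2, cen)^2))
    new_x <- rbind(x, cen)
    new_edges <- .canon_edges(rbind(tree$edges, c(near, nrow(new_x))))
    out <- principal_tree(new_x, new_edges, tree$lambda, tree$mu, tree$roots)
  } else {
    sub <- fit_elastic_tree(points, n_nodes, tree$lambda, tree$mu, seed,
                            topology = if (mode == "curve") "curve" else "tree")
    sx <- sub$node_positions
    d2 <- .point_node_dist2(sx, x)  # sub-node x main-node
    idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    off <- nrow(x)
    new_x <- rbind(x, sx)
    new_edges <- .canon_edges(rbind(tree$edges, sub$edges + off,
                                    c(idx[2], idx[1] + off)))
    out <- principal_tree(new_x, new_edges, tree$lambda, tree$mu, tree$roots)
  }
  # cannot create a cycle by construction
  stopifnot(nrow(out$edges) == nrow(out$node_positions) - 1)
  out
}

#' Split every edge of a tree at its midpoint
#'
#' Each edge is replaced by two equidistant edges meeting at the midpoint;
#' geometry and total edge length are unchanged, node count becomes
#' n + e and edge count 2e.
#'
#' @param tree a \code{\link{principal_tree}}.
#' @return the subdivided \code{\link{principal_tree}}.
#' @export
subdivide_edges <- function(tree) {
  stopifnot(inherits(tree, "principal_tree"))
  x <- tree$node_positions
  edges <- tree$edges
  new_edges <- NULL
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    x <- rbind(x, (x[u, ] + x[v, ]) / 2)
    m <- nrow(x)
    new_edges <- rbind(new_edges, c(u, m), c(m, v))
  }
  principal_tree(x, .canon_edges(new_edges), tree$lambda, tree$mu, tree$roots)
}

#' Total Euclidean edge length of a tree
#' @param tree a \code{\link{principal_tree}}.
#' @return numeric scalar.
#' @export
tree_edge_length <- function(tree) {
  x <- tree$node_positions
  sum(sqrt(rowSums((x[tree$edges[, 1], , drop = FALSE] -
                      x[tree$edges[, 2], , drop = FALSE])^2)))
}

#' Serialize / read a principal tree as JSON
#'
#' @param tree a \code{\link{principal_tree}}.
#' @param path file path.
#' @return \code{read_tree} returns the \code{\link{principal_tree}}.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "principal_tree"))
  jsonlite::write_json(list(node_positions = tree$node_positions,
                            edges = tree$edges, lambda = tree$lambda,
                            mu = tree$mu, roots = tree$roots),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  principal_tree(x$node_positions, x$edges, x$lambda, x$mu,
                 roots = x$roots %||% integer(0))
}
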