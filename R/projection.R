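#' Project cells onto a principal tree
#'
#' Each cell is mapped to its closest point on the union of edge segments
#' (continuous orthogonal projection onto every edge, clamped to [0,1]).
#' Ties are broken by the lowest edge index in the canonical edge ordering.
#'
#' @param tree a \code{\link{principal_tree}}.
#' @param points cell x dimension matrix (same dimension as the tree).
#' @param cell_ids optional cell identifiers (default: rownames).
#' @return data.frame with columns \code{cell_id}, \code{node_from},
#'   \code{node_to}, \code{offset} (in [0,1] along the edge) and
#'   \code{dist} (Euclidean distance to the projection).
#' @export
project_cells <- function(tree, points, cell_ids = rownames(points)) {
  stopifnot(inherits(tree, "principal_tree"))
  points <- as.matrix(points)
  if (nrow(tree$edges) == 0) stop("project_cells: empty tree")
  if (ncol(points) != ncol(tree$node_positions))
    stop("project_cells: dimension mismatch")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(nrow(points)))
  x <- tree$node_positions
  n_e <- nrow(tree$edges)
  best_d2 <- rep(Inf, nrow(points))
  best_e <- integer(nrow(points))
  best_off <- numeric(nrow(points))
  for (e in seq_len(n_e)) {
    u <- x[tree$edges[e, 1], ]
    v <- x[tree$edges[e, 2], ]
    w <- v - u
    len2 <- sum(w^2)
    tt <- if (len2 == 0) rep(0, nrow(points)) else
      pmin(1, pmax(0, (sweep(points, 2, u) %*% w) / len2))
    proj <- outer(as.vector(tt), w) + rep(u, each = nrow(points))
    d2 <- rowSums((points - proj)^2)
    upd <- d2 < best_d2 - 1e-15
    best_d2[upd] <- d2[upd]
    best_e[upd] <- e
    best_off[upd] <- tt[upd]
  }
  data.frame(cell_id = cell_ids,
             node_from = tree$edges[best_e, 1],
             node_to = tree$edges[best_e, 2],
             offset = best_off, dist = sqrt(best_d2),
             stringsAsFactors = FALSE)
}

# branch decomposition: maximal paths between branching/terminal nodes.
# Returns a data.frame mapping each canonical edge row to a segment id,
# plus the ordered node path of every segment.
.tree_segments <- function(tree) {
  edges <- tree$edges
  n <- nrow(tree$node_positions)
  deg <- .node_degrees(tree)
  inc <- lapply(seq_len(n), function(j)
    which(edges[, 1] == j | edges[, 2] == j))
  breakpoints <- which(deg != 2)
  if (length(breakpoints) == 0) breakpoints <- 1L  # single path loop-free
  visited <- rep(FALSE, nrow(edges))
  seg_of_edge <- integer(nrow(edges))
  seg_paths <- list()
  sid <- 0L
  for (b in breakpoints) {
    for (e0 in inc[[b]]) {
      if (visited[e0]) next
      sid <- sid + 1L
      path_nodes <- b
      e <- e0
      cur <- b
      repeat {
        visited[e] <- TRUE
        seg_of_edge[e] <- sid
        nxt <- setdiff(edges[e, ], cur)
        path_nodes <- c(path_nodes, nxt)
        if (deg[nxt] != 2) break
        e <- setdiff(inc[[nxt]], e)
        cur <- nxt
      }
      seg_paths[[sid]] <- path_nodes
    }
  }
  list(seg_of_edge = seg_of_edge, seg_paths = seg_paths)
}

.edge_lengths <- function(tree) {
  x <- tree$node_positions
  sqrt(rowSums((x[tree$edges[, 1], , drop = FALSE] -
                  x[tree$edges[, 2], , drop = FALSE])^2))
}

.tree_graph <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(tree$node_positions) -
                                     igraph::vcount(g)))
  igraph::E(g)$weight <- .edge_lengths(tree)
  g
}

#' Pseudotime as along-graph distance to an assigned root
#'
#' Assigns every projected cell a pseudotime equal to the graph distance
#' (along tree edges, Euclidean edge lengths) from its assigned root to the
#' projected point, plus a segment label from the branch decomposition
#' (maximal paths between branching/terminal nodes). With two roots,
#' segments are partitioned between the roots (default: each segment goes
#' to the root closest along the graph) and cells inherit the root of
#' their segment.
#'
#' @param tree a \code{\link{principal_tree}}.
#' @param projections output of \code{\link{project_cells}}.
#' @param roots root node indices (default: \code{tree$roots}).
#' @param segment_roots optional integer vector mapping segment id to root
#'   node id, overriding the default partition.
#' @return the projections data.frame with added columns
#'   \code{pseudotime}, \code{segment} (\code{"seg_<i>"}) and
#'   \code{assigned_root}; the segment decomposition is attached as
#'   attribute \code{"segments"}.
#' @export
compute_pseudotime <- function(tree, projections, roots = tree$roots,
                               segment_roots = NULL) {
  stopifnot(inherits(tree, "principal_tree"))
  roots <- as.integer(roots)
  if (length(roots) == 0) stop("compute_pseudotime: no root declared")
  g <- .tree_graph(tree)
  segs <- .tree_segments(tree)
  n_seg <- length(segs$seg_paths)
  dmat <- igraph::distances(g, v = roots)  # roots x nodes

  if (is.null(segment_roots)) {
    segment_roots <- vapply(seq_len(n_seg), function(s) {
      ends <- segs$seg_paths[[s]][c(1, length(segs$seg_paths[[s]]))]
      roots[which.min(apply(dmat[, ends, drop = FALSE], 1, min))]
    }, integer(1))
  } else {
    segment_roots <- as.integer(segment_roots)
    stopifnot(length(segment_roots) == n_seg,
              all(segment_roots %in% roots))
  }
  if (any(!is.finite(dmat[, unlist(segs$seg_paths)])))
    stop("compute_pseudotime: segment with unreachable root")

  key <- paste(tree$edges[, 1], tree$edges[, 2])
  e_row <- match(paste(projections$node_from, projections$node_to), key)
  seg_id <- segs$seg_of_edge[e_row]
  lens <- .edge_lengths(tree)
  root_of_cell <- segment_roots[seg_id]
  ri <- match(root_of_cell, roots)
  du <- dmat[cbind(ri, projections$node_from)]
  dv <- dmat[cbind(ri, projections$node_to)]
  pt <- pmin(du + projections$offset * lens[e_row],
             dv + (1 - projections$offset) * lens[e_row])
  out <- projections
  out$pseudotime <- as.numeric(pt)
  out$segment <- sprintf("seg_%02d", seg_id)
  out$assigned_root <- root_of_cell
  attr(out, "segments") <- segs
  attr(out, "segment_roots") <- segment_roots
  out
}

#' Root-to-leaf segment paths of a fitted tree
#'
#' Enumerates, for each declared root, the paths to every leaf belonging to
#' that root's segment partition, expressed as ordered segment labels
#' matching the \code{segment} column of \code{\link{compute_pseudotime}}
#' output.
#'
#' @param tree a \code{\link{principal_tree}}.
#' @param projections output of \code{\link{compute_pseudotime}}.
#' @return list of character vectors of segment labels (root first).
#' @export
tree_paths <- function(tree, projections) {
  segs <- attr(projections, "segments")
  seg_roots <- attr(projections, "segment_roots")
  if (is.null(segs)) stop("tree_paths: run compute_pseudotime first")
  g <- .tree_graph(tree)
  deg <- .node_degrees(tree)
  leaves <- which(deg == 1)
  key <- paste(tree$edges[, 1], tree$edges[, 2])
  paths <- list()
  for (r in unique(seg_roots)) {
    for (l in setdiff(leaves, r)) {
      vp <- igraph::shortest_paths(g, from = r, to = l)$vpath[[1]]
      vp <- as.integer(vp)
      e_rows <- match(paste(pmin(vp[-length(vp)], vp[-1]),
                            pmax(vp[-length(vp)], vp[-1])), key)
      seg_seq <- unique(segs$seg_of_edge[e_rows])
      # keep only leaves inside this root's partition
      last_seg <- seg_seq[length(seg_seq)]
      if (seg_roots[last_seg] != r) next
      paths[[length(paths) + 1]] <- sprintf("seg_%02d", seg_seq)
    }
  }
  paths
}

#' Propose a root node from timepoint annotation
#'
#' Returns the tree node onto which the largest number of
#' earliest-timepoint cells project.
#'
#' @param projections output of \code{\link{project_cells}}.
#' @param timepoints character vector of per-cell timepoints, aligned with
#'   \code{projections}.
#' @return integer node index.
#' @export
suggest_root <- function(projections, timepoints) {
  stopifnot(nrow(projections) == length(timepoints))
  u <- unique(as.character(timepoints))
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", u)))
  first <- if (all(is.finite(num))) u[which.min(num)] else sort(u)[1]
  sel <- timepoints == first
  node <- ifelse(projections$offset[sel] <= 0.5,
                 projections$node_from[sel], projections$node_to[sel])
  as.integer(names(which.max(table(node))))
}
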