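#' Describe one branch for a two-branch comparison
#'
#' @param associated character vector of associated gene ids on the branch.
#' @param profiles a \code{\link{fit_gene_profiles}} result with a single
#'   path covering the branch (root to branch end).
#' @param skeleton list with \code{points} (polyline vertex coordinates in
#'   embedding space, matrix) and \code{pseudotime} (per vertex).
#' @return list of class \code{branch_description}.
#' @export
branch_description <- function(associated, profiles, skeleton) {
  stopifnot(inherits(profiles, "fitted_profiles"),
            is.matrix(skeleton$points),
            length(skeleton$pseudotime) == nrow(skeleton$points))
  structure(list(associated = associated, profiles = profiles,
                 skeleton = skeleton), class = "branch_description")
}

# resample a polyline uniformly by arc length, carrying pseudotime along
.sample_skeleton <- function(skeleton, n_samples) {
  pts <- skeleton$points
  pt <- skeleton$pseudotime
  seg_len <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg_len))
  s <- seq(0, arc[length(arc)], length.out = n_samples)
  coords <- apply(pts, 2, function(col) stats::approx(arc, col, xout = s)$y)
  list(coords = matrix(coords, ncol = ncol(pts)),
       pseudotime = stats::approx(arc, pt, xout = s)$y, arc = s)
}

#' Compare two branches from their closest common point
#'
#' The common point is the pair of positions (one per branch skeleton)
#' minimizing the Euclidean distance in embedding space over a dense
#' uniform sampling of both skeletons. Genes associated on both branches
#' are common; the symmetric difference is branch-specific. Each gene is
#' labelled early or late by a 2-cluster Ward split of its fitted profile
#' re-parameterized from the common point, the earlier-rising cluster
#' being "early".
#'
#' @param branch_a,branch_b \code{\link{branch_description}} objects.
#' @param n_samples skeleton sampling resolution (default 200 per branch).
#' @return list of class \code{branch_comparison}: \code{common_point}
#'   (indices, coordinates, pseudotime per branch, distance),
#'   \code{common_genes}, \code{branch_specific} (named "A"/"B" vector),
#'   \code{early_late} (named "early"/"late" vector).
#' @export
compare_branches <- function(branch_a, branch_b, n_samples = 200) {
  stopifnot(inherits(branch_a, "branch_description"),
            inherits(branch_b, "branch_description"))
  if (!length(branch_a$associated) || !length(branch_b$associated))
    stop("compare_branches: empty association set on a branch")
  sa <- .sample_skeleton(branch_a$skeleton, n_samples)
  sb <- .sample_skeleton(branch_b$skeleton, n_samples)
  d2 <- .point_node_dist2(sa$coords, sb$coords)
  idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  common_point <- list(
    index_a = idx[1], index_b = idx[2],
    coords_a = sa$coords[idx[1], ], coords_b = sb$coords[idx[2], ],
    pseudotime_a = sa$pseudotime[idx[1]], pseudotime_b = sb$pseudotime[idx[2]],
    distance = sqrt(max(0, d2[idx[1], idx[2]])))

  common <- intersect(branch_a$associated, branch_b$associated)
  spec_a <- setdiff(branch_a$associated, common)
  spec_b <- setdiff(branch_b$associated, common)
  branch_specific <- stats::setNames(c(rep("A", length(spec_a)),
                                       rep("B", length(spec_b))),
                                     c(spec_a, spec_b))

  # early/late by 2-cluster Ward split of post-common-point profiles;
  # common genes use their branch A profile
  gene_branch <- c(stats::setNames(rep("A", length(common)), common),
                   branch_specific)
  profs <- list(A = branch_a$profiles$paths[[1]],
                B = branch_b$profiles$paths[[1]])
  cuts <- list(A = common_point$pseudotime_a, B = common_point$pseudotime_b)
  rows <- list()
  half_rise <- numeric()
  for (g in names(gene_branch)) {
    br <- gene_branch[[g]]
    pr <- profs[[br]]
    keep <- pr$grid >= cuts[[br]]
    if (sum(keep) < 3) keep <- rep(TRUE, length(pr$grid))
    v <- pr$values[g, keep]
    v_std <- stats::approx(seq_along(v), v, n = 50)$y
    rows[[g]] <- v_std
    rng <- range(v_std)
    thr <- rng[1] + 0.5 * diff(rng)
    cross <- which(v_std >= thr)[1]
    half_rise[g] <- if (is.na(cross) || diff(rng) == 0) 50 else cross
  }
  m <- do.call(rbind, rows)
  sd_ <- apply(m, 1, stats::sd)
  sd_[sd_ == 0] <- 1
  z <- (m - rowMeans(m)) / sd_
  early_late <- if (nrow(m) >= 2) {
    cl <- stats::cutree(stats::hclust(stats::dist(z), method = "ward.D2"),
                        k = 2)
    means <- tapply(half_rise, cl, mean)
    lab <- c("late", "late")
    lab[as.integer(names(means))[which.min(means)]] <- "early"
    stats::setNames(lab[cl], rownames(m))
  } else stats::setNames(rep("early", nrow(m)), rownames(m))

  structure(list(common_point = common_point, common_genes = common,
                 branch_specific = branch_specific,
                 early_late = early_late),
            class = "branch_comparison")
}
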