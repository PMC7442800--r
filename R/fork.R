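#' Define a bifurcation (fork) on a trajectory
#'
#' A fork separates a root path (pre-bifurcation segments) from two
#' disjoint post-fork branch paths.
#'
#' @param root_segments segment labels upstream of the fork (root first).
#' @param branch1_segments,branch2_segments segment labels of the two
#'   post-fork branches (disjoint).
#' @param fork_pseudotime pseudotime of the fork point.
#' @return list of class \code{fork_definition}.
#' @export
fork_definition <- function(root_segments, branch1_segments,
                            branch2_segments, fork_pseudotime) {
  if (length(intersect(branch1_segments, branch2_segments)))
    stop("fork_definition: branch paths must be disjoint below the fork")
  structure(list(root_segments = as.character(root_segments),
                 branch1_segments = as.character(branch1_segments),
                 branch2_segments = as.character(branch2_segments),
                 fork_pseudotime = fork_pseudotime),
            class = "fork_definition")
}

#' Fork definition from a simulated topology
#'
#' Builds the \code{\link{fork_definition}} at the downstream end of a
#' given segment of a \code{\link{simulation_config}} topology: the two
#' branches are the segment's children together with their descendants.
#'
#' @param config a \code{\link{simulation_config}} or
#'   \code{synthetic_dataset}.
#' @param segment name of the segment whose end is the fork.
#' @return a \code{\link{fork_definition}}.
#' @export
topology_fork <- function(config, segment) {
  if (inherits(config, "synthetic_dataset")) config <- config$config
  topo <- config$topology
  kids <- topo$segment[!is.na(topo$parent) & topo$parent == segment]
  if (length(kids) != 2)
    stop("topology_fork: segment must have exactly two children")
  fork_t <- .seg_start(topo, segment) +
    topo$length[match(segment, topo$segment)]
  fork_definition(
    root_segments = c(rev(.seg_ancestors(topo, segment)), segment),
    branch1_segments = c(kids[1], .seg_descendants(topo, kids[1])),
    branch2_segments = c(kids[2], .seg_descendants(topo, kids[2])),
    fork_pseudotime = fork_t)
}

#' Detect genes differentially upregulated after a bifurcation
#'
#' Per gene, a Wilcoxon rank-sum test compares log expression between the
#' two post-fork branch cell sets (BH-adjusted across genes). An
#' upregulation gate additionally requires the fitted profile along the
#' winning branch (root path + branch) to exceed its value at the fork by
#' at least \code{up_min} at the branch end. Genes passing both are fork
#' genes.
#'
#' @param expr \code{expression_matrix} or gene x cell log-expression
#'   matrix.
#' @param projections projection table with \code{segment} and
#'   \code{pseudotime}.
#' @param fork a \code{\link{fork_definition}}.
#' @param alpha FDR level (default 0.05).
#' @param up_min minimum post-fork fitted increase, natural-log units
#'   (default 0.5).
#' @param gamma smoothing penalty for the gate profiles.
#' @return data.frame with \code{gene_id}, \code{p_branch},
#'   \code{q_branch}, \code{effect} (branch1 - branch2 mean, log units),
#'   \code{upreg} (fitted end-minus-fork increase on the winning branch),
#'   \code{fork_gene}.
#' @export
test_fork_genes <- function(expr, projections, fork, alpha = 0.05,
                            up_min = 0.5, gamma = 5) {
  stopifnot(inherits(fork, "fork_definition"))
  y <- .expr_values(expr)
  c1 <- path_cells(projections, fork$branch1_segments)
  c2 <- path_cells(projections, fork$branch2_segments)
  if (nrow(c1) < 20 || nrow(c2) < 20)
    stop("test_fork_genes: need >= 20 cells on each post-fork branch")
  i1 <- match(c1$cell_id, colnames(y))
  i2 <- match(c2$cell_id, colnames(y))
  y1 <- y[, i1, drop = FALSE]
  y2 <- y[, i2, drop = FALSE]
  p <- vapply(seq_len(nrow(y)), function(g) {
    a <- y1[g, ]; b <- y2[g, ]
    if (stats::var(c(a, b)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  q <- stats::p.adjust(p, method = "BH")
  m1 <- rowMeans(y1)
  m2 <- rowMeans(y2)
  effect <- m1 - m2

  # upregulation gate on the winning branch's fitted profile
  upreg <- rep(NA_real_, nrow(y))
  for (b in 1:2) {
    br <- if (b == 1) fork$branch1_segments else fork$branch2_segments
    pc <- path_cells(projections, c(fork$root_segments, br))
    idx <- match(pc$cell_id, colnames(y))
    sm <- .pspline_smoother(pc$pseudotime, gamma)
    coefs <- sm$v %*% t(y[, idx, drop = FALSE])
    at <- pmin(sm$range[2], pmax(sm$range[1],
                                 c(fork$fork_pseudotime, sm$range[2])))
    bv <- splines::splineDesign(sm$knots, at, ord = 4, outer.ok = TRUE)
    vals <- bv %*% coefs   # 2 x genes: at fork, at end
    win <- if (b == 1) effect > 0 else effect <= 0
    upreg[win] <- vals[2, win] - vals[1, win]
  }
  data.frame(gene_id = rownames(y), p_branch = p, q_branch = q,
             mean_branch1 = m1, mean_branch2 = m2, effect = effect,
             upreg = upreg,
             fork_gene = q < alpha & upreg >= up_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign fork genes to a post-bifurcation branch
#'
#' A gene is assigned to the branch with the higher mean fitted post-fork
#' expression; assignment requires the inter-branch fitted difference to
#' be at least \code{effect_min} log units, otherwise the gene is dropped
#' as ambiguous (\code{NA}).
#'
#' @param fork_genes character vector of fork gene ids (or the
#'   \code{\link{test_fork_genes}} table, whose \code{fork_gene} rows are
#'   used).
#' @param profiles1,profiles2 \code{\link{fit_gene_profiles}} results on
#'   the root+branch1 and root+branch2 paths; a branch with nested forks
#'   may carry several paths, in which case a gene's branch expression is
#'   its maximum post-fork path mean.
#' @param fork a \code{\link{fork_definition}}.
#' @param effect_min minimum fitted inter-branch difference (default 0.5).
#' @return data.frame with \code{gene_id}, \code{mean_branch1},
#'   \code{mean_branch2}, \code{fitted_difference},
#'   \code{assigned_branch} (1, 2 or NA).
#' @export
assign_branch_specific <- function(fork_genes, profiles1, profiles2, fork,
                                   effect_min = 0.5) {
  if (is.data.frame(fork_genes))
    fork_genes <- fork_genes$gene_id[fork_genes$fork_gene]
  # a branch may contain several root-to-leaf paths (nested forks); a
  # gene's branch expression is its best post-fork path mean
  post_mean <- function(profiles) {
    ms <- lapply(Filter(Negate(is.null), profiles$paths), function(p) {
      post <- p$grid >= fork$fork_pseudotime
      rowMeans(p$values[fork_genes, post, drop = FALSE])
    })
    do.call(pmax, ms)
  }
  m1 <- post_mean(profiles1)
  m2 <- post_mean(profiles2)
  diff <- m1 - m2
  assigned <- ifelse(abs(diff) >= effect_min, ifelse(diff > 0, 1L, 2L),
                     NA_integer_)
  data.frame(gene_id = fork_genes, mean_branch1 = as.numeric(m1),
             mean_branch2 = as.numeric(m2),
             fitted_difference = as.numeric(diff),
             assigned_branch = assigned,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Optimum expression and activation time of a fitted profile
#'
#' The optimum is the maximum of the fitted profile along the path; the
#' baseline is the minimum before the optimum; the activation time is the
#' earliest pseudotime at or after the baseline position at which the
#' profile reaches \code{baseline + f * (optimum - baseline)} (linearly
#' interpolated between grid points). Searching from the baseline onward
#' makes the estimate robust to profiles that start above baseline (e.g.
#' normalization-driven elevation near the root). A flat profile has no
#' defined activation time.
#'
#' @param profile numeric vector of fitted log expression along the path.
#' @param grid increasing pseudotime grid matching \code{profile}.
#' @param f activation fraction (default 0.3).
#' @return list with \code{optimum}, \code{baseline},
#'   \code{activation_time} (NA when undefined).
#' @export
estimate_activation <- function(profile, grid, f = 0.3) {
  stopifnot(length(profile) == length(grid), all(diff(grid) > 0),
            f > 0, f < 1)
  i_opt <- which.max(profile)
  optimum <- profile[i_opt]
  baseline <- min(profile[seq_len(i_opt)])
  amp <- optimum - baseline
  if (amp <= 1e-12)
    return(list(optimum = optimum, baseline = baseline,
                activation_time = NA_real_))
  thr <- baseline + f * amp
  i_base <- which.min(profile[seq_len(i_opt)])
  cand <- which(profile >= thr)
  i <- cand[cand >= i_base][1]
  act <- if (i == i_base || i == 1) grid[i] else {
    # linear interpolation of the crossing between grid points
    g0 <- grid[i - 1]; g1 <- grid[i]
    v0 <- profile[i - 1]; v1 <- profile[i]
    g0 + (thr - v0) / (v1 - v0) * (g1 - g0)
  }
  list(optimum = optimum, baseline = baseline, activation_time = act)
}

#' Activation statistics for every gene of a fitted profile set
#'
#' @param profiles a \code{\link{fit_gene_profiles}} result (single path:
#'   root to branch end).
#' @param f activation fraction (default 0.3).
#' @return data.frame with \code{gene_id}, \code{optimum},
#'   \code{baseline}, \code{activation_time}.
#' @export
activation_statistics <- function(profiles, f = 0.3) {
  pr <- Filter(Negate(is.null), profiles$paths)[[1]]
  out <- lapply(rownames(pr$values), function(g)
    estimate_activation(pr$values[g, ], pr$grid, f))
  data.frame(gene_id = rownames(pr$values),
             optimum = vapply(out, `[[`, numeric(1), "optimum"),
             baseline = vapply(out, `[[`, numeric(1), "baseline"),
             activation_time = vapply(out, `[[`, numeric(1),
                                      "activation_time"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split fork genes into early and late modules
#'
#' Early genes activate strictly before \code{early_threshold} (defaulting
#' to the fork pseudotime, configurable to values before it); all others,
#' including a gene activating exactly at the threshold, are late.
#'
#' @param activation named numeric vector of activation times (or an
#'   \code{\link{activation_statistics}} table).
#' @param fork a \code{\link{fork_definition}} (supplies the default
#'   threshold and the valid range).
#' @param early_threshold pseudotime threshold (default: fork pseudotime).
#' @param path_range optional pseudotime range of the path for validation.
#' @return named character vector "early"/"late" (NA activation -> NA).
#' @export
split_early_late <- function(activation, fork,
                             early_threshold = fork$fork_pseudotime,
                             path_range = NULL) {
  if (is.data.frame(activation))
    activation <- stats::setNames(activation$activation_time,
                                  activation$gene_id)
  if (!is.null(path_range) &&
      (early_threshold < path_range[1] || early_threshold > path_range[2]))
    stop("split_early_late: threshold outside the path's pseudotime range")
  out <- ifelse(is.na(activation), NA_character_,
                ifelse(activation < early_threshold, "early", "late"))
  stats::setNames(out, names(activation))
}
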