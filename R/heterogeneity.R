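#' Bootstrap unique-gene accumulation curve
#'
#' Cells are sampled one after the other with replacement; for each
#' sampled cell its \code{top_k} most expressed genes (raw counts, ties
#' broken by canonical gene order) are added to a cumulative union whose
#' size is recorded after every draw. The procedure is repeated
#' \code{n_reps} times and the mean and sd of the curve are reported; a
#' flat curve (low heterogeneity) means cells share their top genes.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param cells cell ids to sample from (e.g. all cells of one timepoint).
#' @param n_draws cells sampled per repetition (default 100).
#' @param top_k top genes per cell (default 100).
#' @param n_reps repetitions (default 100).
#' @param seed RNG seed.
#' @return list of class \code{bootstrap_curve}: \code{draws},
#'   \code{mean_unique}, \code{sd_unique}, \code{per_rep} (reps x draws
#'   matrix), and the parameters.
#' @export
bootstrap_gene_accumulation <- function(counts, cells, n_draws = 100,
                                        top_k = 100, n_reps = 100,
                                        seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"), length(cells) >= 1)
  idx <- match(cells, counts$cell_ids)
  if (anyNA(idx)) stop("bootstrap_gene_accumulation: unknown cell id")
  v <- as.matrix(counts$values[, idx, drop = FALSE])
  k <- min(top_k, nrow(v))
  # per-cell top-k gene indices; ties broken by gene order (canonical)
  tops <- lapply(seq_len(ncol(v)), function(j)
    order(-v[, j], seq_len(nrow(v)))[seq_len(k)])
  set.seed(seed)
  per_rep <- matrix(0L, n_reps, n_draws)
  for (r in seq_len(n_reps)) {
    draws <- sample.int(length(tops), n_draws, replace = TRUE)
    seen <- logical(nrow(v))
    for (d in seq_len(n_draws)) {
      seen[tops[[draws[d]]]] <- TRUE
      per_rep[r, d] <- sum(seen)
    }
  }
  structure(list(draws = seq_len(n_draws),
                 mean_unique = colMeans(per_rep),
                 sd_unique = apply(per_rep, 2, stats::sd),
                 per_rep = per_rep, n_reps = n_reps, n_draws = n_draws,
                 top_k = top_k),
            class = "bootstrap_curve")
}

#' @export
print.bootstrap_curve <- function(x, ...) {
  cat(sprintf(
    "bootstrap_curve: %d draws x %d reps (top %d); unique genes %g -> %g\n",
    x$n_draws, x$n_reps, x$top_k, x$mean_unique[1],
    x$mean_unique[x$n_draws]))
  invisible(x)
}

#' Back-trace identity genes shared by all trajectories
#'
#' A gene defines lineage identity when (i) it is activated in the
#' progenitor pool — its fitted profile over the pool cells (pseudotime
#' <= \code{t0}) has amplitude >= \code{min_amplitude}, an activation
#' time strictly below \code{t0}, and sustained activation (the profile
#' at the pool boundary stays at or above
#' \code{baseline + sustain * amplitude}; transient humps caused by
#' shared depth fluctuations are thereby rejected) — and (ii) on every
#' root-to-leaf trajectory it is present (count > 0 by default) in more
#' than \code{presence} of the cells beyond \code{t0}.
#'
#' @param expr \code{expression_matrix} or gene x cell log-expression
#'   matrix (used for presence when \code{counts} is NULL: value > 0).
#' @param projections projection table with \code{segment},
#'   \code{pseudotime}.
#' @param paths list of root-to-leaf segment paths (see
#'   \code{\link{segment_paths}} / \code{\link{tree_paths}}).
#' @param counts optional \code{\link{count_matrix}} for the raw-count
#'   presence rule.
#' @param t0 pool pseudotime threshold (default 6).
#' @param presence presence fraction threshold, strict (default 0.98).
#' @param f activation fraction (default 0.3).
#' @param gamma smoothing penalty (default 5).
#' @param min_amplitude minimum pool-profile amplitude (natural-log
#'   units) below which activation is undefined (default 0.5).
#' @param sustain fraction of the amplitude the profile must retain at
#'   the pool boundary (default 0.75).
#' @return list of class \code{identity_gene_set}: \code{genes},
#'   \code{presence} (gene x trajectory fractions),
#'   \code{activation_time}, \code{params}.
#' @export
trace_identity_genes <- function(expr, projections, paths, counts = NULL,
                                 t0 = 6, presence = 0.98, f = 0.3,
                                 gamma = 5, min_amplitude = 0.5,
                                 sustain = 0.75) {
  y <- .expr_values(expr)
  pres_mat <- if (is.null(counts)) y > 0 else {
    as.matrix(counts$values[rownames(y), colnames(y), drop = FALSE]) > 0
  }
  genes <- rownames(y)

  # (i) activation in the pool (cells at pseudotime <= t0)
  pool <- projections[projections$pseudotime <= t0, , drop = FALSE]
  if (nrow(pool) < 8) stop("trace_identity_genes: too few pool cells")
  pool <- pool[order(pool$pseudotime, pool$cell_id), ]
  sm <- .pspline_smoother(pool$pseudotime, gamma)
  coefs <- sm$v %*% t(y[, match(pool$cell_id, colnames(y)), drop = FALSE])
  grid <- seq(sm$range[1], sm$range[2], length.out = 104)
  grid <- grid[3:102]  # guard against spline boundary artifacts
  bg <- splines::splineDesign(sm$knots, grid, ord = 4, outer.ok = TRUE)
  prof <- t(bg %*% coefs)  # genes x grid
  act <- vapply(seq_len(nrow(prof)), function(i) {
    a <- estimate_activation(prof[i, ], grid, f)
    amp <- a$optimum - a$baseline
    if (amp < min_amplitude) return(NA_real_)
    if (prof[i, ncol(prof)] < a$baseline + sustain * amp) return(NA_real_)
    a$activation_time
  }, numeric(1))
  names(act) <- genes
  activated <- !is.na(act) & act < t0

  # (ii) presence beyond t0 on every trajectory
  frac <- matrix(NA_real_, length(genes), length(paths),
                 dimnames = list(genes, NULL))
  for (i in seq_along(paths)) {
    pc <- path_cells(projections, paths[[i]])
    late <- pc$cell_id[pc$pseudotime > t0]
    if (length(late) == 0)
      stop("trace_identity_genes: trajectory ", i, " has no cells beyond t0")
    frac[, i] <- rowMeans(pres_mat[, match(late, colnames(y)), drop = FALSE])
  }
  present_all <- apply(frac > presence, 1, all)

  structure(list(genes = genes[activated & present_all],
                 presence = frac, activation_time = act,
                 params = list(t0 = t0, presence = presence, f = f,
                               gamma = gamma,
                               min_amplitude = min_amplitude,
                               sustain = sustain)),
            class = "identity_gene_set")
}

#' Endpoint cluster markers
#'
#' Per cluster and gene: log2 fold change of the de-logged normalized mean
#' expression inside versus outside the cluster (pseudocount
#' \code{eps} = 0.1) and the fraction of cluster cells expressing the
#' gene. Markers satisfy log2fc > 1 and fraction > 0.9 (both strict).
#' Wilcoxon rank-sum p-values (BH-adjusted within cluster) are reported
#' alongside but are not part of the marker rule.
#'
#' @param expr \code{expression_matrix} or gene x cell log-expression
#'   matrix (natural log of normalized counts).
#' @param clusters named character vector: cell id -> endpoint cluster.
#' @param counts optional \code{\link{count_matrix}} for the
#'   fraction-expressed rule (default: expr > 0).
#' @param eps pseudocount in the fold change (default 0.1).
#' @return data.frame with \code{cluster}, \code{gene_id}, \code{log2fc},
#'   \code{fraction_expressed}, \code{p_value}, \code{q_value},
#'   \code{marker}.
#' @export
endpoint_markers <- function(expr, clusters, counts = NULL, eps = 0.1) {
  y <- .expr_values(expr)
  clusters <- clusters[intersect(names(clusters), colnames(y))]
  labs <- sort(unique(clusters))
  if (length(labs) < 2) stop("endpoint_markers: need >= 2 endpoint clusters")
  lin <- expm1(y)  # de-logged normalized expression
  pres <- if (is.null(counts)) y > 0 else
    as.matrix(counts$values[rownames(y), colnames(y), drop = FALSE]) > 0
  out <- list()
  for (cl in labs) {
    inside <- names(clusters)[clusters == cl]
    outside <- setdiff(names(clusters), inside)
    if (length(inside) < 2)
      warning("endpoint_markers: singleton cluster ", cl)
    ii <- match(inside, colnames(y))
    oo <- match(outside, colnames(y))
    m_in <- rowMeans(lin[, ii, drop = FALSE])
    m_out <- rowMeans(lin[, oo, drop = FALSE])
    l2fc <- log2((m_in + eps) / (m_out + eps))
    fr <- rowMeans(pres[, ii, drop = FALSE])
    p <- vapply(seq_len(nrow(y)), function(g) {
      if (stats::var(y[g, c(ii, oo)]) == 0) return(1)
      suppressWarnings(stats::wilcox.test(y[g, ii], y[g, oo],
                                          exact = FALSE)$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    out[[cl]] <- data.frame(cluster = cl, gene_id = rownames(y),
                            log2fc = as.numeric(l2fc),
                            fraction_expressed = as.numeric(fr),
                            p_value = p,
                            q_value = stats::p.adjust(p, method = "BH"),
                            marker = l2fc > 1 & fr > 0.9,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
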