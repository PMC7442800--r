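#' Simulation configuration for branching differentiation
#'
#' Describes a rooted branching topology over named segments, the gene
#' modules committed to those segments (sigmoidal activation programs
#' positioned in pseudotime), ubiquitous root-activated identity genes,
#' flat noise genes, and the count noise model (negative binomial with
#' optional dropout, per-cell depth variation, ERCC spike-in fractions).
#'
#' @param topology data.frame with columns \code{segment} (name),
#'   \code{parent} (name or \code{NA} for a root) and \code{length}
#'   (pseudotime units, > 0). Must describe a connected rooted tree or a
#'   forest with declared roots.
#' @param n_cells_per_segment cells placed uniformly along each segment.
#' @param modules data.frame with columns \code{name}, \code{segment}
#'   (segment of commitment), \code{n_genes}, \code{t_on}, \code{k},
#'   \code{o}, \code{b} (see \code{\link{evaluate_activation_profile}}).
#' @param n_identity_genes ubiquitous root-activated genes (expressed on
#'   every path, switched on early).
#' @param n_noise_genes genes with a flat expected profile.
#' @param nb_dispersion negative-binomial size parameter (variance
#'   \code{mu + mu^2/size}); \code{Inf} gives the Poisson limit.
#' @param dropout_rate independent Bernoulli zeroing probability applied
#'   after count sampling, in [0,1].
#' @param depth_mean,depth_cv mean and coefficient of variation of the
#'   log-normal per-cell depth factor.
#' @param ercc_fraction_mean mean per-cell ERCC spike-in count fraction.
#' @param n_ercc_genes number of simulated ERCC pseudo-genes.
#' @param bias_power exponent of the pre-fork fate-bias ramp (see Details).
#' @param seed integer RNG seed; identical seeds give identical datasets.
#'
#' @details Competing early modules are detected automatically: two modules
#'   committed to sibling segments whose \code{t_on} precedes the fork share
#'   their activation before the fork and diverge after it. Each pre-fork
#'   cell carries a latent fate bias \code{beta = U(-1,1) * (t/t_fork)^bias_power};
#'   the two modules' amplitudes are weighted \code{(1+beta)/2} and
#'   \code{(1-beta)/2}, so modules are co-activated near the root and become
#'   mutually exclusive toward the fork. On the committed branch the weight
#'   is 1; on the opposing branch a module collapses to its baseline.
#' @return A \code{simulation_config} object.
#' @export
simulation_config <- function(topology, n_cells_per_segment, modules,
                              n_identity_genes = 0, n_noise_genes = 0,
                              nb_dispersion = 5, dropout_rate = 0,
                              depth_mean = 1, depth_cv = 0.3,
                              ercc_fraction_mean = 0.05, n_ercc_genes = 20,
                              bias_power = 2, seed = 1L) {
  topology <- as.data.frame(topology)
  stopifnot(all(c("segment", "parent", "length") %in% names(topology)))
  topology$segment <- as.character(topology$segment)
  topology$parent <- as.character(topology$parent)
  if (nrow(topology) == 0) stop("simulation_config: empty topology")
  if (anyDuplicated(topology$segment))
    stop("simulation_config: duplicate segment names")
  if (any(topology$length <= 0)) stop("simulation_config: all lengths must be > 0")
  known <- topology$segment
  par <- topology$parent
  if (!all(is.na(par) | par %in% known))
    stop("simulation_config: parent references unknown segment")
  if (!any(is.na(par))) stop("simulation_config: no root segment (parent = NA)")
  # acyclicity/connectedness: every segment must reach a root
  for (s in known) {
    seen <- character()
    cur <- s
    repeat {
      p <- par[match(cur, known)]
      if (is.na(p)) break
      if (p %in% seen) stop("simulation_config: topology contains a cycle")
      seen <- c(seen, p)
      cur <- p
    }
  }
  if (!is.null(modules) && nrow(modules) > 0) {
    modules <- as.data.frame(modules)
    stopifnot(all(c("name", "segment", "n_genes", "t_on", "k", "o", "b") %in%
                    names(modules)))
    if (!all(modules$segment %in% known))
      stop("simulation_config: module referencing unknown segment")
    if (any(modules$k <= 0) || any(modules$o < modules$b))
      stop("simulation_config: modules require k > 0 and o >= b")
  } else {
    modules <- data.frame(name = character(), segment = character(),
                          n_genes = integer(), t_on = numeric(),
                          k = numeric(), o = numeric(), b = numeric())
  }
  stopifnot(n_cells_per_segment >= 1, n_identity_genes >= 0, n_noise_genes >= 0,
            nb_dispersion > 0, dropout_rate >= 0, dropout_rate <= 1,
            depth_mean > 0, depth_cv >= 0,
            ercc_fraction_mean >= 0, ercc_fraction_mean < 1)
  structure(list(topology = topology,
                 n_cells_per_segment = as.integer(n_cells_per_segment),
                 modules = modules,
                 n_identity_genes = as.integer(n_identity_genes),
                 n_noise_genes = as.integer(n_noise_genes),
                 nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 ercc_fraction_mean = ercc_fraction_mean,
                 n_ercc_genes = as.integer(n_ercc_genes),
                 bias_power = bias_power, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default two-fork branching configuration
#'
#' The package's reference simulation: a trunk of 6 pseudotime units forking
#' into two branches (a second fork subdivides one of them), 80 cells per
#' segment (400 cells), competing pre-fork early modules (t_on = 4), branch
#' exclusive late modules (t_on = 8 and 14), 40 ubiquitous root-activated
#' identity genes and 50 flat noise genes, with negative-binomial counts.
#'
#' @param seed integer RNG seed.
#' @param n_cells_per_segment cells per segment (default 80).
#' @param dropout_rate Bernoulli dropout probability (default 0; the deep
#'   Smart-seq2 regime in which zeros arise from count sampling).
#' @return A \code{\link{simulation_config}}.
#' @export
default_branching_config <- function(seed = 1L, n_cells_per_segment = 80,
                                     dropout_rate = 0) {
  topology <- data.frame(
    segment = c("trunk", "sensA", "sensB", "subA1", "subA2"),
    parent = c(NA, "trunk", "trunk", "sensA", "sensA"),
    length = c(6, 6, 6, 6, 6))
  modules <- data.frame(
    name = c("early_A", "early_B", "late_A", "late_B", "late_A1", "late_A2"),
    segment = c("sensA", "sensB", "sensA", "sensB", "subA1", "subA2"),
    n_genes = c(15, 15, 15, 15, 10, 10),
    t_on = c(4, 4, 8, 8, 14, 14),
    k = c(1.5, 1.5, 2, 2, 2, 2),
    o = c(3, 3, 3, 3, 3, 3),
    b = 0)
  simulation_config(topology, n_cells_per_segment = n_cells_per_segment,
                    modules = modules, n_identity_genes = 40,
                    n_noise_genes = 50, nb_dispersion = 5,
                    dropout_rate = dropout_rate, seed = seed)
}

# ancestors of a segment (strict, root-ward order)
.seg_ancestors <- function(topology, s) {
  out <- character()
  repeat {
    p <- topology$parent[match(s, topology$segment)]
    if (is.na(p)) return(out)
    out <- c(out, p)
    s <- p
  }
}

# descendants of a segment (strict)
.seg_descendants <- function(topology, s) {
  out <- character()
  frontier <- s
  while (length(frontier)) {
    kids <- topology$segment[!is.na(topology$parent) &
                               topology$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# absolute pseudotime at which a segment starts
.seg_start <- function(topology, s) {
  anc <- .seg_ancestors(topology, s)
  sum(topology$length[match(anc, topology$segment)])
}

# 2D planar layout of the segment tree -> principal_tree ground truth
.truth_tree <- function(topology) {
  segs <- topology$segment
  roots <- segs[is.na(topology$parent)]
  pos <- list()
  edges <- NULL
  node_of_seg_end <- character()
  add_node <- function(name, xy) {
    pos[[name]] <<- xy
    name
  }
  for (r in roots) add_node(paste0("start_", r), c(0, 0))
  lay <- function(s, origin, angle) {
    len <- topology$length[match(s, segs)]
    end <- origin + len * c(cos(angle), sin(angle))
    add_node(paste0("end_", s), end)
    kids <- segs[!is.na(topology$parent) & topology$parent == s]
    if (length(kids)) {
      spread <- 0.7
      angs <- angle + seq(-spread, spread, length.out = max(length(kids), 2))[
        seq_along(kids)]
      for (i in seq_along(kids)) lay(kids[i], end, angs[i])
    }
  }
  for (r in roots) lay(r, c(0, 0), 0)
  ids <- names(pos)
  node_positions <- do.call(rbind, pos)
  rownames(node_positions) <- ids
  edge_list <- lapply(segs, function(s) {
    p <- topology$parent[match(s, segs)]
    from <- if (is.na(p)) paste0("start_", s) else paste0("end_", p)
    c(match(from, ids), match(paste0("end_", s), ids))
  })
  edges <- do.call(rbind, edge_list)
  principal_tree(node_positions, edges,
                 roots = match(paste0("start_", roots), ids))
}

#' Simulate a branching scRNA-seq dataset with known ground truth
#'
#' Places cells uniformly in pseudotime along every segment of the
#' configured topology, computes each gene's expected log-expression from
#' its sigmoidal program (with pre-fork fate biasing for competing early
#' module pairs), draws negative-binomial counts scaled by a log-normal
#' per-cell depth factor, applies optional Bernoulli dropout, and appends
#' ERCC spike-in pseudo-genes whose per-cell count fraction is jittered
#' log-normally around \code{ercc_fraction_mean}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list of class \code{synthetic_dataset} with elements
#'   \code{counts} (\code{\link{count_matrix}}), \code{cells}
#'   (\code{\link{cell_annotation}}) and \code{truth} (true tree, per-cell
#'   pseudotime and segment, module membership, activation parameters,
#'   identity and noise gene ids).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  topo <- config$topology
  segs <- topo$segment
  n_per <- config$n_cells_per_segment

  seg_start <- vapply(segs, function(s) .seg_start(topo, s), numeric(1))
  names(seg_start) <- segs

  cell_segment <- rep(segs, each = n_per)
  offsets <- stats::runif(length(cell_segment))
  cell_time <- seg_start[cell_segment] +
    offsets * topo$length[match(cell_segment, segs)]
  n_cells <- length(cell_segment)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  names(cell_time) <- cell_ids

  # gene table: modules, identity, noise
  mods <- config$modules
  gene_rows <- list()
  if (nrow(mods) > 0) {
    for (i in seq_len(nrow(mods))) {
      n_g <- mods$n_genes[i]
      if (n_g > 0)
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          gene_id = sprintf("%s_g%02d", mods$name[i], seq_len(n_g)),
          module = mods$name[i], segment = mods$segment[i],
          t_on = mods$t_on[i], k = mods$k[i], o = mods$o[i], b = mods$b[i],
          kind = "module")
    }
  }
  if (config$n_identity_genes > 0) {
    n_g <- config$n_identity_genes
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      gene_id = sprintf("ident_g%02d", seq_len(n_g)),
      module = NA_character_, segment = NA_character_,
      t_on = stats::runif(n_g, 1.5, 3), k = stats::runif(n_g, 1.5, 2.5),
      o = stats::runif(n_g, 4, 5), b = 0, kind = "identity")
  }
  if (config$n_noise_genes > 0) {
    n_g <- config$n_noise_genes
    gene_rows[[length(gene_rows) + 1]] <- data.frame(
      gene_id = sprintf("noise_g%02d", seq_len(n_g)),
      module = NA_character_, segment = NA_character_,
      t_on = 0, k = 1, o = stats::runif(n_g, 2, 5), b = NA, kind = "noise")
  }
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes) || nrow(genes) == 0)
    stop("simulate_dataset: configuration defines no genes")

  # competing early-module pairs: sibling commitments with t_on before fork
  fork_of_module <- rep(NA_character_, nrow(mods))
  pair_sign <- rep(NA_real_, nrow(mods))
  if (nrow(mods) >= 2) {
    parent_of <- topo$parent[match(mods$segment, segs)]
    fork_time <- seg_start[mods$segment]
    for (p in unique(stats::na.omit(parent_of))) {
      idx <- which(!is.na(parent_of) & parent_of == p &
                     mods$t_on < fork_time)
      idx <- idx[!duplicated(mods$segment[idx])]
      if (length(idx) == 2) {
        fork_of_module[idx] <- p
        pair_sign[idx] <- c(1, -1)
      }
    }
  }

  # per-fork latent fate bias for pre-fork cells
  forks <- unique(stats::na.omit(fork_of_module))
  bias <- matrix(0, n_cells, length(forks),
                 dimnames = list(cell_ids, forks))
  for (f in forks) {
    fork_t <- seg_start[f] + topo$length[match(f, segs)]
    pre_segs <- c(f, .seg_ancestors(topo, f))
    on_pre <- cell_segment %in% pre_segs
    u <- stats::runif(sum(on_pre), -1, 1)
    bias[on_pre, f] <- u * (cell_time[on_pre] / fork_t)^config$bias_power
  }

  # expected log-expression
  mu <- matrix(0, nrow(genes), n_cells,
               dimnames = list(genes$gene_id, cell_ids))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$kind == "noise") {
      mu[i, ] <- g$o
      next
    }
    if (g$kind == "identity") {
      mu[i, ] <- evaluate_activation_profile(cell_time, g$t_on, g$k, g$o, g$b)
      next
    }
    mi <- match(g$module, mods$name)
    s <- g$segment
    own <- c(s, .seg_descendants(topo, s))
    anc <- .seg_ancestors(topo, s)
    w <- numeric(n_cells)
    w[cell_segment %in% own] <- 1
    if (!is.na(fork_of_module[mi])) {
      f <- fork_of_module[mi]
      pre_segs <- c(f, .seg_ancestors(topo, f))
      on_pre <- cell_segment %in% pre_segs
      w[on_pre] <- (1 + pair_sign[mi] * bias[on_pre, f]) / 2
    } else {
      w[cell_segment %in% anc] <- 1
    }
    sig <- evaluate_activation_profile(cell_time, g$t_on, g$k, g$o, g$b)
    mu[i, ] <- g$b + (sig - g$b) * w
  }

  # counts: depth-scaled negative binomial, then dropout
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  depth <- config$depth_mean * stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)
  lambda <- sweep(exp(mu), 2, depth / config$depth_mean, `*`)
  n_entries <- length(lambda)
  counts <- if (is.finite(config$nb_dispersion)) {
    matrix(stats::rnbinom(n_entries, mu = as.vector(lambda),
                          size = config$nb_dispersion),
           nrow(genes), n_cells)
  } else {
    matrix(stats::rpois(n_entries, as.vector(lambda)), nrow(genes), n_cells)
  }
  if (config$dropout_rate > 0) {
    keep <- matrix(stats::runif(n_entries) >= config$dropout_rate,
                   nrow(genes), n_cells)
    counts <- counts * keep
  }

  # ERCC pseudo-genes: per-cell fraction jittered log-normally,
  # depth-independent Poisson split over fixed proportions
  n_ercc <- config$n_ercc_genes
  if (n_ercc > 0) {
    prop <- 2^(-seq_len(n_ercc) / 3)
    prop <- prop / sum(prop)
    frac <- pmin(0.9, config$ercc_fraction_mean *
                   stats::rlnorm(n_cells, -0.3^2 / 2, 0.3))
    endo_tot <- colSums(counts)
    ercc_tot <- frac / (1 - frac) * endo_tot
    ercc <- matrix(stats::rpois(n_ercc * n_cells,
                                outer(prop, ercc_tot)), n_ercc, n_cells)
    counts <- rbind(counts, ercc)
    gene_ids <- c(genes$gene_id, sprintf("ERCC-%05d", seq_len(n_ercc)))
  } else {
    gene_ids <- genes$gene_id
  }

  cm <- count_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids)

  tp_breaks <- seq(0, max(cell_time) + 1e-9, length.out = 5)
  timepoint <- as.character(cut(cell_time, tp_breaks,
                                labels = c("E9.5", "E10.5", "E11.5", "E12.5"),
                                include.lowest = TRUE))
  cells <- cell_annotation(cell_ids, timepoint,
                           tracing_line = "synthetic",
                           cluster_label = cell_segment)

  membership <- stats::setNames(genes$module[genes$kind == "module"],
                                genes$gene_id[genes$kind == "module"])
  truth <- list(
    true_tree = .truth_tree(topo),
    true_pseudotime = stats::setNames(as.numeric(cell_time), cell_ids),
    true_segment = stats::setNames(cell_segment, cell_ids),
    module_membership = membership,
    activation_params = genes[genes$kind != "noise",
                              c("gene_id", "t_on", "k", "o", "b")],
    identity_gene_ids = genes$gene_id[genes$kind == "identity"],
    noise_gene_ids = genes$gene_id[genes$kind == "noise"])
  structure(list(counts = cm, cells = cells, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d cells, %d segments\n",
              length(x$counts$gene_ids), length(x$counts$cell_ids),
              nrow(x$config$topology)))
  invisible(x)
}

#' Ground-truth cell projections of a simulated dataset
#'
#' Packages the simulator's true pseudotime and segment labels in the same
#' table layout that \code{\link{compute_pseudotime}} produces, so every
#' downstream statistic can be run against the ground-truth ordering.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @return data.frame with columns \code{cell_id}, \code{pseudotime},
#'   \code{segment}, \code{assigned_root}.
#' @export
truth_projections <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  tr <- dataset$truth
  data.frame(cell_id = names(tr$true_pseudotime),
             pseudotime = as.numeric(tr$true_pseudotime),
             segment = as.character(tr$true_segment),
             assigned_root = "root", stringsAsFactors = FALSE)
}

#' Root-to-leaf segment paths of a simulated topology
#'
#' @param config a \code{\link{simulation_config}} (or a dataset's config).
#' @return list of character vectors of segment names, one per root-to-leaf
#'   path, ordered root first.
#' @export
segment_paths <- function(config) {
  if (inherits(config, "synthetic_dataset")) config <- config$config
  topo <- config$topology
  leaves <- setdiff(topo$segment, stats::na.omit(topo$parent))
  lapply(leaves, function(l) rev(c(l, .seg_ancestors(topo, l))))
}

#' Read/write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a \code{\link{simulation_config}} (for writing).
#' @return \code{read_simulation_config} returns a
#'   \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_config(
    topology = as.data.frame(lapply(x$topology, unlist),
                             stringsAsFactors = FALSE),
    n_cells_per_segment = x$n_cells_per_segment,
    modules = if (!is.null(x$modules))
      as.data.frame(lapply(x$modules, unlist), stringsAsFactors = FALSE)
    else NULL,
    n_identity_genes = x$n_identity_genes %||% 0,
    n_noise_genes = x$n_noise_genes %||% 0,
    nb_dispersion = x$nb_dispersion %||% 5,
    dropout_rate = x$dropout_rate %||% 0,
    depth_mean = x$depth_mean %||% 1,
    depth_cv = x$depth_cv %||% 0.3,
    ercc_fraction_mean = x$ercc_fraction_mean %||% 0.05,
    n_ercc_genes = x$n_ercc_genes %||% 20,
    seed = x$seed %||% 1L)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- config
  class(x) <- NULL
  x$topology <- as.list(x$topology)
  x$modules <- as.list(x$modules)
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
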