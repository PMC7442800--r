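# Shared fixtures, all generated in code.

# small two-branch topology for fast simulations
two_branch_config <- function(seed = 1, n_cells = 50, modules = NULL,
                              n_noise = 0, n_identity = 0, ...) {
  simulation_config(
    topology = data.frame(segment = c("trunk", "b1", "b2"),
                          parent = c(NA, "trunk", "trunk"), length = 6),
    n_cells_per_segment = n_cells, modules = modules,
    n_identity_genes = n_identity, n_noise_genes = n_noise,
    seed = seed, ...)
}

# noiseless points along an asymmetric Y skeleton (generic branching
# geometry; an exactly symmetric Y has a degenerate axis-collapsed
# stationary configuration)
make_y_points <- function(n = 300) {
  arms <- list(rbind(c(0, 0), c(0, 1)),
               rbind(c(0, 1), c(1.1, 1.7)),
               rbind(c(0, 1), c(-0.7, 2.0)))
  do.call(rbind, lapply(arms, function(a) {
    t <- seq(0, 1, length.out = n / 3)
    cbind(a[1, 1] + t * (a[2, 1] - a[1, 1]),
          a[1, 2] + t * (a[2, 2] - a[1, 2]))
  }))
}

# tiny deterministic count matrix
toy_counts <- function(n_genes = 5, n_cells = 4, seed = 42,
                       ercc_rows = 0) {
  set.seed(seed)
  ids <- c(sprintf("gene%02d", seq_len(n_genes - ercc_rows)),
           if (ercc_rows > 0) sprintf("ERCC-%05d", seq_len(ercc_rows)))
  m <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  count_matrix(m, gene_ids = ids,
               cell_ids = sprintf("c%02d", seq_len(n_cells)))
}

# brute-force BH adjustment: q_i = min_{j >= i} p_(j) * (m / j)
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * (m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
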