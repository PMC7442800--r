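fork_fixture <- function(seed = 1, n_cells = 50, o = 2, k = 3, t_on = 7,
                         n_genes = 30, n_noise = 100, ...) {
  two_branch_config(seed = seed, n_cells = n_cells,
                    modules = data.frame(name = c("m1", "m2"),
                                         segment = c("b1", "b2"),
                                         n_genes = n_genes, t_on = t_on,
                                         k = k, o = o, b = 0),
                    n_noise = n_noise, ...)
}

test_that("fork definitions validate branch disjointness", {
  expect_error(fork_definition("r", c("a", "b"), c("b", "c"), 1), "disjoint")
  fd <- topology_fork(fork_fixture(), "trunk")
  expect_equal(fd$fork_pseudotime, 6)
  expect_setequal(c(fd$branch1_segments, fd$branch2_segments), c("b1", "b2"))
  expect_error(topology_fork(fork_fixture(), "b1"), "two children")
})

test_that("exchangeable genes are not called fork genes", {
  ds <- simulate_dataset(fork_fixture(seed = 31, n_genes = 0, n_noise = 300))
  expr <- normalize_counts(ds$counts)
  ft <- test_fork_genes(expr, truth_projections(ds),
                        topology_fork(ds, "trunk"))
  expect_lte(mean(ft$fork_gene), 0.02)
})

test_that("strong branch-specific genes are detected and assigned", {
  ds <- simulate_dataset(fork_fixture(seed = 32))
  pr <- truth_projections(ds)
  expr <- normalize_counts(ds$counts)
  fork <- topology_fork(ds, "trunk")
  ft <- test_fork_genes(expr, pr, fork)
  m_rows <- grepl("^m[12]_", ft$gene_id)
  expect_gte(mean(ft$fork_gene[m_rows]), 0.9)
  expect_true(all(ft$q_branch[ft$fork_gene] < 0.05))
  # assignment against ground truth
  p1 <- fit_gene_profiles(expr, pr, list(c("trunk", "b1")))
  p2 <- fit_gene_profiles(expr, pr, list(c("trunk", "b2")))
  asg <- assign_branch_specific(ft, p1, p2, fork)
  tru_branch <- ifelse(grepl("^m1_", asg$gene_id), 1L, 2L)
  mod <- grepl("^m[12]_", asg$gene_id)
  expect_gte(mean(asg$assigned_branch[mod] == tru_branch[mod],
                  na.rm = TRUE), 0.9)
  expect_lte(mean(asg$assigned_branch[mod] != tru_branch[mod],
                  na.rm = TRUE), 0.05)
})

test_that("a pre-fork gene decaying on both branches fails the gate", {
  set.seed(33)
  n <- 60
  t <- c(seq(0, 6, length.out = n), seq(6, 12, length.out = n),
         seq(6, 12, length.out = n))
  pr <- data.frame(cell_id = sprintf("c%03d", seq_along(t)), pseudotime = t,
                   segment = rep(c("trunk", "b1", "b2"), each = n),
                   assigned_root = "root", stringsAsFactors = FALSE)
  decay <- 3 - 0.2 * t + rnorm(length(t), 0, 0.1)
  up1 <- ifelse(pr$segment == "b1", 0.5 * (t - 6), 0) +
    rnorm(length(t), 0, 0.1)
  y <- rbind(decay = decay, up1 = up1)
  colnames(y) <- pr$cell_id
  fork <- fork_definition("trunk", "b1", "b2", 6)
  ft <- test_fork_genes(y, pr, fork)
  expect_false(ft$fork_gene[ft$gene_id == "decay"])
  expect_true(ft$fork_gene[ft$gene_id == "up1"])
  # identical distribution on both branches: not a fork gene
  same <- rbind(g = rnorm(length(t)))
  colnames(same) <- pr$cell_id
  expect_false(test_fork_genes(same, pr, fork)$fork_gene)
})

test_that("fork-gene calls are calibrated under the exchangeable null", {
  fr <- numeric(20)
  for (r in 1:20) {
    ds <- simulate_dataset(fork_fixture(seed = 400 + r, n_genes = 0,
                                        n_noise = 500))
    expr <- normalize_counts(ds$counts)
    ft <- test_fork_genes(expr, truth_projections(ds),
                          topology_fork(ds, "trunk"))
    fr[r] <- mean(ft$fork_gene)
  }
  expect_lte(max(fr), 0.07)
})

test_that("activation timing follows the profile geometry", {
  # profile: 0 until t=3, then linear to optimum 10 at t=5; f = 0.3
  grid <- seq(0, 5, length.out = 501)
  prof <- ifelse(grid < 3, 0, (grid - 3) / 2 * 10)
  a <- estimate_activation(prof, grid, f = 0.3)
  expect_equal(a$optimum, 10)
  expect_equal(a$activation_time, 3.6, tolerance = 1e-6)
  # monotone profile: activation never after the optimum
  sigm <- evaluate_activation_profile(grid, 2, 3, 4, 0)
  am <- estimate_activation(sigm, grid)
  expect_lte(am$activation_time, grid[which.max(sigm)])
  # flat profile: activation undefined
  expect_true(is.na(estimate_activation(rep(2, 501), grid)$activation_time))
})

test_that("activation estimates recover the simulator's onset times", {
  cfg <- simulation_config(
    topology = data.frame(segment = "s", parent = NA, length = 12),
    n_cells_per_segment = 250,
    modules = data.frame(name = sprintf("w%02d", 1:12), segment = "s",
                         n_genes = 3, t_on = seq(1.5, 10, length.out = 12),
                         k = 2, o = 3, b = 0),
    n_noise_genes = 40, seed = 34)
  ds <- simulate_dataset(cfg)
  pr <- truth_projections(ds)
  expr <- normalize_counts(ds$counts)
  fp <- fit_gene_profiles(expr, pr, list("s"))
  act <- activation_statistics(fp)
  tru <- ds$truth$activation_params
  m <- merge(act, tru, by = "gene_id")
  m <- m[grepl("^w", m$gene_id), ]
  expect_gte(cor(m$activation_time, m$t_on, method = "spearman",
                 use = "complete.obs"), 0.8)
})

test_that("early/late split is strict at the threshold and symmetric", {
  fork <- fork_definition("trunk", "b1", "b2", 6)
  act <- c(gA = 4.8, gB = 6, gC = 7, gD = NA)
  lab <- split_early_late(act, fork)
  expect_equal(unname(lab["gA"]), "early")   # 0.8 * fork time
  expect_equal(unname(lab["gB"]), "late")    # exactly at threshold -> late
  expect_equal(unname(lab["gC"]), "late")
  expect_true(is.na(lab["gD"]))
  expect_error(split_early_late(act, fork, early_threshold = 99,
                                path_range = c(0, 12)), "outside")
  # invariance to branch relabelling: labels depend only on activation
  fork_swapped <- fork_definition("trunk", "b2", "b1", 6)
  expect_identical(lab, split_early_late(act, fork_swapped))
})

test_that("early/late labels recover constructed module timing", {
  cfg <- two_branch_config(seed = 35, n_cells = 80,
                           modules = data.frame(
                             name = c("early1", "early2", "late1", "late2"),
                             segment = c("b1", "b2", "b1", "b2"),
                             n_genes = 15, t_on = c(4, 4, 8, 8),
                             k = c(1.5, 1.5, 2, 2), o = 3, b = 0),
                           n_noise = 30)
  ds <- simulate_dataset(cfg)
  pr <- truth_projections(ds)
  expr <- normalize_counts(ds$counts)
  fork <- topology_fork(ds, "trunk")
  labs <- character()
  for (br in list(c("trunk", "b1"), c("trunk", "b2"))) {
    fp <- fit_gene_profiles(expr, pr, list(br))
    act <- activation_statistics(fp)
    keep <- grepl(if (br[2] == "b1") "^early1|^late1" else "^early2|^late2",
                  act$gene_id)
    labs <- c(labs, split_early_late(act[keep, ], fork))
  }
  tru <- ifelse(grepl("^early", names(labs)), "early", "late")
  expect_gte(mean(labs == tru, na.rm = TRUE), 0.95)
})
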