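# single-path projection table for constructed expression fixtures
line_projections <- function(t) {
  data.frame(cell_id = sprintf("c%03d", seq_along(t)), pseudotime = t,
             segment = "s1", assigned_root = "root",
             stringsAsFactors = FALSE)
}

test_that("association testing separates signal from constant genes", {
  set.seed(6)
  n <- 120
  t <- seq(0, 10, length.out = n)
  y <- rbind(ramp = 0.2 * t,                       # amplitude 2, noiseless
             flat = rep(3, n) + rnorm(n, 0, 1e-3)) # constant + tiny noise
  colnames(y) <- sprintf("c%03d", 1:n)
  res <- test_associated_genes(y, line_projections(t), list("s1"),
                               alpha = 0.05, A_min = 0.5)
  expect_true(res$associated[res$gene_id == "ramp"])
  expect_lt(res$q_value[res$gene_id == "ramp"], 1e-10)
  expect_false(res$associated[res$gene_id == "flat"])
  expect_gte(min(res$q_value - res$p_value), 0)
  # amplitude gate: strong trend but amplitude below A_min is not called
  y2 <- rbind(small = 0.02 * t, big = 0.5 * t)
  colnames(y2) <- sprintf("c%03d", 1:n)
  res2 <- test_associated_genes(y2, line_projections(t), list("s1"),
                                A_min = 0.5)
  expect_false(res2$associated[res2$gene_id == "small"])
  expect_true(res2$associated[res2$gene_id == "big"])
  expect_error(test_associated_genes(y[, 1:10], line_projections(t[1:10]),
                                     list("s1")), ">= 20 cells")
})

test_that("BH adjustment matches the brute-force formula", {
  # worked example: {0.01, 0.02, 0.03} -> all 0.03
  expect_equal(brute_force_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), brute_force_bh(p), tolerance = 1e-15)
  }
})

test_that("type-I error of the association test is controlled", {
  # pure-noise simulations: fraction called at alpha = 0.05 (A_min = 0)
  fr <- numeric(20)
  for (r in 1:20) {
    ds <- simulate_dataset(two_branch_config(seed = 100 + r, n_cells = 40,
                                             n_noise = 500, depth_cv = 0,
                                             ercc_fraction_mean = 0,
                                             n_ercc_genes = 0))
    expr <- normalize_counts(ds$counts)
    res <- test_associated_genes(expr, truth_projections(ds),
                                 segment_paths(ds), alpha = 0.05, A_min = 0)
    fr[r] <- mean(res$associated)
  }
  expect_lte(mean(fr), 0.07)
})

test_that("monotone sigmoid genes of amplitude >= 1 are detected", {
  hits <- numeric(10)
  for (r in 1:10) {
    cfg <- two_branch_config(seed = 200 + r, n_cells = 80,
                             modules = data.frame(name = "m", segment = "b1",
                                                  n_genes = 20, t_on = 6,
                                                  k = 1.5, o = 1.5, b = 0),
                             n_noise = 20)
    ds <- simulate_dataset(cfg)
    expr <- normalize_counts(ds$counts)
    res <- test_associated_genes(expr, truth_projections(ds),
                                 segment_paths(ds))
    hits[r] <- mean(res$associated[grepl("^m_", res$gene_id)])
  }
  expect_gte(mean(hits), 0.95)
})

test_that("profile fitting is accurate, bounded and penalty-limited", {
  set.seed(9)
  n <- 150
  t <- sort(runif(n, 0, 10))
  pr <- line_projections(t)
  y <- rbind(lin = 1 + 0.3 * t)
  colnames(y) <- pr$cell_id
  fp <- fit_gene_profiles(y, pr, list("s1"), gamma = 5)
  grid <- fp$paths[[1]]$grid
  inner <- grid > 0.5 & grid < 9.5
  expect_lt(max(abs(fp$paths[[1]]$values["lin", inner] -
                      (1 + 0.3 * grid[inner]))), 1e-3)
  expect_gte(length(grid), 100)

  # infinite-penalty limit: constant at the mean
  noisy <- rbind(g = 1 + 0.3 * t + rnorm(n, 0, 0.2))
  colnames(noisy) <- pr$cell_id
  fp_inf <- fit_gene_profiles(noisy, pr, list("s1"), gamma = 1e12)
  v <- fp_inf$paths[[1]]$values["g", ]
  expect_lt(diff(range(v)), 1e-3)
  expect_equal(mean(v), mean(noisy["g", ]), tolerance = 1e-2)

  # no overshoot beyond the observed maximum for monotone data
  mono <- rbind(g = evaluate_activation_profile(t, 5, 2, 3, 0) +
                  rnorm(n, 0, 0.05))
  colnames(mono) <- pr$cell_id
  fp_m <- fit_gene_profiles(mono, pr, list("s1"), gamma = 5)
  expect_lte(max(fp_m$paths[[1]]$values), max(mono["g", ]) + 1e-6)

  # paths with < 4 cells are unavailable, not extrapolated
  pr2 <- pr
  pr2$segment[4:n] <- "s2"
  expect_warning(fp2 <- fit_gene_profiles(y, pr2, list("s1"), gamma = 5),
                 "unavailable")
  expect_null(fp2$paths[[1]])
})

test_that("profile clustering recovers groups and honours n_patterns", {
  set.seed(10)
  t <- seq(0, 10, length.out = 80)
  pr <- line_projections(t)
  up <- evaluate_activation_profile(t, 3, 2, 2, 0)
  down <- 2 - up
  y <- rbind(matrix(rep(up, 6), 6, byrow = TRUE) + rnorm(6 * 80, 0, 0.01),
             matrix(rep(down, 6), 6, byrow = TRUE) + rnorm(6 * 80, 0, 0.01))
  rownames(y) <- sprintf("g%02d", 1:12)
  colnames(y) <- pr$cell_id
  fp <- fit_gene_profiles(y, pr, list("s1"))
  cl2 <- cluster_profiles(fp, n_patterns = 2)
  expect_equal(length(unique(cl2$pattern[1:6])), 1)
  expect_equal(length(unique(cl2$pattern[7:12])), 1)
  expect_false(cl2$pattern[1] == cl2$pattern[7])
  # n_patterns = gene count -> singletons
  cl12 <- cluster_profiles(fp, n_patterns = 12)
  expect_equal(length(unique(cl12$pattern)), 12)
  expect_error(cluster_profiles(fp, 13), "exceeds gene count")
  # input order invariance (up to label permutation)
  fp_rev <- fit_gene_profiles(y[12:1, ], pr, list("s1"))
  cl_rev <- cluster_profiles(fp_rev, n_patterns = 2)
  agree <- table(cl2$pattern[rownames(y)], cl_rev$pattern[rownames(y)])
  expect_equal(sum(agree > 0), 2)
})

test_that("thirty patterns come out non-empty when requested", {
  set.seed(11)
  t <- seq(0, 10, length.out = 60)
  pr <- line_projections(t)
  y <- matrix(rnorm(60 * 60), 60, 60,
              dimnames = list(sprintf("g%02d", 1:60), pr$cell_id))
  fp <- fit_gene_profiles(y, pr, list("s1"))
  cl <- cluster_profiles(fp, n_patterns = 30)
  expect_equal(length(unique(cl$pattern)), 30)
  expect_true(all(table(cl$pattern) >= 1))
})

test_that("branch comparison finds the crossing point and splits gene sets", {
  set.seed(12)
  sk_a <- list(points = cbind(seq(0, 1, length.out = 6), rep(0, 6)),
               pseudotime = seq(0, 10, length.out = 6))
  sk_b <- list(points = cbind(seq(0, 1, length.out = 6),
                              seq(-0.5, 0.5, length.out = 6)),
               pseudotime = seq(0, 10, length.out = 6))
  grid <- seq(0, 10, length.out = 100)
  vals <- rbind(a = evaluate_activation_profile(grid, 3, 2, 2, 0),
                b = evaluate_activation_profile(grid, 7, 2, 2, 0),
                c = rnorm(100, 0, 0.05))
  prof <- structure(list(paths = list(list(grid = grid, values = vals,
                                           segments = "s")),
                         genes = rownames(vals), gamma = 5),
                    class = "fitted_profiles")
  ba <- branch_description(c("a", "b"), prof, sk_a)
  bb <- branch_description(c("b", "c"), prof, sk_b)
  bc <- compare_branches(ba, bb)
  # skeletons cross at (0.5, 0): recovered within grid resolution
  expect_lt(sum((bc$common_point$coords_a - c(0.5, 0))^2), 1e-3)
  expect_lt(bc$common_point$distance, 0.01)
  expect_setequal(bc$common_genes, "b")
  expect_equal(unname(bc$branch_specific["a"]), "A")
  expect_equal(unname(bc$branch_specific["c"]), "B")
  # identical gene sets -> no branch-specific genes
  bc2 <- compare_branches(branch_description(c("a", "b"), prof, sk_a),
                          branch_description(c("a", "b"), prof, sk_b))
  expect_length(bc2$branch_specific, 0)
  expect_error(compare_branches(branch_description(character(), prof, sk_a),
                                bb), "empty association")
})

test_that("TF activity tracks its module and shrinks with the penalty", {
  set.seed(13)
  grid_n <- 50
  mod_mean <- sin(seq(0, pi, length.out = grid_n)) * 2
  genes <- sprintf("g%02d", 1:40)
  y <- matrix(0, 40, grid_n, dimnames = list(genes, NULL))
  y[1:10, ] <- matrix(rep(mod_mean, each = 10), 10)
  tm <- make_target_matrix(genes, list(TF1 = genes[1:10],
                                       decoy = sample(genes[11:40], 10)))
  act <- infer_tf_activity(y, tm, alpha = 0.5)
  inner <- 2:(grid_n - 1)
  expect_gt(cor(act$activity["TF1", inner], mod_mean[inner]), 0.999)
  expect_true(all(act$activity["decoy", ] == 0))
  # L1 limit: huge alpha kills every activity
  expect_true(all(infer_tf_activity(y, tm, alpha = 1e8)$activity == 0))
  # alpha = 0 equals the least-squares solution on invertible designs
  m <- diag(3); colnames(m) <- paste0("t", 1:3)
  a0 <- infer_tf_activity(matrix(c(1, 2, 3), 3, 1), m, alpha = 0)
  expect_equal(as.vector(a0$activity), c(1, 2, 3))
  expect_error(infer_tf_activity(y, matrix(0, 40, 2)), "all-zero")
})

test_that("coordinate-descent lasso agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  set.seed(14)
  for (i in 1:5) {
    m <- matrix(rbinom(40 * 5, 1, 0.3), 40, 5)
    y <- rnorm(40)
    alpha <- runif(1, 0.1, 2)
    own <- forkdyn:::.lasso_cd(m, y, alpha)
    ref <- as.vector(stats::coef(glmnet::glmnet(
      m, y, lambda = alpha / (2 * 40), standardize = FALSE,
      intercept = FALSE, thresh = 1e-12)))[-1]
    expect_equal(own, ref, tolerance = 1e-5)
  }
})
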