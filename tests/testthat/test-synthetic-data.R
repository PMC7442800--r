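test_that("activation profile follows the logistic form", {
  # midpoint: halfway between baseline and optimum
  expect_equal(evaluate_activation_profile(0, t_on = 0, k = 1, o = 10, b = 0), 5)
  # saturation limit
  expect_equal(evaluate_activation_profile(1e6, t_on = 0, k = 2, o = 7, b = 0), 7)
  # closed-form evaluation: 1 / (1 + exp(-2))
  expect_equal(evaluate_activation_profile(2, t_on = 0, k = 1, o = 1, b = 0),
               1 / (1 + exp(-2)), tolerance = 1e-12)
  # strictly increasing in t
  t <- seq(-5, 5, length.out = 50)
  v <- evaluate_activation_profile(t, 0, 1.3, 4, 1)
  expect_true(all(diff(v) > 0))
  expect_error(evaluate_activation_profile(0, 0, -1, 1, 0), "k must be")
  expect_error(evaluate_activation_profile(0, 0, 1, 0, 1), "o must be")
  expect_error(evaluate_activation_profile(NA_real_, 0, 1, 1, 0), "non-finite")
})

test_that("simulated datasets have the configured shape and are seeded", {
  cfg <- two_branch_config(seed = 11, n_cells = 50,
                           modules = data.frame(name = "m", segment = "b1",
                                                n_genes = 10, t_on = 7,
                                                k = 2, o = 3, b = 0))
  # dimension bookkeeping: 10 genes + 20 ERCC x 150 cells
  ds <- simulate_dataset(cfg)
  expect_equal(dim(ds$counts), c(10 + 20, 150))
  expect_equal(sum(ds$counts$is_spikein), 20)
  expect_equal(nrow(ds$cells), 150)
  # determinism: identical seeds give identical counts
  ds2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(ds$counts$values), as.matrix(ds2$counts$values))
  # different seeds differ
  cfg3 <- two_branch_config(seed = 12, n_cells = 50,
                            modules = cfg$modules)
  ds3 <- simulate_dataset(cfg3)
  expect_false(identical(as.matrix(ds$counts$values),
                         as.matrix(ds3$counts$values)))
  # root cells start at pseudotime 0, all cells within topology range
  expect_gte(min(ds$truth$true_pseudotime), 0)
  expect_lte(max(ds$truth$true_pseudotime), 12)
  # every gene in exactly one compartment
  tr <- ds$truth
  all_ids <- ds$counts$gene_ids[!ds$counts$is_spikein]
  expect_setequal(all_ids, c(names(tr$module_membership),
                             tr$identity_gene_ids, tr$noise_gene_ids))
})

test_that("config validation rejects malformed topologies and modules", {
  expect_error(simulation_config(data.frame(segment = character(),
                                            parent = character(),
                                            length = numeric()),
                                 10, NULL), "empty topology")
  expect_error(two_branch_config(modules = data.frame(
    name = "m", segment = "nope", n_genes = 5, t_on = 1, k = 1, o = 1,
    b = 0)), "unknown segment")
  bad <- data.frame(segment = c("a", "b"), parent = c("b", "a"),
                    length = 1)
  expect_error(simulation_config(bad, 10, NULL), "root|cycle")
})

test_that("generator means match its own profile in the Poisson limit", {
  # dropout 0, dispersion -> Inf (Poisson), no depth variation
  cfg <- simulation_config(
    topology = data.frame(segment = "s", parent = NA, length = 4),
    n_cells_per_segment = 1000,
    modules = data.frame(name = "m", segment = "s", n_genes = 5,
                         t_on = 2, k = 1.5, o = 3, b = 0),
    nb_dispersion = Inf, dropout_rate = 0, depth_cv = 0,
    ercc_fraction_mean = 0, n_ercc_genes = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  t <- ds$truth$true_pseudotime
  for (g in sprintf("m_g%02d", 1:5)) {
    expected <- mean(exp(evaluate_activation_profile(t, 2, 1.5, 3, 0)))
    observed <- mean(ds$counts$values[g, ])
    expect_lt(abs(observed - expected) / expected, 0.05)
  }
})

test_that("expected expression is monotone along the committed path", {
  cfg <- two_branch_config(seed = 2, n_cells = 120,
                           modules = data.frame(name = c("mA", "mB"),
                                                segment = c("b1", "b2"),
                                                n_genes = 8, t_on = 4,
                                                k = 1.5, o = 3, b = 0),
                           nb_dispersion = Inf, depth_cv = 0)
  ds <- simulate_dataset(cfg)
  pr <- truth_projections(ds)
  on_path <- pr$segment %in% c("trunk", "b1")
  ord <- order(pr$pseudotime[on_path])
  cells <- pr$cell_id[on_path][ord]
  # the expected (noiseless) profile is non-decreasing along the path
  t_path <- sort(pr$pseudotime[on_path])
  mu <- evaluate_activation_profile(t_path, 4, 1.5, 3, 0)
  expect_true(all(diff(mu) >= 0))
  # and binned log counts of a committed gene rise accordingly
  v <- log1p(as.numeric(ds$counts$values["mA_g01", cells]))
  bins <- split(v, cut(seq_along(v), 6))
  bm <- vapply(bins, mean, numeric(1))
  expect_true(all(diff(bm) > -0.2))
  expect_gt(bm[6], bm[1] + 1)
})

test_that("competing early modules are co-activated then exclusive", {
  # noiseless limit: Poisson with large optimum, no depth variation
  cfg <- two_branch_config(seed = 3, n_cells = 200,
                           modules = data.frame(name = c("eA", "eB"),
                                                segment = c("b1", "b2"),
                                                n_genes = 4, t_on = 4,
                                                k = 2, o = 5, b = 0),
                           nb_dispersion = Inf, depth_cv = 0,
                           ercc_fraction_mean = 0, n_ercc_genes = 0)
  ds <- simulate_dataset(cfg)
  pr <- truth_projections(ds)
  y <- log1p(as.matrix(ds$counts$values))
  pre <- pr$cell_id[pr$segment == "trunk" & pr$pseudotime > 2]
  post <- pr$cell_id[pr$segment %in% c("b1", "b2")]
  # same-module genes strongly positively correlated pre-fork
  expect_gt(cor(y["eA_g01", pre], y["eA_g02", pre]), 0.5)
  # opposing early modules anti-correlated over pooled post-fork cells
  expect_lt(cor(y["eA_g01", post], y["eB_g01", post]), -0.3)
})

test_that("ERCC spike-in fractions are controlled by the config", {
  ds <- simulate_dataset(two_branch_config(seed = 4, n_cells = 60,
                                           n_noise = 30,
                                           ercc_fraction_mean = 0.1))
  v <- ds$counts$values
  frac <- Matrix::colSums(v[ds$counts$is_spikein, ]) / Matrix::colSums(v)
  expect_gt(mean(frac), 0.06)
  expect_lt(mean(frac), 0.16)
})

test_that("dropout zeroes the configured fraction of counts", {
  cfg0 <- two_branch_config(seed = 9, n_cells = 100, n_noise = 50)
  cfg3 <- two_branch_config(seed = 9, n_cells = 100, n_noise = 50,
                            dropout_rate = 0.3)
  z0 <- mean(as.matrix(simulate_dataset(cfg0)$counts$values) == 0)
  z3 <- mean(as.matrix(simulate_dataset(cfg3)$counts$values) == 0)
  expect_gt(z3, z0 + 0.15)
})

test_that("config round-trips through YAML", {
  cfg <- two_branch_config(seed = 8, n_cells = 25, n_noise = 10)
  path <- tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_identical(
    as.matrix(simulate_dataset(cfg)$counts$values),
    as.matrix(simulate_dataset(cfg2)$counts$values))
})
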