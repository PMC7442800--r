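# forkdyn

Branching-trajectory pseudotime analysis for single-cell RNA-seq, built
around the statistics used to dissect binary fate decisions in developing
lineages (the motivating system is sensory neurogenesis: neural crest
progenitors splitting into proprioceptor, mechanoreceptor and nociceptor
fates through successive bi-potential intermediates).

The pipeline, end to end:

1. **QC & normalization** — Smart-seq2 style cell filtering (≥ 5×10⁴
   transcripts, ≥ 2500 genes, ≤ 25% ERCC reads), median-depth scaling,
   ln(1+x), trend-residual overdispersed-gene selection.
2. **Embedding & tree** — diffusion maps with an adaptive kNN Gaussian
   kernel, then an *elastic principal tree*: node positions `v` minimizing

   ```
   E = (1/N) Σᵢ ‖xᵢ − v_a(i)‖²  +  λ Σ_(u,v)∈E ‖v_u − v_v‖²
       + μ Σ_{deg(j)≥2} ‖v_j − mean(neighbours of j)‖²
   ```

   grown by grammar moves (bisect an edge / add a node to a node) with
   closed-form quadratic updates, plus semi-supervised stitching
   (attach centroids, fitted subtrees or principal curves) and midpoint
   edge subdivision.
3. **Pseudotime** — cells project to the closest point on the tree;
   pseudotime is the along-graph distance to a root (two-root trees are
   partitioned by segment).
4. **Gene statistics** — spline-vs-constant F-tests with BH FDR and an
   amplitude gate; penalized-spline profiles (γ = 5); Ward/Euclidean
   pattern clustering (30 patterns); two-branch comparison from the
   inferred closest common point; lasso TF-activity inference
   (min ‖y − Ma‖² + α‖a‖₁, coordinate descent).
5. **Bifurcations** — rank-sum fork-gene tests with an upregulation gate,
   branch assignment, activation timing (t where the fitted profile
   reaches baseline + 0.3·amplitude), early/late module splits at the
   fork pseudotime.
6. **Module dynamics** — sliding-window (w = 40, s = 10) intra-/inter-
   module local Pearson correlations and the repulsion statistic
   `|mean(intra_A, intra_B) − inter|`.
7. **Heterogeneity & identity** — bootstrap unique-gene accumulation
   curves (100 cells × top-100 genes × 100 reps); identity-gene
   back-tracing (activated at pseudotime < 6, present in > 98% of later
   cells on every trajectory); endpoint markers (log2fc > 1 and > 90%
   expressed, both strict).

A negative-binomial branching-differentiation simulator with full ground
truth (topology, per-cell pseudotime, module membership, activation
parameters, competing pre-fork fate biasing, ERCC spike-ins) makes every
stage testable without external data.

## Worked example

```r
library(forkdyn)

ds <- simulate_dataset(default_branching_config(seed = 1))
ds$counts
#> count_matrix: 190 genes (20 spike-ins) x 400 cells

res <- run_trajectory_pipeline(ds$counts, ds$cells$timepoint, seed = 1)
res$tree
#> principal_tree: 39 nodes, 38 edges, 5 leaves, dim 5
head(res$projections[, c("cell_id", "pseudotime", "segment")], 3)
#>     cell_id pseudotime segment
#> 1 cell_0001 0.00000000  seg_03
#> 2 cell_0002 0.05348405  seg_03
#> 3 cell_0003 0.63916186  seg_03
```

The fitted tree tracks the simulated two-fork topology — the root end,
the three branch tips, and here one short spurious stub (harmless for
pseudotime: per-trajectory Spearman correlation with the true ordering
exceeds 0.96, as `scripts/acceptance.R` recomputes). Downstream statistics run on any cell ordering —
here the ground-truth ordering, so the numbers can be read against the
construction:

```r
pr   <- truth_projections(ds)
expr <- normalize_counts(ds$counts)

assoc <- test_associated_genes(expr, pr, segment_paths(ds))
sum(assoc$associated)
#> 170          # every non-spike-in gene varies along this tree

fork <- topology_fork(ds, "trunk")
ft <- test_fork_genes(expr, pr, fork)
sum(ft$fork_gene)
#> 75           # branch-specific upregulated genes at the first fork

ws <- build_windows(path_cells(pr, c("trunk", "sensA", "subA1")))
tr <- module_correlation_track(expr, ws,
        grep("^early_A", rownames(expr$values), value = TRUE),
        grep("^early_B", rownames(expr$values), value = TRUE))
round(tr[c(1, 5, 8), c("center", "intra_A", "inter", "repulsion")], 3)
#>   center intra_A  inter repulsion
#> 1  1.770  -0.010  0.007     0.008
#> 5  4.538   0.279 -0.154     0.428
#> 8  6.763   0.559 -0.422     0.881

ids <- trace_identity_genes(expr, pr, segment_paths(ds), counts = ds$counts)
length(ids$genes)
#> 40           # the constructed ubiquitous root-activated set, exactly
```

The repulsion track is the package's central readout: near the root the
two competing early modules are uncorrelated with each other
(repulsion ≈ 0); approaching the bifurcation at pseudotime 6,
within-module coordination rises (`intra_A` 0.28 → 0.56) while the
modules become antagonistic (`inter` −0.15 → −0.42), so repulsion climbs
to ≈ 0.9 — co-activation resolving into mutual exclusivity before the
fate split.

The methods vignette (`vignettes/branching-trajectories.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.

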