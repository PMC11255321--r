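# qdiffuse

Deformed kernel geometry for full-transcriptome single-cell analysis.

Most single-cell pipelines discard the bulk of the gene library (variable-gene
selection, PCA) before comparing cells, which erases phenotype differences
that are *diffuse*: small coordinated shifts spread across hundreds of genes,
each one below the noise floor. `qdiffuse` compares cells with a
Tsallis-deformed kernel whose squared norm adds discounted products of squared
per-gene differences over every subset of genes,

```
||v||_q^2 = Σ v_i^2  +  α Σ_{i<j} v_i^2 v_j^2  +  α^2 Σ_{i<j<k} v_i^2 v_j^2 v_k^2  +  ...,
α = q − 1,  1 < q ≤ 2,
```

so that differences occurring in many genes concurrently reinforce each other,
while the identity `1 + α‖v‖_q² = Π_i (1 + α v_i²)` keeps evaluation linear in
the number of genes via log-space accumulation. The kernel
`f(v) = exp_q(−‖v/φ‖_q² / ρ²)` carries an inner bandwidth `φ` (a soft
threshold on per-gene differences, chosen as the square root of the median
per-gene pair scatter) and an adaptive, anisotropic outer bandwidth `ρ` (each
cell's k-th nearest deformed norm). On top of this geometry the package
provides:

* **Affinity graphs and clustering** — symmetrized adaptive-bandwidth kernel
  graphs, Leiden community detection (modularity), adjusted Rand index.
* **qNMF** — graph-regularized nonnegative matrix factorization
  (`‖X − WH‖²_F + λ tr(H L Hᵀ)`, monotone multiplicative updates) for gene
  expression programs, plus nonnegative least-squares projection of new
  profiles and sparsity-based weight binarization.
* **qPHATE** — a diffusion-potential (PHATE-style) embedding driven by the
  deformed kernel, with automatic diffusion time by von Neumann entropy.
* **LDS** — local distributional segmentation of spatial transcriptomics:
  k-means "rexels", pairwise maximum-mean-discrepancy distances between rexel
  transcriptome distributions, Leiden/Ward segmentation, and a spatial
  silhouette score.
* **Differential expression** — earth-mover's-distance permutation tests,
  Mann–Whitney U tests, Benjamini–Hochberg correction, Jaccard set
  comparison.
* **Synthetic data + benchmark harness** — seeded generators for
  two-phenotype experiments with tunable noise and signal diffusion, striped
  spatial tissue, and a grid benchmark comparing the deformed geometry
  against the undeformed (Gaussian, q → 1) baseline.

An undeformed baseline (`kernel = "gaussian"`) runs the identical
adaptive-bandwidth pipeline with the plain exponential, so every comparison is
like for like.

## Worked example

Two phenotypes whose separation is spread over 160 of 200 genes (per-gene
shift ≈ 0.97, under per-gene noise that is larger for high-mean genes):

```r
library(qdiffuse)

sim <- simulate_two_phenotypes(n_cells = 400, m_genes = 200,
                               d_signal = 160, total_effect = 150,
                               noise_sd = 1, seed = 1)

graph <- q_affinity(sim$X, qparams(q = 1.2, k = 15))
graph
#> q_affinity: 400 cells, q kernel, q = 1.2, k = 15, phi = 1.365
#>   rho: [1.336e+09, 5.49e+11]

clusters <- leiden_cluster(graph, seed = 1)
adjusted_rand_index(clusters, sim$labels)
#> [1] 1

baseline <- q_affinity(sim$X, qparams(k = 15), kernel = "gaussian")
adjusted_rand_index(leiden_cluster(baseline, seed = 1), sim$labels)
#> [1] 0.618319
```

The deformed graph recovers the two phenotypes perfectly (ARI 1); the
undeformed baseline, fed exactly the same matrix, bandwidth heuristic and
neighbourhood size, badly fragments them (ARI 0.62) because the diffuse
per-gene signal is drowned by a few high-variance genes. At larger sizes the
gap widens: on the benchmark grid at 1000 cells × 500 genes (noise 1,
signal over 400 genes) the deformed graph scores mean ARI ≈ 1.00 against
≈ 0.01 for the Gaussian one.
(The enormous adaptive `rho` values are expected: deformed norms grow
multiplicatively with the number of participating genes, and the outer
bandwidth absorbs that scale.) With a *concentrated* signal
(`d_signal = 5`) both geometries score ARI 1 — the advantage is specific to
the diffuse regime. `run_benchmark_grid()` tabulates this over a noise ×
diffusion grid with standard errors, and `autoplot()` draws it.

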