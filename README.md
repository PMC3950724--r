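# ganet — fast mutual-information gene association networks

`ganet` reconstructs genome-scale **gene association networks (GANs)** from
normalized expression compendia (microarray or RNA-seq), and answers a
question most network-inference tools leave open: *under which experimental
conditions does each inferred association actually operate?*

It is aimed at systems biologists working with large expression
compendia — hundreds to thousands of chips — especially for organisms
(e.g. plants) whose genome size makes kernel-density MI estimation
impractical at all-pairs scale.

## The method

**1. Spearman-transform mutual information.** For a bivariate normal with
correlation ρ, mutual information has the closed form

&nbsp;&nbsp;&nbsp;&nbsp;*I* = −½ · ln(1 − ρ²)   (nats)

`ganet` ranks each gene across samples and plugs the Spearman rank
correlation ρₛ (the Pearson correlation of the ranks, exact under ties)
into this formula. Ranking makes the estimate invariant under any
strictly increasing per-gene transform, so monotone nonlinear dependence
is captured, at O(n²·m) total cost after an O(n·m·log m) ranking step —
orders of magnitude faster than the Gaussian-kernel estimator (also
provided, as the ARACNE-compatible baseline).

**2. Thresholding + DPI.** The default MI threshold keeps the top 10% of
all gene pairs. Likely indirect edges are then removed with the **data
processing inequality**: in a triangle, edge (i,j) is removed iff some
common neighbour k has MI(i,j) < (1−ε)·MI(i,k) **and** MI(i,j) <
(1−ε)·MI(j,k). Tolerance ε = 1 removes nothing (the "coarse" relevance
network); a chain of strictly tightening `refine()` calls implements
coarse-to-fine refinement and is path-independent.

**3. MCL subnetworks.** The weighted network is partitioned into
functional subnetworks with the Markov Clustering Algorithm (expansion,
inflation, prune, renormalize, to a fixed point).

**4. Condition-removing test.** For every edge, the pair's MI is
recomputed m times leaving out one chip at a time; the leave-one-out MI
series is approximately normal for large compendia, so a one-sided
z-test (lower tail) flags chips whose removal significantly reduces MI —
the conditions under which the association operates (default p ≤ 1e-4,
top 10 chips per edge).

**5. Benchmark harness.** A SynTReN-style simulator (scale-free
topology, Hill-type transfer functions, propagated biological noise,
additive measurement noise) plus AUROC / precision-recall / F-score
evaluation against the known topology.

## Worked example

```r
library(ganet)

cfg  <- simulation_config(n_genes = 50, n_samples = 300, seed = 42)
gold <- generate_topology(cfg)          # known regulatory topology
ds   <- simulate_expression(gold, cfg)  # steady-state expression, 50 x 300

net <- build_network(ds$expression, threshold_config(0.10), dpi_config(1.0))
net
#> Network: 37 nodes, 123 edges (MI threshold 0.193, DPI tolerance 1)

refined <- refine(net, new_dpi = dpi_config(0.155))
refined
#> Network: 37 nodes, 88 edges (MI threshold 0.193, DPI tolerance 0.155)

mcl_cluster(refined)
#> MCL partition: 37 nodes in 6 clusters (sizes: 14, 10, 4, 4, 3, 2)

evaluate_scores(pairwise_mi(ds$expression), gold, called = refined$edges)
#> BenchmarkResult: AUROC 0.8339, F 0.4260 (1224 thresholds)
```

The coarse pass keeps the top decile of the 1225 pair MIs (threshold
0.193 nats) — the relevance network. Tightening the DPI tolerance to the
refined setting 0.155 removes 35 likely indirect edges. Scoring all
pairs against the generating topology gives AUROC 0.83; F = 0.43 is
computed at the refined network as the operating point.

The same flow is available from the command line:

```sh
exec/ganet simulate --n-genes 50 --n-samples 300 --seed 42 --output sim
exec/ganet build --input sim_expression.tsv --keep-top 0.10 --dpi-tolerance 1.0 --output net
exec/ganet refine --network net --dpi-tolerance 0.155 --output net2
exec/ganet cluster --edges net2/edges.tsv --inflation 2.0 --output clusters.tsv
exec/ganet conditions --edges net2/edges.tsv --input sim_expression.tsv --alpha 1e-4 --top-k 10
```

All outputs are tab-delimited, `#`-headed with provenance (version,
config hash, seed), and import directly into Cytoscape.

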