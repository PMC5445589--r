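# subnetbench

Synthetic gold standards and a scoring harness for **de novo pathway
enrichment** (active-subnetwork extraction) methods.

## The problem

De novo pathway enrichment tools take a large molecular interaction network
*G = (V, E)* and condition-specific expression data, and extract a
condition-associated subnetwork without restricting the search to predefined
pathways. There is no real gold standard for this task, which makes the
tools hard to compare: nobody knows the "true" module in a patient cohort.

subnetbench sidesteps this by *planting* the truth. It labels a foreground
(FG) node set in the network, simulates case/control expression in which FG
genes carry a controllable signal against the background (BG) genes, runs
any subnetwork-extraction method on the simulated data, and scores the
predicted node set against the planted FG with node-level precision, recall
and F-measure. Difficulty is controlled on two axes:

* **Signal strength** — how different FG expression is from BG expression.
  Under the varying-mean (VM) model, FG genes in cases follow
  *N(μ_FG, v)*, FG genes in controls *N(μ_FGC, v)* and BG genes *N(0, v)*
  with *v* = 1; signal strength is *μ_FG − μ_FGC*. Under the
  varying-variance (VV) model, FG genes in cases follow *N(μ, v_FG)* and
  everything else *N(μ, v_BG)* with *μ* = 0; signal strength is
  *v_FG / v_BG*.
* **Sparsity** — how spread-out the FG nodes are over the network.
  Seed-and-extend (SAE) grows a connected FG set breadth-first from a random
  seed. The average-distance-k (AVD_k) selector finds an FG set whose
  average pairwise shortest-path distance is *k ± α* (α = 1 by default);
  the underlying subset-selection problem is NP-complete, so a restarting
  greedy heuristic is used, with exhaustive enumeration as an exact oracle
  on small instances. Three metrics quantify the result: global FG proximity
  (approximate Steiner-tree size covering FG), global FG connectivity (mean
  FG degree in the network) and local FG density (edge density of the
  FG-induced subgraph).

The package is aimed at method developers who want a bias-free benchmark for
their extraction algorithm, and at analysts choosing between existing tools.
External tools plug in through a subprocess adapter contract; two built-in
baselines (`top_n_differential`, `greedy_module`) make the harness
self-contained.

## A worked example

```r
library(subnetbench)

net <- generate_synthetic_network("preferential_attachment", 500, seed = 42)
split <- avd_k_greedy(net, n = 20, k = 3, alpha = 1, seed = 1)
split
#> <gold_standard_split> AVDk | FG 20 nodes, BG 480 nodes | avg pairwise distance 3.000

sparsity_report(net, split)
#> # A tibble: 1 × 5
#>    n_fg global_proximity global_connectivity local_density avg_pairwise_distance
#> 1    20               27                7.85        0.0421                     3

dataset <- simulate_expression(net, split,
                               simulation_config("VM", mu_fg = 1.5, mu_fgc = 0, seed = 2))
dataset
#> <expression_dataset> 500 genes x 110 samples (100 case, 10 control) | model VM

pred <- run_method_adapter(adapter_greedy_module(20), net, dataset)
evaluate_prediction(split, pred)
#> # A tibble: 1 × 11
#>   method        n_pred    tp    fp    fn precision recall f_measure ...
#> 1 greedy_module     20     9    11    11      0.45   0.45      0.45
```

Reading the numbers: the planted FG set has average pairwise distance
exactly 3 (inside the requested band [2, 4]), touches 7.85 edges per node on
average but induces almost no internal edges (density 0.04) — a genuinely
sparse module. At VM signal strength 1.5 the greedy baseline recovers 9 of
the 20 planted genes in a 20-node prediction, giving precision = recall =
F-measure = 0.45.

Sweeps run through `run_benchmark()` / `aggregate_results()` (or the
YAML-driven `cmd_benchmark()`; a shell front end ships in
`inst/cli/subnetbench`), and `autoplot()` on the result draws mean F against
signal strength or sparsity per method.

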