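---
title: "Designing synthetic gold standards for de novo pathway enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic gold standards for de novo pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subnetbench)
```

## Why simulate the truth

De novo pathway enrichment asks for a condition-associated subnetwork of a
molecular interaction network, guided by expression data but unconstrained
by pathway databases. Real datasets provide no ground truth for this task,
so method comparisons built on them inherit the biases of whatever proxy
(curated pathways, literature genes) is used as "truth". subnetbench takes
the opposite route: it decides the truth first — a foreground (FG) node set
planted in the network — then simulates expression around it and measures
how much of the planted set a method recovers. Both the *visibility* of the
signal and the *topological difficulty* of the planted set are controlled
parameters, so a method's operating range can be mapped rather than guessed.

## Planting the foreground

Two selectors split the node set of an undirected simple graph into FG and
BG. They are deliberately complementary.

**Seed-and-extend (SAE)** draws a seed node uniformly at random and grows
the set breadth-first, layer by layer, until it holds `n` nodes (default
20). When the final layer overshoots, exactly enough of its nodes are
sampled uniformly to land on `n`; we read the size rule this way because
retaining the already-absorbed layers and topping up from the current
frontier is the only interpretation that keeps the result both connected
and exactly sized. If the seed's component runs out of nodes first, the
whole component becomes the FG with a warning. SAE foregrounds are always
connected — the easy case for extraction methods.

**Average-distance-k (AVD_k)** instead prescribes how *spread out* the FG
should be: the mean shortest-path (hop) distance over all FG pairs must lie
in `k ± α`, with `α = 1` by default to allow slack; `AVD_3` therefore
returns sets with average pairwise distance between 2 and 4. Deciding
whether such a set exists is NP-complete, so `avd_k_greedy()` uses a
restarting greedy construction: starting from a random node, it adds the
candidate whose inclusion keeps the running pair-distance sum closest to
its target `k * choose(|W|+1, 2)`, breaking score ties uniformly at random,
and restarts from a fresh node (up to `max_restarts = 50`) if the finished
set misses the band. The deviation-from-target-sum score is this package's
own concretisation of the greedy idea; it has the useful property that the
partial sums are steered toward the final target at every step rather than
only at the end. Candidates are confined to the start node's component so
all distances are finite. AVD_k sets need not induce connected subgraphs —
intentionally so, since deregulated genes in real conditions are not
guaranteed to be direct neighbours.

`avd_k_exhaustive()` enumerates all size-`n` subsets (guarded at 10^6) and
is the exact oracle: on graphs up to 14 nodes the test suite checks that
every greedy solution is a true solution and that the greedy finds one
whenever one exists. Infeasibility (e.g. `k = 3` on a complete graph) is
reported as an error carrying the best achieved average, never silently
absorbed.

Distances are unweighted hop counts throughout; the framework models
interaction confidence and direction as out of scope.

## Simulating expression

The design is 100 case (patient) samples and 10 controls — an intentionally
asymmetric cohort of the kind clinical series produce. Every matrix entry
is an independent normal draw whose parameters depend only on (gene class,
sample class):

| model | FG x case | FG x control | BG x any | signal strength |
|-------|-----------|--------------|----------|-----------------|
| VM    | N(mu_fg, v) | N(mu_fgc, v) | N(0, v), v = 1 | mu_fg − mu_fgc |
| VV    | N(mu, v_fg) | N(mu, v_bg)  | N(mu, v_bg), mu = 0 | v_fg / v_bg |

In the VV model the control-FG cell shares the background distribution:
only diseased samples express the planted deregulation, which is what makes
the variance ratio the meaningful knob. The shipped default grids are VM
differences {0, 0.25, 0.5, 1, 1.5, 2} and VV ratios {1, 2, 4, 8}; both are
plain numeric vectors a config can override.

Entries are independent across genes. Real expression data are not: they
carry gene–gene correlation, batch structure and heavy tails. Passing
benchmarks here therefore demonstrates that a method can exploit a clean
planted signal at a given strength and sparsity — not that it is robust to
correlated noise, and conclusions about real-data performance need that
caveat.

Tool-facing inputs come from `differential_stats()`: per-gene Welch t-tests
of case against control. The unequal-variance form is the only defensible
default given that the VV model breaks variance homogeneity by
construction. Both raw and Benjamini–Hochberg-adjusted p-values are
exported, plus a signed z-score, so adapters can feed whichever their tool
expects. Degenerate genes (constant in both classes) get p = 1 when the
class means agree — no evidence, rather than an error.

## Measuring sparsity

Three views of how an FG set sits in the network: *global proximity* — the
edge count of a tree covering the FG set, formalised as an approximate
minimum Steiner tree because a tree is the minimal covering structure;
*global connectivity* — mean FG degree in the full network (not the induced
subgraph, since reachability is what matters to an extraction method); and
*local density* — induced edge density, left undefined below two nodes so
degenerate configurations fail loudly. Proximity uses the metric-closure
2-approximation (complete graph on FG weighted by shortest-path distances,
MST, paths expanded and re-spanned), which is polynomial and never more
than twice the optimum; for three or fewer terminals the exact optimum is
computed directly (the pairwise distance, or the best median-vertex spider
`min_v Σ_i d(v, t_i)`), since the closure MST alone is not guaranteed
optimal even at three terminals.

## Scoring and sweeping

Evaluation is node-level over all of V with FG as the positive class:
precision = tp/(tp+fp), recall = tp/(tp+fn), and the F-measure is F1, their
harmonic mean, with the conventions F = 0 for an empty prediction and
precision = 0 when nothing is predicted. Predicted edges are ignored, BG
nodes earn no partial credit however close they sit to the FG, and when a
tool reports several modules the union of their nodes is scored — a single
consistent rule rather than a per-tool choice. `run_benchmark()` sweeps the
full Cartesian grid of splits x simulation configs x adapters x
internal-parameter settings; each (split, config) dataset is simulated once
under a seed derived deterministically from the master seed and shared
across adapters, so methods are compared on identical data. A failing
adapter run becomes a `status = "failed"` row, never a lost sweep.

## Reproducibility mechanics

Every randomised function takes an explicit integer seed and restores the
caller's RNG state on exit; collection and batch drivers derive per-item
seeds as `master + index` (wrapped into the 32-bit range). Identical
configurations therefore produce byte-identical output files, which the
test suite asserts at file level. The YAML config schema is strict — any
unknown key anywhere is an error — and every output directory carries a
manifest with the config, its hash, the master seed and the package
version.

## Problem sizes in the shipped checks

The test suite exercises the qualitative findings at desk scale, chosen so
the whole suite runs in a couple of minutes: a 500-node
preferential-attachment substrate (scale-free, like real interactomes,
though an order of magnitude smaller and without their annotation biases),
30 FG sets of 20 nodes per condition, the VM grid {0, 0.5, 1, 2} for the
signal-response check and k in {1, 2, 3, 4} at signal strength 1 for the
sparsity response; the built-in `greedy_module` baseline is the probe. On
this substrate mean F rises monotonically with signal strength and falls
monotonically with k — the two behaviours any sound benchmark of this
design must show. Oracle comparisons (greedy vs. exhaustive AVD_k, Steiner
bound) run on random graphs of 8–14 nodes where enumeration is exact.

## Known limitations

* Gaussian intensities only; no count-based (RNA-seq) simulation, missing
  values, batch effects or correlated noise.
* Networks are unweighted, undirected and identifier-agnostic; no
  gene-symbol normalisation is attempted.
* The AVD_k greedy is a heuristic: it can report infeasibility on instances
  that are feasible (the restart budget bounds the search), and its
  solution distribution is not uniform over the solution space.
* External tools are consumed through the adapter contract only; nothing is
  claimed about any specific published tool's ranking.
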