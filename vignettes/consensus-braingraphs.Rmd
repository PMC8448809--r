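---
title: "Consensus braingraphs from repeated tractography: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus braingraphs from repeated tractography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincons)
```

## The aggregation model

Probabilistic tractography is a randomized reconstruction: every run on the
same diffusion scan produces a different set of streamlines, hence a
different braingraph. Treating the fiber count of a fixed region pair as a
random variable $X$, the identity $E(X - E(X)) = 0$ says deviations average
out, so aggregating repeated runs increases reliability. The package
implements the standard robust aggregation:

* **Edge rule.** An unordered region pair $\{a, b\}$ is an edge of a single
  run iff at least one streamline connects the two regions; consequently
  per-run fiber counts are integers $\ge 1$.
* **Presence rule.** An edge enters the consensus graph only if it occurs
  in all $n$ runs (default $n = 10$; `consensus_policy(required_presence =)`
  relaxes this). The consensus edge set is then exactly the intersection of
  the per-run edge sets, so adding runs can only shrink it.
* **Trimmed averaging.** For each surviving edge, one minimal and one
  maximal fiber count are deleted and the remaining $n - 2$ values averaged
  (`n_trim_low`/`n_trim_high` generalize this). This is a min/max-trimmed
  mean: resistant to the single wild run that probabilistic seeding
  occasionally produces, while keeping $80\%$ efficiency of the
  observations at $n = 10$.
* **Three weights.** The consensus edge carries the trimmed mean fiber
  count, the mean streamline length (mm) and the mean FA.

### Which runs do lengths and FA average over?

The trim is defined on the fiber-count vector only. Two populations for the
length/FA means are defensible: all $n$ runs containing the edge, or the
$n-2$ runs surviving the fiber-count trim. The package defaults to the
**trim-surviving runs** (`length_fa_population = "trimmed"`): a run whose
fiber count was extremal is the run most suspected of a reconstruction
artifact, and using one consistent run subset per edge keeps the three
weights mutually comparable. The `"all"` option is provided because the
choice is genuinely open.

### Tie-breaks in the trim

When several runs attain the extremal fiber count, *which* occurrence is
deleted changes nothing for the fiber weight but does change the
co-observations (length, FA) that survive. `aggregate_edge()` therefore
orders observations lexicographically by (fiber count, length, FA, run
index) and deletes the first and last — a rule that depends only on the
multiset of observations, making the consensus invariant under permutation
of the runs. The standalone `trim_extremes()` keeps the simpler
lowest-run-index rule, which is adequate for a plain numeric vector.

### Degenerate configurations

`required_presence` minus the total trim must be at least 1, otherwise an
edge could survive filtering with nothing left to average;
`build_consensus()` rejects such policies loudly rather than guessing.
Zero-mean replicate vectors make the coefficient of variation undefined;
since consensus fiber means are always $\ge 1$, `relative_sd()` treats a
zero mean as an input error.

## Vertex contraction across resolutions

Coarser parcellation levels are derived from the finest-level graph, never
re-tracked: vertices sharing a coarse label are merged, parallel fine edges
between two coarse vertices are replaced by one edge whose fiber count is
the **sum** of the fine counts, and fine edges internal to a coarse vertex
become self-loops, which are dropped. Three choices here were open:

* **Length/FA under contraction:** fiber-count-weighted arithmetic means.
  Each fine edge's mean is a mean over its streamline population, so
  weighting by fiber count is the population-level mean of the merged
  bundle; it also guarantees the coarse value lies inside the range of the
  merged fine values.
* **Self-loop mass:** reported in the `ContractionReport`
  (`self_loop_mass_dropped`), so that
  `mass_after + dropped == mass_before` is auditable, exactly for integer
  inputs and to $10^{-9}$ relative error for averaged (fractional) inputs.
* **Coarse node positions:** unweighted centroids of the constituent fine
  nodes; hemispheres are kept only when all constituents agree.

Contraction composes: fine→mid followed by mid→coarse equals fine→coarse
(fiber counts exactly; weighted means to rounding), which the tests verify
on random 3-level hierarchies.

## The repetition sweep

To choose the repetition count $k$, the package builds, for each candidate
$k$, $R$ independent $k$-run-averaged graphs (default $R = 10$), discards
edges absent from any replicate, and computes for each edge the relative
standard deviation of its $R$ replicate weights,
$c_v = \sigma / \mu$ with the Bessel-corrected $\sigma$
($1/(R-1)$ inside the square root). Summaries per $k$ are the median,
quartiles (median-of-halves convention, i.e. the "middle half of the data
points" box), min and max over edges.

* **Presence semantics of a $k$-run average.** "Averaging the fiber numbers
  over the $k$ runs" is ambiguous when an edge misses some runs. The
  default (`presence_rule = "any"`) keeps an edge seen in $\ge 1$ of the
  $k$ runs and counts absences as zero fibers — the literal average over
  $k$ runs; `"all"` keeps only all-run edges. Neither is asserted as the
  canonical reading; both are first-class options.
* **Recommendation rule.** For i.i.d. runs the replicate mean has
  $c_v \propto 1/\sqrt{k}$, so the median curve flattens;
  `recommend_k()` returns the smallest sampled $k$ whose relative
  median improvement to the next sampled $k$ falls below a tolerance
  (default 5%). Monte-Carlo jitter can make the raw median sequence
  non-monotone, so a width-3 running median (endpoints kept) is applied
  first. If no $k$ qualifies the largest is returned with a warning —
  a sign the grid should extend further.
* **Statistical power.** The median at each $k$ should be taken over
  enough edges: with $R = 10$ replicates a single edge's $c_v$ estimate
  has relative error $\approx 1/\sqrt{2(R-1)} \approx 24\%$, so sweeps on
  graphs with only a handful of edges give unstable recommendations. The
  shipped acceptance analysis uses a ~200-edge graph, where the median is
  stable to a few percent.

## The tractography simulator

Real diffusion MRI inputs are out of scope; the simulator generates per-run
braingraphs with the stochastic structure that matters for the aggregation
method:

| parameter | law | default range | rationale |
|---|---|---|---|
| detection $p$ | Bernoulli per run | 0.7–1.0 | anatomical connections are found in most runs |
| fiber count | zero-truncated Poisson($\lambda$) | $\lambda \in$ 5–150 | the edge rule requires $\ge 1$ streamline, so presence noise ($p$) and count noise ($\lambda$) are modelled separately |
| length (mm) | normal, truncated positive | mean 20–120, sd 5–20% of mean | short association to long projection tracts |
| FA | Beta(mean $\mu$, concentration $\kappa$) | $\mu \in$ 0.25–0.6, $\kappa \in$ 50–200 | support [0, 1] matches the FA invariant by construction |

No false-positive edges are generated by default (keeping the noiseless
limit exactly assertable: with $p = 1$ and `noise = "none"` every run
equals the ground truth and all sweep $c_v$ are zero); a `spurious_rate`
knob exists for stress tests. Seeding uses one master seed with
per-(k, replicate, run) substreams derived through an avalanche hash —
adjacent raw integer seeds are avoided deliberately, because their first
Mersenne-Twister draws are correlated enough to bias joint-presence
frequencies (e.g. the $p^{10}$ retention probability).

**What the simulator does not emulate:** spatial correlation between edges
sharing a region, the heavy right tail of real fiber-count distributions,
distance-dependent detection, or anatomically realistic parcellations.
Passing tests therefore demonstrate the correctness of the aggregation
arithmetic and its statistical behavior under a clean i.i.d. noise model —
not the fidelity of any tractography algorithm.

## File formats and numerics

* GraphML in the CMTK-style connectome dialect: attribute keys first, then
  nodes (label, hemisphere, x/y/z), then undirected edges with the three
  weights. Key names are configurable via `default_attribute_map()`
  because the dialect's exact strings vary between producers; directed
  files are rejected rather than symmetrized. Floats are serialized with
  17 significant digits so write→read is the exact identity.
* Parcellation hierarchies are plain CSV/TSV: header = level names
  (finest first), one row per finest label. Totality, strictly decreasing
  level sizes and functional consistency of consecutive-level maps are
  validated on read.
* JSON (ground-truth models, manifests, simulation configs) uses 17
  significant digits where exact round-trips matter.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses run on simulated graphs of 2–30
nodes, 10 runs per consensus, 500 replicates for the $1/\sqrt{k}$ decay
check at $k \in \{1, 4, 16, 25\}$, 20,000 model replicates for the
$2^{-10}$ retention frequency, and one ~10⁶-edge run for the mean-deviation
identity — sizes at which the Monte-Carlo standard errors are comfortably
inside the asserted tolerances.

## Known limitations

* The consensus stage assumes all runs share one node set (one subject,
  one parcellation); cross-subject aggregation is a different problem.
* `recommend_k()` encodes one operationalization of "the curve has
  flattened"; on coarse k-grids the relative-improvement test refers to
  the next *sampled* k, which is the natural reading but means tolerances
  are not comparable across grids.
* Edge sets under the `"any"` presence rule vary with $k$ (weak edges
  enter the all-replicates intersection more easily at larger $k$), so
  per-$k$ medians mix a selection effect with the $1/\sqrt{k}$ decay on
  small graphs.
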