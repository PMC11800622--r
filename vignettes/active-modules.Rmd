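---
title: "Diffusion and module search on multiplex-heterogeneous networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion and module search on multiplex-heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amendr)
```

# The model

`amendr` ranks nodes of a molecular network by random walk with restart
(RWR) and extracts a connected, high-scoring subnetwork (an *active
module*). The walk's fixed point solves

$$ p = (1 - r)\,M\,p + r\,p_0 $$

where $M$ is a left-stochastic transition matrix, $p_0$ the seed vector
built from experimental values, and $r$ the restart probability. Without
restart the walk forgets its seeds entirely: for a degree-normalized
symmetric adjacency it converges to the stationary distribution
$s_j = \sum_i a_{ij} / \sum_{ik} a_{ik}$, i.e. to weighted degree. The
restart term is what makes experimental data matter, and the stationary
distribution is, throughout this package, the reference for how much degree
alone would explain.

## Transition matrices for multiplex-heterogeneous graphs

A *component* holds one node type; a multiplex component holds several
*layers* (edge types) over partially overlapping node sets; components are
linked by bipartite edges. Each replica of a node (one per layer it appears
in) is a separate state of the chain.

$M$ is assembled from three block families, each column-normalized
**independently**: intra-layer adjacency, inter-layer couplings (replicas of
a shared node id across layers of one multiplex, coupling weight
configurable, default 1), and inter-component bipartite blocks (normalized
per component pair). Crosstalk parameters then mix the classes per source
column:

| target class    | mass                      |
|-----------------|---------------------------|
| same layer      | $(1-\delta)(1-\lambda)$   |
| other layer     | $(1-\delta)\lambda$       |
| other component | $\delta$                  |

Because blocks are normalized before mixing, each class's mass is *affine*
in its own parameter over the whole $[0,1]$ range — the behavior of the
walk changes predictably with $\lambda$ and $\delta$, which is the point of
this parameterization (normalizing after mixing, as some earlier multiplex
walkers do, makes transition rates a nonlinear function of the crosstalk
setting).

Corner cases are resolved as follows. A parameter whose target class does
not exist for a source replica is vacuous there: a monoplex node keeps all
mass intra-layer whatever $\lambda,\delta$ say. Mass belonging to an absent
class is redistributed proportionally to the configured weights of the
classes that do exist; when several partner components exist, $\delta$ is
split equally among those with targets. A class whose targets exist but
whose configured mass is zero stays at zero — with $\lambda=\delta=0$ the
matrix is exactly block-diagonal, and a replica whose only neighbors sit in
zero-mass classes becomes *dangling*: its column is all zero and the
diffusion engine adds the lost mass to the restart term each step, which
keeps every iterate stochastic without densifying $M$.

## Seed vectors

Per-layer value maps are normalized to sum 1 independently, then scaled by
layer weights $\tau$ (simplex per component) and component weights $\eta$
(simplex), and concatenated. Nodes missing from a value map get seed 0 but
stay in the graph — molecules not captured by an assay can still enter the
module through diffusion. An all-zero layer donates its $\tau$ weight
proportionally to its siblings (and an all-zero component its $\eta$
weight); inventing a uniform prior over unmeasured nodes would drown the
measured signal instead.

## Biased random walk

A nonnegative attribute $\mu$ reweights target rows before normalization,
$m_{ij} = \mu_i a_{ij} / \sum_l \mu_l a_{lj}$, so nodes with larger
attributes attract the walker in proportion to their local competition.
From nodes of interest $V$ the package derives
$\mu_i = e^{-k\,d_i}$, with $d_i$ the mean unweighted shortest-path
distance from replica $i$ to $V$ on the full replica graph (all edge
classes unit length; unreachable pairs count as diameter + 1). Distances
are computed once on the input graph and subset as the search shrinks it.
If a column's entire neighborhood has $\mu = 0$ the biased rate is
undefined; that column falls back to unbiased normalization with a warning
rather than becoming a sink.

## Degree-bias adjustment

Hubs of curated interactomes are partly artifacts of study bias, so the
package offers four corrections, all cheap enough to run inside the
iterative search (permutation nulls are deliberately out of scope):

* **SDS** — divide scores by stationary probabilities, $p'_i = p_i / s_i$.
  A post-hoc rank transform; not renormalized. Overcorrects by design: the
  resulting score–degree correlation is typically negative.
* **Bistochastic scaling (BS)** — iterative proportional fitting of $M$
  toward unit row and column sums (a bistochastic matrix has the
  maximum-entropy stationary distribution). Defaults: tolerance `1e-6`,
  1000 iterations; a final exact column renormalization guarantees a valid
  transition matrix even for matrices that are not fully indecomposable,
  where IPF can only approximate.
* **Inflation-normalization (IN)** — per round, raise row $i$ entrywise to
  $\alpha_i = 1 + \gamma\,(s_i - \min s)/(\max s - \min s)$ and renormalize
  columns. Entries are at most 1, so exponents above 1 shrink them most
  where $s$ is large, displacing incoming mass away from hubs. The affine
  min–max exponent is this package's choice: it guarantees $\alpha \ge 1$,
  reduces to the identity on regular graphs and at $\gamma = 0$, and moves
  mass monotonically. Defaults $\gamma = 1$, one round.
* **Penalized degree normalization** — $a'_{ij} = a_{ij}/d_i^{k}$ before
  column normalization, an inverse-degree biased walk applied at
  construction time (within-layer degrees; $k = 0$ is plain
  normalization).

BS and IN apply to chosen `(component, layer)` blocks *before* crosstalk
assembly, so global column stochasticity holds by construction and columns
outside the scope are untouched. SDS composes with any transition variant
and, inside the search loop, uses the current subnetwork's stationary
distribution, since degree structure changes as the graph shrinks.

A caution observed in the package's own experiments: IPF on sparse graphs
can concentrate weight on near-matching structures, making the scaled chain
almost periodic; the stationary solver then falls back to a damped walk
(factor 0.999) with a warning.

# The module search

Each iteration: (1) assemble $M$ on the current subnetwork and diffuse the
(renormalized) seeds; (2) optionally adjust for degree bias; (3) aggregate
each multiplex component — union node set, edge set preferring a primary
layer (an edge from a secondary layer enters only if its node pair is absent
from all earlier layers), per-node score summarized over replicas (default
mean), bipartite edges preserved; (4) standardize scores on the current
subnetwork and subtract the quantile that leaves `ceiling(n * f)` nodes
nonnegative; (5) extract a maximum-weight connected subgraph; (6) score the
candidate and recurse on it. Stops at the target size, on shrinkage
stalling, or when no node has positive weight; the best-scoring iteration
is returned, expanded back into the original layers with full provenance.

**Retention schedule.** The retention fraction is a constant `decay`
(default 0.5) per iteration, so subnetwork size decays geometrically and
the final subnetwork lands in `[decay * n_target, n_target]`. Landing *at
or below* the target, rather than flooring the last step to hit it exactly,
is intentional: the module is chosen by score across iterations, and a
floored schedule would make modules at or below the requested size
unreachable, inflating every module to `n_target` nodes regardless of how
concentrated the signal is. A subnetwork already at or below the target is
kept whole (the degenerate single-iteration case). Termination is bounded
by `log(N / n_target) / log(1 / decay) + 2` iterations.

**MWCS heuristic.** Maximum-weight connected subgraph extraction is
NP-hard; the package uses a two-candidate heuristic and keeps the heavier
result. Both start by contracting connected clusters of positive-weight
nodes into supernodes (summed weight) and pricing connections by cheapest
paths where a negative node costs $|w|$ (positive nodes are free).
Candidate one builds a minimum-cost spanning structure over supernodes and
keeps the maximum-weight subtree by dynamic programming, evaluated from
every root. Candidate two grows greedily from the heaviest supernode,
repeatedly attaching the supernode with the best net gain and zeroing
connector costs once paid — this captures solutions where several clusters
share one connector, which tree DP prices twice — and returns the best
prefix of the growth sequence. The result is connected by construction and
never worse than the best single positive cluster. On exhaustively
enumerable graphs (≤ 12 nodes) the suite checks the heuristic stays within
90% of the optimum.

**Subnetwork score.** `score = experimental * topological`, where the
experimental term is the mean seed value of module nodes standardized
against the full input network (so "how many standard deviations above
background"), and the topological term is the fraction of module nodes in
the largest connected component times `d / (d + 1)` for mean induced degree
`d` — it saturates instead of rewarding density without bound, so the
experimental term dominates once a module is reasonably cohesive. The score
only selects among iterations; alternatives can be swapped without touching
the loop.

# Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `r` | 0.5 | restart probability; larger keeps scores closer to the seeds |
| `lambda` | 0.5 | layer-switch probability within a multiplex |
| `delta` | 0.5 | component-jump probability along bipartite edges |
| `tau`, `eta` | uniform | per-layer / per-component seed weights (simplex) |
| `k_pen` | 0 | degree-penalization exponent at construction |
| `gamma`, `rounds` | 1, 1 | inflation strength and repetitions (IN) |
| `ipf_tol`, `ipf_max_iter` | 1e-6, 1000 | bistochastic scaling controls |
| `k_scale` | 1 | distance decay of the nodes-of-interest attribute |
| `n_target` | — | requested module size (aggregated nodes) |
| `decay` | 0.5 | per-iteration retention fraction |
| `tol`, `max_iter` | 1e-10, 1000 | L1 convergence of the restart walk |

Convergence uses the L1 norm; mass conservation is enforced each step, so
the tolerance is a genuine fixed-point gap. Non-convergence is an error
carrying the residual trace. Ties in evaluation ranks share the mean rank;
ranking excludes the seed nodes themselves, which would otherwise pad the
top of every ranking uninformatively.

# What the synthetic generators emulate

`generate_graph()` produces scale-free layers by undirected preferential
attachment (default 2 edges per node) — reproducing the hub structure that
makes degree adjustment meaningful — or binomial (Erdős–Rényi) layers at a
chosen density; layer overlap is realized by a shared node-id block;
bipartite couplings are sampled independently. `plant_module()` grows a
connected truth set by random-walk sampling and assigns it $|N(3,1)|$ seed
values against an $|N(0,1)|$ background (the recovery benchmark's
conditions; the effect size is configurable and 0 gives the null).
`de_seed_values()` draws $-\log_{10}$ p-value shaped seeds: a null
component $\mathrm{Exp}(\ln 10)$ — exactly $-\log_{10}$ of a uniform
p-value — plus a 10% signal component $|N(8,4)|$.
`anti_degree_seeds()` assigns sorted values to nodes in reverse degree
order, the worst case for degree-driven retention.

Benchmark problem sizes are chosen so the full suite exercises every
property at desk scale: recovery on 1000-node scale-free graphs with
20-node planted modules over 20 generator seeds; correlation orderings on
twenty 300-node graphs; retention on 2000-node binomial graphs of density
0.008 (mean degree 16, emulating the density of functional-interaction
networks). That last choice is deliberate: in a sparse preferential-
attachment graph, nodes with the largest (degree-anticorrelated) seeds are
scattered leaves whose only connectors are mega-hubs, so *any* connected
module pays a hub penalty and the seed-versus-degree ECDF difference is
structurally depressed; at functional-interaction densities the
high-seed nodes interconnect through moderate nodes and retention reflects
the algorithm rather than the topology's veto.

What the generators do **not** emulate: correlation structure among seed
values (real differential-expression statistics are correlated along
pathways), weighted confidence scores on edges, annotation and study bias
(hubs here are honest), and the heavy-tailed layer-overlap patterns of
curated multi-omic compendia. Passing the suite therefore demonstrates the
algorithmic contracts — stochasticity, oracle equivalence, direction of
change under bias and adjustment, recovery of a planted signal — not
biological performance on any particular interactome.

# Numerical and degenerate-input choices

* Duplicate edges are collapsed by summing weights; self-loops are rejected
  unless explicitly enabled; missing weights default to 1.
* Node identity across layers and components is exact string match; no
  identifier mapping is attempted (that is study-specific preprocessing).
* The global replica index orders components and layers as configured and
  node ids lexicographically; it is a checked bijection.
* Stationary distributions use the closed form where it applies, otherwise
  power iteration on the lazy chain $(M + I)/2$ (same fixed point, immune
  to periodicity), with a damped fallback for reducible chains.
* Constant diffusion scores make the score shift degenerate (all weights
  zero); the search stops and reports it rather than fabricating an
  ordering.
* All-negative weight vectors yield an empty extraction; at the first
  iteration this is an error (the seed support cannot start a module),
  later it simply stops the loop.

# Known limitations

* The crosstalk algebra fixes one defensible redistribution scheme;
  per-pair $\delta$ overrides beyond the equal split are not implemented.
* The MWCS heuristic has no approximation guarantee; the 90% figure is an
  empirical property at enumerable sizes.
* Module recovery at the benchmark's default settings is conservative: with
  the restart at 0.5, half the probability mass is repeatedly smoothed into
  the neighborhood, and recovery of weakly seeded planted nodes competes
  with background hubs. Raising `r` sharpens seed fidelity at the cost of
  less network learning; the package keeps 0.5 as the default for
  comparability across its own benchmarks.
* Runtime is dominated by the MWCS step on the first iterations; graphs in
  the tens of thousands of replicas are practical, millions are not.
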