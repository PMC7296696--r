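---
title: "Source/Sink centrality in pathway graphs: models, validation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source/Sink centrality in pathway graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscentrality)
```

## The modeling problem

A curated pathway is a directed graph: genes and proteins as nodes,
directed interactions as edges. Signal flows from upstream elements
(receptors, typically with no incoming edges) to downstream elements
(effectors and transcription factors, typically with no outgoing edges).
A directed centrality model scores each node's topological importance,
and most spectral models do so *asymmetrically*: the fixed point of a
recurrence driven by either outgoing or incoming edges. A node at the
"wrong" end of the graph receives exactly the baseline score, as if it
were isolated. Since biologically critical genes occur at both ends of
pathways, this asymmetry discards real signal.

Source/Sink centrality (SSC) resolves this with a symmetric recipe:
compute the model on the graph (the **source** component, importance as a
sender), compute it again on the transposed graph (the **sink**
component, importance as a receiver), with the same parameters, and sum
the two. The package applies this recipe to degree, PageRank, Katz, a
directed Laplacian-influence model, and harmonic closeness.

## Models and their fixed points

All graphs use a strictly 0/1 adjacency `A` (`A[i,j] = 1` iff edge
`i -> j`). Duplicate edges collapse; self-loops are removed at
construction with a warning — none of the centrality recurrences here is
defined with self-influence, and KEGG files occasionally encode
autoregulation that would otherwise put mass on the diagonal. Degree
matrices used inside the spectral operators are clamped at one
(`max(deg, 1)`) so sink and source nodes do not make the operators
singular; clamping is *never* applied to degree centrality itself.

Every spectral variant is the fixed point of `C = beta + M C` for a
non-negative contraction `M`:

* PageRank sink: `M = alpha * t(A) %*% solve(D_out)` — a random walk with
  restart; a node with no incoming edges scores exactly `beta`, because
  the walk only reaches it by restarting there.
* PageRank source: the same model on the transpose,
  `M = alpha * A %*% solve(D_in)`.
* Katz source/sink: `M = alpha * A` / `alpha * t(A)` — damped path
  counting. Convergence requires `alpha < 1 / lambda1` (largest adjacency
  eigenvalue); both components share the same bound.
* Laplacian source/sink: `M = alpha * solve(D_out) %*% A` /
  `alpha * solve(D_in) %*% t(A)` — a node's score relates to the
  *average* score of its neighbors; equivalently the geometric series of
  the influence matrix `alpha * D^{-1} A` applied to the all-ones vector.

Closeness is not spectral: source closeness is the harmonic sum
`sum(1/d(v, u))` over nodes reachable from `v` (unreachable pairs
contribute zero, the distance to itself is excluded), sink closeness uses
distances *into* `v`. The harmonic convention is forced by disconnected
pathway graphs: a plain sum of distances would be infinite.

Undirected variants run the model on the underlying undirected graph,
represented internally as a symmetric directed graph so that one code
path serves all variants. Undirected Katz is not offered (a usable global
`alpha` would have to be smaller than the reciprocal of every pathway's
largest eigenvalue), and neither is undirected Laplacian (constant on
connected components).

### A caution on PageRank conventions

The PageRank here is solved literally as
`C = (I - alpha * t(A) %*% solve(D_out))^{-1} beta` with a *constant*
restart vector `beta` and out-degrees clamped at one. There is no
dangling-node mass redistribution and no normalization of scores to sum
to one. Raw scores therefore differ from igraph's or networkx's PageRank;
within-pathway ranks and z-normalized scores — all the validation
pipeline uses — are unaffected by any global rescaling, but raw-profile
comparisons against other software will not match.

### Parameters

| model | alpha | beta | rationale |
|---|---|---|---|
| PageRank | 0.85 | 0.15 | the classical damping/restart pair |
| Katz | 0.1 | 1 | small enough that every pathway passing the eigenvalue filter (`lambda1 <= 10`) converges |
| Laplacian | 0.85 | 1 | consistent with the PageRank damping |

`alpha` is dimensionless damping (contraction strength); `beta` a
dimensionless per-node baseline. Both are configurable per run; source
and sink components of one SSC score always share the same pair. Katz
refuses `alpha >= 0.999 / lambda1`: near the spectral radius the inverse
may exist numerically while the underlying series diverges, so a margin
is enforced rather than trusting the solver.

## Numerical choices

* Closed-form solves use dense LU (`solve`); graphs here are at most ~1000
  nodes. The iterative solver starts at `beta`, iterates the recurrence,
  and stops when the max-norm change drops below `1e-12` (cap 10 000
  iterations); closed form and iteration agree within `1e-9` whenever the
  contraction condition holds, and the test suite enforces this against
  truncated geometric-series oracles.
* Spectral radius: dense eigendecomposition up to 200 nodes, power
  iteration (tolerance `1e-9`) above, with a dense fallback if the
  iteration stalls. Only the modulus is used anywhere.
* Quantile ranking resolves ties by average ranks *before* the ceiling —
  deterministic, order-independent, and consistent with the tie handling
  of the Wilcoxon test used elsewhere. A constant profile has no defined
  ranking and raises an error; the pathway filter removes such pathways
  beforehand.
* Z-normalization uses the sample (n−1) standard deviation. The choice is
  immaterial for everything downstream (ranks and KS comparisons are
  scale-invariant) but is stated for reproducibility.
* The Wilcoxon test uses the exact Mann-Whitney tail when the combined
  sample is at most 50 and tie-free, otherwise the normal approximation
  with average-rank tie correction and no continuity correction.
* The one-sided two-sample KS p-value is the asymptotic bound
  `exp(-2 D^2 m n / (m + n))`.

## The two kinds of quantiles

The pipeline deliberately contains two distinct quantile constructions:

1. **Within-pathway quantile ranks** (`quantile_ranks`): nodes of one
   pathway are ranked ascending by score and mapped to
   `ceiling(100 * rank / n)`, so the most central node of every pathway
   lands at 100 regardless of pathway size. The regression pools, per
   quantile, the important and total gene counts across pathways — a gene
   occurring in k pathways contributes k observations — and fits the
   importance percentage on the quantile index by OLS. The quantile
   construction is a rank transform: applying the ceiling to raw scores
   rather than ranks would not put the most central gene at 100, so the
   rank reading is the only one consistent with the construction's stated
   purpose.
2. **Pooled CDF quantiles** (`pooled_cdf_quantiles`): scores are
   z-normalized within each pathway, pooled, and the pooled sample is
   ranked into 100 quantiles. The one-sided KS test then compares
   important vs other genes on this common scale.

Empty quantile bins are omitted from the regression input; the fit
requires at least three populated bins.

## Pathway quality filters

Applied in a fixed order, first failing rule recorded (so the
kept/excluded partition is deterministic):

1. too large: more than 1000 nodes **and** more than 4000 edges;
2. too small: at most 20 nodes **or** at most 20 edges;
3. eigenvalue: spectral radius above 10, *or* the configured Katz alpha
   violating its convergence margin — the second clause closes a sliver
   (`lambda1` in (0.999/alpha, 10]) where a pathway would pass the
   eigenvalue cut yet be uncomputable by Katz at the configured alpha;
4. constant centrality: any configured model yields a constant score
   vector (e.g. a directed cycle), which would make quantile ranking
   undefined;
5. too few important genes: 5 or fewer of the pathway's nodes occur in
   the important set (tests on smaller overlaps are not meaningful).

The AND in rule 1 versus the OR in rule 2 is intentional and literal.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces layered DAGs shaped like signaling cascades:
a narrow first layer (2–3 receptor-like nodes), three middle layers of
6–12 nodes, a narrow last layer (2–3 effector-like nodes), default depth
5. Adjacent layers connect with probability 0.35; the two terminal
interfaces are denser (factor 2.5, capped at 1), reflecting receptors
broadcasting into the cascade and the cascade converging onto effectors.
A 10% fraction of middle nodes are degree-boosted hubs. Skip edges
(probability 0.05) stay forward, so graphs are acyclic — the adjacency is
nilpotent, the spectral radius 0, and Katz converges at any alpha. An
optional feedback setting adds effector-to-receptor edges (the canonical
feedback motif) for exercising the solvers on cyclic graphs.

Importance models: `terminal_ends` marks first- and last-layer nodes with
probability 0.6 and middle nodes at 0.15 (a quarter of the terminal
rate), giving an overall important fraction around 20%, comparable to
cancer-gene fractions in curated pathway collections; `hubs` marks
designated hubs; `uniform` marks all nodes i.i.d. — the null
configuration for type-I checks. Node ids encode pathway, layer and
position (`p{k}_l{j}_n{i}`), so positional claims are testable without
side tables. Pathway `k` derives its RNG stream from `seed + k`, which
keeps cohorts stable when only `n_pathways` changes; consequently,
*replicate* cohorts must use base seeds spaced further apart than the
cohort size (the test suite and the acceptance script space them 1000
apart).

What the generator does **not** emulate: signed (activation/inhibition)
edges, edge weights or types, biochemical semantics, the heavy-tailed
size and density distributions of real KEGG pathways, cross-pathway gene
sharing (node ids are pathway-specific, so a gene never recurs across
pathways — the pooling code still supports recurrence), or annotation
noise in the important sets. Passing the synthetic recovery tests
therefore demonstrates that the pipeline detects planted positional
signal of the stated shape, not that any particular real gene set will
show it.

### Expected signal, and the Laplacian caveat

On `terminal_ends` cohorts, path-counting and walk-based SSC variants
(Katz, PageRank, closeness, degree) recover positive regression slopes
while pure source and sink variants stay null — the two planted ends
occupy opposite extremes of a directed ranking and cancel. Undirected
PageRank is positive but explains less variance than SSC, which uses
direction *and* both ends.

Laplacian SSC behaves differently: its recurrence averages rather than
sums over neighbors, so a node's component grows with the *depth* of the
cascade beyond it, saturating geometrically. The sum of the two
components is then largest mid-cascade (the sum of a concave function of
depth-from-start and depth-from-end), and on homogeneous layered DAGs the
planted terminal nodes rank *low*: the terminal-ends slope for Laplacian
SSC is reliably negative, and `expected_signal()` says so. This is a
structural property of averaging dynamics on homogeneous cascades, not a
solver artifact; on real pathway topologies, with their heterogeneous
depths and dense local clusters, the same model can rank terminal hubs
highly. Conclusions about the Laplacian variant drawn from this generator
do not transfer to real data.

## Statistical pipeline details

* Regression: OLS of the pooled importance percentage on the quantile
  index, coefficient table plus adjusted r². No weighting by bin counts —
  the construction keeps bins comparably populated when cohorts are not
  tiny.
* Per-pathway tests: one-sided Welch (difference of means, raw scores,
  Welch–Satterthwaite df) and one-sided Wilcoxon rank-sum, alternative
  "important genes score higher". Pathways with fewer than 2 observations
  in a group (Welch) or an empty group are marked untestable and excluded
  from the FDR family.
* FDR: Benjamini–Hochberg per family, one family = all pathways for one
  (model, variant, test type), level 0.05 by default (configurable, e.g.
  0.25 for permissive screens).
* Sensitivity: the four PageRank variants recomputed over an alpha grid
  (default 0.1–0.9 step 0.01, 81 values), refitting the regression per
  alpha, and comparing the SSC and undirected fits' correlations by
  Fisher-Z at each alpha.

## Problem sizes used by the shipped checks

The test suite validates transpose duality on 200 random graphs (≤ 50
nodes), solver-vs-series equivalence on 100, statistical components
against reference implementations on 1000 random fixtures, signal
recovery on 100 replicate terminal-ends cohorts of 150 pathways, and
type-I control on 200 uniform-null cohorts of 40 pathways. The acceptance
script uses one 150-pathway cohort, 20 recovery replicates and 100 null
replicates. These sizes give stable rates (binomial standard errors of a
few percent) at desk-scale runtimes.

## Known limitations

* Edges are unweighted, unsigned and untyped; inhibitory interactions are
  treated as any other edge.
* Gene identifiers are matched by exact string equality after the user's
  own namespace normalization; no identifier mapping is bundled.
* KGML multi-gene entries and groups are fanned out to all member genes;
  other tools may expand entries differently, so node counts on real KEGG
  files can differ from other parsers'.
* The quantile ceiling-and-average-ties convention is one of several
  defensible readings of a rank-to-percentile map; alternative tie rules
  shift individual bins by at most one quantile.
* The exact Wilcoxon tail is unavailable under ties (the normal
  approximation with tie correction is used instead), as in standard
  implementations.
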