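---
title: "Does network clustering leave a signal in transmission trees?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Does network clustering leave a signal in transmission trees?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seirtrees)
```

## The question

Contact networks — hosts as nodes, potential transmission routes as
edges — are standard models of the substrate on which epidemics spread,
but it is unclear which of their structural features can be recovered
from epidemic data. `seirtrees` implements a fully simulation-based
experiment asking one such question: if two networks share an *identical
per-node degree sequence* and differ only in their *clustering* (the
propensity of triangles to form), do the epidemics they carry — and in
particular the transmission trees those epidemics leave behind — look
systematically different?

The design compares paired arms. For each replicate, a base network is
sampled, rewired once toward high and once toward low clustering without
changing any node's degree, a stochastic SEIR epidemic is run on each arm
from a common index case conditioned on a major outbreak, and the two
outbreaks are reduced to curve- and tree-based summary statistics whose
distributions are then compared across replicates.

## Network models

Two base models are used, at the study sizes:

* **Bernoulli (Erdős–Rényi)**: `N = 500`, each pair linked independently
  with `p = 7/N = 0.014` (mean degree 7). Sampling draws the edge count
  from `Binomial(N(N-1)/2, p)` and then that many distinct pairs
  uniformly.
* **Approximate power law**: `N = 600` degrees drawn i.i.d. with
  `P(d = k) ∝ k^-1.8`, assembled by Reed–Molloy stub pairing with
  self-loops removed and multi-edges collapsed. Because the exponent is
  below 2 the distribution needs a cutoff to have a mean; we normalise
  over `k = 1, …, N-1`, the widest support a simple graph admits. Degree
  0 is excluded — an isolated node can never join the giant component, so
  admitting it would only inflate the node count without touching the
  epidemic. An odd stub total is resolved by redrawing the degree of one
  uniformly chosen node until the total is even, which leaves the
  marginal distribution untouched. Loop/multi-edge cleanup means realised
  degrees can only fall below requested ones; the loss is small at these
  sizes and is covered by a test against a naive stub-pairing oracle.

Clustering is measured by the mean-of-local-coefficients clustering
coefficient: `C_i = 2 n_i / (d_i (d_i - 1))` with `C_i = 0` for degrees
0 and 1, averaged over **all** `N` nodes. An empty network scores 0 by
the same convention.

## Degree-preserving rewiring

The two arms are produced by `rewire_network()`, a Metropolis–Hastings
sampler whose target is the exponential random graph density
`p(Y) ∝ exp(θ · u(Y; τ))` with the geometrically weighted
edgewise-shared-partner statistic

```
u(Y; τ) = e^τ Σ_{i≥1} [1 − (1 − e^{−τ})^i] · EP_i(Y),
```

where `EP_i` counts edges whose endpoints share exactly `i` partners.
Each edge contributes more as it sits in more triangles, with
geometrically diminishing returns controlled by the decay `τ`. The study
settings are `τ = 0.2` fixed, `θ = +5` (high-clustering arm) or `θ = −5`
(low-clustering arm), and a burn-in of `5 × 10⁵` proposals, counting
invalid ones.

Proposals are uniform double-edge swaps: two distinct edges `(a,b)`,
`(c,d)` are drawn uniformly and replaced, with probability ½ each, by
`(a,d),(c,b)` or `(a,c),(b,d)`. Either move preserves every node's
degree exactly — a deliberate strengthening from "preserving the degree
distribution" to preserving the per-node degree sequence, which is what
the paired design needs. Proposals creating a loop or duplicate edge are
rejected outright. The proposal is symmetric (the reverse swap is
generated with the same probability), so the acceptance ratio reduces to
`min(1, exp(θ·Δu))`. `Δu` is computed incrementally in compiled code —
only edges incident to the four endpoints can change their
shared-partner count, and each extant edge's count is maintained in a
hash map — which is what makes `5 × 10⁵`-proposal burn-ins across
hundreds of replicates affordable; a test asserts the incremental delta
equals full recomputation to `10⁻⁹`.

Two numerical points deserve note. First, connectivity is *not*
constrained: rewiring can and does change the size of the largest
connected component, which is itself one of the observed effects in the
power-law arms. Second, with uniform swap proposals the pro-clustering
Bernoulli chain needs roughly `2 × 10⁶` proposals to reach its
stationary clustering level (about 0.30); at `5 × 10⁵` it attains about
0.27–0.30. Samplers with differently tuned proposals mix faster, so
where the attained-range checks are made at convergence the package runs
the longer burn-in and documents it; all headline settings elsewhere use
the study burn-in unchanged.

## The SEIR epidemic

`simulate_seir()` is an event-driven stochastic SEIR simulation: the
index node is exposed at `t = 0`; latent and infectious periods are
gamma distributed (`shape k_E = 1, scale θ_E = 3` and
`k_I = 1, θ_I = 3` days, i.e. exponential with mean 3 days at the
defaults); while a node is infectious, infection crosses each edge to a
susceptible neighbour as a Poisson process with rate `β = 0.1` per day.
Removed nodes play no further part and re-infection cannot occur — which
also means only the *first* potential contact per infectious–susceptible
pair matters, so exactly one exponential first-contact time is drawn per
pair, an exact simplification rather than an approximation. Simultaneous
events are ordered (time, exposure < onset < recovery, node id), making
replay under a fixed seed byte-identical. A worked two-node consequence
used as a test oracle: with `k_I = 1` the per-neighbour transmission
probability is the exponential race `β/(β + 1/θ_I) ≈ 0.2308`.

Outbreaks are conditioned on reaching at least 20 infections
(`simulate_conditioned()`), re-running the epidemic with fresh
randomness from the *same* index. The paired driver picks the index
uniformly from nodes lying in the largest component of *both* arms; only
if conditioning fails repeatedly for that index is a new index drawn,
restarting both arms. The alternative — redrawing the index on every
failure — is equally defensible given the design's description; we chose
the fixed-index rule because it keeps the two arms maximally comparable.

## Transmission trees and summaries

`build_tree()` converts an event log into the timed transmission tree:
one root (the index exposure), one internal node per transmission
`(t, u, v)` ("`v` infected `u` at `t`"), one leaf per recovery. Each
internal node has two children — the continuation of the infector's
timeline and the start of the infectee's — and the root has one, so a
tree with `n` leaves has exactly `2n − 1` branches and the branch
lengths sum to the total infected time (asserted to `10⁻⁹` on every
built tree). Branches are classified by their child endpoint: internal
(time between successive transmissions) versus external (last event to
removal). A single-host tree has no internal branch and its internal
mean is `NA`, excluded from aggregation.

Summaries per outbreak: final size; epidemic length (first infection to
last recovery); peak prevalence and its time, computed *exactly* from
the piecewise-constant prevalence (it changes only at events; the daily
curve is for display), with ties resolved to the earliest time; mean
internal/external branch lengths; per-individual secondary-infection and
infective-descendant counts (the recursion and the equivalent
leaf-ancestor counting are cross-checked in tests); and the cherry ratio
— cherries (internal nodes with two leaf children) over the maximum
possible `⌊n/2⌋`, undefined for `n = 1`. "Infected" in the prevalence
curve counts exposed plus infectious hosts by default, matching "ever
infected" = ever exposed; counting infectious only is available via an
argument since the curves' compartment convention is a modelling choice.

## The replicated experiment

`run_experiment()` repeats the paired replicate: sample base network →
rewire to both arms → take each arm's largest component → paired
conditioned epidemics → summary rows. Power-law order of operations is
rewire first, then component, so clustering-induced changes in
giant-component size are part of the measured effect. Per-replicate RNG
substreams are derived deterministically from the master seed (a fixed
linear-congruential hash, recorded in the output), so any replicate can
be reproduced in isolation and results do not depend on execution order.
Failed replicates (conditioning exhausted) are kept as flagged `NA`
rows, never silently resampled. `compare_distributions()` reports
per-arm mean/min/max of every statistic plus a range-overlap coefficient
`|range ∩| / |range ∪|`, with zero-width ranges treated as overlap 1
when equal and 0 otherwise.

The study design runs 500 replicates per model; the packaged tests
exercise the pipeline at 100 Bernoulli and 50 power-law pairs, sizes at
which the directional effects (longer, flatter, later-peaking epidemics
under high clustering; smaller outbreaks but near-complete overlap of
proportion-of-giant-component infected) are already stable. What the
synthetic generators do *not* emulate — degree assortativity control,
household or spatial structure, waning or re-infection, observation
noise — bounds what passing tests say about real contact networks: the
conclusions concern clustering isolated at fixed degrees, nothing more.

## A worked example

```{r example}
log <- example_transmission_log()
tree <- build_tree(log)
count_cherries(tree)
max_cherries(sum(tree$type == "leaf"))
branch_length_summaries(tree)
write_newick(tree)
```

## Limitations

* The rewiring chain targets the same density family as the reference
  ERGM formulation, but proposal details differ, so attained clustering
  at a fixed finite burn-in is sampler-dependent (see the burn-in note
  above); results are reported as ranges over replicates for this
  reason. The effect is most visible in the power-law pro-clustering
  arm, where at the study burn-in the chain reaches the top of the
  target clustering range and condenses the graph into a smaller,
  denser giant component; the infected *share* of that component then
  runs systematically higher than in the anti-clustering arm, so the
  proportion-of-giant-component distributions of the two arms overlap
  only weakly here (the corresponding distribution-overlap check in the
  acceptance suite documents this as an expected failure), while every
  directional comparison behaves as designed.
* Power-law graphs are approximate: cleanup after stub pairing thins
  heavy-tailed degrees, and `α = 1.8 < 2` makes the degree mean
  cutoff-dependent by construction.
* The pipeline measures distributional differences; it deliberately
  stops short of a statistical power analysis or of inferring clustering
  from data.
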