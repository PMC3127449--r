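# seirtrees

Simulation toolkit for a question in network epidemiology: **does
clustering in a contact network leave a detectable signal in epidemic
transmission trees when the degree of every host is held fixed?**

Hosts are nodes of an undirected simple graph; edges are potential
transmission routes. *Clustering* is the propensity of triangles to
form, measured by the clustering coefficient
`C = (1/N) Σ_i C_i`, `C_i = 2 n_i / (d_i (d_i − 1))` (and `C_i = 0` for
`d_i ≤ 1`), where `n_i` counts edges among node `i`'s neighbours. The
package implements the full paired-simulation pipeline:

1. **Network generation** — Bernoulli graphs (`N = 500`,
   `p = 7/N = 0.014`) and approximate power-law graphs (`N = 600`,
   `P(d = k) ∝ k^−1.8`) via Reed–Molloy stub pairing with loop removal
   and multi-edge collapse.
2. **Degree-preserving rewiring** — Metropolis–Hastings over uniform
   double-edge swaps targeting the exponential random graph density
   `p(Y) ∝ exp(θ·u(Y; τ))` with the geometrically weighted
   edgewise-shared-partner statistic
   `u(Y; τ) = e^τ Σ_{i≥1} [1 − (1 − e^{−τ})^i] EP_i(Y)`
   (`τ = 0.2`; `θ = +5` for the high-clustering arm, `−5` for the low;
   burn-in 5×10⁵ proposals). Every node keeps its degree exactly; the
   Δu computation is incremental and compiled.
3. **SEIR epidemics** — event-driven stochastic
   susceptible–exposed–infectious–removed simulation with per-edge
   Poisson transmission (`β = 0.1`/day) and gamma latent/infectious
   periods (`k_E = k_I = 1`, `θ_E = θ_I = 3` days), conditioned on
   outbreaks of ≥ 20 hosts, started from a common index node in both
   arms.
4. **Transmission trees** — timed rooted trees (root = index exposure,
   internal nodes = transmissions `(t, u, v)`, leaves = recoveries) with
   branch, cherry, secondary-infection and infective-descendant
   statistics, plus Newick export.
5. **Paired experiment & comparison** — replicated high- vs
   low-clustering arms with per-replicate reproducible RNG substreams
   and range-overlap comparison of all summary distributions.

## A worked example

```r
library(seirtrees)

# the five-host example outbreak
log  <- example_transmission_log()
tree <- build_tree(log)
count_cherries(tree)
#> [1] 1
max_cherries(sum(tree$type == "leaf"))
#> [1] 2
write_newick(tree)
#> [1] "(((((4:1.8,5:2.8):0.9,2:2):0.4,3:1.9):0.8,1:1.8):1.3);"

# one paired replicate at the study settings
set.seed(42)
g  <- sample_bernoulli(500, 0.014)
hi <- rewire_network(g, coefficient =  5)   # tau = 0.2, burn-in 5e5
lo <- rewire_network(g, coefficient = -5)
c(global_clustering(g), global_clustering(hi), global_clustering(lo))
#> [1] 0.01129031 0.27911035 0.00000000
```

The base Bernoulli network has incidental clustering ≈ 0.011; the
pro-clustering arm reaches ≈ 0.28 while the anti-clustering arm is
driven exactly triangle-free — with every node's degree unchanged. From
here, `paired_epidemics(largest_component(hi), largest_component(lo),
epidemic_params())` runs the two conditioned outbreaks,
`summarize_replicate()` reduces each to its scalar summaries, and
`run_experiment(experiment_config("bernoulli", n_replicates = 100, seed = 1))`
drives the whole replicated study and feeds
`compare_distributions()`, whose `range_overlap` column quantifies how
much the two arms' summary ranges overlap (the study's central finding
is that they overlap almost completely).

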