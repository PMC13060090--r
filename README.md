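# metabodule

Discovery of disease-associated *metabolic modules* from paired
microbiome–metabolome data.

Case-control cohorts are increasingly profiled with both shotgun
metagenomics (summarised as enzyme-class abundances, EC numbers) and
metabolomics. Differential-abundance testing yields per-feature association
p-values for each omic, but single features are hard to interpret and
predefined pathways dilute localised perturbations. `metabodule` integrates
the two p-value tables on a global bipartite enzyme–metabolite network
(edges join each reaction to its substrate and product compounds) and
extracts connected subgraphs — custom modules — enriched for
disease-associated enzymes *and* metabolites, with a topology-aware
permutation test for significance. It is aimed at microbiome researchers who
already have per-feature association statistics and a reference metabolic
network, and at methodologists benchmarking active-module discovery.

## Method in brief

1. **Projection.** P-values are assigned to the network nodes that have
   them ("observed"); the rest are "unobserved".
2. **Mixture modelling.** Each omic's p-values are modelled as a
   beta-uniform mixture
   `f(x | a, λ) = λ + (1 − λ) a x^(a−1)` (uniform noise + Beta(a, 1)
   signal), fitted by maximum likelihood. A threshold τ at FDR 0.1 follows
   in closed form from the noise bound `π_ub = λ + (1 − λ)a`; observed nodes
   with `p < τ` are **anchors**.
3. **Co-membership sampling.** Over `n_iter` Monte-Carlo iterations,
   unobserved nodes get p-values drawn from the fitted mixture, every node
   is labelled disease-associated (DA) with probability decreasing in its
   p-value, and `M[u, v]` records how often two anchors are joined by a path
   of < k edges through DA nodes.
4. **Clustering + Steiner completion.** Anchors are clustered by
   average-linkage on `1 − M` (dendrogram cut at 0.8) and each cluster is
   completed into a connected module with a shortest-path Steiner-tree
   heuristic.
5. **Significance.** Observed p-values are shuffled within node type B
   times, the whole pipeline is rerun per shuffle, and each real module with
   (N_EC, N_met, p̂) gets a permutation p-value — the fraction of shuffles
   yielding at least as many valid modules and a module dominating it —
   followed by Benjamini–Hochberg correction (significance at q < 0.1).

Baselines for comparison with predefined pathways are included: one-sided
Fisher's exact over-representation analysis (`ora()`) and module–pathway
overlap tests with a containment ("mostly contained", > 80% of module
nodes) flag (`module_pathway_overlap()`).

A synthetic benchmark (`generate_network()`, `plant_signal()`,
`recovery_metrics()`) plants a connected module with Beta-distributed
p-values at configurable coverage, so every stage is testable without any
external data.

## Worked example

```r
library(metabodule)

net <- generate_network(n_ec = 60, n_met = 60, seed = 5)
sim <- plant_signal(net, module_size = 8, a_signal = 0.05,
                    coverage_ec = 1, coverage_met = 1, seed = 5)
an   <- project_scores(net, sim$ec_scores, sim$met_scores)
fits <- fit_bum_per_type(an)
fits$EC
#> Beta-uniform mixture fit
#>   a = 0.0740, lambda = 0.9028, noise bound pi_ub = 0.9100
#>   n = 60, logLik = 45.42
#>   anchor threshold tau = 0.008321 at FDR = 0.1

cfg    <- sampling_config(n_iter = 300, seed = 7)
disc   <- discover_modules(an, fits, cfg)
tested <- permutation_test(an, fits, cfg, disc$modules, B = 49, seed = 11)
summary(tested)
#> Module set: 1 module(s), 1 valid
#>  module_id n_nodes n_ec_anchors n_met_anchors        p_hat valid p_perm    q
#>          1       8            4             3 0.0002438433  TRUE   0.02 0.02

recovery_metrics(tested, sim$truth)
#> best_jaccard    precision       recall
#>            1            1            1
```

Reading the output: the EC mixture fit estimates ~90% of observed EC
p-values as noise and sets the anchor threshold at τ ≈ 0.0083; discovery
finds one module of 8 nodes built around 4 EC and 3 metabolite anchors with
mean anchor p-value 2.4e-4; 0 of 49 score shuffles produced a comparable
module, so p_perm = (0+1)/(49+1) = 0.02, significant at q < 0.1. The module
exactly recovers the planted truth (Jaccard 1).

For file-based runs, `run_pipeline(run_config(...))` reads the edge list and
score TSVs and writes `anchors.tsv`, `module_nodes.tsv`,
`module_summary.tsv`, a fit report, enrichment tables (when a pathway file
is given) and a `manifest.yaml` from which the run can be reproduced
byte-identically. The same pipeline is scriptable via
`inst/scripts/metabodule.R` (subcommands `simulate`, `fit-bum`, `discover`,
`test`, `enrich`, `run`).

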