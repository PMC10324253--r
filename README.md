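# amendr

Active module identification from paired differential-expression
contrasts on a protein–protein interaction (PPI) network.

Many experiments come in pairs whose *relationship* is the question: a
knockout and an over-expression of the same gene (inverse regulation
expected), or two drugs for the same condition (equivalent regulation
expected). For gene $i$ with log2 fold changes $\beta_{i1}, \beta_{i2}$
and p-values $p_{i1}, p_{i2}$ from the two contrasts, the **equivalent
change index**

$$\lambda_i = \mathrm{sign}(\beta_{i1}\beta_{i2})\,
  \frac{\min(|\beta_{i1}|,|\beta_{i2}|)}{\max(|\beta_{i1}|,|\beta_{i2}|)}\,
  (1 - \max(p_{i1}, p_{i2})) \in [-1, 1]$$

scores that relationship per gene. `amendr` finds a **single connected
subnetwork** of the PPI network enriched for extreme ECIs in the chosen
direction, by iterating: ECI-derived seeds → random walk with restart on
a coreness-normalized transition matrix $(A_N)_{ij} = k_i/\sum_{l\sim j}k_l$
(restart probability chosen per iteration by grid search) → shift of the
propagation scores by a decaying quantile $f(i)=\eta_0 e^{-d(i-1)}$ → a
Heinz-style heuristic for the maximum-weight connected subgraph → module
score $f(G)=\bar Z_G \times \bar C_G$ (mean standardized ECI × mean
core-clustering coefficient). The decay $d$ is calibrated to land the
schedule at a user-chosen module size $n$; the highest-scoring module
along the trace is returned. The package is aimed at computational
biologists with DE result tables (limma/edgeR style) and a STRING-like
interaction network in hand.

Also included: hypergeometric overrepresentation analysis, the
permutation-based empirical-to-hypergeometric ratio (EHR/mEHR), Jaccard
and nested consistency indices with bootstrap significance, a synthetic
planted-module generator used for end-to-end validation, readers for
edge-list/GraphML/STRING-links/GMT formats, and a small CLI
(`inst/cli/amend.R`) with `run`, `simulate`, `eval` and `consistency`
verbs.

## Worked example

A synthetic instance with a 15-gene inversely-regulated module planted in
a 500-node scale-free background:

```r
library(amendr)

sim <- simulate_amend_data(synthetic_spec(N = 500, m = 15, seed = 1))
run <- run_amend(sim$graph, sim$stats, amend_config(n = 15, s = -1, eta0 = 0.5))
run
#> <amend_run> module of 13 nodes / 33 edges (score 3.9774, iteration 9 of 9,
#>   alpha 0.821, eta0 0.5, decay 0.173)

glance(run)
#> # A tibble: 1 × 8
#>   n_nodes n_edges score iteration alpha  eta0 decay n_iterations
#>     <int>   <dbl> <dbl>     <int> <dbl> <dbl> <dbl>        <int>
#> 1      13      33  3.98         9 0.821   0.5 0.173            9

jaccard(run$module$nodes, sim$planted)
#> [1] 0.8666667

module_stats(run, stats = sim$stats)
#> # A tibble: 1 × 5
#>   n_nodes n_edges edge_density median_eci prop_significant
#>     <int>   <dbl>        <dbl>      <dbl>            <dbl>
#> 1      13      33        0.423     -0.838                1
```

Thirteen of the 15 planted genes are recovered and nothing else (Jaccard
0.87): the run filtered 515 nodes down through nine iterations
(`tidy(run)` shows the trace: 254 → 163 → … → 13 nodes, with the mean
standardized ECI rising monotonically from 0.34 to 4.72), and the
returned module's median ECI of −0.84 reflects the planted inverse
signal. `autoplot(run)` draws the trajectory; `plot_module(run,
sim$stats)` draws the module shaded by ECI.

With real data, replace the synthetic instance by
`load_network()`/`read_de_table()`/`prepare_gene_stats()`, and evaluate
with `hypergeom_ora()` + `ehr()` against a GMT collection via
`read_gmt()`.

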