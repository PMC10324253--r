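---
title: "Identifying active modules from paired differential-expression contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying active modules from paired differential-expression contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amendr)
```

## The problem

Given two treatment-versus-control experiments measured on the same genes
and a protein–protein interaction (PPI) network, we want a *single
connected* subnetwork — an active module — whose genes are strongly and
consistently regulated across the two experiments. Typical use cases are
knockout/over-expression pairs, where inverse regulation is expected, and
two-drug comparisons, where equivalent regulation is expected.

## The per-gene statistic: the equivalent change index

For gene $i$ with log2 fold changes $\beta_{i1}, \beta_{i2}$ and p-values
$p_{i1}, p_{i2}$ from the two contrasts, the equivalent change index is

$$\lambda_i = \mathrm{sign}(\beta_{i1}\beta_{i2})\,
  \frac{\min(|\beta_{i1}|,|\beta_{i2}|)}{\max(|\beta_{i1}|,|\beta_{i2}|)}\,
  \bigl(1 - \max(p_{i1}, p_{i2})\bigr) \in [-1, 1].$$

$+1$ is exactly equivalent change, $-1$ exactly inverse change. The user
supplies the direction of interest (DOI) $s = \pm 1$. We define
$\lambda_i = 0$ whenever either $\beta$ is zero (this also covers the
$0/0$ ratio) — the data carry no usable evidence of joint change; the
source experiments do not prescribe a convention for this corner, so it is
a package choice. ECI significance flags can be carried through from an
upstream bootstrap test; the package reports the proportion of significant
module genes as unavailable rather than re-deriving the flags, which is
out of scope.

Standardized values $z_i = s\,(\lambda_i - \bar\lambda)/\mathrm{sd}(\lambda)$
are computed once over the full data set (and kept fixed as the network
shrinks), so that DOI genes score positive. The sign flip is applied after
centering/scaling; the two orders differ only by the sign of the affine
map, and one is fixed for reproducibility.

## The iterative procedure

Each iteration runs on the current (connected) network:

1. **Seeds.** $p_{0i} \propto |\lambda_i|$ if $s\lambda_i > 0$, else
   $c\,|\lambda_i|$, normalized to sum 1. Seeds are re-derived from the
   *original* ECIs of the surviving nodes each iteration — propagated
   scores are never fed back, which would compound diffusion bias. The
   default $c = 0.5$ halves the prior weight of genes regulated against
   the DOI, which still outrank unchanged genes.
2. **Random walk with restart.** $P_t = (1-\alpha) A_N P_{t-1} + \alpha P_0$
   iterated to its fixed point. $A_N$ is column-stochastic with entries
   $k_i / \sum_{l \sim j} k_l$, where $k$ is node coreness: PPI databases
   over-ascertain hub proteins, and coreness normalization attenuates that
   degree bias (on a $k$-regular graph it reduces exactly to degree
   normalization). The restart probability is chosen per iteration by a
   grid search (default: 8 evenly spaced values in $[0.05, 0.95]$), taking
   the value whose downstream module scores best; ties go to the smaller
   restart.
3. **Quantile shift.** Scores are shifted by their $k$-th sample quantile,
   producing signed node weights with roughly a fraction $k$ negative;
   $k$ is the filtering rate for the iteration.
4. **Maximum-weight connected subgraph.** A Heinz-style heuristic extracts
   a connected subgraph of large total shifted weight (below).
5. **Scoring.** $f(G) = \bar Z_G \times \bar C_G$: mean standardized ECI
   times mean core-clustering coefficient. The core-clustering coefficient
   of a node (an MCODE statistic) is the edge density of the maximal
   $k$-core of its closed neighborhood, computed within the module's
   induced subgraph; unlike the ordinary clustering coefficient it is not
   dragged down by sparsely connected neighbors. We include the node
   itself in the neighborhood (the MCODE convention); a single node or an
   edgeless core has density 0.

The filtering rate decays as $f(i) = \eta_0 e^{-d(i-1)}$. Given $\eta_0$
and a target module size $n$, the decay $d$ is calibrated by simulating
sizes $s_{i+1} = \max(1, \lceil s_i (1 - f(i)) \rceil)$ until they stop
changing, and taking the smallest value on a fixed geometric grid (60
points in $[10^{-3}, 10]$) whose simulated final size reaches $n$; the
final size is non-decreasing in $d$, which the scan relies on. The ceiling
with floor 1 is a package choice the calibration depends on, hence fixed
and documented.

### Stopping and module selection

The run stops when any of these holds: the node set did not change; the
iteration's best score failed to improve on the previous one; the module
fell below the target size $n$; the size fell below 2; or 100 iterations
elapsed. The returned module is the argmax of the score over the recorded
trace.

The first rule alone is not a practical stopping criterion: for any
filtering rate $k > 0$ the interpolated quantile leaves at least one node
strictly negative, the subgraph solver can almost always shed it
beneficially, and because $\bar Z$ of a module of the most extreme genes
exceeds $\bar Z$ of any superset while $\bar C$ of a 2-clique is 1, the
trace would otherwise walk down to the single most extreme adjacent pair
and the argmax would follow it. The score-improvement rule implements
"stop when the network score stops changing", and the size guard enforces
the calibration's own model — the decay was chosen so the schedule lands
at $\approx n$ nodes, so filtering past $n$ means the schedule's
approximation has run out, not that better modules lie below.

### The subgraph solver

Exact maximum-weight connected subgraph solving reduces to a
prize-collecting Steiner tree and is expensive; the package uses a
deterministic heuristic: (i) contract each connected component of
positive-weight nodes into a meta-node carrying the component's total
weight; (ii) connect meta-nodes by shortest paths through negative nodes,
a path costing the sum of $|w|$ along its interior; (iii) build the
complete meta-graph and take its minimum spanning tree under edge cost
(path cost) − (incident meta weights); (iv) prune tree leaves whose
connector cost exceeds their weight, worst first; (v) expand back to
original nodes and absorb any positive node adjacent to the selection
(always cost-free). All tie-breaks are by ascending node identifier. The
output is guaranteed connected and never lighter than the heaviest single
positive meta-node (enforced by an explicit fallback). An exact bitmask
enumeration (`mwcs_exact()`, up to 16 nodes) serves as an independent
oracle in the tests; on the randomized test suite the heuristic is checked
to stay within the enumerated optimum and above 60% of it.

### Choosing the starting filtering rate

$\eta_0$ can be fixed (default 0.5) or optimized by global-best particle
swarm over $[0.1, 0.9]$ (defaults: swarm 10, 20 iterations, inertia 0.7,
cognitive = social = 1.5), each evaluation being one full deterministic
run; the swarm RNG is fully seeded, so the result is reproducible. These
hyperparameters are package defaults — the method itself does not
prescribe them.

## Numerical choices

* RWR convergence: max-norm change $\le 10^{-10}$, cap $10^4$ iterations;
  hitting the cap flags the result instead of failing. The power iteration
  is validated against the direct solve
  $P = \alpha (I - (1-\alpha)A_N)^{-1} P_0$.
* Quantiles: linear interpolation between order statistics (R type 7),
  fixed so shifted weights are reproducible across implementations.
* Degenerate inputs: zero-variance ECIs, all-zero seed vectors, isolated
  nodes in the transition matrix, empty gene universes and all-nonpositive
  weight vectors raise classed errors (`amendr_input_error`,
  `amendr_algorithm_error`); the command-line wrapper maps them to exit
  codes 2 and 3.
* Disconnected inputs are reduced to the largest connected component with
  a warning; equal-sized components tie-break to the one holding the
  lexicographically smallest identifier.

## Evaluation statistics

Overrepresentation uses the upper-tail hypergeometric test against the
network's gene universe with Benjamini–Hochberg adjustment. The
empirical-to-hypergeometric ratio (EHR) re-runs the full pipeline on data
whose ECIs (and flags) were permuted uniformly across genes — the
permutation scheme is a package choice, as the source method leaves it
unspecified — building a per-pathway null of enrichment scores
($\max$ over modules of $-\log_{10} p$); a pathway is empirically
validated if its empirical p (ties counted toward the null, the
conservative reading of "greater than") and its minimum adjusted
hypergeometric p are both $\le 0.05$. Consistency between modules uses the
Jaccard and nested indices with a bootstrap that resamples each module's
binary membership vector over the shared universe. The package default of
50 permutations for the EHR keeps desk-scale runs affordable;
publication-scale analyses would raise it (the original analyses used
1000).

## The synthetic generator

`synthetic_spec()` describes the regime the method targets: a
preferential-attachment background of `N = 500` nodes (heavy-tailed
degrees, mimicking PPI ascertainment), a connected planted module of
`m = 15` nodes (random spanning tree plus extra edges with probability
0.3) tied in by 2 bridge edges, planted $|\lambda| \in [0.7, 0.95]$ in the
DOI and background ECIs $\sim N(0, 0.1)$, essentially all below 0.3 in
magnitude. DE quadruples are constructed to reproduce the drawn ECIs
exactly through `compute_eci()`, so the whole pipeline — not just the
graph layer — is exercised. What the generator does *not* emulate:
correlated expression noise between neighboring genes, mis-mapped
identifiers, edge-confidence structure, multiple overlapping true modules.
Passing the recovery test therefore demonstrates correct mechanics and
sensible behavior under the intended signal regime, not performance on
real transcriptomes.

Test and acceptance runs use deliberately small problem sizes — a
515-node recovery instance, oracle suites of 200 graphs of up to 14
nodes, 10–50 permutations — chosen so the full suite completes in a few
minutes while still exercising every code path; all are parameters, not
limits of the implementation.

## A worked run

```{r example}
sim <- simulate_amend_data(synthetic_spec(N = 500, m = 15, seed = 1))
run <- run_amend(sim$graph, sim$stats, amend_config(n = 15, eta0 = 0.5))
glance(run)
jaccard(run$module$nodes, sim$planted)
tidy(run)
```

```{r plot, fig.width = 7, fig.height = 5}
autoplot(run)
```

## Limitations

* One connected module per run; methods returning several disconnected
  modules answer a different question.
* The MWCS step is heuristic; its tested floor (≥ 60% of the enumerated
  optimum on small graphs) is an empirical regression bound, not a proof.
* Identifier matching is exact-string; mapping tables must be supplied
  explicitly.
* The score's preference for small extreme cliques is held in check by the
  stopping rules, so the returned module size tracks the target `n`; `n`
  itself remains a user judgement, and scanning a few values is advisable.
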