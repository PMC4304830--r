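# grndesign

Quantify the **topological robustness** of gene regulatory networks (GRNs)
and **evolve robust network wirings** in silico.

A GRN is represented as a signed adjacency matrix `M` (`M[i, j] = +1` if
gene *j* activates gene *i*, `-1` if it inhibits it, `0` otherwise) and
simulated with Hill-kinetics ODEs,

```
dG_i/dt = a_i * prod_j K_ij^n / (G_j^n + K_ij^n)      (inhibitors j)
              * prod_k G_k^n / (G_k^n + Ka_ik^n)      (activators k)
        - b_i * G_i
```

with uniform cooperativity `n` (Hill coefficient, 2/3/4 = low/medium/high).
The robustness of a *wiring* for a behavior `a` is the fraction of the
kinetic-parameter space over which the behavior survives, estimated by
Monte Carlo over uniform draws from biologically feasible ranges
(`a_i ∈ [10, 100]` nM/min, `b_i ∈ [0.02, 0.15]` /min, thresholds
`∈ [10, 100]` nM):

```
R_a^G = 100/S * sum_i 1{ f_a(p_i) satisfies criterion rho },   S = 10,000
```

Two behaviors ship with the package: **sustained oscillation**
(per-gene score `f_osc = min(SD, SD_max) · LC · PN` on a 2100-min
trajectory, satisfied when the gene-average reaches `SD_max/2` and every
gene shows at least two peaks) and **bistability** (paired 600-min
simulations with swapped high/low initializations; flat within 0.01 nM
over minutes 400–600 and the higher-initialized gene settles higher, in
both runs). A quantitative semantics accumulating `|f_a(0) − f_a(p)|` is
also available.

On top of the estimator sits a **genetic algorithm** over topology
matrices (tournament selection, block crossover, single-entry mutation,
worst-half replacement) with a two-stage **fitness approximation** (cheap
probe, full evaluation only above a threshold) and an **archive** that
memoizes every evaluated wiring and retains its best-known score. Analysis
tools include complexity metrics (`c = I/N²`, `K = I/N`), replicated
robustness verification, comparison reports and **phase response curves**.

The ODE right-hand side, the Dormand–Prince 5(4) integrator, the behavior
detectors and the Monte Carlo loop are implemented in C++ (Rcpp); a
10,000-sample robustness estimate for a 3-gene oscillator takes tens of
seconds on one core.

## Worked example

```r
library(grndesign)

toggle <- library_topology("toggle_switch")
toggle
#> GRN topology: 2 genes, 4 interactions (c = 1.00, K = 2.00)
#>    A  B
#> A  1 -1
#> B -1  1

set.seed(1)
estimate_robustness(toggle, bistability_spec(), coop = 2, n_samples = 2000)
#> bistability robustness (boolean): 36.85% over 2000 samples
```

About 37% of uniformly drawn parameter sets leave the toggle switch
bistable at low cooperativity — the wiring, not a tuned parameter set,
carries the behavior. Robustness rises steeply with cooperativity (rerun
with `coop = 3` and `coop = 4`). The same one-liner scores oscillators:

```r
dnf <- library_topology("delayed_negative_feedback_3")  # A -> B -> C -| A
set.seed(1)
estimate_robustness(dnf, oscillation_spec(), coop = 3, n_samples = 2000)
#> oscillation robustness (boolean): 78.1% over 2000 samples

complexity_metrics(dnf)   # I = 3, c = 0.33, K = 1
```

Evolving a robust bistable wiring from scratch (scaled-down budget; the
search recovers the mutual-repression toggle switch):

```r
set.seed(7001)
run <- evolve_topology(bistability_spec(), coop = 2, n_genes = 2,
                       config = ga_config(population_size = 20, generations = 10,
                                          probe_samples = 200, full_samples = 2000))
run$best$topology   # A -> A, B -> B, A -| B, B -| A
```

Other entry points: `simulate_grn()` / `write_trajectory_csv()` for
trajectories, `verify_robustness()` for replicated estimates,
`compare_topologies()` for ranked reports, `phase_response_curve()` for
sensitivity analysis, and `inst/scripts/grn-design.R` for a command-line
interface (`simulate`, `robustness`, `evolve`, `compare`, `prc`,
`complexity`; all honor `--seed`).

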