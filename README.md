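# burstid

Transcription in single cells happens in bursts: a gene's promoter switches
stochastically between an inactive state G and an active state G\* (rates
`kon`, `koff`), mRNA is made only in the active state (rate `ksyn`) and
degraded at rate `kd`. With time in units of `kd` (so `kd = 1`), the
telegraph model has three free parameters θ = (kon, koff, ksyn), and a
popular idea is to infer them per gene from snapshot scRNA-seq count
histograms via the stationary distribution of the chemical master equation
(CME). **burstid** does that inference — and, just as importantly, tells you
when the data cannot support it.

The package provides:

* a truncated-state-space CME steady-state solver for the telegraph model,
  with a guaranteed neglected-tail bound (≤ 1e-4) and validation against
  the analytic Beta–Poisson stationary law;
* binomial "dropout" noise at a known capture rate β;
* a precomputed log-spaced grid **model library** (default 60³ points over
  kon, koff ∈ [1e-3, 1e3], ksyn ∈ [10^-0.3, 10^2.3]) that turns
  maximum-likelihood fitting into one coarse surface pass plus a bounded
  local refinement;
* **profile-likelihood confidence intervals** (the χ²₁(0.95)/2 ≈ 1.92
  threshold) and the **APM** precision metric,
  `APM = log_T(ub/lb)` with T = 3 for `ksyn` and T = 100 for `kon`/`koff`;
  a parameter set is practically identifiable when the maximum APM over
  the three parameters is below 1;
* a sampling-free **a priori** mode: replacing data with exact model
  probabilities turns −LL into the cross-entropy surrogate
  `H(θ) = −N Σ_x P_tar(x) log P_sim(x|θ)`, whose linearity in the cell
  number N makes cell-number sweeps and landscape scans cheap;
* bootstrap replicate fitting, distribution summary statistics, and a
  sensitivity-matrix (minimum singular value) structural check.

It is written tidyverse-style: histograms and results are tibbles, fitted
objects have `tidy()`/`glance()` methods and `autoplot()`.

## Worked example

Can an experiment with 200 cells and perfect capture pin down the kinetics
of a bursty gene with kon = 0.05, koff = 0.1, ksyn = 10?

```r
library(burstid)

lib <- build_model_library(grid_spec(n = 12), beta = 1)   # reduced library
tgt <- apriori_target(telegraph_params(kon = 0.05, koff = 0.1, ksyn = 10),
                      N = 200)
pr  <- ground_truth_profile(tgt, lib)
pr
#> <telegraph_profile> N = 200  beta = 1  max APM = 0.2995 (identifiable)
#>   param         lb          ub       apm
#> 1   kon 0.02659636  0.08206233 0.2446608
#> 2  koff 0.04798214  0.19055478 0.2994701
#> 3  ksyn 9.04032053 11.17975419 0.1933438
```

Each row is one parameter's 95% profile-likelihood CI and its APM. The
widest is `koff` (CI 0.048–0.19, i.e. a factor ~4, APM = 0.30 on the
T = 100 scale); since the maximum APM is below 1, this parameter set is
practically identifiable at 200 cells. Slowing deactivation tenfold
(koff = 0.01) puts the gene on the slow-switching ridge where only the
kon/koff ratio is well constrained — the switching-rate CIs blow up to
1.4 decades and the maximum APM rises to 0.68.

The same machinery answers design questions: for kon = 0.23, koff = 0.1,
ksyn = 3.5,

```r
cells_for_identifiability(telegraph_params(0.23, 0.1, 3.5),
                          build_model_library(grid_spec(n = 12), beta = 0.3),
                          N_ladder = c(1e3, 1e4, 1e5, 1e6))$N_min
#> [1] 1e+05
```

at 30% capture you need 100k cells, while at 100% capture 1000 cells
suffice — degraded capture costs two orders of magnitude in cells here.

For real data: `read_counts()` ingests a genes × cells TSV/CSV or
MatrixMarket triplet, `infer_kinetics()` fits and profiles every gene, and
`write_results()` emits a TSV plus a JSON provenance sidecar. A thin CLI
(`exec/burstid`) wraps the same functions
(`build-library`, `infer`, `simulate`, `apriori`, `apriori-scan`,
`sensitivity`).

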