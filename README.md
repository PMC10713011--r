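# stablefc

Stable estimation of time-varying functional connectivity (FC) states from
multichannel neural time series.

Resting-state fMRI and MEG studies describe the temporal reorganization of
brain networks as switching between a small set of recurring FC states,
commonly modeled with a hidden Markov model whose states are zero-mean
Gaussians with full covariance matrices:

```
x_t | s_t = k  ~  N(0, Sigma_k)          (state k = one FC pattern)
P(s_t = k1 | s_t-1 = k2) = theta_k1k2,   P(s_0 = k) = eta_k
```

The model is fit by variational Bayes from a random initialization, so
repeated runs on the same data can return different state decompositions.
`stablefc` implements the model (session-aware: the first sample after a
recording discontinuity uses `eta`, not `theta`) together with two ensemble
procedures that stabilize the estimate, and the tooling to quantify
stability:

* **BR-HMM (best-ranked)** — run the inference `R` times, keep the run with
  the lowest variational free energy (`run_ensemble()`, `select_best()`).
* **HC-HMM (hierarchical-clustered)** — pool all `R x K` state time series,
  cluster them with Ward's linkage on the distance `1 - Pearson
  correlation`, and aggregate each cluster into one state: averaged (and
  row-rescaled) cluster time series `S`, and occupancy-weighted covariance
  `Q_i = sum_j beta_j C_j / sum_j beta_j` (`hc_hmm()`).
* **Alignment and similarity** — states of two runs are paired with the
  Hungarian algorithm on summed joint activation probabilities; similarity
  `1 - cost/max_cost` lies in [0, 1] (`align_states()`).
* **Stability protocols** — between-run similarity histograms,
  free-energy-sorted similarity matrices, and repetition-based stability
  curves versus `R` (`pairwise_similarities()`, `repetition_stability()`),
  plus per-state dynamics: fractional occupancy, lifetimes, switching rate
  (`state_metrics()`).
* **Simulator** — seeded Markov-switching Gaussian data with session
  structure and a covariance `separation` dial that controls how
  reproducible the inference is (`simulate_fc()`).

## Worked example

```r
library(stablefc)

# 3 FC states, 6 channels, 4 sessions of 500 samples, well separated
sim <- simulate_fc(K = 3, P = 6, session_lengths = rep(500, 4),
                   stay_prob = 0.94, separation = 2, seed = 7)
ts  <- standardize(sim$ts)

ens  <- run_ensemble(ts, K = 3, R = 10, base_seed = 0)
best <- select_best(ens)
best
#> hmm_fit: K=3 states, T=2000, free energy 16485.76 (converged, 70 iterations, seed 4)

hc_hmm(ens)
#> hc_hmm: 30 stacked states -> 3 clusters (sizes 10, 11, 9)

align_states(best$Gamma, path_indicator(sim$truth$true_path, 3))
#> state_alignment: K=3, similarity 0.8568 (cost 286.50 / max 2000.00)
#> pairing: 1->2 2->3 3->1

state_metrics(best$Gamma, ts$lengths)
#>  state fractional_occupancy mean_lifetime
#>      1               0.2829         17.16
#>      2               0.3736         28.33
#>      3               0.3435         22.13
#> switching rate: 0.0431 changes per modeled transition

mean(pairwise_similarities(ens))
#> [1] 0.808
```

Reading the output: the best of ten restarts matches the ground-truth state
sequence with aligned similarity 0.86 (soft posteriors cap this below 1
even for a perfect decoding), the states are sticky (mean lifetimes 17-28
samples), and the ten restarts agree with each other at 0.81 on average.
The cluster sizes 10/11/9 instead of 10/10/10 show one restart that split
one state and merged two others — exactly the run-to-run variability the
ensemble procedures are designed to absorb.

A command-line interface over the same functions ships with the package
(`simulate`, `fit`, `br`, `hc`, `align`, `stability` subcommands):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/stablefc.R", package = "stablefc"))')
Rscript $CLI simulate --k 4 --channels 10 --sessions 4x1000 --seed 0 --out sim/
Rscript $CLI hc --data sim/X.csv --sessions sim/sessions.txt \
               --k 4 --runs 20 --seed 0 --out hc/
```

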