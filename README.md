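# myoratchet

Single-molecule trajectory inference for muscle myosin weak and strong
binding.

When a myosin II head, held in a thick-filament geometry, searches an actin
filament, it diffuses about its tether, weakly and transiently binds actin
sites for hundreds of microseconds, and finally binds strongly where it will
ATP-cycle. Microsecond gold-nanoparticle tracking (40 &mu;s frames,
sub-nanometre localization) sees all of this as a 1D position record along
the actin axis. This package implements the full analysis chain for such
records, plus a synthetic-data generator so every stage is testable without
raw microscopy data:

* **Simulation** — `kinetic_scheme()` / `simulate_trajectory()`: hidden-state
  trajectories (Gaussian detached state, SD 12.5 nm; Gaussian binding states,
  SD 4.7 nm; exponential dwells; ATP-dependent strong binding with rate
  `slope*[ATP] + intercept`), plus `simulate_spot_stack()` (Poisson spot
  images) and `simulate_atp_trace()` (fluorescent-ATP spike trains).
* **Localization** — `localize_radial_symmetry()`,
  `localize_gaussian_refine()`, `screen_tracks()`, `project_major_axis()`.
* **Step size** — `fit_two_state_hmm()`: EM for a two-state Gaussian HMM
  with fixed emission SDs; the step is the bound minus detached mean.
  `compare_step_groups()` for group statistics (t-test, Hedges' g).
* **Transient-state detection** — `run_ihmm()` / `run_repeated()`: a
  beam-sampled hierarchical-Dirichlet-process HMM with one reserved detached
  state, an unbounded pool of binding states sharing a fixed emission SD,
  and binding&rarr;binding transitions forbidden. States under 1% occupancy
  or with sub-resolution dwells are filtered (`filter_states()`).
* **Summaries** — `fit_gaussian_mixture_1d()` (binding-position peaks),
  `summarize_peaks()` (access ratios and dwells per peak),
  `fit_exponential_dwell()` (left-truncated exponential dwell fits),
  `dwell_ratio()`, `powerstroke_decompose()`.
* **ATP kinetics** — `extract_trace()`, `detect_spikes()`,
  `fit_waiting_times()` (double-exponential, slower rate = binding rate),
  `correct_cy3_rate()` (2.8&times;), `fit_rate_line()`,
  `rate_from_binding_dwells()`.

## Worked example

Simulate a 400 ms record with two weak-binding sites hidden in the detached
state, run 5 constrained-iHMM chains, and summarize:

```r
library(myoratchet)

sch <- kinetic_scheme(sites = list(weak_site(-15, 0.5, 200),
                                   weak_site(22, 0.5, 300)),
                      duration_us = 4000 * 40)
traj <- simulate_trajectory(sch, seed = 81)

cfg  <- ihmm_config(mcmc_iterations = 400, window_frames = 4000)
runs <- run_repeated(traj, cfg, n = 5, seed = 80)
runs
#> iHMM runs: 5 chains; 10 retained binding states (median 2 per chain)

head(pooled_states(runs), 4)
#>   chain state relative_position_nm occupancy n_events mean_dwell_us
#> 1     1     2            -15.56386   0.08050       54      238.5185
#> 2     1     3             21.72522   0.14350       54      425.1852
#> 3     2     2            -13.93236   0.08800       55      256.0000
#> 4     2     3             22.57213   0.14825       60      395.3333
```

Each chain reports binding states by their position relative to the inferred
detached mean (here the two sites are recovered within ~1 nm), their
occupancy, visit count, and mean dwell; `summarize_peaks()` pools chains
into per-peak access ratios and dwell-time fits. The step-size route:

```r
sch2 <- kinetic_scheme(sites = list(weak_site(44, 1, 1000)),
                       strong_site_index = 1, atp_nM = 2000,
                       encounter_rate_s = 50, duration_us = 4e5)
fit <- fit_two_state_hmm(simulate_trajectory(sch2, seed = 2))
fit
#> Two-state HMM fit (n = 10000): detached -0.69 nm, bound 43.99 nm, step 44.68 nm
#>   occupancy detached 10.5%, bound 89.5%; logLik -30932.6
```

The step (44.7 nm here) is the detached-to-strong-binding displacement; at
2 &mu;M ATP the bound state dominates occupancy, which is why states are
identified by their fixed emission SDs rather than by occupancy.

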