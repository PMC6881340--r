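---
title: "Detecting transient myosin binding states in microsecond tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient myosin binding states in microsecond tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoratchet)
```

## The measurement and the model

A muscle myosin head tethered in a synthetic (DNA-origami) thick filament
diffuses along an actin filament, transiently and weakly binds actin sites
during its diffusive search, and eventually binds strongly, swings its lever
arm, and waits for ATP. Gold-nanoparticle darkfield tracking resolves this at
40 microseconds and better than a nanometre, projected on the actin (major)
axis. Statistically, the 1D position record is a hidden Markov process:

* a **detached** state — tethered diffusion, Gaussian emission with a large
  SD (12.5 nm by default, set by the tether geometry);
* a set of **binding** states — one per actin site the head can reach, all
  sharing a small emission SD (4.7 nm, the strong-binding residual motion),
  each with its own mean position and a sub-millisecond exponential dwell;
* an optional **strong-binding** state whose dwell at limiting ATP is the
  ATP waiting time, `1 / (slope * [ATP] + intercept)`.

The number of binding states is not known in advance. That is the point of
the nonparametric (HDP-HMM) inference: the state space is unbounded and the
data decide how many binding states are occupied.

## What the simulator generates (and what it does not)

`kinetic_scheme()` + `simulate_trajectory()` implement an
alternating-renewal process. From the detached state the head enters site
*k* each frame with probability `encounter_rate_s * dt * access_weight[k]`;
dwells are drawn in continuous time from the site's exponential and rounded
to whole frames with a one-frame minimum — the 40 microsecond observability
floor. Emissions are frame-wise independent Gaussians.

Defaults are the study conditions: 12.5 / 4.7 nm emission SDs, 40
microsecond frames, 10,000-frame (400 ms) records. Two quantities the
tracking data do not constrain are set once here:

* **encounter rate** (default 1000 per second, i.e. a 1 ms mean detached
  sojourn): gives a realistic total weak-binding occupancy near 20% under
  the five-peak layout and per-site occupancies safely above the 1%
  reporting floor;
* **lever-arm substeps** default off — the tracking data resolve a single
  apparent step; substeps exist in the generator only to exercise the
  decomposition arithmetic.

Not emulated: motion blur within an exposure, nanoparticle optics, camera
noise beyond Poisson photon statistics plus Gaussian read noise. Passing
tests therefore validate the inference chain under the stated statistical
model, not instrument-specific artifacts.

`simulate_spot_stack()` integrates the Gaussian point-spread function over
pixel areas (difference of normal CDFs), so noiseless centroids equal the
true center analytically and localization oracles are exact. Pixel centers
sit at integer coordinates with the first pixel's center at the origin;
nanometres are pixels times pitch (123 nm by default).

## Spot localization and axis projection

`localize_radial_symmetry()` is the standard non-iterative
radial-symmetry-center estimator (gradients on the half-pixel midpoint grid,
weighted least-squares intersection of gradient lines); it reaches the
sub-nanometre regime at high photon counts and is cheap enough for
25,000 fps stacks. `localize_gaussian_refine()` runs a per-frame
Levenberg-Marquardt fit of an isotropic Gaussian plus background; note that
its fitted width includes the pixel-integration variance (sigma^2 + 1/12
pixels squared).

`project_major_axis()` takes the leading eigenvector of the 2D position
covariance. The sign of the axis is chosen data-driven so that binding
excursions are positive: frames in low-local-variance windows (bound-like,
narrow emission) should have a larger mean position than high-variance
(diffusing) frames. A pure skewness rule fails here because the broad
detached component dominates the third moment even when binding sits on the
positive side; the local-variance rule targets the binding side directly and
reduces to a skewness fallback on very short records. The convention is
recorded in the output metadata.

Screening (`screen_tracks()`) uses two rules — major-axis span within a
window around the expected tether span, major/minor SD ratio at least 1.5 —
as a stated approximation of the original geometric screening, whose exact
criteria are not public. Both thresholds are arguments.

## The two-state step fit

`fit_two_state_hmm()` estimates the detached-to-strong-binding displacement
with EM over two Gaussian means and a 2x2 transition matrix, emission SDs
held fixed at 12.5 / 4.7 nm. Fixing the SDs is what identifies the states
structurally: the broad state is detached whatever its occupancy. This
matters because at micromolar ATP the bound state dominates occupancy, so an
occupancy- or mode-based labeling would swap states; instead EM runs from
two deterministic initializations (histogram mode assigned to either state)
and keeps the higher likelihood. Convergence: log-likelihood change below
1e-6 (at most 500 iterations); the likelihood trace is exposed and tested
for monotonicity. A fit with a state under 1% occupancy or a single-state
Viterbi path is flagged unreliable rather than trusted.

`compare_step_groups()` reports group means, SEMs, the difference with
propagated SEM, a two-tailed Student's t-test and Hedges' g with the
small-sample correction. (With 26 + 26 trajectories and SEMs of 2.4 nm these
formulas give g of about 0.87 and p of about 0.003; published step-size
tables sometimes quote other combinations, and this implementation simply
computes the standard formulas.)

## The constrained infinite HMM

`run_ihmm()` is a beam-sampled hierarchical-Dirichlet-process HMM with three
structural constraints:

1. state 1 is reserved as detached: emission SD fixed at `sd_detached`,
   mean free;
2. all binding states share `sd_bound` with distinct free means ("shared
   emission distribution" is interpreted as shared SD — distinct means are
   what makes binding positions informative);
3. binding-to-binding transition probabilities are fixed at zero: rows of
   binding states are renormalized over self-transition and
   return-to-detached. Every binding excursion is separated by the detached
   state, which is what makes "visits" and dwells well defined.

Each sweep: sample transition rows from their Dirichlet conditionals; draw
slice (beam) variables under the current path; extend the represented state
set by stick-breaking while unrepresented mass remains reachable (new state
means drawn from the prior); run forward-filter backward-sampling over the
truncated set with the constraint enforced; drop unoccupied states; update
state means conjugately; resample table counts, the shared sticks, and the
concentrations alpha and gamma under Gamma(1, 1) hyperpriors by the standard
auxiliary-variable schemes. The first sweep uses zero slice variables, which
yields an emission-driven, constraint-respecting initial path without any
separate initialization heuristic.

Choices the original description leaves open, decided here:

* **Reported sample**: the final MCMC sweep (iteration 1000) of each chain.
  Posterior spread comes from many independent chains (1000 in the original
  protocol; tests and the acceptance script use 10-25), seeded
  `seed, seed + 1, ...` so pooling is schedule-independent.
* **Mean prior**: Gaussian centered on the window mean with 50 nm SD —
  weakly informative over the ~80 nm tether span.
* **Windows**: inference requires exactly the configured window (10,000
  frames); longer records are windowed by the caller and positions made
  comparable by per-window detached-mean referencing.

### State filters

States with under 1% occupancy or sub-resolution dwells are excluded
(`filter_states()`), their frames reassigned to detached. One subtlety: a
frame-quantized dwell event is never shorter than one frame (40
microseconds), so a "mean dwell below 40 microseconds" predicate could never
fire. The filter therefore compares the truncation-corrected mean,
`mean(events) - frame_interval` — the left-truncated-exponential estimate —
to the floor. This restores the filter's purpose: flicker states whose runs
are mostly single frames fail it, which is exactly what keeps pure-detached
windows clean (the false-positive rate per chain on detached-only data is
tested at or below 10%). The raw-mean predicate remains available
(`dwell_filter = "mean"`).

### What detection can and cannot do

Detection accuracy for *positions* depends on how close a site sits to the
detached mean relative to the 12.5 nm detached SD. In the four-site
detection-accuracy layout (-12.9, -1.1, 9.9, 22.8 nm; 100 microsecond
dwells) the 9.9 nm site — 0.8 detached-SDs from center — is typically not
resolved, and near-center sites can be biased by a couple of nanometres;
outer sites are recovered within 1-2 nm. Pooled *dwell* estimates do not
depend on which sites get resolved, but they do inherit two upward pushes:
frame quantization of the generator inflates the realized mean dwell by
about 7% at the 2.5-frame scale, and chains that merge nearby sites into
one state bridge short detached gaps and lengthen apparent runs, adding
roughly 5-25% depending on the realization. Across repeated full-scale
runs the pooled estimate of a generating 100 microsecond dwell typically
lands near 110-115 microseconds. At the experimental dwell scale (160-513
microseconds, well-separated occupancies) all five peaks are recovered in
essentially every chain and these effects shrink.

## Dwell-time estimation conventions

`fit_exponential_dwell()` computes two estimates and the distinction
matters:

* the least-squares fit of the empirical CDF (midpoint plotting positions)
  to `1 - exp(-(t - truncation)/tau)` — appropriate for genuinely
  left-truncated continuous samples, e.g. dwells observed above a hard
  floor;
* the maximum-likelihood value `mean(dwells) - truncation`.

For **frame-quantized** run-length dwells (what the inference produces) the
rounding is mean-preserving, not truncating, so they are fitted with
`truncation = 0`; and because the quantized distribution has a large atom at
one frame, the continuous-CDF least-squares fit is biased upward by roughly
10-25% at 2-3-frame dwell scales while the MLE stays consistent. Pipeline
summaries of quantized dwell pools therefore headline the MLE, with the CDF
fit retained as the display/cross-check value; for continuous truncated
samples the CDF fit is the primary estimate and the two agree within a few
percent.

`summarize_peaks()` assigns each retained state to the mixture peak whose
mean plus or minus one SD contains it, computes per-chain access ratios as
fractions of binding *events* (so access and dwell stay independent
quantities; a point-fraction mode is available), averages across chains, and
pools dwell events per peak. Peaks below a 5% access floor are excluded from
dwell reporting — at the printed access ratios this excludes exactly the
1.4% leftmost peak, whose visits are too rare to dwell-fit.

The mixture itself (`fit_gaussian_mixture_1d()`) is a fixed-K (default 5)
1D Gaussian EM with seeded k-means++ restarts, an SD floor of 0.1% of the
sample SD against component collapse, dead-component reseeding, and an
exposed likelihood trace. K is user-set; no automatic model selection, since
the peak count is fixed by the analysis design.

## ATP kinetics

Fluorescent-ATP traces are reduced by `extract_trace()` (ROI mean minus the
one-pixel perimeter ring), spikes detected by a robust threshold (median
baseline, MAD noise, default 3 robust SDs, at least 2 frames — both
exposed). Waiting times are the dark gaps between spikes.
`fit_waiting_times()` fits the waiting-time survival curve with a
two-exponential mixture and designates the slower rate as the ATP binding
rate (the fast component absorbs short non-productive events); it collapses
to a flagged single exponential when the rates agree within 10%, a component
weight vanishes, or the second exponential improves the survival SSE by less
than 5%. Cy3-ATP rates convert to ATP rates by an explicit 2.8x factor
(`correct_cy3_rate()`), never silently. `fit_rate_line()` is weighted least
squares of rate on concentration; `rate_from_binding_dwells()` inverts the
single-exponential time constant of strong-binding dwells.

When simulating detection pipelines, spike durations should span several
frames (the tests use 50 ms at 1000 fps): spikes near one frame fall under
the two-frame detection floor and the missed events bias waiting times
upward.

## Problem sizes used in tests and the acceptance script

Chosen as the package's working scale: single 10,000-frame windows; 10
chains of 1000 MCMC sweeps for full-scale recovery runs (25 for the pooled
position check), smaller windows (1,500-4,000 frames) and 150-500 sweeps
for unit properties; 26 trajectories per group for the step comparison; the
printed sample sizes (4,660 positions, 708 dwells) where the analysis
quotes them. Exact-inference checks (path enumeration against
forward-filter backward-sampling) run at 8 frames and 3 states with 1e5
draws, total-variation tolerance 0.02.

## Known limitations

* Emissions are 1D after projection; lateral information is discarded.
* The sampler reports last-sweep samples, not posterior averages; single
  chains are noisy by design and conclusions should pool many chains.
* Position detection near the detached mean is density-limited (above).
* The screening rules approximate, not reproduce, the original geometric
  screen.
* No photobleaching correction or multi-channel colocalization in the
  fluorescence path.
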