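---
title: "Rotational dynamics, representational tuning, and the covariance-matched permutation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational dynamics, representational tuning, and the covariance-matched permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotdyn)
```

## The scientific question

Two families of models compete to explain motor-cortex activity during
reaching. *Representational* models treat each neuron as encoding movement
parameters — classically, a cosine function of reach direction scaled by hand
speed. *Dynamical-systems* models treat the population as a machine whose
internal state evolves under its own dynamics to generate muscle-like
outputs; their signature is rotational structure in population state space,
found by jPCA. `rotdyn` implements both generative accounts for a 13-direction
center-out reaching task, the jPCA analysis, and a permutation test — the
covariance-matched permutation test (CMPT) — that asks whether observed
rotations depend *uniquely* on the assignment of trials to task conditions,
which is what a dynamical account predicts and a tuned-neuron account does
not.

The package is simulation-first: every analysis can be exercised end to end
on data it generates itself, and externally recorded trial-averaged rates can
be analyzed by wrapping them in `population_activity()`.

## Generative models

### Cosine tuning with neuron-kinematic latencies

`simulate_representational()` draws, per neuron, a preferred angle (uniform)
and a latency `tau ~ Normal(0, latency_sd)`. The noiseless rate is a constant
preparatory level `phi * b` before the neuron's latency and a Gaussian
movement burst `b * exp(-(t - tau - mu0)^2 / (2 sigma^2))` after it, with
gain `b = (1 + cos(theta_c - theta_n)) / 2`. The offset
`mu0 = sigma * sqrt(-2 log(phi))` makes the two branches meet continuously at
`t = tau`. Variants allow signed gains (`cos` instead of the offset cosine)
and a per-neuron random gain magnitude on [0.5, 1.5]. Defaults: 200 neurons,
latency SD 72 ms (the empirically reported spread of neuron-kinematic
latencies), movement SD 56 ms (a 300–400 ms movement), `phi = 0.2`, additive
Gaussian noise with SD 0.01 drawn i.i.d. per sample (a per-trace option
exists). The simulation window is [-300, +800] ms around the go cue at a
10-ms step; the rate function is evaluated directly on the analysis grid, so
no internal oversampling is needed.

The point of this generator is a pitfall: time-shifted copies of one signal
have Fourier-like principal components (see `demo_latency_pcs()`, which also
reproduces the "horseshoe" in the PC1–PC2 plane), so a population of
identically shaped, differently delayed bursts acquires apparent rotational
structure. `latency_sweep()` maps the rotational goodness-of-fit ratio over
latency-SD x movement-SD grids; rotation grows sharply once the latency
spread exceeds the movement SD.

### Two-oscillator dynamical model

`simulate_dynamical()` builds each condition from two fixed-frequency complex
oscillators (2.8 and 0.3 Hz) with per-condition phase (uniform on [0, pi/2]),
amplitude (uniform on [-2.5, -1.5]) and a constant offset (uniform on
[-5.5, -4.5]); each neuron combines them with five standard-normal weights
(real and imaginary parts of two complex coefficients, plus an offset
coefficient). The movement epoch is 300 ms; the preparatory epoch extends the
first (noisy) sample 100 ms back in time; noise matches the representational
model's SD 0.01 without rescaling (the rates live on a different natural
scale; all acceptance checks on this model are banded). Note that negative
amplitudes only flip oscillator phase, so drawing them from [-2.5, -1.5]
rather than the printed descending order "-1.5 to -2.5" is inconsequential.

A structural consequence worth stating plainly: this signal is exactly rank
five (two oscillator planes plus the offset direction), so after any
per-neuron centering the first two jPCA planes necessarily capture nearly all
variance (~90% here). The variance-per-plane figures this package reports for
the dynamical model are therefore much higher than for the representational
model, even though both models' rotational *quality* metrics behave as
expected. No parameter choice compatible with near-perfect rotations can make
the two-plane variance small; treat published two-plane variance figures for
rank-deficient generators with care.

### Complex-kinematic variant

`simulate_complex_kinematic()` extends the velocity model with sensitivity to
position, acceleration and (in 30% of neurons) jerk of a 20-cm reach. Each
kinematic trace is normalized to unit peak, projected onto the neuron's
preferred direction, weighted, shifted by the neuron's latency and summed.
Weights are velocity-dominant (uniform [0.5, 1.5]) with the other parameters
an order of magnitude weaker (uniform [0.05, 0.15]); the upstream sources do
not print usable weight values, so these are package defaults chosen once for
realism (velocity dominance with secondary kinematic sensitivity), and all
checks on this model are tolerance-banded. Position holds its endpoint after
the movement, so this population — unlike the velocity-only model — has
sustained post-movement activity; onset detection on it should use the RMS
summary trace (`detect_movement_onset(..., method = "rms")`) because the
signed rates average to zero across neurons.

### Trained recurrent network

`rnn_init()`/`rnn_train()` implement a 200-unit continuous-rate network,
`tau x' = -x + J r + B u`, rectified-tanh rates, Euler-integrated at 10 ms
with `tau = 50` ms. Inputs are a hold signal (1 until the go cue, 0 after)
and the target's sine and cosine (on throughout the trial); the two linear
outputs must produce the reach's x/y velocity after delays of 600, 800 and
1000 ms with a fixed 100-ms reaction time. Targets are expressed in m/s so
that outputs, weights and regularizer terms share a unit scale. The loss is
the normalized squared output error plus three penalties with weights 1e-2,
2e-5 and 5e-5: mean squared rate, summed squared input and output weights,
and mean squared per-step state change (a tractable surrogate for trajectory
complexity; the normalization by element count is a package choice and the
penalty is configurable). Training uses Adam on the exact back-propagated
gradient (verified against finite differences in the test suite); any
optimizer reaching the error criterion is scientifically equivalent, and the
stop criterion is a normalized error below 0.1%, with 1% as the hard
acceptance gate.

Two printed scale factors required interpretation. Read literally as SDs,
`g/N` for the recurrent weights and `1/N` for the input weights give, at
N = 200, recurrent inputs of order 0.01: the trained network then solves the
task essentially feedforward and exhibits *no* rotational structure, flatly
contradicting the phenomenon the network is meant to display. Read as
variances — SDs `g/sqrt(N)` and `1/sqrt(N)`, the standard scaling for rate
networks with rich internal dynamics — the trained network shows both strong
representational read-outs and significant CMPT rotations. The variance
reading is the default (`init_scale = "variance"`); the literal reading
remains available (`init_scale = "sd"`).

## jPCA

`jpca()` normalizes each neuron by its response range over the analysis
window plus a softening constant (default 0.05, suited to unit-scale
simulated rates; use ~5 for spike rates in Hz), centers each neuron, and by
default also removes each neuron's cross-condition mean time course before
PCA. The cross-condition subtraction matters: without it the
condition-independent response dominates the leading components and the
variance captured per rotation plane roughly doubles; with it the representational model lands where such populations are
conventionally reported (16%/30% variance in the first one/two planes,
rotational goodness-of-fit ratio near 0.8). The flag `subtract_cc_mean` exposes both conventions.

The top `d = 6` principal-component scores form the reduced state; the
temporal derivative is the difference of adjacent samples within each
condition, divided by the 10-ms step. Two linear dynamics fits share the same
least-squares objective: an unconstrained matrix `M`, and `M_skew`
constrained to be exactly antisymmetric, solved in closed form via the
Sylvester equation `S A + A S = B - B^T` (`A = X X^T`, `B = X_dot X^T`) in
the eigenbasis of `A`. Planes are the eigenplanes of `M_skew`, ordered by
rotation frequency (ties keep first occurrence) and oriented so net rotation
is anticlockwise; a zero-frequency plane is retained with a warning.

Three metrics (`rotation_metrics()`):

* **variance per plane** — variance of the data projected onto the plane,
  relative to total (preprocessed) data variance;
* **RGR** — the R-squared of the skew fit divided by the R-squared of the
  unconstrained fit, with residuals and derivative projected onto a chosen
  plane set (with d = 6, the "first three planes" span the whole fitted
  space, so that set and "all planes" coincide);
* **circularity** — the mean acute angle between state and derivative
  (arccos of the magnitude of their normalized inner product) over the chosen
  plane span, divided by pi/2, so 1 is purely circular flow and 0 purely
  radial. The acute-angle reading needs no clipping and gives sensible values for
  both simulated models (about 0.66 representational, 0.95 dynamical); a signed top-plane variant is
  available via `rotation_metrics(fit, planes = 1)`.

Analysis windows follow the generator: the representational and
complex-kinematic models use the 10%-threshold onset/offset of the population
summary trace (`detect_movement_onset()`, prep level estimated before
-200 ms, with a noise-floor guard that rejects flat signals); the dynamical
model and the RNN use the go cue to go + 300 ms; user data takes an explicit
window.

## The covariance-matched permutation test

One CMPT repetition (i) randomly reassigns, within each neuron separately,
the entire time course of every condition; (ii) proposes random within-neuron
swaps of two condition traces, accepting a swap only if it strictly increases
the similarity between the permuted and observed neuron-by-neuron covariance
matrices, until the similarity reaches 95% (99% in strict mode); and (iii)
re-runs jPCA and records the RGR over all planes. Similarity is
`1 - SSD/TSS`: the summed squared difference between the covariance matrices
over the summed squared deviation of the observed covariance from its entry
mean. The p-value is the fraction of repetitions whose null RGR reaches the
observed one (`>=`, the conservative reading), and the effect size is the
observed RGR minus the null mean, in null-SD units.

No data value is ever altered: per-neuron trace multisets, per-neuron means,
and the total population rate are conserved exactly (tested), and the
similarity after matching is at least the threshold for every retained
repetition; a repetition that fails to converge within the proposal cap
(default `200 * neurons * conditions`) is discarded with a warning, never
kept silently.

Numerical design: the per-neuron range, per-neuron mean and cross-condition
mean trace are all invariant under within-neuron condition permutations, so
the matcher operates on a fixed preprocessed matrix and updates the
covariance incrementally — a swap changes only the affected neuron's row and
column, and only through the two swapped blocks. The incremental update is
verified against full recomputation to 1e-10, and an exact recomputation
guards the reported final similarity. Swap proposals are uniform over neurons
and unordered condition pairs.

Which covariance to match is a genuine design choice. The test's logic is
that matching should restore everything PCA depends on; PCA here consumes
range-normalized, centered data. Matching the raw-rate covariance to 95%
leaves the representational model's null slightly but systematically below
the observed RGR (a spurious effect size around 1.5); matching the fully
CC-mean-subtracted covariance overshoots in the other direction. Matching the
normalized, centered covariance *without* CC subtraction — the covariance of
the signals themselves — behaves correctly on both models (representational p well above 0.05 with
|effect size| < 1 on most seeds; dynamical p near 0) and is the default; `preprocess` and `match_cc_mean`
expose the alternatives.

`unshuffle_check()` guards against the matcher merely undoing the shuffle: it
sorts each repetition's assignment-matrix rows by their most common condition
(the most conservative comparison), computes the fraction of entries restored
to the identity, and correlates that fraction with the repetition's RGR.
`subset_grid()` repeats the CMPT over neuron-count x condition-count grids
with fresh random subsets per repetition; the p-value is the paired
exceedance fraction and the effect size compares the mean observed RGR on the
subsets with the null distribution. Cells with fewer than two conditions are
untestable (`NA`).

Calibration: running the CMPT with one of its own matched permutations as the
"observed" data yields approximately uniform p-values (Kolmogorov–Smirnov
check in the test suite).

## Representational read-outs

* `fit_preferred_directions()` regresses mean movement-period rates (go cue
  to go + 300 ms) on `b1 + b2 sin(theta) + b3 cos(theta)`; the preferred
  direction is `(b3, b2)` normalized by the modulation depth
  `k = sqrt(b2^2 + b3^2)`; `k` below tolerance flags the neuron untuned.
* `population_vector()` sums baseline-subtracted rates times preferred
  directions; the summed vector's angle predicts reach direction and its
  running integral traces a predicted trajectory. For an ideal population of
  uniformly distributed cosine-tuned neurons the prediction is exact up to
  discretization (tested to 1 degree), and the error shrinks with population
  size.
* `velocity_regression()` fits, per neuron, speed-scaled directional tuning
  with a neuron-kinematic lag `tau` and a preparatory-tuning scale `a5` that
  shares the directional coefficients (and so also allows inverted movement
  tuning). The model is linear in `(a1, a2, a3, a4)` given `a5`, so `a5` is
  profiled over a grid (default 31 points spanning +/-1.5 peak speed) and the
  lag searched over -200..200 ms in 10-ms steps; ties in adjusted R-squared
  break toward the smallest `|tau|`, which also resolves the scale
  non-identifiability between `a5` and the directional coefficients.
  Responses shifted beyond the recorded axis are clamped to the edge sample.
  The adjusted R-squared uses the standard small-sample correction with 6
  parameters (a1..a5 plus the searched lag; `n_par` exposes the alternative).
  Zero-variance responses get R-squared 0 by convention, not 1.
* `tuning_stability()` correlates each neuron's across-condition rate vector
  between a reference time and later times; `preferred_direction_timecourse()`
  labels each neuron's highest-rate condition over time, marking time points
  with a rate range below 1e-4 as untuned. The full per-neuron correlation
  matrix is returned so the shape of the distribution (e.g. absence of
  bimodality at long lags) can be inspected directly; no formal dip test is
  bundled.

## What the simulations do and do not establish

The generators produce trial-averaged, noiseless-to-mildly-noisy rates with
exactly the structure their equations state: no spiking variability, no
trial-to-trial noise, no heterogeneous tuning nonlinearities, no sensory
feedback. Passing the acceptance bands therefore shows that the analysis
chain is faithful and that the *models* behave as described — not that real
motor cortex does. Empirical motor-cortex recordings are out of scope: where published analyses
depend on them (e.g. the minimum neuron/condition counts needed for
significance), only the procedures (`subset_grid()`) are provided, exercised
on synthetic data.

Reproduction notes: headline quantities are means over 20 simulation seeds;
permutation tests use 100 repetitions (full-scale analyses of this kind use
up to 1000); the RNN acceptance path trains one 200-unit network to the 0.1%
error criterion (about 90 Adam iterations, under a minute) rather than
averaging over many trained networks. On one core the whole test suite runs
in about three minutes and the acceptance script in about a minute.

Known limitations: the dynamical model's per-plane variance is structurally
pinned near its maximum (rank argument above); the CMPT effect size for the
dynamical model lands near 2 rather than 3+ (greedy matcher details that the
source does not fully specify — proposal schedule, stopping exactly at
threshold — shift the null's spread); and the trained network's rotational
goodness-of-fit varies by ~0.1 across training seeds around ~0.6, somewhat below what networks of this type trained with Hessian-free
optimization attain (about 0.74).
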