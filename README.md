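# rotdyn

Simulation and analysis of motor-cortex population dynamics during
center-out reaching, for computational neuroscientists comparing
*representational* accounts (single neurons tuned to movement parameters)
with *dynamical-systems* accounts (a population whose internal state rotates
to generate muscle-like output).

The package provides, as plain R functions over a common
`population_activity` container (a neurons x conditions x time rate tensor
with a time axis and event markers):

* **Generative models** — a cosine velocity-tuning population with
  per-neuron neuron-kinematic latencies
  (`simulate_representational()`), a two-oscillator dynamical population
  (`simulate_dynamical()`), a complex-kinematic variant sensitive to
  position/velocity/acceleration/jerk (`simulate_complex_kinematic()`), and
  a trainable continuous-rate recurrent network that produces reach velocity
  profiles (`rnn_init()`, `rnn_train()`, `rnn_population()`).
* **jPCA** (`jpca()`) — PCA to 6 dimensions, least-squares fits of
  unconstrained (`M`) and exactly skew-symmetric (`M_skew`) linear dynamics
  to the state and its temporal derivative, rotation planes from the
  eigenvectors of `M_skew`, and the three standard metrics: variance per
  plane, the rotational goodness-of-fit ratio
  `RGR = R²(M_skew) / R²(M)`, and circularity (mean acute angle between
  state and derivative, normalized so 1 = purely circular).
* **The covariance-matched permutation test** (`cmpt()`) — reassigns
  condition labels within each neuron, greedily swaps condition pairs until
  the neuron-by-neuron covariance matches the observed data to 95%, and
  compares the observed RGR with the permutation distribution:

  `effect size = (RGR_observed − mean(RGR_permuted)) / sd(RGR_permuted)`

  with an unshuffle control (`unshuffle_check()`) and neuron/condition
  subsampling grids (`subset_grid()`).
* **Representational read-outs** — preferred directions from sinusoidal
  regression (`fit_preferred_directions()`), population-vector decoding and
  integrated trajectories (`population_vector()`), lagged speed-scaled
  velocity regression with a profiled preparatory-tuning term
  (`velocity_regression()`), tuning-stability time courses
  (`tuning_stability()`), preferred-direction maps
  (`preferred_direction_timecourse()`), and the time-shifted-signal PCA
  demonstration (`demo_latency_pcs()`).

The scientific point the package makes reproducible: variable
neuron-kinematic latencies alone make a classical cosine-tuning model *look*
rotational under jPCA, but the CMPT separates the accounts — after
covariance-matched permutation the representational model's rotations are
restored (large p), while the dynamical model's and the trained network's
rotations are destroyed (small p, large effect size), because only in the
latter is the neuron-to-condition assignment essential.

## Worked example

```r
library(rotdyn)

pop <- simulate_representational(seed = 1)   # 200 neurons, 13 directions,
                                             # latency SD 72 ms, movement SD 56 ms
pop <- detect_movement_onset(pop)
pop
#> Population activity [representational]: 200 neurons, 13 conditions, 111 samples (-300..800 ms, dt = 10)
#>   events: go_cue = 0, neural_movement_onset = -70, movement_end = 220

fit <- jpca(pop)
fit
#> jPCA fit: d = 6, 13 conditions x 30 samples (window -70..220 ms)
#>   variance: plane 1 = 15.9%, planes 1-2 = 32.6%
#>   RGR (all planes) = 0.797, circularity = 0.651

res <- cmpt(pop, n_reps = 100, seed = 2)
res
#> CMPT: observed RGR = 0.797, 100/100 repetitions matched (similarity >= 0.95)
#>   null RGR = 0.784 +/- 0.013, p = 0.19, effect size = 0.97
```

Reading the output: this purely representational population captures 33% of
its variance in the first two jPCA planes with a rotational goodness-of-fit
ratio near 0.8 — strong apparent rotations. But the CMPT p-value is large:
after reassigning conditions within neurons and matching the covariance,
permuted data rotate about as well as the observed data, so the rotations do
not depend on the neuron-to-condition assignment. Running the same test on
`simulate_dynamical(seed = 1)` gives p below 0.01 with an effect size near 2:
there the condition structure is essential. `vignettes/rotational-dynamics.Rmd`
documents the models, conventions, and every tunable parameter.

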