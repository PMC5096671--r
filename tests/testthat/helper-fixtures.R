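# Small populations and toy systems shared across tests. Everything is
# generated in code; sizes are kept small so each file runs in seconds.

small_task <- function(n = 8) reach_task(n)

# compact representational population (fast jPCA / CMPT)
small_repr <- function(seed = 1, n_neurons = 60, ...) {
  detect_movement_onset(
    simulate_representational(small_task(), n_neurons = n_neurons, seed = seed, ...)
  )
}

# compact dynamical population
small_dyn <- function(seed = 1, n_neurons = 60, ...) {
  simulate_dynamical(small_task(), n_neurons = n_neurons, seed = seed, ...)
}

# exact trajectory of xdot = S x for skew S via the matrix exponential
# (unitary eigendecomposition of the skew matrix)
skew_trajectory <- function(S, x0, times) {
  ev <- eigen(S)
  Vi <- solve(ev$vectors)
  sapply(times, function(t) Re(ev$vectors %*% (exp(ev$values * t) * (Vi %*% x0))))
}

# random skew-symmetric matrix
random_skew <- function(d, seed = NULL, scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d, 0, scale), d)
  (A - t(A)) / 2
}

# population whose neurons linearly read out a planar rotation (plus phases
# per condition); ideal input for rotation metrics
rotation_population <- function(n_neurons = 12, n_cond = 6, omega = 2 * pi / 200,
                                radial = 0, seed = 1) {
  set.seed(seed)
  t <- seq(0, 300, by = 10)
  # orthonormal loadings keep the latent circle circular in neuron space
  L <- qr.Q(qr(matrix(rnorm(n_neurons * 2), n_neurons, 2)))
  rates <- array(0, c(n_neurons, n_cond, length(t)))
  for (c in seq_len(n_cond)) {
    ph <- 2 * pi * (c - 1) / n_cond
    g <- exp(radial * t)
    xy <- rbind(g * cos(omega * t + ph), g * sin(omega * t + ph))
    rates[, c, ] <- L %*% xy
  }
  population_activity(rates, t, events = c(go_cue = 0))
}
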