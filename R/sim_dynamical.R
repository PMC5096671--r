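#' Sample per-condition oscillator parameters for the dynamical model
#'
#' Draws, independently for every condition, the phases of the two oscillatory
#' modes (uniform on `[0, pi/2]`), their amplitudes (uniform on
#' `[-2.5, -1.5]`) and a constant offset (uniform on `[-5.5, -4.5]`).
#'
#' @param task A [reach_task()].
#' @param phase_range,amplitude_range,offset_range Uniform ranges.
#' @param seed Optional RNG seed.
#' @return List with matrices `phase`, `amplitude` (conditions x 2) and
#'   vector `offset`.
#' @export
sample_condition_params <- function(task, phase_range = c(0, pi / 2),
                                    amplitude_range = c(-2.5, -1.5),
                                    offset_range = c(-5.5, -4.5),
                                    seed = NULL) {
  nc <- task$n_conditions
  with_seed(seed, list(
    phase = matrix(runif(2 * nc, phase_range[1], phase_range[2]), nc, 2),
    amplitude = matrix(runif(2 * nc, amplitude_range[1], amplitude_range[2]), nc, 2),
    offset = runif(nc, offset_range[1], offset_range[2])
  ))
}

#' Complex oscillator trace
#'
#' `F(t) = a * exp(1i * (2*pi*f*t - theta))` with `t` taken in seconds.
#'
#' @param a Amplitude.
#' @param f Frequency, Hz.
#' @param theta Phase, radians.
#' @param time_ms Time axis in ms.
#' @return Complex vector of length `length(time_ms)`.
#' @export
oscillator <- function(a, f, theta, time_ms) {
  a * exp(1i * (2 * pi * f * time_ms / 1000 - theta))
}

#' Simulate the two-oscillator dynamical-model population
#'
#' Each condition is assigned random phases, amplitudes and an offset for two
#' fixed-frequency oscillatory modes (defaults 2.8 and 0.3 Hz); each neuron
#' combines the two condition-level complex oscillations with its own complex
#' weights `w_1`, `w_2` and offset coefficient `s` (all standard normal):
#'
#' \deqn{r_{n,c}(t) = Re(w_{n,1} F_{c,1}(t) + w_{n,2} F_{c,2}(t)) + s_n o_c + \epsilon}
#'
#' The preparatory epoch is built by extending the first movement sample
#' (including its noise) backwards by `prep_extension` ms; the
#' `neural_movement_onset` event is the go cue (t = 0).
#'
#' @param task A [reach_task()] (only the number of conditions matters).
#' @param n_neurons Number of neurons.
#' @param frequencies The two oscillator frequencies, Hz.
#' @param duration Movement epoch, ms.
#' @param prep_extension Length of the constant preparatory epoch, ms.
#' @param noise_sd SD of additive Gaussian noise (matched to the
#'   representational model's default).
#' @param dt Sampling step, ms.
#' @param condition_params Optionally a list from [sample_condition_params()];
#'   drawn internally when `NULL`.
#' @param seed Optional RNG seed.
#' @return A [population_activity()] with events `go_cue = 0`,
#'   `neural_movement_onset = 0`, `movement_end = duration` and neuron weights
#'   in `neuron_meta`.
#' @export
simulate_dynamical <- function(task = reach_task(13), n_neurons = 200,
                               frequencies = c(2.8, 0.3), duration = 300,
                               prep_extension = 100, noise_sd = 0.01,
                               dt = 10, condition_params = NULL, seed = NULL) {
  nc <- task$n_conditions
  with_seed(seed, {
    cp <- condition_params %||% sample_condition_params(task)
    t_move <- seq(0, duration, by = dt)
    nt <- length(t_move)
    F1 <- t(vapply(seq_len(nc), function(c)
      oscillator(cp$amplitude[c, 1], frequencies[1], cp$phase[c, 1], t_move),
      complex(nt)))
    F2 <- t(vapply(seq_len(nc), function(c)
      oscillator(cp$amplitude[c, 2], frequencies[2], cp$phase[c, 2], t_move),
      complex(nt)))
    w1 <- complex(real = rnorm(n_neurons), imaginary = rnorm(n_neurons))
    w2 <- complex(real = rnorm(n_neurons), imaginary = rnorm(n_neurons))
    s <- rnorm(n_neurons)
    move <- array(0, dim = c(n_neurons, nc, nt))
    for (c in seq_len(nc)) {
      osc <- outer(w1, F1[c, ]) + outer(w2, F2[c, ])  # n x nt complex
      move[, c, ] <- Re(osc) + s * cp$offset[c]
    }
    if (noise_sd > 0)
      move <- move + array(rnorm(length(move), 0, noise_sd), dim = dim(move))
    n_prep <- as.integer(round(prep_extension / dt))
    rates <- array(0, dim = c(n_neurons, nc, n_prep + nt))
    for (k in seq_len(n_prep)) rates[, , k] <- move[, , 1]
    rates[, , n_prep + seq_len(nt)] <- move
    time_ms <- seq(-n_prep * dt, duration, by = dt)
    population_activity(
      rates, time_ms,
      events = c(go_cue = 0, neural_movement_onset = 0, movement_end = duration),
      neuron_meta = data.frame(w1_re = Re(w1), w1_im = Im(w1),
                               w2_re = Re(w2), w2_im = Im(w2), s = s),
      condition_meta = data.frame(target_angle = task$target_angles,
                                  offset = cp$offset,
                                  phase1 = cp$phase[, 1], phase2 = cp$phase[, 2],
                                  amp1 = cp$amplitude[, 1], amp2 = cp$amplitude[, 2]),
      generator = "dynamical"
    )
  })
}
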