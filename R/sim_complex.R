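#' Simulate a complex-kinematic tuned population with latencies
#'
#' Extends the velocity-tuning representational model: each neuron is
#' sensitive not only to reach velocity but also to position, acceleration
#' and (for a fraction of neurons) jerk. Every kinematic trace is projected
#' onto the neuron's preferred direction, scaled by the neuron's per-parameter
#' sensitivity weight, time-shifted by the neuron's latency `tau_n`, and
#' summed:
#'
#' \deqn{r_{n,c}(t) = \sum_p w_{n,p} \langle k_p(c, t - \tau_n), u(\theta_n)\rangle + \epsilon}
#'
#' Kinematic traces are normalized to unit peak magnitude before weighting so
#' that the sensitivity weights are comparable across parameters; velocity
#' weights are dominant (uniform on `[0.5, 1.5]`) and position/acceleration/
#' jerk weights are an order of magnitude weaker (uniform on `[0.05, 0.15]`).
#' Position holds its endpoint after the movement; the derivative traces are
#' zero outside it. With all non-velocity weights zero the model reduces to
#' pure directional velocity tuning.
#'
#' @param task A [reach_task()] (default: 13 directions, 20-cm radius).
#' @param kin A [kinematic_traces()] set sampled over the movement epoch
#'   (movement is taken to start at the go cue, t = 0).
#' @param n_neurons,latency_sd,noise_sd,window,dt,seed As in
#'   [simulate_representational()].
#' @param weight_ranges Named list of uniform sensitivity ranges per
#'   parameter (`velocity`, `position`, `acceleration`, `jerk`).
#' @param jerk_fraction Fraction of neurons with a nonzero jerk weight.
#' @return A [population_activity()] with ground-truth `tau`, `theta` and the
#'   sensitivity weights in `neuron_meta`.
#' @export
simulate_complex_kinematic <- function(task = reach_task(13),
                                       kin = kinematic_traces(task, bell_profile(300, 10, radius = task$radius)),
                                       n_neurons = 200, latency_sd = 72,
                                       noise_sd = 0.01, window = c(-300, 800),
                                       dt = 10,
                                       weight_ranges = list(
                                         velocity = c(0.5, 1.5),
                                         position = c(0.05, 0.15),
                                         acceleration = c(0.05, 0.15),
                                         jerk = c(0.05, 0.15)),
                                       jerk_fraction = 0.3, seed = NULL) {
  params <- c("position", "velocity", "acceleration", "jerk")
  for (p in params) if (is.null(kin[[p]])) stop("missing kinematic trace: ", p)
  nc <- task$n_conditions
  tfull <- seq(window[1], window[2], by = dt)
  with_seed(seed, {
    theta_n <- runif(n_neurons, 0, 2 * pi)
    tau_n <- rnorm(n_neurons, 0, latency_sd)
    w <- sapply(params, function(p) {
      rng <- weight_ranges[[p]] %||% c(0, 0)
      runif(n_neurons, rng[1], rng[2])
    })
    w[, "jerk"] <- w[, "jerk"] * (runif(n_neurons) < jerk_fraction)
    rates <- array(0, dim = c(n_neurons, nc, length(tfull)))
    for (p in params) {
      tr <- kin[[p]] / max(abs(kin[[p]]))      # conditions x time x 2, unit peak
      hold_end <- p == "position"              # position holds its endpoint
      for (i in seq_len(n_neurons)) {
        if (all(w[i, p] == 0)) next
        tq <- tfull - tau_n[i]
        for (c in seq_len(nc)) {
          px <- shift_trace(kin$time_ms, tr[c, , 1], tq, hold_end)
          py <- shift_trace(kin$time_ms, tr[c, , 2], tq, hold_end)
          rates[i, c, ] <- rates[i, c, ] +
            w[i, p] * (cos(theta_n[i]) * px + sin(theta_n[i]) * py)
        }
      }
    }
    if (noise_sd > 0)
      rates <- rates + array(rnorm(length(rates), 0, noise_sd), dim = dim(rates))
    population_activity(
      rates, tfull, events = c(go_cue = 0),
      neuron_meta = data.frame(tau = tau_n, theta = theta_n, w),
      condition_meta = data.frame(target_angle = task$target_angles),
      generator = "complex_kinematic"
    )
  })
}

# Linear interpolation of a movement-epoch trace onto query times, padding
# with zero before the movement and with zero (or the final value) after it.
shift_trace <- function(t_src, y, t_query, hold_end = FALSE) {
  right <- if (hold_end) y[length(y)] else 0
  stats::approx(c(t_src[1] - 1e6, t_src, t_src[length(t_src)] + 1e-6, t_src[length(t_src)] + 1e6),
                c(0, y, right, right), xout = t_query, rule = 2)$y
}
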