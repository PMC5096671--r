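#' Simulate a cosine-tuned representational population with neuron-kinematic
#' latencies
#'
#' Generates trial-averaged rates of `n_neurons` velocity-tuned neurons in a
#' center-out task. Each neuron `n` has a preferred angle `theta_n` (uniform
#' on `[0, 2*pi)`) and a latency `tau_n ~ Normal(0, latency_sd)`. Its
#' noiseless rate for condition `c` is
#'
#' \deqn{f_{n,c}(t) = b_{n,c} \exp(-(t - \tau_n - \mu_0)^2 / 2\sigma^2)}
#'
#' for `t >= tau_n` and the constant preparatory level `phi * b_{n,c}` for
#' `t < tau_n`, where `mu_0 = sigma * sqrt(-2 * log(phi))` makes the two
#' branches meet continuously at `t = tau_n`. The gain is
#' `b = (1 + cos(theta_c - theta_n)) / 2` by default; `gain_mode = "signed"`
#' uses `b = cos(theta_c - theta_n)` (positive and negative rates) and
#' `gain_mode = "random"` additionally scales each neuron's gain magnitude by
#' a uniform draw on `[0.5, 1.5]`. I.i.d. Gaussian noise of SD `noise_sd` is
#' added to every sample (set `noise_per = "trace"` for one draw per
#' neuron/condition instead).
#'
#' @param task A [reach_task()].
#' @param n_neurons Number of simulated neurons.
#' @param latency_sd SD of the latency distribution, ms.
#' @param movement_sd Duration parameter `sigma` of the Gaussian movement
#'   activity, ms (56 ms corresponds to a 300-400 ms movement).
#' @param phi Preparatory activity as a fraction of peak movement activity,
#'   strictly in (0, 1).
#' @param noise_sd SD of additive Gaussian noise (rate units).
#' @param window Simulation window in ms relative to the go cue.
#' @param dt Sampling step, ms.
#' @param gain_mode `"offset"` (default), `"signed"` or `"random"`.
#' @param noise_per `"sample"` (default) or `"trace"`.
#' @param seed Optional RNG seed.
#' @return A [population_activity()] with per-neuron ground truth (`tau`,
#'   `theta`) in `neuron_meta` and event `go_cue = 0`.
#' @export
simulate_representational <- function(task = reach_task(13), n_neurons = 200,
                                      latency_sd = 72, movement_sd = 56,
                                      phi = 0.2, noise_sd = 0.01,
                                      window = c(-300, 800), dt = 10,
                                      gain_mode = c("offset", "signed", "random"),
                                      noise_per = c("sample", "trace"),
                                      seed = NULL) {
  gain_mode <- match.arg(gain_mode)
  noise_per <- match.arg(noise_per)
  if (!is.finite(phi) || phi <= 0 || phi >= 1)
    stop("`phi` must lie strictly between 0 and 1 (mu0 is undefined otherwise)")
  if (latency_sd < 0 || movement_sd <= 0) stop("invalid spread parameters")
  with_seed(seed, {
    theta_n <- runif(n_neurons, 0, 2 * pi)
    tau_n <- rnorm(n_neurons, 0, latency_sd)
    gain_scale <- if (gain_mode == "random") runif(n_neurons, 0.5, 1.5) else rep(1, n_neurons)
    time_ms <- seq(window[1], window[2], by = dt)
    rates <- eq1_rates(theta_n, tau_n, gain_scale, task$target_angles,
                       time_ms, movement_sd, phi, gain_mode)
    if (noise_sd > 0) {
      noise <- if (noise_per == "sample") {
        array(rnorm(length(rates), 0, noise_sd), dim = dim(rates))
      } else {
        array(rep(rnorm(prod(dim(rates)[1:2]), 0, noise_sd), dim(rates)[3]),
              dim = dim(rates))
      }
      rates <- rates + noise
    }
    population_activity(
      rates, time_ms, events = c(go_cue = 0),
      neuron_meta = data.frame(tau = tau_n, theta = theta_n, gain_scale = gain_scale),
      condition_meta = data.frame(target_angle = task$target_angles),
      generator = "representational"
    )
  })
}

# Noiseless Eq-1 rate tensor. Exposed internally so tests can evaluate the
# model on dense grids.
eq1_rates <- function(theta_n, tau_n, gain_scale, target_angles, time_ms,
                      movement_sd, phi, gain_mode = "offset") {
  n <- length(theta_n); nc <- length(target_angles); nt <- length(time_ms)
  mu0 <- movement_sd * sqrt(-2 * log(phi))
  rates <- array(0, dim = c(n, nc, nt))
  for (c in seq_len(nc)) {
    b <- switch(gain_mode,
      offset = (1 + cos(target_angles[c] - theta_n)) / 2,
      signed = ,
      random = cos(target_angles[c] - theta_n)
    ) * gain_scale
    for (i in seq_len(n)) {
      tt <- time_ms
      move <- tt >= tau_n[i]
      r <- rep(phi * b[i], nt)
      r[move] <- b[i] * exp(-(tt[move] - tau_n[i] - mu0)^2 / (2 * movement_sd^2))
      rates[i, c, ] <- r
    }
  }
  rates
}

#' Detect neural movement onset from population activity
#'
#' Finds the time at which a population summary trace first exceeds the
#' preparatory level by `threshold_fraction` of the prep-to-maximum range,
#' and the last time it remains above that level. The summary trace is the
#' grand average rate over neurons and conditions (`method = "mean"`), or the
#' RMS deviation from each neuron's preparatory mean (`method = "rms"`,
#' appropriate for signed-rate populations whose grand average is flat).
#'
#' @param pop A [population_activity()].
#' @param threshold_fraction Fraction of the prep-to-max range (default 0.1).
#' @param baseline_end End of the preparatory epoch used to estimate the prep
#'   level, ms (default -200; must precede any rise).
#' @param method Summary trace: `"mean"` or `"rms"`.
#' @param noise_floor Minimum prep-to-max range (in units of the summary
#'   trace's SD over the baseline) below which the signal is declared flat.
#' @return The population with events `neural_movement_onset` and
#'   `movement_end` added.
#' @export
detect_movement_onset <- function(pop, threshold_fraction = 0.1,
                                  baseline_end = -200,
                                  method = c("mean", "rms"),
                                  noise_floor = 3) {
  stopifnot(inherits(pop, "population_activity"))
  method <- match.arg(method)
  base <- pop$time_ms <= baseline_end
  if (!any(base)) stop("no samples before `baseline_end` to estimate the preparatory level")
  s <- if (method == "mean") {
    apply(pop$rates, 3, mean)
  } else {
    prep_n <- apply(pop$rates[, , base, drop = FALSE], 1, mean)
    apply(sweep(pop$rates, 1, prep_n)^2, 3, function(z) sqrt(mean(z)))
  }
  prep <- mean(s[base])
  prep_sd <- sd(s[base])
  smax <- max(s)
  if (!is.finite(prep_sd)) prep_sd <- 0
  if (smax - prep <= noise_floor * max(prep_sd, .Machine$double.eps * (abs(smax) + 1)))
    stop("flat population signal: no movement-related rise detected")
  level <- prep + threshold_fraction * (smax - prep)
  above <- which(s >= level)
  onset <- pop$time_ms[min(above)]
  offset <- pop$time_ms[max(above)]
  pop$events["neural_movement_onset"] <- onset
  pop$events["movement_end"] <- offset
  pop
}

#' Sweep latency and movement-duration SDs and measure rotational structure
#'
#' Repeats the representational simulation over a grid of latency SDs and
#' movement SDs and records the mean rotational goodness-of-fit ratio (RGR,
#' all jPCA planes) per cell, averaged over `reps` seeds.
#'
#' @param latency_sds,movement_sds Grids of SDs, ms (both non-empty).
#' @param reps Repetitions (seeds) per cell.
#' @param task,n_neurons,... Passed to [simulate_representational()].
#' @param d Number of principal components for [jpca()].
#' @param seed Base RNG seed.
#' @return Matrix `length(latency_sds)` x `length(movement_sds)` of mean RGR.
#' @export
latency_sweep <- function(latency_sds, movement_sds, reps = 3,
                          task = reach_task(13), n_neurons = 200, d = 6,
                          seed = NULL, ...) {
  if (!length(latency_sds) || !length(movement_sds)) stop("empty sweep grid")
  grid <- matrix(NA_real_, length(latency_sds), length(movement_sds),
                 dimnames = list(latency_sds, movement_sds))
  with_seed(seed, {
    for (i in seq_along(latency_sds)) for (j in seq_along(movement_sds)) {
      vals <- vapply(seq_len(reps), function(r) {
        pop <- simulate_representational(task, n_neurons,
                                         latency_sd = latency_sds[i],
                                         movement_sd = movement_sds[j], ...)
        pop <- detect_movement_onset(pop)
        res <- jpca(pop, d = d)
        rotation_metrics(res, planes = "all")$rgr
      }, numeric(1))
      grid[i, j] <- mean(vals)
    }
  })
  grid
}
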