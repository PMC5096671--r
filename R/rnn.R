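#' Initialize a continuous-rate recurrent network
#'
#' Builds an N-unit rate network with 3 inputs (hold signal, sin and cos of
#' the target angle) and 2 linear velocity outputs. Recurrent weights `J` are
#' zero-mean normal scaled by `g` over `N`, input weights `B` zero-mean
#' normal scaled by `1` over `N`, output weights `W` zero. With the default
#' `init_scale = "variance"` the `g/N` and `1/N` factors are taken as
#' variances (SDs `g/sqrt(N)` and `1/sqrt(N)`, the standard scaling at which
#' a rate network has rich internal dynamics); `init_scale = "sd"` takes them
#' literally as SDs, which at N = 200 yields near-zero recurrence and an
#' almost feedforward solution. Units pass their activation through the
#' rectified hyperbolic tangent (0 for `x < 0`, `tanh(x)` otherwise).
#'
#' @param n_units Number of recurrent units.
#' @param n_inputs Number of inputs.
#' @param n_outputs Number of linear readouts.
#' @param g Synaptic scaling factor.
#' @param tau Time constant, ms.
#' @param dt Euler integration step, ms.
#' @param init_scale `"variance"` (default) or `"sd"`; see above.
#' @param seed Optional RNG seed.
#' @return Object of class `rnn_model` with weights `J`, `B`, `W` and the
#'   dynamics constants.
#' @export
rnn_init <- function(n_units = 200, n_inputs = 3, n_outputs = 2, g = 1.5,
                     tau = 50, dt = 10, init_scale = c("variance", "sd"),
                     seed = NULL) {
  init_scale <- match.arg(init_scale)
  if (n_units < 2) stop("need at least 2 units")
  sd_j <- if (init_scale == "sd") g / n_units else g / sqrt(n_units)
  sd_b <- if (init_scale == "sd") 1 / n_units else 1 / sqrt(n_units)
  with_seed(seed, structure(list(
    J = matrix(rnorm(n_units^2, 0, sd_j), n_units, n_units),
    B = matrix(rnorm(n_units * n_inputs, 0, sd_b), n_units, n_inputs),
    W = matrix(0, n_outputs, n_units),
    n_units = n_units, n_inputs = n_inputs, n_outputs = n_outputs,
    g = g, tau = tau, dt = dt, init_scale = init_scale
  ), class = "rnn_model"))
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("Rate RNN: %d units, %d inputs, %d outputs (tau = %g ms, dt = %g ms, g = %g)\n",
              x$n_units, x$n_inputs, x$n_outputs, x$tau, x$dt, x$g))
  if (!is.null(x$training)) cat(sprintf("  trained: normalized error = %.3g (%d iterations)\n",
                                        x$training$normalized_error, x$training$iterations))
  invisible(x)
}

#' Build the delayed center-out trial set for RNN training
#'
#' One trial set per delay. Inputs: a hold signal equal to 1 from trial start
#' and released (set to 0) at the go cue, plus `sin(theta_c)` and
#' `cos(theta_c)` of the target, on throughout the trial. Targets: zero
#' until `reaction_time` ms after the go cue, then a bell-shaped velocity
#' profile along the target direction for `movement_duration` ms. Target
#' velocities are expressed in m/s (peak about 1.6 m/s for a 20-cm reach over
#' 300 ms) so that outputs, weights and regularizers live on a unit scale.
#'
#' @param task A [reach_task()].
#' @param delays Go-cue times (trial start to go), ms.
#' @param reaction_time Go cue to movement onset, ms.
#' @param movement_duration Movement epoch, ms.
#' @param dt Step, ms.
#' @return Object of class `rnn_trials`: per-delay input/target arrays plus
#'   timing metadata.
#' @export
make_trials <- function(task = reach_task(13), delays = c(600, 800, 1000),
                        reaction_time = 100, movement_duration = 300, dt = 10) {
  nc <- task$n_conditions
  speed_cm_s <- bell_profile(movement_duration, dt, radius = task$radius)
  speed <- speed_cm_s / 100            # m/s
  dirs <- rbind(cos(task$target_angles), sin(task$target_angles)) # 2 x C
  sets <- lapply(delays, function(delay) {
    T <- as.integer((delay + reaction_time + movement_duration) / dt)
    go_step <- as.integer(delay / dt)  # go cue at the end of step `go_step`
    u <- array(0, dim = c(3, nc, T))
    u[1, , seq_len(go_step)] <- 1
    u[2, , ] <- sin(task$target_angles)
    u[3, , ] <- cos(task$target_angles)
    v <- array(0, dim = c(2, nc, T))
    mv <- go_step + reaction_time / dt + seq_along(speed)
    for (k in seq_along(speed)) v[, , mv[k]] <- dirs * speed[k]
    list(delay = delay, T = T, go_step = go_step, u = u, v = v,
         movement_steps = mv)
  })
  structure(list(sets = sets, delays = delays, task = task, dt = dt,
                 speed = speed, reaction_time = reaction_time,
                 movement_duration = movement_duration),
            class = "rnn_trials")
}

#' Simulate a rate RNN
#'
#' Euler-integrates the network over an input array.
#'
#' @param model An [rnn_init()] model.
#' @param u Input array `n_inputs x conditions x time`.
#' @param x0 Optional initial state (defaults to zeros).
#' @return List of arrays `x` (states), `r` (rates), `z` (outputs), each with
#'   time as the last dimension.
#' @export
rnn_simulate <- function(model, u, x0 = NULL) {
  stopifnot(inherits(model, "rnn_model"))
  if (length(dim(u)) == 2L) u <- array(u, dim = c(dim(u)[1], 1L, dim(u)[2]))
  if (!is.null(x0)) {
    # fold a nonzero initial state in via a one-step equivalent input; keep
    # the common zero-start path in compiled code
    out <- rnn_simulate_from(model, u, x0)
    return(out)
  }
  res <- rnn_forward_cpp(model$J, model$B, model$W, model$dt / model$tau, u)
  list(x = res$x, r = res$r, z = res$z)
}

# Reference implementation with arbitrary x0 (used by rnn_simulate and tests).
rnn_simulate_from <- function(model, u, x0) {
  a <- model$dt / model$tau
  N <- model$n_units; C <- dim(u)[2]; T <- dim(u)[3]
  rt_fun <- function(x) ifelse(x < 0, 0, tanh(x))
  x <- array(0, dim = c(N, C, T)); r <- x
  z <- array(0, dim = c(nrow(model$W), C, T))
  xt <- matrix(x0, N, C); rt <- rt_fun(xt)
  for (t in seq_len(T)) {
    xt <- (1 - a) * xt + a * (model$J %*% rt + model$B %*% u[, , t, drop = TRUE])
    if (!all(is.finite(xt))) stop("RNN state diverged")
    rt <- rt_fun(xt)
    x[, , t] <- xt; r[, , t] <- rt; z[, , t] <- model$W %*% rt
  }
  list(x = x, r = r, z = z)
}

#' Normalized output error
#'
#' Sum of squared output errors over all times, output dimensions and
#' conditions, divided by the total variance of the target signal (summed
#' squared deviation of the targets from their grand mean).
#'
#' @param z,v Output and target arrays of identical shape.
#' @return Scalar fraction (0 = perfect).
#' @export
normalized_error <- function(z, v) {
  if (!identical(dim(z) %||% length(z), dim(v) %||% length(v))) stop("shape mismatch")
  sst <- sum((v - mean(v))^2)
  if (sst <= 0) stop("zero-variance target")
  sum((z - v)^2) / sst
}

# loss/gradient wrapper (all delays)
rnn_loss_grad <- function(model, trials, reg) {
  us <- lapply(trials$sets, `[[`, "u")
  vs <- lapply(trials$sets, `[[`, "v")
  vall <- unlist(vs)
  sst <- sum((vall - mean(vall))^2)
  counts <- model$n_units * trials$task$n_conditions *
    sum(vapply(trials$sets, `[[`, integer(1), "T"))
  rnn_loss_grad_cpp(model$J, model$B, model$W, model$dt / model$tau,
                    us, vs, sst, reg[["rate"]], reg[["weights"]],
                    reg[["complexity"]], counts, counts)
}

#' Train the RNN on the reach-velocity task
#'
#' Minimizes the normalized squared output error plus three regularizers (a
#' cost on mean squared firing rate, on the squared sum of input and output
#' weights, and on the mean squared per-step state change, a trajectory
#' complexity surrogate) with Adam on the full-batch backpropagated gradient.
#' All of `J`, `B` and `W` are trained. Training stops when the normalized
#' error falls below `target_error` or after `max_iter` iterations.
#'
#' @param model An [rnn_init()] model.
#' @param trials An [make_trials()] trial set.
#' @param reg Named regularizer weights `rate`, `weights`, `complexity`.
#' @param lr Adam learning rate (decayed by `lr_decay` per iteration).
#' @param lr_decay Multiplicative learning-rate decay.
#' @param max_iter Iteration cap.
#' @param target_error Normalized-error stopping criterion (0.001 = the 0.1%
#'   training criterion).
#' @param verbose Print progress every 100 iterations.
#' @return The trained model, with a `training` list holding the error trace,
#'   final `normalized_error`, `iterations` and `reached_target`.
#' @export
rnn_train <- function(model, trials, reg = c(rate = 1e-2, weights = 2e-5,
                                             complexity = 5e-5),
                      lr = 5e-3, lr_decay = 0.9995, max_iter = 3000,
                      target_error = 1e-3, verbose = FALSE) {
  stopifnot(inherits(model, "rnn_model"), inherits(trials, "rnn_trials"))
  vall <- unlist(lapply(trials$sets, `[[`, "v"))
  sst <- sum((vall - mean(vall))^2)
  pars <- c("J", "B", "W")
  m1 <- m2 <- lapply(model[pars], function(p) p * 0)
  names(m1) <- names(m2) <- pars
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  err_trace <- numeric(0)
  rate <- lr
  for (it in seq_len(max_iter)) {
    gr <- rnn_loss_grad(model, trials, reg)
    nerr <- gr$err_ss / sst
    err_trace[it] <- nerr
    if (nerr < target_error) break
    gl <- list(J = gr$dJ, B = gr$dB, W = gr$dW)
    for (p in pars) {
      m1[[p]] <- b1 * m1[[p]] + (1 - b1) * gl[[p]]
      m2[[p]] <- b2 * m2[[p]] + (1 - b2) * gl[[p]]^2
      mh <- m1[[p]] / (1 - b1^it)
      vh <- m2[[p]] / (1 - b2^it)
      model[[p]] <- model[[p]] - rate * mh / (sqrt(vh) + eps)
    }
    rate <- rate * lr_decay
    if (verbose && it %% 100 == 0)
      cat(sprintf("iter %d: normalized error %.4g (loss %.4g)\n", it, nerr, gr$loss))
  }
  model$training <- list(
    error_trace = err_trace,
    normalized_error = tail(err_trace, 1),
    iterations = length(err_trace),
    reached_target = tail(err_trace, 1) < target_error,
    reg = reg
  )
  model
}

#' Export RNN unit rates as a population-activity object
#'
#' Runs the (trained) network on one delay's trial set and packages the unit
#' firing rates as a [population_activity()] on a time axis relative to the
#' go cue, with `neural_movement_onset` set to the go cue and `movement_end`
#' 300 ms later (the analysis convention for generated models).
#'
#' @param model A trained [rnn_init()] model.
#' @param trials An [make_trials()] trial set.
#' @param delay Which delay's set to export (ms; default 800).
#' @return A [population_activity()] (rates in `[0, 1)`).
#' @export
rnn_population <- function(model, trials, delay = 800) {
  k <- match(delay, trials$delays)
  if (is.na(k)) stop("`delay` is not one of the trained delays")
  set <- trials$sets[[k]]
  sim <- rnn_simulate(model, set$u)
  time_ms <- seq_len(set$T) * trials$dt - set$delay
  population_activity(
    sim$r, time_ms,
    events = c(go_cue = 0, neural_movement_onset = 0,
               movement_end = min(300, max(time_ms))),
    condition_meta = data.frame(target_angle = trials$task$target_angles),
    generator = "rnn"
  )
}

#' Peak output during the delay period relative to peak target speed
#'
#' Measures null-space output suppression: the maximum absolute readout over
#' the last `check_ms` ms of the delay period, as a fraction of the peak
#' target speed.
#'
#' @param model A trained model.
#' @param trials Trial set.
#' @param check_ms Portion of the delay to check (default 300 ms before go).
#' @return Named vector, one fraction per delay.
#' @export
delay_suppression <- function(model, trials, check_ms = 300) {
  peak <- max(abs(trials$speed))
  vapply(trials$sets, function(set) {
    sim <- rnn_simulate(model, set$u)
    steps <- seq(max(1, set$go_step - check_ms / trials$dt), set$go_step)
    max(abs(sim$z[, , steps])) / peak
  }, numeric(1))
}
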