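#' Fit preferred directions by sinusoidal regression
#'
#' Regresses each neuron's mean movement-period rate on
#' `R_c = b1 + b2*sin(theta_c) + b3*cos(theta_c)` across conditions. The
#' modulation depth is `k = sqrt(b2^2 + b3^2)` and the unit preferred-
#' direction vector is `C = (b3, b2)/k` (x = cos component, y = sin
#' component). Neurons with `k` below `untuned_tol` are flagged untuned.
#'
#' @param pop A [population_activity()] whose `condition_meta$target_angle`
#'   holds the target angles.
#' @param window Averaging window, ms (default: go cue to go + 300).
#' @param untuned_tol Modulation depth below which a neuron is untuned.
#' @return Object of class `tuning_fit`: data.frame `coef` (b1, b2, b3, k,
#'   pd_x, pd_y, pd_angle, untuned) plus the window and angles used.
#' @export
fit_preferred_directions <- function(pop, window = c(0, 300), untuned_tol = 1e-12) {
  angles <- pop$condition_meta$target_angle
  if (is.null(angles)) stop("population lacks condition target angles")
  if (length(angles) < 3) stop("need at least 3 conditions to fit 3 coefficients")
  idx <- window_index(pop, window)
  Rbar <- apply(pop$rates[, , idx, drop = FALSE], c(1, 2), mean)  # n x c
  X <- cbind(1, sin(angles), cos(angles))
  b <- t(qr.solve(X, t(Rbar)))                                    # n x 3
  k <- sqrt(b[, 2]^2 + b[, 3]^2)
  untuned <- k < untuned_tol
  pd_x <- ifelse(untuned, NA_real_, b[, 3] / k)
  pd_y <- ifelse(untuned, NA_real_, b[, 2] / k)
  structure(list(
    coef = data.frame(b1 = b[, 1], b2 = b[, 2], b3 = b[, 3], k = k,
                      pd_x = pd_x, pd_y = pd_y,
                      pd_angle = atan2(pd_y, pd_x) %% (2 * pi),
                      untuned = untuned),
    window = window, angles = angles
  ), class = "tuning_fit")
}

#' Population-vector decoding
#'
#' Computes the population vector `P(t) = sum_i (R_i(t) - b_{i,1}) C_i` from
#' instantaneous rates and fitted preferred directions, per condition. The
#' overall predicted direction is the angle of the summed population vector
#' over the movement; integrating `P` over time traces a predicted trajectory.
#'
#' @param pop A [population_activity()].
#' @param fit A [fit_preferred_directions()] result for the same population.
#' @param window Movement window, ms (default: the fit's window).
#' @return List with `P` (conditions x time x 2), `predicted_angle` and
#'   `target_angle` per condition, `angular_error` (radians, wrapped to
#'   `[-pi, pi]`), `trajectory` (running integral of P, conditions x time x 2)
#'   and `endpoint_angle`.
#' @export
population_vector <- function(pop, fit, window = NULL) {
  stopifnot(inherits(fit, "tuning_fit"))
  window <- window %||% fit$window
  idx <- window_index(pop, window)
  tuned <- !fit$coef$untuned
  if (!any(tuned)) stop("all neurons untuned: population vector undefined")
  Cmat <- cbind(fit$coef$pd_x, fit$coef$pd_y)[tuned, , drop = FALSE]  # n x 2
  b1 <- fit$coef$b1[tuned]
  nc <- dim(pop$rates)[2]; nt <- length(idx)
  P <- aperm(array(vapply(seq_len(nc), function(c) {
    R <- matrix(pop$rates[tuned, c, idx], sum(tuned), nt)
    t(Cmat) %*% (R - b1)
  }, matrix(0, 2, nt)), dim = c(2, nt, nc)), c(3, 2, 1))
  sumP <- apply(P, c(1, 3), sum)                                       # c x 2
  predicted <- atan2(sumP[, 2], sumP[, 1]) %% (2 * pi)
  target <- fit$angles
  traj <- array(0, dim = dim(P))
  for (c in seq_len(nc)) traj[c, , ] <- apply(P[c, , , drop = FALSE][1, , ], 2, cumsum)
  endpoint <- atan2(traj[, nt, 2], traj[, nt, 1]) %% (2 * pi)
  wrap <- function(a) (a + pi) %% (2 * pi) - pi
  list(P = P, predicted_angle = predicted, target_angle = target,
       angular_error = wrap(predicted - target),
       trajectory = traj, endpoint_angle = endpoint,
       endpoint_error = wrap(endpoint - target))
}

#' Lagged velocity-tuning regression
#'
#' Fits, per neuron, the speed-scaled directional tuning model
#' `R(t - tau) = a1 + |V(t)| (a2 + a3 sin(theta) + a4 cos(theta)) +
#' a5 (a3 sin(theta) + a4 cos(theta))` over the movement window and all
#' conditions, where `tau` is the neuron-kinematic lag. The model is linear
#' in `(a1, a2, a3, a4)` given `a5`, so `a5` is profiled over a grid (with a
#' final 1-D refinement) and `tau` searched over `lag_grid`; the fit
#' maximizing adjusted R-squared is kept, ties broken toward the smallest
#' `|tau|`.
#'
#' @param pop A [population_activity()] with condition target angles.
#' @param speed Speed values `|V(t)|` on the window grid (recycled across
#'   conditions), e.g. the target speed profile aligned to the window.
#' @param window Movement window, ms.
#' @param lag_grid Candidate lags, ms (default -200..200 in steps of the
#'   population's dt).
#' @param a5_grid Grid for the preparatory-tuning scale `a5`, in the units of
#'   `speed` (default: 31 points spanning +/- 1.5 peak speed).
#' @param n_par Parameter count for the adjusted R-squared correction
#'   (default 6: a1..a5 plus the searched lag).
#' @return Data.frame, one row per neuron: `a1..a5`, `tau`, `r2`, `adj_r2`.
#' @export
velocity_regression <- function(pop, speed, window = c(0, 300),
                                lag_grid = NULL, a5_grid = NULL, n_par = 6) {
  angles <- pop$condition_meta$target_angle
  if (is.null(angles)) stop("population lacks condition target angles")
  idx <- window_index(pop, window)
  nt <- length(idx)
  if (length(speed) != nt) stop("`speed` must have one value per window sample")
  if (sd(speed) == 0 && length(unique(angles)) < 2)
    stop("degenerate design: constant speed and a single condition")
  lag_grid <- lag_grid %||% seq(-200, 200, by = pop$dt)
  a5_grid <- a5_grid %||% (seq(-1.5, 1.5, length.out = 31) * max(abs(speed)))
  d <- dim(pop$rates)
  nc <- d[2]; m <- nc * nt

  sin_c <- rep(sin(angles), each = nt)
  cos_c <- rep(cos(angles), each = nt)
  sp <- rep(speed, times = nc)

  # responses: R(t - tau) for every neuron and lag, columns = (lag, neuron)
  tq <- pop$time_ms[idx]
  Y <- matrix(NA_real_, m, length(lag_grid) * d[1])
  for (li in seq_along(lag_grid)) {
    ti <- vapply(tq - lag_grid[li], function(x) which.min(abs(pop$time_ms - x)), 1L)
    block <- (li - 1L) * d[1]
    for (c in seq_len(nc)) {
      rows <- (c - 1L) * nt + seq_len(nt)
      Y[rows, block + seq_len(d[1])] <- t(matrix(pop$rates[, c, ti], d[1], nt))
    }
  }

  best <- matrix(-Inf, d[1], 8)  # a1..a5, tau, r2, adj
  colnames(best) <- c("a1", "a2", "a3", "a4", "a5", "tau", "r2", "adj_r2")
  ybar <- colMeans(Y)
  sst <- colSums(Y^2) - m * ybar^2
  flat <- sst <= 1e-12 * pmax(colSums(Y^2), 1)  # zero-variance responses
  for (a5 in a5_grid) {
    X <- cbind(1, sp, (sp + a5) * sin_c, (sp + a5) * cos_c)
    qx <- qr(X)
    beta <- qr.coef(qx, Y)
    res <- Y - X %*% beta
    r2 <- 1 - colSums(res^2) / pmax(sst, .Machine$double.eps)
    r2[flat] <- 0                                # untuned: no explainable variance
    adj <- 1 - (1 - r2) * (m - 1) / (m - n_par - 1)
    for (li in seq_along(lag_grid)) {
      cols <- (li - 1L) * d[1] + seq_len(d[1])
      a <- adj[cols]
      upd <- a > best[, 8] + 1e-12 |
        (abs(a - best[, 8]) <= 1e-12 & abs(lag_grid[li]) < abs(best[, 6]))
      if (any(upd)) {
        best[upd, 1:4] <- t(beta[, cols[upd], drop = FALSE])
        best[upd, 5] <- a5
        best[upd, 6] <- lag_grid[li]
        best[upd, 7] <- r2[cols[upd]]
        best[upd, 8] <- a[upd]
      }
    }
  }
  out <- as.data.frame(best)
  out$tau[!is.finite(out$adj_r2)] <- NA
  out
}

#' Tuning stability over time
#'
#' Correlates each neuron's condition-tuning vector (its rates across
#' conditions at one time point) between a reference time and later times,
#' then averages over neurons. Declining mean correlation indicates unstable
#' preferred directions.
#'
#' @param pop A [population_activity()].
#' @param reference Reference time, ms (default: the
#'   `neural_movement_onset` event).
#' @param deltas Elapsed times to compare, ms.
#' @param method Correlation method (`"pearson"` or `"spearman"`).
#' @return List with `mean_correlation` (named by delta), `correlations`
#'   (neurons x deltas matrix) and `n_skipped` zero-variance neurons.
#' @export
tuning_stability <- function(pop, reference = NULL, deltas = seq(0, 200, by = 10),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (dim(pop$rates)[2] < 3) stop("need at least 3 conditions")
  reference <- reference %||% pop$events[["neural_movement_onset"]]
  if (is.null(reference)) stop("no reference time: set `reference` or the onset event")
  t_ref <- which.min(abs(pop$time_ms - reference))
  ref <- pop$rates[, , t_ref]
  ok <- apply(ref, 1, sd) > 0
  cors <- vapply(deltas, function(dl) {
    t_k <- which.min(abs(pop$time_ms - (reference + dl)))
    lat <- pop$rates[, , t_k]
    good <- ok & apply(lat, 1, sd) > 0
    out <- rep(NA_real_, nrow(ref))
    out[good] <- vapply(which(good), function(i)
      cor(ref[i, ], lat[i, ], method = method), numeric(1))
    out
  }, numeric(nrow(ref)))
  colnames(cors) <- deltas
  list(mean_correlation = colMeans(cors, na.rm = TRUE),
       correlations = cors,
       n_skipped = sum(!ok))
}

#' Preferred-direction time course
#'
#' For each neuron and time point, the preferred direction is the condition
#' with the highest rate; when the rate difference between the preferred and
#' least-preferred condition is below `untuned_epsilon` the unit is deemed
#' untuned at that time (coded `NA`).
#'
#' @param pop A [population_activity()].
#' @param untuned_epsilon Rate-difference threshold (default 1e-4).
#' @return Matrix neurons x time of condition indices (NA = untuned), with
#'   attribute `order_at_go` sorting rows by preferred direction at the go
#'   cue.
#' @export
preferred_direction_timecourse <- function(pop, untuned_epsilon = 1e-4) {
  d <- dim(pop$rates)
  pd <- matrix(NA_integer_, d[1], d[3])
  for (k in seq_len(d[3])) {
    slice <- matrix(pop$rates[, , k], d[1], d[2])
    rngs <- apply(slice, 1, function(r) diff(range(r)))
    pk <- max.col(slice, ties.method = "first")
    pk[rngs < untuned_epsilon] <- NA_integer_
    pd[, k] <- pk
  }
  go <- which.min(abs(pop$time_ms - (pop$events[["go_cue"]] %||% 0)))
  attr(pd, "order_at_go") <- order(pd[, go], na.last = TRUE)
  pd
}

#' Principal components of time-shifted copies of one signal
#'
#' Demonstrates how identical signals with random latencies produce
#' Fourier-like principal components and a "horseshoe" trace in the PC1-PC2
#' plane: `n_signals` Gaussian bumps with shifts drawn from
#' `Normal(0, shift_sd)` are analyzed with PCA over time.
#'
#' @param n_signals Number of shifted copies (>= 3).
#' @param shift_sd SD of the time shifts, ms.
#' @param signal_sd SD of the Gaussian bump, ms.
#' @param window,dt Time axis, ms.
#' @param seed Optional RNG seed.
#' @return List with `pcs` (time x component score matrix), `variance`
#'   (fraction per PC), `plane` (the PC1-PC2 trace) and the signals.
#' @export
demo_latency_pcs <- function(n_signals = 6, shift_sd = 72, signal_sd = 56,
                             window = c(-300, 500), dt = 10, seed = NULL) {
  if (n_signals < 3) stop("need at least 3 signals")
  with_seed(seed, {
    t <- seq(window[1], window[2], by = dt)
    shifts <- rnorm(n_signals, 0, shift_sd)
    S <- vapply(shifts, function(s) exp(-(t - s)^2 / (2 * signal_sd^2)),
                numeric(length(t)))                       # time x signals
    Sc <- scale(S, center = TRUE, scale = FALSE)
    sv <- svd(Sc)
    scores <- sv$u %*% diag(sv$d)
    list(pcs = scores, variance = sv$d^2 / sum(sv$d^2),
         plane = scores[, 1:2], signals = S, time_ms = t, shifts = shifts)
  })
}
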