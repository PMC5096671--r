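#' Define a center-out reaching task
#'
#' Creates the set of equally spaced reach targets on a circle. The standard
#' task used throughout the package is 13 directions on a 20-cm circle.
#'
#' @param n_conditions Number of reach directions (at least 2).
#' @param start_angle Angle of the first target, radians.
#' @param radius Reach distance in cm.
#' @return An object of class `reach_task` with fields `n_conditions`,
#'   `target_angles` (radians, equally spaced over `[0, 2*pi)`) and `radius`.
#' @examples
#' task <- reach_task(13)
#' task$target_angles
#' @export
reach_task <- function(n_conditions = 13, start_angle = 0, radius = 20) {
  n_conditions <- as.integer(n_conditions)
  if (is.na(n_conditions) || n_conditions < 2L)
    stop("a reaching task needs at least 2 target directions")
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  angles <- (start_angle + 2 * pi * (seq_len(n_conditions) - 1L) / n_conditions) %% (2 * pi)
  structure(
    list(n_conditions = n_conditions, target_angles = angles, radius = radius),
    class = "reach_task"
  )
}

#' @export
print.reach_task <- function(x, ...) {
  cat(sprintf("Center-out reaching task: %d directions, radius %g cm\n",
              x$n_conditions, x$radius))
  invisible(x)
}

#' Bell-shaped reach speed profile
#'
#' A truncated-Gaussian speed profile (the conventional "bell-shaped velocity
#' profile" of reaching), rescaled so that the path length (the time integral
#' of speed) equals `radius`. The Gaussian is centered at
#' `peak_fraction * duration` with SD one third of the distance to the nearer
#' endpoint, so the profile is essentially zero at both ends.
#'
#' @param duration Movement duration in ms.
#' @param dt Sampling step in ms; must divide `duration`.
#' @param peak_fraction Fractional time of peak speed (0.5 = symmetric).
#' @param radius Reach distance in cm the profile integrates to.
#' @return Numeric vector of speeds (cm/s) sampled at
#'   `seq(dt/2, duration - dt/2, by = dt)` (midpoint grid, so the discrete
#'   integral `sum(speed) * dt/1000` equals `radius` almost exactly).
#' @export
bell_profile <- function(duration = 300, dt = 10, peak_fraction = 0.5, radius = 20) {
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be positive")
  n <- duration / dt
  if (abs(n - round(n)) > 1e-8) stop("`dt` must divide `duration`")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 0.5) * dt
  center <- peak_fraction * duration
  sdev <- min(center, duration - center) / 3
  v <- exp(-(t - center)^2 / (2 * sdev^2))
  v <- v - min(v)                     # exact zero at the far end
  v * radius / (sum(v) * dt / 1000)   # cm/s so that integral = radius cm
}

#' Assemble per-condition kinematic traces
#'
#' Combines a reach task and a speed profile into straight-line reach
#' kinematics: per-condition velocity, position, acceleration and jerk traces
#' sampled on the profile's grid. Velocity is `speed * (cos, sin)` of the
#' target angle; position is the cumulative integral of velocity;
#' acceleration and jerk are successive discrete derivatives of velocity.
#'
#' @param task A [reach_task()].
#' @param speed Speed profile from [bell_profile()] (cm/s).
#' @param dt Sampling step of `speed`, ms.
#' @return Object of class `kinematic_set`: list with `time_ms`, `dt`,
#'   `speed`, and arrays `velocity`, `position`, `acceleration`, `jerk` of
#'   dimension `c(n_conditions, length(speed), 2)` (x/y last).
#' @export
kinematic_traces <- function(task, speed, dt = 10) {
  stopifnot(inherits(task, "reach_task"))
  nt <- length(speed)
  nc <- task$n_conditions
  time_ms <- (seq_len(nt) - 0.5) * dt
  dts <- dt / 1000 # seconds
  dirs <- cbind(cos(task$target_angles), sin(task$target_angles)) # nc x 2
  vel <- pos <- acc <- jrk <- array(0, dim = c(nc, nt, 2))
  for (c in seq_len(nc)) {
    v <- outer(speed, dirs[c, ])        # nt x 2
    p <- apply(v * dts, 2, cumsum)
    a <- apply(v, 2, function(z) c(z[1], diff(z)) / dts)
    j <- apply(a, 2, function(z) c(z[1], diff(z)) / dts)
    vel[c, , ] <- v; pos[c, , ] <- p; acc[c, , ] <- a; jrk[c, , ] <- j
  }
  structure(
    list(time_ms = time_ms, dt = dt, speed = speed, velocity = vel,
         position = pos, acceleration = acc, jerk = jrk,
         target_angles = task$target_angles, radius = task$radius),
    class = "kinematic_set"
  )
}

#' @export
print.kinematic_set <- function(x, ...) {
  cat(sprintf("Kinematic set: %d conditions, %d samples at dt = %g ms, peak speed %.1f cm/s\n",
              dim(x$velocity)[1], dim(x$velocity)[2], x$dt, max(x$speed)))
  invisible(x)
}
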