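# helper: population with rates R_ic(t) = b1 + k cos(theta_c - pd) * shape(t)
cosine_population <- function(b, pd = NULL, n_cond = 13, nt = 31, shape = NULL,
                              angles = NULL) {
  angles <- angles %||% (2 * pi * (seq_len(n_cond) - 1) / n_cond)
  shape <- shape %||% rep(1, nt)
  n <- nrow(b)
  rates <- array(0, c(n, n_cond, nt))
  for (i in seq_len(n)) for (c in seq_len(n_cond))
    rates[i, c, ] <- b[i, 1] + (b[i, 2] * sin(angles[c]) + b[i, 3] * cos(angles[c])) * shape
  population_activity(rates, seq(0, by = 10, length.out = nt),
                      events = c(go_cue = 0, neural_movement_onset = 0),
                      condition_meta = data.frame(target_angle = angles))
}

test_that("preferred-direction regression recovers exact sinusoidal tuning", {
  # R = sin(theta) -> b = (0, 1, 0), k = 1, PD = 90 degrees
  pop <- cosine_population(matrix(c(0, 1, 0), 1))
  fit <- fit_preferred_directions(pop)
  expect_equal(unlist(fit$coef[1, c("b1", "b2", "b3")]), c(b1 = 0, b2 = 1, b3 = 0),
               tolerance = 1e-10)
  expect_equal(fit$coef$k, 1, tolerance = 1e-10)
  expect_equal(fit$coef$pd_angle, pi / 2, tolerance = 1e-10)

  # synthesis-recovery oracle: random coefficients on 13 noiseless angles
  set.seed(8)
  b <- cbind(rnorm(20), rnorm(20), rnorm(20))
  popr <- cosine_population(b)
  fitr <- fit_preferred_directions(popr)
  expect_equal(as.matrix(fitr$coef[, c("b1", "b2", "b3")]), b,
               tolerance = 1e-10, ignore_attr = TRUE)

  # constant rate -> untuned
  popc <- cosine_population(matrix(c(0.4, 0, 0), 1))
  fitc <- fit_preferred_directions(popc)
  expect_true(fitc$coef$untuned[1])
  expect_true(is.na(fitc$coef$pd_x[1]))

  two <- subset_population(pop, conditions = 1:2)
  expect_error(fit_preferred_directions(two), "at least 3")
})

test_that("population vector is exact for ideal uniformly tuned cosine populations", {
  set.seed(2)
  n <- 120
  pds <- 2 * pi * (seq_len(n) - 1) / n
  shape <- bell_profile(300, 10)[1:30]
  b <- cbind(runif(n, 1, 2), sin(pds), cos(pds))
  pop <- cosine_population(b, nt = 30, shape = shape)
  fit <- fit_preferred_directions(pop, window = c(0, 290))
  pv <- population_vector(pop, fit, window = c(0, 290))
  # Sanger-type exactness: predicted angle within 1 degree of every target
  expect_lt(max(abs(pv$angular_error)), pi / 180)
  expect_lt(max(abs(pv$endpoint_error)), pi / 180)

  # doubling rates and baselines doubles the population vector exactly
  pop2 <- pop; pop2$rates <- 2 * pop$rates
  fit2 <- fit
  fit2$coef$b1 <- 2 * fit$coef$b1
  pv2 <- population_vector(pop2, fit2, window = c(0, 290))
  expect_equal(pv2$P, 2 * pv$P, tolerance = 1e-10)

  # error decreases with population size for uniform cosine tuning
  n_small <- 50
  pds_s <- 2 * pi * (seq_len(n_small) - 1) / n_small + 0.01 * rnorm(n_small)
  b_s <- cbind(runif(n_small, 1, 2), sin(pds_s), cos(pds_s))
  pop_s <- cosine_population(b_s, nt = 30, shape = shape)
  pv_s <- population_vector(pop_s, fit_preferred_directions(pop_s, window = c(0, 290)),
                            window = c(0, 290))
  n_big <- 500
  pds_b <- 2 * pi * (seq_len(n_big) - 1) / n_big + 0.01 * rnorm(n_big)
  b_b <- cbind(runif(n_big, 1, 2), sin(pds_b), cos(pds_b))
  pop_b <- cosine_population(b_b, nt = 30, shape = shape)
  pv_b <- population_vector(pop_b, fit_preferred_directions(pop_b, window = c(0, 290)),
                            window = c(0, 290))
  expect_lt(mean(abs(pv_b$angular_error)), mean(abs(pv_s$angular_error)) + 1e-9)
})

test_that("lagged velocity regression recovers generating parameters", {
  task <- reach_task(13)
  nt <- 31
  t_ms <- seq(-300, 500, by = 10)
  speed_full <- c(rep(0, 30), bell_profile(300, 10), rep(0, 21))  # movement at 0..300
  a_true <- c(a1 = 0.3, a2 = 0.004, a3 = 0.006, a4 = -0.003, a5 = 40)
  tau_true <- 40
  rates <- array(0, c(3, 13, length(t_ms)))
  for (c in 1:13) {
    th <- task$target_angles[c]
    drive <- a_true["a1"] +
      speed_full * (a_true["a2"] + a_true["a3"] * sin(th) + a_true["a4"] * cos(th)) +
      a_true["a5"] * (a_true["a3"] * sin(th) + a_true["a4"] * cos(th))
    # R(t - tau) = drive(t): the neuron's rate leads the kinematics by tau
    rates[1, c, ] <- approx(t_ms - tau_true, drive, t_ms, rule = 2)$y
    rates[2, c, ] <- 0.5                                  # constant neuron
    rates[3, c, ] <- rates[1, c, ] + rnorm(length(t_ms), 0, 1e-4)
  }
  pop <- population_activity(rates, t_ms,
                             events = c(go_cue = 0, neural_movement_onset = 0),
                             condition_meta = data.frame(target_angle = task$target_angles))
  win_speed <- speed_full[t_ms >= 0 & t_ms <= 300]
  fit <- velocity_regression(pop, win_speed, window = c(0, 300),
                             a5_grid = seq(0, 80, by = 5))
  expect_equal(fit$tau[1], tau_true, tolerance = 10)      # within one grid step
  expect_gt(fit$adj_r2[1], 0.99)                          # noiseless member of Eq-12 class
  expect_equal(fit$a5[1], 40, tolerance = 5)
  for (p in c("a2", "a3", "a4"))
    expect_equal(fit[[p]][1], unname(a_true[p]), tolerance = 0.05 * abs(a_true[p]))

  # constant neuron: no tuning, adjusted R^2 about zero
  expect_lt(abs(fit$adj_r2[2]), 0.05)
  expect_lt(max(abs(unlist(fit[2, c("a2", "a3", "a4")]))), 1e-6)

  # near-noiseless neuron still recovered
  expect_equal(fit$tau[3], tau_true, tolerance = 10)
  expect_gt(fit$adj_r2[3], 0.98)
})

test_that("tuning stability is 1 at zero lag and flat for static tuning", {
  pop <- simulate_representational(reach_task(8), n_neurons = 30, noise_sd = 0,
                                   latency_sd = 0, seed = 6)
  pop$events["neural_movement_onset"] <- 50  # inside the rising movement phase
  ts <- tuning_stability(pop, deltas = seq(0, 100, 10))
  expect_equal(unname(ts$mean_correlation["0"]), 1, tolerance = 1e-12)
  # static tuning: the condition profile is b * shape(t); correlation stays 1
  expect_true(all(ts$mean_correlation > 0.999))

  two <- subset_population(pop, conditions = 1:2)
  expect_error(tuning_stability(two), "at least 3")
})

test_that("preferred-direction time course matches a brute-force scan", {
  pop <- small_dyn(seed = 9, n_neurons = 10)
  pd <- preferred_direction_timecourse(pop, untuned_epsilon = 1e-4)
  d <- dim(pop$rates)
  for (i in c(1, 7)) for (k in c(3, 20)) {
    r <- pop$rates[i, , k]
    if (diff(range(r)) < 1e-4) expect_true(is.na(pd[i, k]))
    else expect_equal(pd[i, k], which.max(r))
  }

  # ideal cosine neuron keeps one preferred direction throughout
  popc <- cosine_population(matrix(c(1, 0.5, 0.5), 1), nt = 20)
  pdc <- preferred_direction_timecourse(popc)
  expect_length(unique(pdc[1, ]), 1)

  # equal rates at a time point are untuned
  flat <- population_activity(array(0.2, c(2, 4, 5)), seq(0, 40, 10))
  expect_true(all(is.na(preferred_direction_timecourse(flat))))
})

test_that("time-shifted copies of one signal produce Fourier-like PCs and a horseshoe", {
  d0 <- demo_latency_pcs(n_signals = 10, shift_sd = 0, seed = 3)
  expect_gt(d0$variance[1], 0.999)

  d <- demo_latency_pcs(n_signals = 60, shift_sd = 72, seed = 4)
  # crossing-count oracle: zero crossings non-decreasing over the first 4 PCs
  crossings <- vapply(1:4, function(k)
    rotdyn:::zero_crossings(d$pcs[, k], tol = 0.02), integer(1))
  expect_true(all(diff(crossings) >= 0))

  # discrete-curvature sign oracle: the PC1-PC2 trace bends one way
  seg <- diff(d$plane)
  cross <- seg[-nrow(seg), 1] * seg[-1, 2] - seg[-nrow(seg), 2] * seg[-1, 1]
  main_sign <- sign(sum(sign(cross)))
  expect_gt(mean(sign(cross) == main_sign), 0.9)

  expect_error(demo_latency_pcs(n_signals = 2), "at least 3")
})
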