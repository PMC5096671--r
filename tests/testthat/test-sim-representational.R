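# direct evaluations of the cosine-tuned latency model (noiseless unless noted)

test_that("directional gain follows the offset-cosine rule", {
  # one neuron preferring angle 0, two conditions at 0 and pi
  r <- rotdyn:::eq1_rates(theta_n = 0, tau_n = 0, gain_scale = 1,
                          target_angles = c(0, pi), time_ms = seq(-100, 400, 10),
                          movement_sd = 56, phi = 0.2)
  expect_equal(max(r[1, 1, ]), 1, tolerance = 1e-3)   # b = 1 at preferred (10-ms grid)
  expect_equal(max(abs(r[1, 2, ])), 0)                # b = 0 at anti-preferred

  # signed-gain variant allows negative rates
  rs <- rotdyn:::eq1_rates(0, 0, 1, c(0, pi), seq(-100, 400, 10), 56, 0.2,
                           gain_mode = "signed")
  expect_lt(min(rs[1, 2, ]), -0.9)
})

test_that("the two branches meet continuously at t = tau_n", {
  sigma <- 56; phi <- 0.2; tau <- 37
  mu0 <- sigma * sqrt(-2 * log(phi))
  # symbolic check of mu0: the movement branch at t = tau equals phi * b
  expect_equal(exp(-mu0^2 / (2 * sigma^2)), phi, tolerance = 1e-12)
  # grid containing tau exactly: both branches evaluate to phi * b there
  tgrid <- sort(c(seq(-300, 600, 10), tau, tau - 1e-9))
  r <- rotdyn:::eq1_rates(0, tau, 1, 0, tgrid, sigma, phi)
  at_tau <- r[1, 1, which(tgrid == tau)]
  just_before <- r[1, 1, which(tgrid == tau - 1e-9)]
  expect_equal(at_tau, phi * 1, tolerance = 1e-12)
  expect_equal(just_before, at_tau, tolerance = 1e-6)
})

test_that("noiseless peak sits at tau + mu0 with height b (dense-grid argmax oracle)", {
  sigma <- 40; phi <- 0.2
  taus <- c(-80, 0, 55)
  mu0 <- sigma * sqrt(-2 * log(phi))
  dense <- seq(-400, 700, by = 1)
  r <- rotdyn:::eq1_rates(rep(0.7, 3), taus, rep(1, 3), 0.7, dense, sigma, phi)
  for (i in 1:3) {
    expect_equal(dense[which.max(r[i, 1, ])], taus[i] + mu0, tolerance = 1)
    expect_equal(max(r[i, 1, ]), 1, tolerance = 1e-4)  # b = 1 (1-ms grid)
  }
})

test_that("default-gain noiseless rates stay in [0, 1] and zero-spread populations share one time course", {
  pop <- simulate_representational(reach_task(5), n_neurons = 30, noise_sd = 0,
                                   seed = 2)
  expect_true(all(pop$rates >= 0 & pop$rates <= 1))

  pop0 <- simulate_representational(reach_task(5), n_neurons = 12, noise_sd = 0,
                                    latency_sd = 0, seed = 3)
  # every (neuron, condition) trace is b * common shape: normalized traces equal
  shape <- NULL
  for (i in 1:12) for (c in 1:5) {
    tr <- pop0$rates[i, c, ]
    if (max(tr) < 1e-3) next
    tr <- tr / max(tr)
    if (is.null(shape)) shape <- tr else expect_equal(tr, shape, tolerance = 1e-8)
  }
})

test_that("peak times recover the sampled latencies (noiseless oracle)", {
  pop <- simulate_representational(reach_task(7), n_neurons = 25, noise_sd = 0,
                                   latency_sd = 72, movement_sd = 56,
                                   window = c(-400, 800), dt = 1, seed = 9)
  mu0 <- 56 * sqrt(-2 * log(0.2))
  # per neuron: argmax over its best condition
  est <- vapply(seq_len(25), function(i) {
    flat <- apply(pop$rates[i, , ], 2, max)
    pop$time_ms[which.max(flat)] - mu0
  }, numeric(1))
  expect_equal(sort(est), sort(pop$neuron_meta$tau), tolerance = 2.5)
})

test_that("random-gain variant scales each neuron's gain magnitude within [0.5, 1.5]", {
  pop <- simulate_representational(reach_task(4), n_neurons = 40, noise_sd = 0,
                                   gain_mode = "random", seed = 5)
  gs <- pop$neuron_meta$gain_scale
  expect_true(all(gs >= 0.5 & gs <= 1.5))
  expect_gt(sd(gs), 0.1)
  i <- which.max(gs)
  best_align <- max(abs(cos(pop$condition_meta$target_angle[1:4] -
                            pop$neuron_meta$theta[i])))
  expect_equal(max(abs(pop$rates[i, , ])), gs[i] * best_align, tolerance = 0.01)
})

test_that("simulation is reproducible under a seed and parameters are validated", {
  a <- simulate_representational(reach_task(4), n_neurons = 6, seed = 42)
  b <- simulate_representational(reach_task(4), n_neurons = 6, seed = 42)
  expect_identical(a$rates, b$rates)
  expect_error(simulate_representational(phi = 0), "phi")
  expect_error(simulate_representational(phi = 1), "phi")
})

test_that("movement onset detection matches the analytic Gaussian crossing", {
  # single aligned neuron: grand average = prep 0.2, peak 1.0 Gaussian
  sigma <- 56; phi <- 0.2
  mu0 <- sigma * sqrt(-2 * log(phi))
  pop <- simulate_representational(reach_task(2, start_angle = 0), n_neurons = 1,
                                   noise_sd = 0, latency_sd = 0, seed = 1)
  # make it a clean single-neuron aligned population
  r <- rotdyn:::eq1_rates(0, 0, 1, 0, pop$time_ms, sigma, phi)
  pop2 <- population_activity(array(r[1, 1, ], c(1, 1, length(pop$time_ms))),
                              pop$time_ms)
  # closed-form crossing of prep + 0.1 * (max - prep) = 0.28
  level <- phi + 0.1 * (1 - phi)
  t_on <- mu0 - sigma * sqrt(-2 * log(level))
  t_off <- mu0 + sigma * sqrt(-2 * log(level))
  det <- suppressWarnings(detect_movement_onset(pop2, baseline_end = -200))
  expect_equal(det$events[["neural_movement_onset"]], t_on, tolerance = 10)
  expect_equal(det$events[["movement_end"]], t_off, tolerance = 10)

  # flat signal errors
  flat <- population_activity(array(0.3, c(2, 2, 40)), seq(-300, 90, 10))
  expect_error(detect_movement_onset(flat), "flat")
})

test_that("latency sweep has grid shape and rotational structure grows with latency spread", {
  grid <- latency_sweep(latency_sds = c(0, 100), movement_sds = 56, reps = 4,
                        task = reach_task(8), n_neurons = 40, seed = 77)
  expect_equal(dim(grid), c(2, 1))
  expect_true(all(is.finite(grid)))
  # Monte-Carlo ordering: latencies much wider than the movement SD produce
  # more rotational structure
  expect_gt(grid["100", 1], grid["0", 1])
  expect_error(latency_sweep(numeric(0), 56), "empty")
})
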