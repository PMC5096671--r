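test_that("condition permutation relabels whole traces and conserves per-neuron statistics", {
  pop <- small_dyn(seed = 3, n_neurons = 15)
  pm <- permute_conditions(pop, seed = 9)
  d <- dim(pop$rates)

  for (i in seq_len(d[1])) {
    # permutation-check oracle: each assignment column is a bijection
    expect_setequal(pm$assignment[, i], seq_len(d[2]))
    # multiset of traces identical (relabeling only)
    a <- apply(pop$rates[i, , ], 1, paste, collapse = "|")
    b <- apply(pm$pop$rates[i, , ], 1, paste, collapse = "|")
    expect_setequal(a, b)
    # traces moved according to the assignment
    expect_identical(pm$pop$rates[i, , ], pop$rates[i, pm$assignment[, i], ])
  }
  # per-neuron means conserved to machine precision
  expect_identical(apply(pm$pop$rates, 1, mean), apply(pop$rates, 1, mean))
  expect_identical(sum(pm$pop$rates), sum(pop$rates))

  one <- subset_population(pop, conditions = 1)
  expect_error(permute_conditions(one), "single-condition")
})

test_that("covariance similarity is 1 for identical data and for global relabels", {
  pop <- small_dyn(seed = 7, n_neurons = 5)
  expect_equal(covariance_similarity(pop, pop), 1)

  # algebraic oracle on a 5-neuron toy: relabeling conditions identically in
  # all neurons permutes columns of the data matrix; covariance is unchanged
  relab <- pop
  relab$rates <- pop$rates[, c(3, 1, 2, 5, 4, 7, 6, 8), ]
  expect_equal(covariance_similarity(pop, relab), 1, tolerance = 1e-12)
  expect_equal(covariance_similarity(pop, relab, preprocess = FALSE), 1,
               tolerance = 1e-12)

  flat <- population_activity(array(1, c(3, 4, 5)), seq(0, 40, 10))
  expect_error(covariance_similarity(flat, flat), "zero-variance")
})

test_that("greedy matching increases similarity monotonically and reaches the threshold", {
  pop <- simulate_dynamical(seed = 2)  # full-size dynamical data
  pm <- permute_conditions(pop, seed = 5)
  m <- match_covariance(pop, pm$assignment, window = c(0, 300),
                        threshold = 0.95, record_trace = TRUE, seed = 6)
  expect_true(m$converged)
  expect_gte(m$similarity, 0.95)
  # accepted-swap similarity sequence strictly increasing
  expect_true(all(diff(m$trace) > 0))
  # incremental covariance update agrees with full recomputation
  expect_equal(m$similarity_incremental, m$similarity, tolerance = 1e-10)
  expect_equal(covariance_similarity(pop, m$pop, window = c(0, 300)),
               m$similarity, tolerance = 1e-10)

  # matching preserves the per-neuron trace multisets
  for (i in c(1, 50, 200)) {
    a <- apply(pop$rates[i, , ], 1, paste, collapse = "|")
    b <- apply(m$pop$rates[i, , ], 1, paste, collapse = "|")
    expect_setequal(a, b)
  }
})

test_that("permutation p-value and effect size follow their definitions (hand oracle)", {
  s <- cmpt_summary(0.7, c(0.2, 0.4, 0.6, 0.8))
  expect_equal(s$p_value, 0.25)
  expect_equal(s$effect_size, (0.7 - 0.5) / sd(c(0.2, 0.4, 0.6, 0.8)))
  s2 <- cmpt_summary(0.9, c(0.2, 0.4, 0.6, 0.8))
  expect_equal(s2$p_value, 0)
  expect_equal(s2$p_string, "< 0.25")
})

test_that("assignment rows are sorted by their most common condition (hand oracle)", {
  # 3 conditions x 4 neurons; row 1 mostly condition 2, row 2 mostly 3, row 3 mostly 1
  a <- matrix(c(2, 3, 1,
                2, 3, 1,
                2, 1, 3,
                3, 2, 1), nrow = 3)
  sorted <- rotdyn:::sort_assignment_rows(a)
  # hand-sorted: row with most 1s (row 3) first, most 2s (row 1) second,
  # most 3s (row 2) third
  expect_identical(sorted, a[c(3, 1, 2), ])
  # retained fraction after sorting = share of entries equal to the row label
  expect_equal(mean(sorted == row(sorted)), 8 / 12)
})

test_that("the unshuffle control flags zero-variance retained fractions", {
  pop <- small_dyn(seed = 1, n_neurons = 12)
  res <- cmpt(pop, n_reps = 6, d = 4, seed = 2)
  uc <- unshuffle_check(res)
  expect_true(is.numeric(uc$retained_fraction))
  expect_length(uc$retained_fraction, length(res$null_rgrs))
  if (!uc$zero_variance) {
    expect_true(abs(uc$r) <= 1)
    expect_true(uc$p >= 0 && uc$p <= 1)
  }

  fake <- res
  fake$assignments <- rep(list(res$assignments[[1]]), length(res$assignments))
  expect_true(unshuffle_check(fake)$zero_variance)

  fake2 <- res; fake2$assignments <- res$assignments[1:2]
  expect_error(unshuffle_check(fake2), "at least 3")
})

test_that("CMPT p-values are approximately uniform under their own null (calibration)", {
  # small, fast dynamical population; each replicate treats one matched
  # permutation of the data as the "observed" set
  base <- simulate_dynamical(reach_task(5), n_neurons = 15, duration = 200,
                             prep_extension = 0, seed = 40)
  ps <- vapply(1:50, function(k) {
    pm <- permute_conditions(base, seed = 500 + k)
    m <- match_covariance(base, pm$assignment, window = c(0, 200),
                          threshold = 0.95, seed = 700 + k)
    res <- cmpt(m$pop, n_reps = 20, d = 4, window = c(0, 200),
                keep_assignments = FALSE, seed = 900 + k)
    res$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subset grid has the requested shape and flags untestable cells", {
  pop <- small_dyn(seed = 8, n_neurons = 30)
  g <- subset_grid(pop, neuron_counts = c(10, 20), condition_counts = c(1, 4, 8),
                   n_reps = 4, d = 4, seed = 3)
  expect_equal(dim(g$p_value), c(2, 3))
  expect_equal(dim(g$effect_size), c(2, 3))
  expect_true(all(is.na(g$p_value[, 1])))     # single condition untestable
  expect_true(all(!is.na(g$p_value[, 2:3])))
  expect_true(all(g$p_value[, 2:3] >= 0 & g$p_value[, 2:3] <= 1))
  expect_error(subset_grid(pop, 100, 4, n_reps = 2), "exceed")
})
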