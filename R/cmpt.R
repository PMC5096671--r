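#' Randomly reassign conditions within each neuron
#'
#' The first stage of the covariance-matched permutation test: for each
#' neuron separately, the entire time course of each condition is randomly
#' reassigned to another condition. No values are altered and no data is
#' exchanged between neurons, so per-neuron means and trace multisets are
#' conserved exactly.
#'
#' @param pop A [population_activity()] with at least 2 conditions.
#' @param seed Optional RNG seed.
#' @return List with `pop` (the permuted population) and `assignment`, a
#'   conditions x neurons matrix whose entry `(c, n)` is the original
#'   condition now occupying slot `c` for neuron `n` (each column a
#'   permutation).
#' @export
permute_conditions <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "population_activity"))
  d <- dim(pop$rates)
  if (d[2] < 2) stop("cannot permute a single-condition population")
  with_seed(seed, {
    assignment <- vapply(seq_len(d[1]), function(i) sample.int(d[2]), integer(d[2]))
    list(pop = apply_assignment(pop, assignment), assignment = assignment)
  })
}

# Rebuild a population with per-neuron condition slots taken from
# `assignment` (conditions x neurons).
apply_assignment <- function(pop, assignment) {
  d <- dim(pop$rates)
  out <- pop$rates
  for (i in seq_len(d[1])) out[i, , ] <- pop$rates[i, assignment[, i], ]
  pop$rates <- out
  pop
}

#' Covariance similarity between two populations
#'
#' `1 - SSD / TSS`, where SSD is the summed squared difference between the
#' observed and permuted neuron-by-neuron covariance matrices (computed from
#' the neurons x (conditions*time) matrix over the analysis window) and TSS
#' is the summed squared deviation of the observed covariance entries from
#' their mean.
#'
#' @param obs,perm Two [population_activity()] objects of identical shape.
#' @param window Analysis window in ms (default: full axis).
#' @param preprocess If `TRUE` (default), compare covariances of the
#'   normalized data (per-neuron range normalization and centering, the
#'   covariance that determines the PCA stage); `FALSE` compares raw-rate
#'   covariances.
#' @param soften,subtract_cc_mean Preprocessing options, as in [jpca()];
#'   `subtract_cc_mean` defaults to `FALSE` here: the neuron-by-neuron
#'   covariance is that of the normalized signals themselves, not of the
#'   jPCA-specific cross-condition residuals.
#' @return Similarity fraction (1 = identical covariance).
#' @export
covariance_similarity <- function(obs, perm, window = NULL, preprocess = TRUE,
                                  soften = 0.05, subtract_cc_mean = FALSE) {
  if (!identical(dim(obs$rates), dim(perm$rates))) stop("shape mismatch")
  co <- neuron_covariance(obs, window, preprocess, soften, subtract_cc_mean)
  cp <- neuron_covariance(perm, window, preprocess, soften, subtract_cc_mean)
  tss <- sum((co - mean(co))^2)
  if (tss <= 0) stop("zero-variance observed covariance: similarity undefined")
  1 - sum((co - cp)^2) / tss
}

neuron_covariance <- function(pop, window = NULL, preprocess = FALSE,
                              soften = 0.05, subtract_cc_mean = TRUE) {
  X <- if (preprocess) jpca_preprocess(pop, window, soften, subtract_cc_mean)
       else flatten_rates(pop, window)
  X <- X - rowMeans(X)
  (X %*% t(X)) / (ncol(X) - 1)
}

#' Greedy covariance matching of a permuted population
#'
#' Starting from a within-neuron condition permutation, repeatedly proposes a
#' random within-neuron swap of two condition traces and accepts it iff the
#' covariance similarity to the observed data strictly increases, stopping
#' once the similarity reaches `threshold` (or the proposal cap is hit).
#'
#' @param obs The observed [population_activity()].
#' @param assignment Initial assignment matrix from [permute_conditions()].
#' @param window Analysis window (the window later analyzed with jPCA).
#' @param threshold Target covariance similarity (default 0.95).
#' @param max_swaps Cap on swap proposals (default `200 * neurons * conditions`).
#' @param record_trace Keep the similarity value after every accepted swap.
#' @param preprocess Match the covariance of the normalized data (default)
#'   or of the raw rates. The preprocessing statistics (per-neuron range and
#'   means, cross-condition mean trace) are permutation-invariant, so either
#'   way the matched population is an exact within-neuron relabeling of the
#'   observed traces.
#' @param soften,subtract_cc_mean Preprocessing options, as in [jpca()]
#'   (`subtract_cc_mean` defaults to `FALSE` for the covariance target; see
#'   [covariance_similarity()]).
#' @param seed Optional RNG seed.
#' @return List with the matched `pop`, final `assignment`, `similarity`,
#'   `converged`, `proposals`, `accepted` and (optionally) `trace`.
#' @export
match_covariance <- function(obs, assignment, window = NULL, threshold = 0.95,
                             max_swaps = NULL, record_trace = FALSE,
                             preprocess = TRUE, soften = 0.05,
                             subtract_cc_mean = FALSE, seed = NULL) {
  d <- dim(obs$rates)
  idx <- if (is.null(window)) seq_along(obs$time_ms) else window_index(obs, window)
  max_swaps <- max_swaps %||% (200 * d[1] * d[2])
  X <- if (preprocess) jpca_preprocess(obs, window, soften, subtract_cc_mean)
       else flatten_rates(obs, window)
  res <- with_seed(seed,
    cmpt_match_cpp(X, d[2], length(idx), assignment, threshold,
                   as.double(max_swaps), record_trace))
  list(pop = apply_assignment(obs, res$assignment),
       assignment = res$assignment, similarity = res$similarity,
       similarity_incremental = res$similarity_incremental,
       converged = res$converged, proposals = res$proposals,
       accepted = res$accepted, trace = res$trace)
}

#' Covariance-matched permutation test (CMPT) for rotational dynamics
#'
#' Tests whether the rotational structure found by [jpca()] depends uniquely
#' on the neuron-to-condition assignment. Each repetition randomly reassigns
#' conditions within every neuron, greedily swaps condition pairs until the
#' neuron-by-neuron covariance matches the observed data to `similarity`,
#' and recomputes the jPCA rotational goodness-of-fit ratio (RGR). The
#' p-value is the fraction of repetitions whose null RGR reaches the observed
#' RGR; the effect size is
#' `(RGR_observed - mean(RGR_permuted)) / sd(RGR_permuted)`.
#'
#' @param pop A [population_activity()].
#' @param n_reps Number of permutation repetitions.
#' @param similarity Covariance-similarity threshold (0.95; 0.99 = strict).
#' @param d Retained principal components for jPCA.
#' @param window Analysis window; defaults to the population's
#'   `neural_movement_onset`..`movement_end` events (the observed window is
#'   reused for every repetition).
#' @param planes Plane set for the RGR statistic (default `"all"`, the full
#'   6-PC fit spanning all three planes).
#' @param max_swaps Proposal cap per repetition.
#' @param keep_assignments Store per-repetition assignment matrices (needed
#'   by [unshuffle_check()]).
#' @param preprocess,soften Covariance-matching and jPCA preprocessing
#'   options (see [match_covariance()] and [jpca()]).
#' @param subtract_cc_mean Cross-condition mean subtraction for the jPCA
#'   stage (default `TRUE`, as in [jpca()]).
#' @param match_cc_mean Whether the matched covariance target also has the
#'   cross-condition mean removed (default `FALSE`; see
#'   [covariance_similarity()]).
#' @param seed Optional RNG seed.
#' @return Object of class `cmpt_result`: `observed_rgr`, `null_rgrs`,
#'   `p_value` (and `p_string`), `effect_size`, `similarity_achieved`,
#'   `swap_stats`, `n_failed`, `assignments`.
#' @export
cmpt <- function(pop, n_reps = 100, similarity = 0.95, d = 6, window = NULL,
                 planes = "all", max_swaps = NULL, keep_assignments = TRUE,
                 preprocess = TRUE, soften = 0.05, subtract_cc_mean = TRUE,
                 match_cc_mean = FALSE, seed = NULL) {
  stopifnot(inherits(pop, "population_activity"))
  if (n_reps < 1) stop("`n_reps` must be at least 1")
  if (similarity <= 0 || similarity > 1) stop("`similarity` must be in (0, 1]")
  if (is.null(window)) {
    ev <- pop$events
    window <- if (all(c("neural_movement_onset", "movement_end") %in% names(ev)))
      c(ev[["neural_movement_onset"]], ev[["movement_end"]])
    else range(pop$time_ms)
  }
  obs_fit <- jpca(pop, d = d, window = window, soften = soften,
                  subtract_cc_mean = subtract_cc_mean)
  observed_rgr <- rotation_metrics(obs_fit, planes = planes)$rgr
  dms <- dim(pop$rates)
  max_swaps <- max_swaps %||% (200 * dms[1] * dms[2])

  null_rgrs <- sims <- numeric(0)
  props <- accs <- numeric(0)
  assignments <- list()
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      pm <- permute_conditions(pop)
      m <- match_covariance(pop, pm$assignment, window = window,
                            threshold = similarity, max_swaps = max_swaps,
                            preprocess = preprocess, soften = soften,
                            subtract_cc_mean = match_cc_mean)
      if (!m$converged) {
        n_failed <- n_failed + 1L
        warning(sprintf("repetition %d discarded: similarity %.3f below threshold %.2f",
                        r, m$similarity, similarity))
        next
      }
      fit <- jpca(m$pop, d = d, window = window, soften = soften,
                  subtract_cc_mean = subtract_cc_mean)
      null_rgrs <- c(null_rgrs, rotation_metrics(fit, planes = planes)$rgr)
      sims <- c(sims, m$similarity)
      props <- c(props, m$proposals); accs <- c(accs, m$accepted)
      if (keep_assignments) assignments[[length(assignments) + 1L]] <- m$assignment
    }
  })
  if (!length(null_rgrs)) stop("all CMPT repetitions failed covariance matching: test invalid")
  summ <- cmpt_summary(observed_rgr, null_rgrs)
  structure(list(
    observed_rgr = observed_rgr, null_rgrs = null_rgrs,
    p_value = summ$p_value,
    p_string = summ$p_string,
    effect_size = summ$effect_size,
    similarity_achieved = sims,
    swap_stats = data.frame(proposals = props, accepted = accs),
    n_reps = n_reps, n_failed = n_failed, assignments = assignments,
    planes = planes, window = window, d = d, similarity = similarity
  ), class = "cmpt_result")
}

#' Permutation p-value and effect size from a null distribution
#'
#' The p-value is the fraction of null statistics that reach or exceed the
#' observed statistic (reported as `"< 1/n"` when none do); the effect size
#' is `(observed - mean(null)) / sd(null)`, analogous to Cohen's d.
#'
#' @param observed Observed statistic.
#' @param nulls Vector of permutation statistics.
#' @return List with `p_value`, `p_string`, `effect_size`.
#' @export
cmpt_summary <- function(observed, nulls) {
  n <- length(nulls)
  if (n < 2) stop("need at least 2 permutation statistics")
  exceed <- sum(nulls >= observed)
  list(p_value = exceed / n,
       p_string = if (exceed == 0) sprintf("< %g", 1 / n) else sprintf("%g", exceed / n),
       effect_size = (observed - mean(nulls)) / sd(nulls))
}

#' @export
print.cmpt_result <- function(x, ...) {
  cat(sprintf("CMPT: observed RGR = %.3f, %d/%d repetitions matched (similarity >= %.2f)\n",
              x$observed_rgr, length(x$null_rgrs), x$n_reps, x$similarity))
  cat(sprintf("  null RGR = %.3f +/- %.3f, p = %s, effect size = %.2f\n",
              mean(x$null_rgrs), sd(x$null_rgrs), x$p_string, x$effect_size))
  invisible(x)
}

#' Unshuffle control for the CMPT
#'
#' Checks that covariance matching did not merely restore the original
#' condition assignment: each repetition's assignment matrix has its rows
#' sorted so the condition most common in a row maps to that row's label
#' (most conservative comparison), the retained fraction of original
#' assignments is computed, and that fraction is correlated (Pearson) with
#' the repetition's null RGR.
#'
#' @param result A `cmpt_result` run with `keep_assignments = TRUE`.
#' @return List with `r`, `p`, `retained_fraction` per repetition; `r`/`p`
#'   are `NA` (flagged via `zero_variance`) when retained fractions are
#'   constant.
#' @export
unshuffle_check <- function(result) {
  stopifnot(inherits(result, "cmpt_result"))
  if (length(result$assignments) < 3) stop("need at least 3 repetitions with stored assignments")
  retained <- vapply(result$assignments, function(a)
    mean(sort_assignment_rows(a) == row(matrix(0, nrow(a), ncol(a)))), numeric(1))
  if (sd(retained) == 0 || sd(result$null_rgrs) == 0) {
    return(list(r = NA_real_, p = NA_real_, retained_fraction = retained,
                zero_variance = TRUE))
  }
  ct <- cor.test(retained, result$null_rgrs, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, retained_fraction = retained,
       zero_variance = FALSE)
}

# Reorder the rows of an assignment matrix so that condition k's
# most-frequent row sits at row k (greedy over conditions, ties to the
# first/highest count, each row used once).
sort_assignment_rows <- function(a) {
  nc <- nrow(a)
  counts <- vapply(seq_len(nc), function(k) rowSums(a == k), numeric(nc)) # rows x conds
  target <- integer(nc)   # target[k] = row placed at position k
  used <- rep(FALSE, nc)
  for (k in seq_len(nc)) {
    cand <- counts[, k]
    cand[used] <- -Inf
    pick <- which.max(cand)
    target[k] <- pick
    used[pick] <- TRUE
  }
  a[target, , drop = FALSE]
}

#' CMPT over subsampled neuron/condition grids
#'
#' Runs the covariance-matched permutation test on random subsets of a
#' population over a grid of neuron and condition counts. For every
#' repetition of every cell a fresh random subset is drawn; the observed RGR
#' is computed on that subset and compared with the RGR of one matched
#' permutation of it, so the p-value is the paired exceedance fraction and
#' the effect size compares the mean observed RGR with the null distribution.
#'
#' @param pop A [population_activity()].
#' @param neuron_counts,condition_counts Grids of subset sizes.
#' @param n_reps Repetitions per cell.
#' @param similarity,d,window,planes,max_swaps As in [cmpt()].
#' @param seed Optional RNG seed.
#' @return List of matrices `p_value` and `effect_size`
#'   (`length(neuron_counts)` x `length(condition_counts)`; cells with fewer
#'   than 2 conditions are `NA`, untestable).
#' @export
subset_grid <- function(pop, neuron_counts, condition_counts, n_reps = 100,
                        similarity = 0.95, d = 6, window = NULL,
                        planes = "all", max_swaps = NULL, preprocess = TRUE,
                        soften = 0.05, subtract_cc_mean = TRUE,
                        match_cc_mean = FALSE, seed = NULL) {
  dms <- dim(pop$rates)
  if (any(neuron_counts > dms[1]) || any(condition_counts > dms[2]))
    stop("requested subset sizes exceed the population")
  pmap <- emap <- matrix(NA_real_, length(neuron_counts), length(condition_counts),
                         dimnames = list(neuron_counts, condition_counts))
  with_seed(seed, {
    for (i in seq_along(neuron_counts)) for (j in seq_along(condition_counts)) {
      nn <- neuron_counts[i]; nc <- condition_counts[j]
      if (nc < 2 || nn < d) next
      obs_r <- null_r <- numeric(0)
      for (r in seq_len(n_reps)) {
        sub <- subset_population(pop, sample.int(dms[1], nn), sample.int(dms[2], nc))
        o <- tryCatch(rotation_metrics(jpca(sub, d = d, window = window,
                                            soften = soften,
                                            subtract_cc_mean = subtract_cc_mean),
                                       planes = planes)$rgr,
                      error = function(e) NA_real_)
        if (!is.finite(o)) next
        pm <- permute_conditions(sub)
        m <- match_covariance(sub, pm$assignment, window = window,
                              threshold = similarity, max_swaps = max_swaps,
                              preprocess = preprocess, soften = soften,
                              subtract_cc_mean = match_cc_mean)
        if (!m$converged) next
        nl <- tryCatch(rotation_metrics(jpca(m$pop, d = d, window = window,
                                             soften = soften,
                                             subtract_cc_mean = subtract_cc_mean),
                                        planes = planes)$rgr,
                       error = function(e) NA_real_)
        if (!is.finite(nl)) next
        obs_r <- c(obs_r, o); null_r <- c(null_r, nl)
      }
      if (length(null_r) >= 2) {
        pmap[i, j] <- mean(null_r >= obs_r)
        emap[i, j] <- (mean(obs_r) - mean(null_r)) / sd(null_r)
      }
    }
  })
  list(p_value = pmap, effect_size = emap)
}
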