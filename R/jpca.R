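#' jPCA: rotational dynamics in neural population activity
#'
#' Reduces a population to its top `d` principal components and fits linear
#' dynamics `X_dot = M X_red` by least squares, both unconstrained and
#' constrained to an exactly skew-symmetric `M_skew` (pure rotation).
#' Rotation planes are the eigenplanes of `M_skew`, ordered by rotation
#' frequency and oriented so the net rotation is anticlockwise.
#'
#' Preprocessing: each neuron is normalized by its response range over the
#' analysis window plus a softening constant, then mean-centered; PCA is run
#' on the neurons x (conditions*time) matrix and the top `d` scores retained.
#' The temporal derivative is the difference of adjacent time points within
#' each condition (never across condition boundaries), divided by `dt`.
#'
#' @param pop A [population_activity()].
#' @param d Number of retained principal components (even, >= 2; default 6).
#' @param window Analysis window `c(start, end)` in ms. Defaults to
#'   `neural_movement_onset`..`movement_end` events when present, otherwise
#'   the full time axis.
#' @param soften Softening constant added to each neuron's range before
#'   normalization (0.05 suits unit-scale simulations; use ~5 for spike rates
#'   in Hz). `Inf` disables normalization.
#' @param subtract_cc_mean If `TRUE` (default, the reference-toolbox
#'   convention), subtract each neuron's cross-condition mean time course
#'   from every condition before PCA, so that condition-independent activity
#'   does not enter the fitted space or the variance denominators.
#' @return Object of class `jpca_result` with elements `X_red`, `X_state`,
#'   `X_dot`, `M`, `M_skew`, `planes` (list of d x 2 orthonormal bases),
#'   `plane_variance` (fraction of total data variance per plane),
#'   `eig_freq_hz` (rotation frequency per plane), `metrics` (RGR for plane
#'   sets 1, 1:3 and all, plus circularity), and bookkeeping fields.
#' @references The method follows the jPCA approach of Churchland et al.
#'   (2012), Neural population dynamics during reaching, Nature 487:51-56.
#' @export
jpca <- function(pop, d = 6, window = NULL, soften = 0.05,
                 subtract_cc_mean = TRUE) {
  stopifnot(inherits(pop, "population_activity"))
  if (d %% 2 != 0 || d < 2) stop("`d` must be even and >= 2")
  dims <- dim(pop$rates)
  if (dims[1] < d) stop("fewer neurons than requested dimensions `d`")
  if (dims[2] < 2) stop("jPCA needs at least 2 conditions")
  if (is.null(window)) {
    ev <- pop$events
    window <- if (all(c("neural_movement_onset", "movement_end") %in% names(ev)))
      c(ev[["neural_movement_onset"]], ev[["movement_end"]])
    else range(pop$time_ms)
  }
  idx <- window_index(pop, window)
  if (length(idx) < 3) stop("analysis window must contain at least 3 time samples")
  X <- jpca_preprocess(pop, window, soften, subtract_cc_mean)
  nc <- dims[2]; nt <- length(idx)

  sv <- svd(t(X), nu = d, nv = d)               # samples x neurons
  total_var <- sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d)  # (c*t) x d
  X_red <- t(scores)                            # d x (c*t)
  pc_var <- sv$d[seq_len(d)]^2 / total_var

  # temporal derivative within condition blocks
  keep <- unlist(lapply(seq_len(nc), function(c) (c - 1L) * nt + seq_len(nt - 1L)))
  nxt <- keep + 1L
  X_state <- X_red[, keep, drop = FALSE]
  X_dot <- (X_red[, nxt, drop = FALSE] - X_state) / pop$dt

  fit <- fit_dynamics(X_state, X_dot)
  pl <- extract_planes(fit$M_skew, X_state, X_dot)

  # variance captured by each plane, relative to total data variance
  plane_variance <- vapply(pl$planes, function(Q)
    sum((t(X_red) %*% Q)^2) / total_var, numeric(1))

  res <- structure(list(
    X_red = X_red, X_state = X_state, X_dot = X_dot,
    M = fit$M, M_skew = fit$M_skew,
    planes = pl$planes, eig_freq_hz = pl$freq_hz,
    plane_variance = plane_variance, pc_variance = pc_var,
    loadings = sv$v, d = d, dt = pop$dt, window = window,
    n_conditions = nc, n_time = nt
  ), class = "jpca_result")
  res$metrics <- list(
    variance_plane1 = plane_variance[1],
    variance_planes12 = sum(plane_variance[seq_len(min(2, length(plane_variance)))]),
    rgr_plane1 = rotation_metrics(res, planes = 1)$rgr,
    rgr_all = rotation_metrics(res, planes = "all")$rgr,
    circularity = rotation_metrics(res, planes = "all")$circularity
  )
  res
}

#' @export
print.jpca_result <- function(x, ...) {
  cat(sprintf("jPCA fit: d = %d, %d conditions x %d samples (window %g..%g ms)\n",
              x$d, x$n_conditions, x$n_time, x$window[1], x$window[2]))
  cat(sprintf("  variance: plane 1 = %.1f%%, planes 1-2 = %.1f%%\n",
              100 * x$metrics$variance_plane1, 100 * x$metrics$variance_planes12))
  cat(sprintf("  RGR (all planes) = %.3f, circularity = %.3f\n",
              x$metrics$rgr_all, x$metrics$circularity))
  invisible(x)
}

# Normalized, centered (and optionally cross-condition-mean-subtracted)
# neurons x (conditions*time) matrix: the exact input to the PCA stage. The
# per-neuron range, per-neuron mean and cross-condition mean trace are all
# invariant under within-neuron condition permutations, which is what makes
# covariance matching on this matrix well-defined for the CMPT.
jpca_preprocess <- function(pop, window = NULL, soften = 0.05,
                            subtract_cc_mean = TRUE) {
  X <- flatten_rates(pop, window)               # n x (c*t), condition blocks
  nc <- dim(pop$rates)[2]
  nt <- ncol(X) / nc
  if (is.finite(soften)) {
    rng <- apply(X, 1, function(r) diff(range(r)))
    X <- X / (rng + soften)
  }
  X <- X - rowMeans(X)
  if (subtract_cc_mean) {
    for (k in seq_len(nt)) {
      cols <- (seq_len(nc) - 1L) * nt + k
      X[, cols] <- X[, cols] - rowMeans(X[, cols, drop = FALSE])
    }
  }
  X
}

#' Least-squares linear and skew-symmetric dynamics fits
#'
#' Finds `M` minimizing `||X_dot - M X||_F` over all d x d matrices (ordinary
#' least squares) and `M_skew` minimizing the same objective over exactly
#' skew-symmetric matrices. The skew fit is solved in closed form: the
#' stationarity condition is the Sylvester equation
#' `S A + A S = B - B^T` with `A = X X^T`, `B = X_dot X^T`, solved entrywise
#' in the eigenbasis of the symmetric matrix `A`.
#'
#' @param X State matrix, d x m.
#' @param X_dot Derivative matrix, d x m.
#' @return List with `M` and `M_skew` (the latter exactly skew-symmetric).
#' @export
fit_dynamics <- function(X, X_dot) {
  d <- nrow(X)
  if (ncol(X) < d + 1) stop("need at least d + 1 samples to fit dynamics")
  A <- X %*% t(X)
  B <- X_dot %*% t(X)
  qa <- qr(A)
  if (qa$rank < d) stop("rank-deficient state matrix: dynamics fit is singular")
  M <- t(solve(qa, t(B)))           # solves M A = B
  eg <- eigen(A, symmetric = TRUE)
  Ct <- t(eg$vectors) %*% (B - t(B)) %*% eg$vectors
  St <- Ct / outer(eg$values, eg$values, `+`)
  S <- eg$vectors %*% St %*% t(eg$vectors)
  S <- (S - t(S)) / 2               # exact skew symmetry against round-off
  list(M = M, M_skew = S)
}

#' Extract ordered, anticlockwise-oriented rotation planes
#'
#' The eigenvalues of a real skew-symmetric matrix are purely imaginary
#' conjugate pairs `+/- i*omega`; each pair spans a 2-D plane in which the
#' dynamics are a pure rotation at angular velocity `omega`. Planes are
#' ordered by `|omega|` (fastest first; ties keep first occurrence) and each
#' basis is flipped, when trajectories are supplied, so that the mean signed
#' angular velocity of the projected data is positive (anticlockwise).
#'
#' @param M_skew Skew-symmetric d x d matrix (d even).
#' @param X,X_dot Optional state/derivative matrices used for orientation.
#' @return List with `planes` (list of d x 2 orthonormal bases),
#'   `omega` (rad per time unit) and `freq_hz` (assuming time in ms).
#' @export
extract_planes <- function(M_skew, X = NULL, X_dot = NULL) {
  d <- nrow(M_skew)
  if (d %% 2 != 0) stop("skew matrix must have even dimension")
  ev <- eigen(M_skew)
  pos <- which(Im(ev$values) > 0)
  zero <- setdiff(seq_len(d), c(pos, which(Im(ev$values) < 0)))
  if (length(zero) >= 2) {
    warning("zero eigenvalues: plane(s) with no rotation retained")
    pos <- c(pos, zero[seq(1, length(zero) - 1, by = 2)])
  }
  ord <- order(abs(Im(ev$values[pos])), decreasing = TRUE)
  pos <- pos[ord]
  planes <- lapply(pos, function(k) {
    v <- ev$vectors[, k]
    Q <- qr.Q(qr(cbind(Re(v), Im(v))))
    if (!is.null(X) && !is.null(X_dot)) {
      p <- t(Q) %*% X; pd <- t(Q) %*% X_dot
      r2 <- colSums(p^2)
      ok <- r2 > .Machine$double.eps
      omega_signed <- mean((p[1, ok] * pd[2, ok] - p[2, ok] * pd[1, ok]) / r2[ok])
      if (is.finite(omega_signed) && omega_signed < 0) Q[, 2] <- -Q[, 2]
    }
    Q
  })
  omega <- abs(Im(ev$values[pos]))
  list(planes = planes, omega = omega, freq_hz = omega / (2 * pi) * 1000)
}

#' Rotation metrics: variance per plane, RGR, circularity
#'
#' The rotational goodness-of-fit ratio (RGR) is the R-squared of the
#' skew-symmetric dynamics fit divided by the R-squared of the unconstrained
#' fit, computed over a chosen set of planes (residuals and derivative
#' projected onto the planes' span; with d = 6 the "first three planes" and
#' "all planes" sets both span the full fitted space). Circularity is the
#' mean over conditions and time points of the acute angle between the state
#' and its derivative (the angle between the lines they span, from the
#' magnitude of their normalized dot product), divided by `pi/2`; 1 means
#' purely circular flow, 0 purely radial.
#'
#' @param res A `jpca_result`.
#' @param planes `"all"`, `"first"`, or an integer vector of plane indices.
#' @return List with `variance` (per selected plane), `rgr`, `r2_skew`,
#'   `r2_unconstrained` and `circularity` (measured in the span of the
#'   selected planes).
#' @export
rotation_metrics <- function(res, planes = "all") {
  stopifnot(inherits(res, "jpca_result"))
  sel <- if (identical(planes, "all")) seq_along(res$planes)
         else if (identical(planes, "first")) 1L
         else as.integer(planes)
  Q <- do.call(cbind, res$planes[sel])
  proj <- function(m) t(Q) %*% m
  Xd <- proj(res$X_dot)
  sst <- sum((Xd - rowMeans(Xd))^2)
  if (sst <= 0) stop("degenerate derivative: undefined RGR")
  r2 <- function(M) 1 - sum((Xd - proj(M %*% res$X_state))^2) / sst
  r2m <- r2(res$M); r2s <- r2(res$M_skew)
  if (abs(r2m) < 1e-12) stop("unconstrained fit explains no variance: undefined RGR")
  ang <- angle_between(proj(res$X_state), proj(res$X_dot), acute = TRUE)
  circ <- mean(ang) / (pi / 2)
  list(variance = res$plane_variance[sel], rgr = r2s / r2m,
       r2_skew = r2s, r2_unconstrained = r2m, circularity = circ)
}
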