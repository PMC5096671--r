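#' @useDynLib rotdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats prcomp cor cor.test sd rnorm runif optim optimize ks.test
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Number of sign changes of a numeric trace, ignoring excursions smaller
# than `tol` times the trace's max absolute value.
zero_crossings <- function(x, tol = 1e-8) {
  s <- sign(x)
  s[abs(x) < tol * max(abs(x))] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Angle between corresponding columns of two d x m matrices; `acute = TRUE`
# returns the angle between the spanned lines (in [0, pi/2]).
angle_between <- function(a, b, acute = FALSE) {
  na <- sqrt(colSums(a^2))
  nb <- sqrt(colSums(b^2))
  ok <- na > 0 & nb > 0
  cosang <- pmin(1, pmax(-1, colSums(a * b)[ok] / (na[ok] * nb[ok])))
  if (acute) cosang <- abs(cosang)
  acos(cosang)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
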