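#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `code`, and
#' restores the previous state on exit. With `seed = NULL` the code runs under
#' the ambient RNG stream. All stochastic functions in this package route
#' their randomness through this helper so that seeded runs are bit-identical
#' and never disturb the session RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# row variances without a matrixStats dependency
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least two columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# lognormal noise factors with unit mean and the requested coefficient of
# variation; cv = 0 returns exact ones
lognormal_noise <- function(n, cv) {
  stopifnot(cv >= 0)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
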