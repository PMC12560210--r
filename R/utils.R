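## Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with a private RNG state so library calls never disturb
## the caller's random stream. All exported stochastic operations route
## their draws through this.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a stream-specific child seed (kept well below 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(stream) %% 1000L)
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
}

## Complex Gaussian noise, sd per real/imaginary component.
rcnorm <- function(n, sd = 1) complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))

## Population standard deviation (divides by n, not n-1).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## A^H B for complex matrices.
cdot <- function(a, b) crossprod(Conj(a), b)

is_roi_arg_ok <- function(roi, n_vox) is.logical(roi) && length(roi) == n_vox
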