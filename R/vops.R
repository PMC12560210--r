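## Synthetic virtual observation points (VOPs): Hermitian positive
## semi-definite channel x channel matrices whose worst case over the set
## upper-bounds relative peak local SAR for a weight vector b. Stand-ins for
## VOPs compressed from EM body-model simulations (which are out of reach on
## the desk); labelled synthetic throughout.

#' Generate a synthetic VOP set
#'
#' Each matrix is `Q = sum_k e_k e_k^H` over `rank` random complex vectors
#' (Hermitian PSD by construction), rescaled so that the median of `b^H Q b`
#' over unit-norm random weight vectors equals one; SAR values are therefore
#' in relative units.
#'
#' @param n_channels number of transmit channels.
#' @param n_vops number of matrices (>= 1).
#' @param rank number of rank-one terms per matrix (>= 1).
#' @param seed integer seed.
#' @return a `ptx_vops`: list with `matrices` (list of complex
#'   `n_channels x n_channels`), `count`, `n_channels`.
#' @export
generate_vops <- function(n_channels, n_vops, rank = 3L, seed = 1L) {
  if (n_vops < 1) stop("n_vops must be at least 1")
  if (rank < 1) stop("rank must be at least 1")
  n_channels <- as.integer(n_channels)
  mats <- with_seed(seed, {
    ## fixed probe set for the median normalization
    bprobe <- matrix(rcnorm(n_channels * 500L), nrow = n_channels)
    bprobe <- sweep(bprobe, 2, sqrt(colSums(Mod(bprobe)^2)), `/`)
    lapply(seq_len(n_vops), function(v) {
      E <- matrix(rcnorm(n_channels * rank), nrow = n_channels)
      Q <- E %*% Conj(t(E))
      Q <- (Q + Conj(t(Q))) / 2  # exact Hermitian symmetry
      vals <- Re(colSums(Conj(bprobe) * (Q %*% bprobe)))
      Q / stats::median(vals)
    })
  })
  structure(list(matrices = mats, count = as.integer(n_vops),
                 n_channels = n_channels),
            class = "ptx_vops")
}

#' Check the VOP invariants (Hermitian symmetry and PSD)
#'
#' @param vops a `ptx_vops`.
#' @param herm_tol relative Hermitian-asymmetry tolerance.
#' @param eig_tol lower bound allowed for the smallest eigenvalue.
#' @return `TRUE` invisibly; errors describing the first violation otherwise.
#' @export
validate_vops <- function(vops, herm_tol = 1e-12, eig_tol = -1e-10) {
  for (v in seq_along(vops$matrices)) {
    Q <- vops$matrices[[v]]
    asym <- max(Mod(Q - Conj(t(Q))))
    if (asym > herm_tol * max(Mod(Q)))
      stop(sprintf("VOP %d is not Hermitian (asymmetry %g)", v, asym))
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < eig_tol)
      stop(sprintf("VOP %d is not PSD (min eigenvalue %g)", v, min(ev)))
  }
  invisible(TRUE)
}

#' @export
print.ptx_vops <- function(x, ...) {
  cat(sprintf("<ptx_vops> %d synthetic VOPs for %d channels (relative units)\n",
              x$count, x$n_channels))
  invisible(x)
}
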