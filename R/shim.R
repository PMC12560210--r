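## Static pTx shimming: one complex weight per transmit channel (phase-only,
## or magnitude and phase), chosen by multi-start quasi-Newton minimization
## of a cost trading the coefficient of variation (CV) of the superposed
## |B1+| in the ROI against transmit efficiency eta.

shim_weights_vector <- function(weights, n_channels) {
  w <- if (inherits(weights, "ptx_shim")) weights$weights else as.complex(weights)
  if (length(w) != n_channels) stop("one weight per channel is required")
  w
}

eval_voxels <- function(b1, roi) {
  roi <- roi %||% as.vector(b1$phantom$roi_mask)
  if (!is_roi_arg_ok(as.vector(roi), nrow(b1$maps)))
    stop("roi must be a logical mask over all voxels")
  keep <- as.vector(roi)
  if (!is.null(b1$validity_mask)) keep <- keep & b1$validity_mask
  if (!any(keep)) stop("ROI contains no valid voxels")
  keep
}

#' Coefficient of variation of the superposed field over the ROI
#'
#' Population standard deviation divided by mean of `|sum_ch B_ch b_ch|`
#' over the evaluated (ROI and valid) voxels: the flip-angle homogeneity
#' metric. Invariant under global phase and positive rescaling of the
#' weights.
#'
#' @param b1 a `ptx_b1set`.
#' @param roi logical mask over voxels, or `NULL` for the phantom ROI.
#' @param weights complex weight vector or `ptx_shim`.
#' @return scalar CV (>= 0).
#' @export
compute_cv <- function(b1, roi = NULL, weights) {
  keep <- eval_voxels(b1, roi)
  w <- shim_weights_vector(weights, b1$n_channels)
  m <- Mod(b1$maps[keep, , drop = FALSE] %*% w)
  mu <- mean(m)
  if (mu <= .Machine$double.eps * max(m, 1))
    stop("all-destructive shim: mean superposed field is zero, CV undefined")
  sd_pop(m) / mu
}

#' Transmit efficiency of a shim over the ROI
#'
#' ROI mean of the constructive-interference fraction
#' `|sum_ch B_ch b_ch| / sum_ch |B_ch b_ch|` per voxel; equals 1 iff all
#' channel fields are in phase at every evaluated voxel.
#'
#' @inheritParams compute_cv
#' @return scalar efficiency in [0, 1].
#' @export
compute_efficiency <- function(b1, roi = NULL, weights) {
  keep <- eval_voxels(b1, roi)
  w <- shim_weights_vector(weights, b1$n_channels)
  B <- b1$maps[keep, , drop = FALSE]
  num <- Mod(B %*% w)
  den <- Mod(B) %*% Mod(w)
  ok <- den > 0
  if (!all(ok))
    warning(sprintf("%d voxels with zero channel-magnitude sum excluded", sum(!ok)))
  if (!any(ok)) stop("no voxels with nonzero channel-magnitude sum")
  mean(num[ok] / den[ok])
}

## cost = cv - cost_weight * eta and its analytic gradient in the
## unconstrained parametrization (phases; plus log-magnitudes in
## mag_phase mode). B: design matrix restricted to active channels.
shim_cost_fn <- function(B, mode, cost_weight) {
  n_act <- ncol(B)
  absB <- Mod(B)
  eps <- 1e-300
  unpack <- function(par) {
    phi <- par[seq_len(n_act)]
    a <- if (mode == "mag_phase") exp(par[n_act + seq_len(n_act)]) else rep(1, n_act)
    a * exp(complex(imaginary = phi))
  }
  fn <- function(par) {
    w <- unpack(par)
    m <- Mod(B %*% w)
    mu <- mean(m)
    if (mu <= 0) return(1e6)
    cv <- sd_pop(m) / mu
    cost <- cv
    if (cost_weight != 0) {
      s <- absB %*% Mod(w)
      cost <- cost - cost_weight * mean(m / pmax(s, eps))
    }
    cost
  }
  gr <- function(par) {
    w <- unpack(par)
    f <- as.vector(B %*% w)
    m <- pmax(Mod(f), eps)
    mu <- mean(m)
    sig <- sd_pop(Mod(f))
    C <- sweep(B, 2, w, `*`)          # B_ich * w_ch
    u <- Conj(f) / m                   # unit conjugate phase per voxel
    dphi <- Re(C * (1i * u))           # dm/dphi (n x p), u recycled by column
    grad_from_dm <- function(dm) {
      dmu <- colMeans(dm)
      dsig <- (colMeans(dm * (m - mu))) / max(sig, eps)
      dsig / mu - sig * dmu / mu^2
    }
    g <- grad_from_dm(dphi)
    if (mode == "mag_phase") {
      dell <- Re(C * u)                # dm/dlog a
      g <- c(g, grad_from_dm(dell))
    }
    if (cost_weight != 0) {
      a <- Mod(w)
      s <- pmax(as.vector(absB %*% a), eps)
      geta_phi <- colMeans(dphi / s)
      g[seq_len(n_act)] <- g[seq_len(n_act)] - cost_weight * geta_phi
      if (mode == "mag_phase") {
        dell <- Re(C * u)
        ds <- sweep(absB, 2, a, `*`)   # ds/dlog a
        geta_l <- colMeans((dell * s - m * ds) / s^2)
        g[n_act + seq_len(n_act)] <- g[n_act + seq_len(n_act)] - cost_weight * geta_l
      }
    }
    g
  }
  list(fn = fn, gr = gr, unpack = unpack)
}

#' Optimize a static pTx shim over the ROI
#'
#' Minimizes `cv - cost_weight * eta` with a quasi-Newton (BFGS) local
#' search from `n_starts` pseudo-random starting phases with equal
#' amplitudes (the first start is the zero-phase shim). In `phase_only`
#' mode all active-channel magnitudes are held equal; `mag_phase`
#' additionally optimizes log-magnitudes. The returned weights are rescaled
#' to `power_norm = sum |b_ch|^2` and the reported metrics are recomputed
#' from them.
#'
#' @param b1 a `ptx_b1set` (>= 2 active channels).
#' @param roi logical voxel mask or `NULL` for the phantom ROI.
#' @param mode `"phase_only"` or `"mag_phase"`.
#' @param n_starts number of random restarts (default 100).
#' @param cost_weight weight of the efficiency term. Both terms are
#'   dimensionless and O(1); the default 1 balances homogeneity against
#'   constructive interference (a pure-CV optimization, `cost_weight = 0`,
#'   admits flat but destructive solutions that waste RF power and is only
#'   appropriate when CV minimization itself is the question).
#' @param seed integer seed for the starting phases.
#' @param power_norm total `sum |b|^2` of the returned weights (default 1).
#' @param init_weights optional complex vector used as an additional start
#'   (e.g. a phase-only solution to warm-start `mag_phase`).
#' @param maxit BFGS iteration cap per start.
#' @return list with `weights` (a `ptx_shim`), `metrics` (list `cv`,
#'   `efficiency`, `integrated_power`), and `starts` (per-start diagnostics).
#' @export
optimize_static_shim <- function(b1, roi = NULL,
                                 mode = c("phase_only", "mag_phase"),
                                 n_starts = 100L, cost_weight = 1,
                                 seed = 1L, power_norm = 1,
                                 init_weights = NULL, maxit = 200L) {
  mode <- match.arg(mode)
  act <- which(b1$active_mask)
  if (length(act) < 2L) stop("at least 2 active channels are required")
  keep <- eval_voxels(b1, roi)
  B <- b1$maps[keep, act, drop = FALSE]
  nz <- rowSums(Mod(B)) > 0
  B <- B[nz, , drop = FALSE]
  n_act <- length(act)

  cost <- shim_cost_fn(B, mode, cost_weight)
  npar <- if (mode == "mag_phase") 2L * n_act else n_act

  starts <- with_seed(seed, {
    s <- lapply(seq_len(n_starts), function(i) {
      phi <- if (i == 1L) rep(0, n_act) else stats::runif(n_act, 0, 2 * pi)
      c(phi, if (mode == "mag_phase") rep(0, n_act))
    })
    s
  })
  if (!is.null(init_weights)) {
    wi <- shim_weights_vector(init_weights, b1$n_channels)[act]
    a <- Mod(wi); a[a == 0] <- 1e-8
    starts <- c(starts, list(c(Arg(wi), if (mode == "mag_phase") log(a / sqrt(mean(a^2))))))
  }

  diag_tab <- data.frame(start = seq_along(starts), cost = NA_real_,
                         convergence = NA_integer_)
  best <- NULL
  for (i in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], cost$fn, cost$gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    ## keep whichever of start/final is better (BFGS never reports a worse
    ## value than it found, but guard against line-search failures)
    f0 <- cost$fn(starts[[i]])
    if (f0 < res$value) res <- list(par = starts[[i]], value = f0, convergence = 0L)
    diag_tab$cost[i] <- res$value
    diag_tab$convergence[i] <- res$convergence
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || all(is.na(diag_tab$cost)))
    stop(paste0("shim optimizer failed to converge on every start\n",
                paste(utils::capture.output(print(diag_tab)), collapse = "\n")))

  w_act <- cost$unpack(best$par)
  w <- rep(0 + 0i, b1$n_channels)
  w[act] <- w_act
  w <- w * sqrt(power_norm / sum(Mod(w)^2))
  shim <- structure(list(weights = w, mode = mode, power_norm = power_norm),
                    class = "ptx_shim")
  metrics <- list(cv = compute_cv(b1, roi, shim),
                  efficiency = compute_efficiency(b1, roi, shim),
                  integrated_power = integrated_rf_power(shim))
  list(weights = shim, metrics = metrics, starts = diag_tab)
}

#' @export
print.ptx_shim <- function(x, ...) {
  cat(sprintf("<ptx_shim> %s, %d channels, sum|b|^2 = %g\n",
              x$mode, length(x$weights), sum(Mod(x$weights)^2)))
  invisible(x)
}

#' The zero-phase (equal weight) shim for a map set
#'
#' @param b1 a `ptx_b1set`.
#' @param power_norm total `sum |b|^2` (default 1).
#' @return a `ptx_shim` with equal real weights on active channels.
#' @export
zero_phase_shim <- function(b1, power_norm = 1) {
  w <- as.complex(b1$active_mask)
  w <- w * sqrt(power_norm / sum(Mod(w)^2))
  structure(list(weights = w, mode = "phase_only", power_norm = power_norm),
            class = "ptx_shim")
}
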