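## kT-point pulse design in the small-tip-angle approximation: timing under
## the ~1 ms pulse budget, excitation system matrix, regularized
## magnitude-least-squares solve (variable exchange / phase adoption),
## interleaved greedy k-space placement plus local refinement, and the
## beta sweep generating L-curves.

#' Subpulse duration under the ~1 ms pulse budget
#'
#' The RF-on plus blip time is fixed at `on_plus_blip_budget_us` with a
#' fixed blip duration between subpulses, so the individual subpulse
#' duration decreases with the number of kT-points:
#' `round((budget - (n_kt - 1) * blip_us) / n_kt)` microseconds.
#' The single-subpulse (static shim) case uses a 1000 us pulse.
#'
#' @param n_kt number of kT-points (>= 1).
#' @param blip_us gradient blip duration in us (default 80).
#' @param on_plus_blip_budget_us total RF-on plus blip budget in us.
#' @return integer subpulse duration in us.
#' @export
build_timing <- function(n_kt, blip_us = 80L, on_plus_blip_budget_us = 920L) {
  if (n_kt < 1) stop("n_kt must be at least 1")
  if (n_kt == 1L) return(1000L)
  avail <- on_plus_blip_budget_us - (n_kt - 1) * blip_us
  if (avail <= 0) stop("pulse budget leaves no RF-on time after blips")
  tau <- as.integer(round(avail / n_kt))
  if (tau <= 0) stop("non-positive subpulse duration")
  tau
}

#' Build the small-tip excitation system matrix
#'
#' `A[i; ch, j] = deg_scale * (tau_j / 1 ms) * B_ch(r_i) * exp(i k_j . r_i)`
#' so that `|A b|` is the predicted flip angle in degrees. Columns are
#' ordered subpulse-major (channel fastest), restricted to active channels.
#' Off-resonance is neglected (the ~1 ms total duration keeps its influence
#' small).
#'
#' @param b1 a `ptx_b1set`.
#' @param roi logical voxel mask or `NULL` for the phantom ROI (intersected
#'   with the validity mask when present).
#' @param k_locations `n_kt x 3` matrix of excitation k-space locations in
#'   rad/m (final row must be the origin for a fully refocused pulse).
#' @param subpulse_us subpulse duration(s) in us (scalar or length `n_kt`).
#' @param deg_scale degrees of flip per unit relative field per unit weight
#'   per ms (the single unit-conversion scalar; default 1).
#' @param k_max optional per-axis |k| bound in rad/m; exceeding it errors.
#' @param voxels optional integer vector of voxel indices to use instead of
#'   the mask (e.g. a design subsample).
#' @return a `ptx_sysmat`: list with `A`, `coords`, `voxels`, `channels`,
#'   `n_kt`, `k_locations`, `subpulse_us`, `deg_scale`, `n_channels`.
#' @export
build_system_matrix <- function(b1, roi = NULL, k_locations, subpulse_us,
                                deg_scale = 1, k_max = NULL, voxels = NULL) {
  k_locations <- matrix(k_locations, ncol = 3)
  n_kt <- nrow(k_locations)
  if (!is.null(k_max) && any(abs(k_locations) > k_max + 1e-12))
    stop(sprintf("k location beyond configured k_max = %g rad/m", k_max))
  if (length(subpulse_us) == 1L) subpulse_us <- rep(subpulse_us, n_kt)
  if (length(subpulse_us) != n_kt) stop("one subpulse duration per kT-point required")
  if (is.null(voxels)) voxels <- which(eval_voxels(b1, roi))
  if (length(voxels) == 0L) stop("empty ROI")
  coords <- phantom_coords(b1$phantom)[voxels, , drop = FALSE]
  act <- which(b1$active_mask)
  B <- b1$maps[voxels, act, drop = FALSE]
  A <- matrix(0 + 0i, nrow = length(voxels), ncol = length(act) * n_kt)
  for (j in seq_len(n_kt)) {
    ph <- exp(complex(imaginary = coords %*% k_locations[j, ]))
    A[, (j - 1L) * length(act) + seq_along(act)] <-
      (deg_scale * subpulse_us[j] / 1000) * B * as.vector(ph)
  }
  structure(list(A = A, coords = coords, voxels = voxels, channels = act,
                 n_kt = n_kt, k_locations = k_locations,
                 subpulse_us = subpulse_us, deg_scale = deg_scale,
                 n_channels = b1$n_channels),
            class = "ptx_sysmat")
}

sysmat_matrix <- function(A) if (inherits(A, "ptx_sysmat")) A$A else A

## Objective of the regularized magnitude least-squares problem at fixed
## target phase theta.
mls_objective <- function(Ab, md, theta, b, beta) {
  0.5 * sum(Mod(md * exp(complex(imaginary = theta)) - Ab)^2) +
    0.5 * beta * sum(Mod(b)^2)
}

#' Solve for kT-point weights by regularized magnitude least squares
#'
#' Variable-exchange (phase adoption) solve of
#' `min_b 1/2 || m_d exp(i theta) - A b ||^2 + beta/2 ||b||^2`
#' with `theta` updated to the phase of `A b` after each Tikhonov solve.
#' The objective is monotone non-increasing across iterations.
#'
#' @param A a `ptx_sysmat` or complex matrix.
#' @param target_fa_deg desired flip angle magnitude (uniform target).
#' @param beta Tikhonov regularization parameter (>= 0).
#' @param theta_init initial target phase per row; `NULL` uses the phase of
#'   the equal-weight (zero-phase shim) field.
#' @param max_iter maximum variable-exchange iterations.
#' @param tol relative weight-change convergence tolerance.
#' @param gram optional precomputed `A^H A`.
#' @return list with `weights` (complex vector), `theta`, `objective`,
#'   `residual` (data term only), `trace` (objective per iteration),
#'   `iterations`, `converged`.
#' @export
solve_weights <- function(A, target_fa_deg = 10, beta, theta_init = NULL,
                          max_iter = 50L, tol = 1e-9, gram = NULL) {
  Am <- sysmat_matrix(A)
  if (beta < 0) stop("beta must be non-negative")
  md <- rep(target_fa_deg, nrow(Am))
  G <- gram %||% cdot(Am, Am)
  p <- ncol(Am)
  theta <- theta_init %||% Arg(Am %*% rep(1 + 0i, p))
  theta <- as.vector(theta)

  ridge <- 0
  solve_once <- function(rhs) {
    M <- G
    diag(M) <- diag(M) + beta + ridge
    tryCatch(solve(M, rhs), error = function(e) {
      if (beta + ridge == 0) {
        ridge <<- 1e-10 * Re(sum(diag(G))) / p
        warning("singular normal equations at beta = 0; ridge fallback applied")
        M <- G; diag(M) <- diag(M) + ridge
        solve(M, rhs)
      } else stop(e)
    })
  }

  b <- rep(0 + 0i, p)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    y <- md * exp(complex(imaginary = theta))
    b_new <- as.vector(solve_once(cdot(Am, y)))
    Ab <- as.vector(Am %*% b_new)
    obj <- mls_objective(Ab, md, theta, b_new, beta)
    ## phase adoption (never increases the objective)
    nz <- Mod(Ab) > 0
    theta[nz] <- Arg(Ab)[nz]
    trace <- c(trace, mls_objective(Ab, md, theta, b_new, beta))
    rel <- sqrt(sum(Mod(b_new - b)^2)) / max(sqrt(sum(Mod(b_new)^2)), 1e-300)
    b <- b_new
    if (rel < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  y <- md * exp(complex(imaginary = theta))
  Ab <- as.vector(Am %*% b)
  list(weights = b, theta = theta,
       objective = mls_objective(Ab, md, theta, b, beta),
       residual = 0.5 * sum(Mod(y - Ab)^2),
       trace = trace, iterations = it, converged = converged)
}

#' Default symmetric Cartesian candidate grid for kT-point placement
#'
#' Spans `[-k_max, k_max]` per axis with `n_per_axis` points, where
#' `k_max = pi / (2 * extent)` per axis and `extent` is the ROI
#' bounding-box extent.
#'
#' @param coords ROI voxel coordinates (metres), `n x 3`.
#' @param n_per_axis grid points per axis (default 7).
#' @return list with `k` (candidate matrix, rows ordered by increasing
#'   `||k||` so greedy ties resolve toward low k) and `spacing` per axis.
#' @export
candidate_k_grid <- function(coords, n_per_axis = 7L) {
  ext <- apply(coords, 2, function(x) max(x) - min(x))
  ext[ext <= 0] <- max(ext)
  kmax <- pi / (2 * ext)
  axes <- lapply(1:3, function(d) seq(-kmax[d], kmax[d], length.out = n_per_axis))
  k <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(k) <- NULL
  k <- k[order(rowSums(k^2)), , drop = FALSE]
  list(k = k, spacing = 2 * kmax / (n_per_axis - 1), k_max = kmax)
}

## Build the per-subpulse phase factors and full A from a base block.
kt_make_A <- function(base, coords, kmat) {
  n_kt <- nrow(kmat)
  na <- ncol(base)
  A <- matrix(0 + 0i, nrow = nrow(base), ncol = na * n_kt)
  for (j in seq_len(n_kt)) {
    ph <- exp(complex(imaginary = coords %*% kmat[j, ]))
    A[, (j - 1L) * na + seq_len(na)] <- base * as.vector(ph)
  }
  A
}

#' Design a kT-point pulse
#'
#' Interleaved greedy placement and local refinement: starting from the
#' k-space origin, candidate locations are added one at a time (each scored
#' by its optimal Tikhonov weights at the current target phase), then the
#' non-origin locations are refined by coordinate search with weight
#' re-solves. The final subpulse is always at the k-space origin. With a
#' power target set, the regularization parameter is re-adapted every 50
#' weight re-solves. The best of `n_starts` target-phase initializations is
#' retained; everything is deterministic for a fixed seed.
#'
#' @param b1 a `ptx_b1set`.
#' @param roi logical voxel mask or `NULL` for the phantom ROI.
#' @param n_kt number of kT-points (>= 1; 1 reduces to a magnitude+phase
#'   static shim under the same objective).
#' @param beta regularization parameter.
#' @param n_starts number of pseudo-random target-phase starts (the first is
#'   the zero-phase-shim field phase).
#' @param candidate_grid optional list as from [candidate_k_grid()].
#' @param seed integer seed.
#' @param n_design_voxels ROI voxels (seeded subsample) used in the design;
#'   metrics are always recomputed over the full valid ROI.
#' @param deg_scale unit-conversion scalar (degrees per unit field per ms).
#' @param target_fa_deg nominal flip angle (default 10).
#' @param power_target optional integrated-power target for the adaptive
#'   beta update.
#' @param refine_sweeps local-refinement coordinate sweeps (0 disables).
#' @param blip_us,budget_us timing parameters, see [build_timing()].
#' @param subpulse_us optional override of the subpulse duration (us); by
#'   default taken from [build_timing()].
#' @param warm_start optional `ptx_ktpulse` whose k-locations (and target
#'   phase) seed the design.
#' @return list with `pulse` (a `ptx_ktpulse`), `metrics` (`cv`,
#'   `integrated_power`, `objective`, `fa_mean_deg` over the full valid
#'   ROI), and `fit` (design internals: theta, beta used, design voxels).
#' @export
design_kt_pulse <- function(b1, roi = NULL, n_kt, beta, n_starts = 4L,
                            candidate_grid = NULL, seed = 1L,
                            n_design_voxels = 2500L, deg_scale = 1,
                            target_fa_deg = 10, power_target = NULL,
                            refine_sweeps = 3L, blip_us = 80L,
                            budget_us = 920L, subpulse_us = NULL,
                            warm_start = NULL) {
  if (n_kt < 1) stop("n_kt must be at least 1")
  tau <- subpulse_us %||% build_timing(n_kt, blip_us, budget_us)
  act <- which(b1$active_mask)
  keep_full <- which(eval_voxels(b1, roi))
  design_vox <- if (length(keep_full) > n_design_voxels) {
    sort(with_seed(child_seed(seed, 1L), sample(keep_full, n_design_voxels)))
  } else keep_full
  coords <- phantom_coords(b1$phantom)[design_vox, , drop = FALSE]
  base <- (deg_scale * tau / 1000) * b1$maps[design_vox, act, drop = FALSE]
  md <- rep(target_fa_deg, length(design_vox))

  grid <- candidate_grid %||% candidate_k_grid(coords)
  if (nrow(grid$k) == 0L) stop("candidate grid is empty")
  if (n_kt > nrow(grid$k) + 1L) stop("n_kt exceeds the candidate grid size")

  n_solves <- 0L
  adapt_beta <- function(beta_cur, b, tau_all) {
    if (is.null(power_target)) return(beta_cur)
    P <- sum(Mod(b)^2 * rep(tau_all * 1e-6, each = length(act)))
    beta_cur * sqrt(max(P, 1e-300) / power_target)
  }
  ve <- function(kmat, theta, beta_cur, iters = 30L) {
    A <- kt_make_A(base, coords, kmat)
    n_solves <<- n_solves + 1L
    solve_weights(A, target_fa_deg, beta_cur, theta_init = theta,
                  max_iter = iters)
  }

  ## --- initial k set and target phase -------------------------------------
  origin <- c(0, 0, 0)
  if (!is.null(warm_start)) {
    kw <- warm_start$k_locations
    kmat <- rbind(kw[-nrow(kw), , drop = FALSE], origin)
    theta0 <- warm_start$fit$theta %||% NULL
  } else {
    kmat <- matrix(origin, nrow = 1)
    theta0 <- NULL
  }
  theta0 <- theta0 %||% as.vector(Arg(base %*% rep(1 + 0i, length(act))))
  cur <- ve(kmat, theta0, beta)

  ## --- greedy growth ------------------------------------------------------
  while (nrow(kmat) < n_kt) {
    y <- md * exp(complex(imaginary = cur$theta))
    Ae <- kt_make_A(base, coords, kmat)
    Gee <- cdot(Ae, Ae)
    rhs_e <- cdot(Ae, y)
    Gbb <- cdot(base, base)          # |exp(ikr)| = 1: same for every candidate
    best_c <- NULL
    for (ci in seq_len(nrow(grid$k))) {
      kc <- grid$k[ci, ]
      if (any(apply(kmat, 1, function(kk) all(abs(kk - kc) < 1e-12)))) next
      Mc <- base * as.vector(exp(complex(imaginary = coords %*% kc)))
      G <- rbind(cbind(Gee, cdot(Ae, Mc)),
                 cbind(cdot(Mc, Ae), Gbb))
      diag(G) <- diag(G) + beta
      rhs <- c(rhs_e, cdot(Mc, y))
      bb <- tryCatch(as.vector(solve(G, rhs)), error = function(e) NULL)
      if (is.null(bb)) next
      pe <- ncol(Ae)
      Ab <- as.vector(Ae %*% bb[seq_len(pe)] + Mc %*% bb[-seq_len(pe)])
      obj <- mls_objective(Ab, md, cur$theta, bb, beta)
      if (is.null(best_c) || obj < best_c$obj - 1e-12)   # strict: ties go to low |k|
        best_c <- list(obj = obj, k = kc)
    }
    if (is.null(best_c)) stop("greedy placement found no usable candidate")
    kmat <- rbind(best_c$k, kmat)    # origin stays last
    cur <- ve(kmat, cur$theta, beta)
  }

  ## --- multi-start over target-phase initializations ----------------------
  rand_thetas <- with_seed(child_seed(seed, 2L), {
    lapply(seq_len(max(n_starts - 1L, 0L)), function(i) {
      b0 <- exp(complex(imaginary = stats::runif(ncol(base) * nrow(kmat), 0, 2 * pi)))
      as.vector(Arg(kt_make_A(base, coords, kmat) %*% b0))
    })
  })
  for (th in rand_thetas) {
    cand <- ve(kmat, th, beta)
    if (cand$objective < cur$objective) cur <- cand
  }

  ## --- local refinement (coordinate search on non-origin locations) -------
  beta_cur <- beta
  if (n_kt > 1L && refine_sweeps > 0L) {
    step0 <- grid$spacing / 2
    for (sweep in seq_len(refine_sweeps)) {
      improved <- FALSE
      for (p in seq_len(n_kt - 1L)) {
        for (d in 1:3) {
          for (s in c(-1, 1)) {
            ktry <- kmat
            ktry[p, d] <- ktry[p, d] + s * step0[d] / 2^(sweep - 1)
            if (abs(ktry[p, d]) > 1.5 * grid$k_max[d]) next
            cand <- ve(ktry, cur$theta, beta_cur, iters = 10L)
            if (cand$objective < cur$objective - 1e-12) {
              kmat <- ktry; cur <- cand; improved <- TRUE
            }
            if (!is.null(power_target) && n_solves %% 50L == 0L) {
              beta_cur <- adapt_beta(beta_cur, cur$weights, rep(tau, n_kt))
              cur <- ve(kmat, cur$theta, beta_cur)
            }
          }
        }
      }
      if (!improved && sweep > 1L) break
    }
  }
  cur <- ve(kmat, cur$theta, beta_cur, iters = 200L)

  ## --- assemble pulse and recompute metrics on the full valid ROI ---------
  W <- matrix(0 + 0i, nrow = b1$n_channels, ncol = n_kt)
  W[act, ] <- matrix(cur$weights, nrow = length(act))
  pulse <- structure(list(n_kt = n_kt, k_locations = kmat, weights = W,
                          subpulse_us = rep(as.integer(tau), n_kt),
                          blip_us = as.integer(blip_us),
                          nominal_fa_deg = target_fa_deg,
                          deg_scale = deg_scale,
                          beta = beta_cur, seed = as.integer(seed),
                          fit = list(theta = cur$theta,
                                     design_vox = design_vox,
                                     objective = cur$objective)),
                     class = "ptx_ktpulse")
  fa <- predict_fa_smalltip(pulse, b1, voxels = keep_full)
  metrics <- list(cv = fa$cv, integrated_power = integrated_rf_power(pulse),
                  objective = cur$objective, fa_mean_deg = fa$mean)
  list(pulse = pulse, metrics = metrics,
       fit = list(theta = cur$theta, beta = beta_cur,
                  design_vox = design_vox, n_solves = n_solves))
}

#' @export
print.ptx_ktpulse <- function(x, ...) {
  cat(sprintf("<ptx_ktpulse> %d kT-points, %d us subpulses + %d us blips (total %d us), nominal %g deg\n",
              x$n_kt, x$subpulse_us[1], x$blip_us,
              sum(x$subpulse_us) + (x$n_kt - 1L) * x$blip_us, x$nominal_fa_deg))
  invisible(x)
}

#' Default logarithmic beta grid for L-curves
#'
#' @param n number of points (default 27).
#' @param lo,hi range (default 1e-10 .. 1e3).
#' @return numeric vector, increasing.
#' @export
lcurve_beta_grid <- function(n = 27L, lo = 1e-10, hi = 1e3) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Sweep the regularization parameter to generate an L-curve
#'
#' One design per beta, descending. Each beta is solved twice — once
#' warm-started from the previous beta's solution (k-locations and target
#' phase) and once from scratch — and the solution with the lower objective
#' is kept, so warm starts accelerate the sweep but can never corrupt it.
#' Each point's integrated RF power and CV are recomputed from the stored
#' solution over the full valid ROI.
#'
#' @inheritParams design_kt_pulse
#' @param beta_grid vector of beta values (default [lcurve_beta_grid()]).
#' @param refine_sweeps_warm refinement sweeps for the warm-started pass.
#' @param ... further arguments passed to [design_kt_pulse()].
#' @return a `ptx_lcurve`: data.frame with columns `beta`, `power`, `cv`
#'   (betas increasing), with the per-beta pulses in `attr(, "pulses")` and
#'   the configuration fingerprint in `attr(, "config")`.
#' @export
sweep_lcurve <- function(b1, roi = NULL, n_kt, beta_grid = lcurve_beta_grid(),
                         seed = 1L, refine_sweeps_warm = 1L, ...) {
  if (any(beta_grid < 0)) stop("all beta values must be non-negative")
  ord <- order(beta_grid, decreasing = TRUE)
  betas <- beta_grid[ord]
  pulses <- vector("list", length(betas))
  res <- data.frame(beta = betas, power = NA_real_, cv = NA_real_)
  warm <- NULL
  for (i in seq_along(betas)) {
    d <- design_kt_pulse(b1, roi, n_kt = n_kt, beta = betas[i], seed = seed,
                         ...)
    if (!is.null(warm)) {
      dw <- design_kt_pulse(b1, roi, n_kt = n_kt, beta = betas[i], seed = seed,
                            warm_start = warm,
                            refine_sweeps = refine_sweeps_warm, ...)
      if (dw$metrics$objective < d$metrics$objective) d <- dw
    }
    pulses[[i]] <- d$pulse
    res$power[i] <- d$metrics$integrated_power
    res$cv[i] <- d$metrics$cv
    warm <- d$pulse
  }
  back <- order(res$beta)
  out <- res[back, ]
  rownames(out) <- NULL
  attr(out, "pulses") <- pulses[back]
  attr(out, "config") <- list(n_kt = n_kt, seed = seed,
                              n_channels_active = sum(b1$active_mask))
  class(out) <- c("ptx_lcurve", "data.frame")
  out
}

#' Lowest CV attainable within an integrated-power budget
#'
#' Reads an L-curve the way the horizontal reference lines in the power/CV
#' trade-off plots are read: the best homogeneity among all swept solutions
#' whose integrated RF power does not exceed the budget.
#'
#' @param lcurve a `ptx_lcurve`.
#' @param power integrated-power budget (relative units).
#' @return scalar CV, or `NA` with a warning if no point fits the budget.
#' @export
cv_at_power <- function(lcurve, power) {
  ok <- lcurve$power <= power
  if (!any(ok)) {
    warning("no L-curve point within the power budget")
    return(NA_real_)
  }
  min(lcurve$cv[ok])
}

#' Lowest integrated power achieving a CV target
#'
#' @param lcurve a `ptx_lcurve`.
#' @param cv CV target.
#' @return scalar power, or `NA` with a warning if the target is not reached.
#' @export
power_at_cv <- function(lcurve, cv) {
  ok <- lcurve$cv <= cv
  if (!any(ok)) {
    warning("no L-curve point reaches the CV target")
    return(NA_real_)
  }
  min(lcurve$power[ok])
}
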