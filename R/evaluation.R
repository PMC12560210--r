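## Pulse evaluation: fast small-tip flip-angle prediction, a brute-force
## Bloch rotation oracle, RF power and relative local-SAR metrics, channel
## grouping, and the cross-configuration comparison report.

as_ktpulse <- function(pulse, deg_scale = NULL) {
  if (inherits(pulse, "ptx_ktpulse")) return(pulse)
  if (inherits(pulse, "ptx_shim")) {
    return(structure(list(n_kt = 1L, k_locations = matrix(0, 1, 3),
                          weights = matrix(pulse$weights, ncol = 1),
                          subpulse_us = 1000L, blip_us = 80L,
                          nominal_fa_deg = NA_real_,
                          deg_scale = deg_scale %||% 1,
                          fit = NULL),
                     class = "ptx_ktpulse"))
  }
  stop("pulse must be a ptx_ktpulse or ptx_shim")
}

new_famap <- function(fa_deg, voxels) {
  structure(list(fa_deg = fa_deg, voxels = voxels,
                 mean = mean(fa_deg), sd = sd_pop(fa_deg),
                 cv = sd_pop(fa_deg) / mean(fa_deg),
                 min = min(fa_deg)),
            class = "ptx_famap")
}

#' @export
print.ptx_famap <- function(x, ...) {
  cat(sprintf("<ptx_famap> %d voxels | mean %.3f deg, CV %.4f, min %.3f deg\n",
              length(x$fa_deg), x$mean, x$cv, x$min))
  invisible(x)
}

#' Small-tip flip-angle prediction
#'
#' `FA(r) = deg_scale * | sum_j (tau_j / 1 ms) (sum_ch B_ch(r) b_ch,j)
#' exp(i k_j . r) |` in degrees.
#'
#' @param pulse a `ptx_ktpulse` or `ptx_shim`.
#' @param b1 a `ptx_b1set`.
#' @param roi logical voxel mask, or `NULL` for the phantom ROI (valid part).
#' @param voxels optional explicit voxel indices (overrides `roi`).
#' @param deg_scale unit scale; defaults to the pulse's own.
#' @return a `ptx_famap` with per-voxel `fa_deg` and cached ROI statistics.
#' @export
predict_fa_smalltip <- function(pulse, b1, roi = NULL, voxels = NULL,
                                deg_scale = NULL) {
  pulse <- as_ktpulse(pulse, deg_scale)
  ds <- deg_scale %||% pulse$deg_scale
  if (is.null(ds) || is.na(ds)) stop("deg_scale (unit conversion) is unset")
  voxels <- voxels %||% which(eval_voxels(b1, roi))
  coords <- phantom_coords(b1$phantom)[voxels, , drop = FALSE]
  field <- rep(0 + 0i, length(voxels))
  for (j in seq_len(pulse$n_kt)) {
    ph <- exp(complex(imaginary = coords %*% pulse$k_locations[j, ]))
    field <- field + (pulse$subpulse_us[j] / 1000) *
      as.vector(b1$maps[voxels, , drop = FALSE] %*% pulse$weights[, j]) * as.vector(ph)
  }
  new_famap(ds * Mod(field), voxels)
}

#' Brute-force Bloch rotation oracle
#'
#' Per-voxel rigid-rotation integration of the piecewise-constant RF at a
#' fixed raster, with the gradient blips applied as ideal instantaneous
#' k-space jumps (a transverse-phase rotation of `(k_j - k_{j+1}) . r`
#' between subpulses). Off-resonance is zero. The flip angle is the angle
#' between the final and initial magnetization.
#'
#' @inheritParams predict_fa_smalltip
#' @param raster_us integration step in us; must divide every subpulse
#'   duration and not exceed the shortest subpulse.
#' @return a `ptx_famap`; the final transverse magnitude is attached as
#'   attribute `"mxy"`.
#' @export
bloch_oracle <- function(pulse, b1, roi = NULL, voxels = NULL, raster_us = 1,
                         deg_scale = NULL) {
  pulse <- as_ktpulse(pulse, deg_scale)
  ds <- deg_scale %||% pulse$deg_scale
  if (raster_us > min(pulse$subpulse_us)) stop("raster exceeds the shortest subpulse")
  if (any(pulse$subpulse_us %% raster_us != 0))
    stop("raster must divide every subpulse duration")
  voxels <- voxels %||% which(eval_voxels(b1, roi))
  coords <- phantom_coords(b1$phantom)[voxels, , drop = FALSE]
  B <- b1$maps[voxels, , drop = FALSE]

  mt <- rep(0 + 0i, length(voxels))  # transverse (Mx + i My)
  mz <- rep(1, length(voxels))
  for (j in seq_len(pulse$n_kt)) {
    u <- as.vector(B %*% pulse$weights[, j])
    dth <- deg2rad(ds * Mod(u)) * (raster_us / 1000)   # rad per raster step
    cd <- cos(dth); sd <- sin(dth)
    psi <- Arg(u)
    eip <- exp(complex(imaginary = psi)); ein <- Conj(eip)
    nstep <- pulse$subpulse_us[j] %/% raster_us
    for (s in seq_len(nstep)) {
      mrot <- mt * ein
      my <- Im(mrot)
      my2 <- my * cd + mz * sd
      mz <- -my * sd + mz * cd
      mt <- complex(real = Re(mrot), imaginary = my2) * eip
    }
    if (j < pulse$n_kt) {
      dk <- pulse$k_locations[j, ] - pulse$k_locations[j + 1L, ]
      mt <- mt * exp(complex(imaginary = as.vector(coords %*% dk)))
    }
  }
  fa <- new_famap(rad2deg(acos(pmin(pmax(mz, -1), 1))), voxels)
  attr(fa, "mxy") <- Mod(mt)
  fa
}

#' Integrated RF power of a pulse (relative units)
#'
#' `sum_ch sum_j |b_ch,j|^2 * tau_j` with tau in seconds; gradient blips
#' contribute no RF. Invariant under a global phase rotation of the weights.
#'
#' @param pulse a `ptx_ktpulse` or `ptx_shim`.
#' @return scalar power (relative units).
#' @export
integrated_rf_power <- function(pulse) {
  pulse <- as_ktpulse(pulse)
  sum(sweep(Mod(pulse$weights)^2, 2, pulse$subpulse_us * 1e-6, `*`))
}

#' Relative peak local SAR of a pulse over a VOP set
#'
#' `max_v` of the subpulse-duration-weighted time average of
#' `b_j^H Q_v b_j`, scaled by the duty cycle. A single identity VOP reduces
#' this to the mean RF power per unit time.
#'
#' @param pulse a `ptx_ktpulse` or `ptx_shim`.
#' @param vops a `ptx_vops` with matching channel count.
#' @param duty_cycle fraction of TR the pulse is playing (default 1).
#' @return scalar relative peak local SAR.
#' @export
peak_local_sar <- function(pulse, vops, duty_cycle = 1) {
  pulse <- as_ktpulse(pulse)
  if (vops$n_channels != nrow(pulse$weights))
    stop(sprintf("VOP channel count (%d) does not match the pulse (%d)",
                 vops$n_channels, nrow(pulse$weights)))
  tau <- pulse$subpulse_us * 1e-6
  wsum <- sum(tau)
  vals <- vapply(vops$matrices, function(Q) {
    s <- 0
    for (j in seq_len(pulse$n_kt)) {
      bj <- pulse$weights[, j]
      s <- s + tau[j] * Re(sum(Conj(bj) * (Q %*% bj)))
    }
    s / wsum
  }, numeric(1))
  duty_cycle * max(vals)
}

#' Per-channel average-power compliance check
#'
#' Checks the channel-wise time-averaged forward power of a pulse repeated
#' every `tr_s` seconds against a per-channel limit (the shape of a
#' power-controlled safety supervision), in relative units with a
#' configurable watts-per-unit scale.
#'
#' @param pulse a `ptx_ktpulse` or `ptx_shim`.
#' @param limit_w per-channel average power limit in watts (default 6.6,
#'   a 10 s-average limit).
#' @param tr_s repetition time in seconds.
#' @param watt_per_unit watts corresponding to `|b|^2 = 1` (relative scale).
#' @return data.frame with `channel`, `avg_w`, `ok`; attribute
#'   `"compliant"` is `TRUE` when every channel passes.
#' @export
check_channel_power <- function(pulse, limit_w = 6.6, tr_s = 0.01,
                                watt_per_unit = 1) {
  pulse <- as_ktpulse(pulse)
  e <- rowSums(sweep(Mod(pulse$weights)^2, 2, pulse$subpulse_us * 1e-6, `*`))
  avg_w <- watt_per_unit * e / tr_s
  out <- data.frame(channel = seq_along(avg_w), avg_w = avg_w,
                    ok = avg_w <= limit_w)
  attr(out, "compliant") <- all(out$ok)
  out
}

#' Group transmit channels with zero intra-group phase
#'
#' Emulates driving a reduced channel count: all elements of a group share
#' one weight, so the group map is the exact complex sum of its (active)
#' member maps. Total available RF power is kept constant across
#' configurations by the power normalization applied at comparison time.
#'
#' @param b1 a `ptx_b1set`.
#' @param scheme list with `mapping` (integer group id per channel, 1-based)
#'   and `n_groups`.
#' @return a `ptx_b1set` with `n_groups` channels.
#' @export
group_channels <- function(b1, scheme) {
  mapping <- scheme$mapping
  n_groups <- scheme$n_groups
  if (length(mapping) != b1$n_channels) stop("one group id per channel required")
  if (!setequal(unique(mapping[b1$active_mask]), seq_len(n_groups)) &&
      !all(unique(mapping[b1$active_mask]) %in% seq_len(n_groups)))
    stop("group ids must lie in 1..n_groups")
  gm <- matrix(0 + 0i, nrow = nrow(b1$maps), ncol = n_groups)
  for (g in seq_len(n_groups)) {
    members <- which(mapping == g & b1$active_mask)
    if (length(members) == 0L)
      stop(sprintf("group %d is empty after dead-channel removal", g))
    gm[, g] <- rowSums(b1$maps[, members, drop = FALSE])
  }
  new_b1set(gm, b1$phantom, active_mask = rep(TRUE, n_groups),
            validity_mask = b1$validity_mask,
            reference_label = b1$reference_label)
}

#' Default grouping schemes for the three-ring 32-element array
#'
#' Ring-adjacent groupings reducing 32 elements (rings of 10/12/10) to 8,
#' 16 or 20 driven channels; editable defaults mirroring an
#' adjacent-element box pattern.
#'
#' @param n_groups one of 8, 16, 20, 32.
#' @return list with `mapping` (group id per element) and `n_groups`.
#' @export
default_grouping <- function(n_groups) {
  ring <- rep(1:3, times = c(10L, 12L, 10L))
  idx_in_ring <- unlist(lapply(c(10L, 12L, 10L), seq_len))
  mapping <- switch(as.character(n_groups),
    "32" = 1:32,
    "16" = { # adjacent pairs everywhere: 5 + 6 + 5
      base <- c(0L, 5L, 11L)[ring]
      base + (idx_in_ring + 1L) %/% 2L
    },
    "8" = { # outer rings in fives, inner ring in threes: 2 + 4 + 2
      per <- ifelse(ring == 2L, 3L, 5L)
      base <- c(0L, 2L, 6L)[ring]
      base + (idx_in_ring - 1L) %/% per + 1L
    },
    "20" = { # outer rings in 3/2/3/2 blocks, inner ring individual
      blk <- c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L)
      base <- c(0L, 4L, 16L)[ring]
      ifelse(ring == 2L, base + idx_in_ring, base + blk[idx_in_ring])
    },
    stop("n_groups must be one of 8, 16, 20, 32"))
  list(mapping = as.integer(mapping), n_groups = as.integer(n_groups))
}

#' Integrated power of a phase shim scaled to the nominal flip angle
#'
#' The reference power used for matched-power comparisons: the phase-only
#' shim's weights are rescaled so its mean small-tip flip angle over the
#' valid ROI equals the nominal target, and the integrated power of the
#' resulting 1 ms pulse is returned (together with the scaled shim).
#'
#' @param b1 a `ptx_b1set`.
#' @param roi logical voxel mask or `NULL`.
#' @param shim a `ptx_shim` (e.g. an optimized phase shim).
#' @param nominal_fa_deg flip-angle target in degrees (default 10).
#' @param deg_scale unit scale (default 1).
#' @return list with `power`, `shim` (rescaled), `fa` (the `ptx_famap`).
#' @export
reference_power_phase_shim <- function(b1, roi = NULL, shim,
                                       nominal_fa_deg = 10, deg_scale = 1) {
  fa <- predict_fa_smalltip(shim, b1, roi, deg_scale = deg_scale)
  s <- nominal_fa_deg / fa$mean
  shim$weights <- shim$weights * s
  shim$power_norm <- sum(Mod(shim$weights)^2)
  list(power = integrated_rf_power(shim), shim = shim,
       fa = predict_fa_smalltip(shim, b1, roi, deg_scale = deg_scale))
}

#' Compare transmit configurations (channel counts x kT-points)
#'
#' Full factorial of L-curves over grouping schemes and kT-point counts,
#' summarised as the CV at a matched reference power, the CV improvement
#' factor of each scheme relative to the first (largest) scheme, and the
#' power ratio at matched CV.
#'
#' @param b1 a `ptx_b1set` (full channel count).
#' @param roi logical voxel mask or `NULL`.
#' @param n_kt_list integer vector of kT-point counts (1 = static shim).
#' @param schemes named list of grouping schemes (see [default_grouping()]);
#'   the first is the reference configuration.
#' @param beta_grid beta sweep for each L-curve.
#' @param seed integer seed.
#' @param reference_power matched power; `NULL` derives it from a phase
#'   shim on the reference scheme at the nominal flip angle.
#' @param nominal_fa_deg nominal flip angle (default 10).
#' @param deg_scale unit scale (default 1).
#' @param ... passed to [sweep_lcurve()] / [design_kt_pulse()].
#' @return list with `lcurves` (nested: scheme -> n_kt), `summary`
#'   data.frame, `reference_power`.
#' @export
compare_configurations <- function(b1, roi = NULL, n_kt_list, schemes,
                                   beta_grid = lcurve_beta_grid(13L),
                                   seed = 1L, reference_power = NULL,
                                   nominal_fa_deg = 10, deg_scale = 1, ...) {
  if (length(schemes) < 1L || length(n_kt_list) < 1L)
    stop("at least one scheme and one kT-point count are required")
  if (is.null(names(schemes)))
    names(schemes) <- vapply(schemes, function(s) as.character(s$n_groups), "")
  grouped <- lapply(schemes, function(s) group_channels(b1, s))

  if (is.null(reference_power)) {
    ps <- optimize_static_shim(grouped[[1]], roi, mode = "phase_only",
                               n_starts = 50L, seed = child_seed(seed, 7L))
    reference_power <- reference_power_phase_shim(grouped[[1]], roi, ps$weights,
                                                  nominal_fa_deg, deg_scale)$power
  }

  lcurves <- list()
  rows <- list()
  for (sc in names(schemes)) {
    lcurves[[sc]] <- list()
    for (nk in n_kt_list) {
      lc <- sweep_lcurve(grouped[[sc]], roi, n_kt = nk, beta_grid = beta_grid,
                         seed = seed, deg_scale = deg_scale,
                         target_fa_deg = nominal_fa_deg, ...)
      lcurves[[sc]][[as.character(nk)]] <- lc
      rows[[length(rows) + 1L]] <-
        data.frame(scheme = sc, n_kt = nk,
                   cv_at_ref_power = cv_at_power(lc, reference_power))
    }
  }
  summary <- do.call(rbind, rows)
  ref_sc <- names(schemes)[1]
  summary$cv_ratio_vs_ref <- vapply(seq_len(nrow(summary)), function(i) {
    ref <- summary$cv_at_ref_power[summary$scheme == ref_sc &
                                     summary$n_kt == summary$n_kt[i]]
    summary$cv_at_ref_power[i] / ref
  }, numeric(1))
  summary$power_at_ref_cv <- vapply(seq_len(nrow(summary)), function(i) {
    ref_cv <- summary$cv_at_ref_power[summary$scheme == ref_sc &
                                        summary$n_kt == summary$n_kt[i]]
    suppressWarnings(power_at_cv(lcurves[[summary$scheme[i]]][[as.character(summary$n_kt[i])]],
                                 ref_cv))
  }, numeric(1))
  list(lcurves = lcurves, summary = summary, reference_power = reference_power)
}

#' SAR-regularized weight solve
#'
#' Variant of [solve_weights()] in which the power penalty is replaced by a
#' smoothed worst-case local-SAR penalty: the max over VOPs is smoothed by
#' log-sum-exp with constant `smoothing`, and each iteration solves a ridge
#' system whose quadratic penalty is the softmax-weighted combination of the
#' VOP matrices (time-weighted per subpulse), interleaved with phase
#' adoption.
#'
#' The log-sum-exp temperature is relative: at each iteration it is
#' `smoothing` times the current worst-case SAR, so the softmax spreads
#' over all near-critical VOPs regardless of the SAR scale, and the
#' penalty matrix update is damped to stabilize the fixed point.
#'
#' @param A a `ptx_sysmat` (needed for channel/subpulse structure).
#' @param vops a `ptx_vops` for the active channels.
#' @param target_fa_deg flip-angle target.
#' @param sar_weight penalty weight (plays the role of beta).
#' @param smoothing log-sum-exp temperature as a fraction of the current
#'   peak SAR (default 0.2).
#' @param theta_init,max_iter,tol as in [solve_weights()].
#' @return list as [solve_weights()], plus `peak_sar` of the solution.
#' @export
solve_weights_sar <- function(A, vops, target_fa_deg = 10, sar_weight,
                              smoothing = 0.2, theta_init = NULL,
                              max_iter = 100L, tol = 1e-8) {
  if (!inherits(A, "ptx_sysmat")) stop("A must be a ptx_sysmat")
  n_act <- length(A$channels)
  if (vops$n_channels != n_act)
    stop("VOP channel count must match the active channels of A")
  Am <- A$A
  md <- rep(target_fa_deg, nrow(Am))
  G <- cdot(Am, Am)
  tau <- A$subpulse_us * 1e-6
  tw <- tau / sum(tau)
  theta <- theta_init %||% as.vector(Arg(Am %*% rep(1 + 0i, ncol(Am))))

  sar_of <- function(b) {
    W <- matrix(b, nrow = n_act)
    vapply(vops$matrices, function(Q) {
      s <- 0
      for (j in seq_len(A$n_kt)) s <- s + tw[j] * Re(sum(Conj(W[, j]) * (Q %*% W[, j])))
      s
    }, numeric(1))
  }
  b <- rep(0 + 0i, ncol(Am))
  Qeff <- Reduce(`+`, vops$matrices) / vops$count
  rel <- Inf
  for (it in seq_len(max_iter)) {
    P <- matrix(0 + 0i, ncol(Am), ncol(Am))
    for (j in seq_len(A$n_kt)) {
      idx <- (j - 1L) * n_act + seq_len(n_act)
      P[idx, idx] <- tw[j] * Qeff
    }
    y <- md * exp(complex(imaginary = theta))
    b_new <- as.vector(solve(G + sar_weight * P, cdot(Am, y)))
    Ab <- as.vector(Am %*% b_new)
    nz <- Mod(Ab) > 0
    theta[nz] <- Arg(Ab)[nz]
    s <- sar_of(b_new)
    temp <- max(smoothing * max(s), 1e-300)
    w <- exp((s - max(s)) / temp)
    w <- w / sum(w)
    ## damped update of the active-VOP combination
    Qeff <- 0.5 * Qeff + 0.5 * Reduce(`+`, Map(`*`, vops$matrices, as.list(w)))
    rel <- sqrt(sum(Mod(b_new - b)^2)) / max(sqrt(sum(Mod(b_new)^2)), 1e-300)
    b <- b_new
    if (rel < tol) break
  }
  y <- md * exp(complex(imaginary = theta))
  Ab <- as.vector(Am %*% b)
  s <- sar_of(b)
  temp <- max(smoothing * max(s), 1e-300)
  lse <- temp * log(sum(exp((s - max(s)) / temp))) + max(s)
  list(weights = b, theta = theta,
       objective = 0.5 * sum(Mod(y - Ab)^2) + 0.5 * sar_weight * lse,
       residual = 0.5 * sum(Mod(y - Ab)^2),
       peak_sar = max(s), iterations = it,
       converged = rel < tol)
}
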