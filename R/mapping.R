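## Relative B1+ map estimation from the calibration stack. The ratio
## estimator divides each single-channel image by the sum of all
## single-channel images, so the unknown receive profile and the common
## small-flip scaling cancel voxel-wise; the result is each channel's share
## of the channel sum (the channel sum of the estimates is exactly 1 at
## every valid voxel).

#' Estimate channel-wise relative B1+ maps from a calibration stack
#'
#' `map_ch(r) = (I_ch(r) - bias) / sum_ch' (I_ch'(r) - bias)` where `bias`
#' is the spatial complex mean of the all-off (noise-only) image — a scalar
#' proxy for any residual DC offset; it is zero for noiseless data, making
#' the receive-profile cancellation exact there. Voxels where the
#' denominator magnitude falls below `noise_floor_factor` times the noise
#' level estimated from the all-off image are flagged invalid.
#'
#' Because the transmit field varies smoothly on the few-centimetre scale
#' (mapping resolutions well above the acquisition voxel are known to
#' suffice), the ratio maps are optionally denoised with a validity-masked
#' boxcar average. Smoothing acts on the already-cancelled ratio, so the
#' receive-profile independence and the sum-to-one identity are preserved
#' exactly. The default (`smooth_vox = NULL`) applies a one-voxel-radius
#' kernel only when the all-off image indicates nonzero noise, keeping the
#' noiseless estimator exact.
#'
#' @param stack a `ptx_calstack` containing `all_on`, `all_off` and all
#'   single-channel measurements.
#' @param noise_floor_factor multiple of the all-off noise level below which
#'   a voxel's channel-sum is considered unreliable (default 3).
#' @param smooth_vox boxcar half-width in voxels applied to the ratio maps
#'   (0 = none); `NULL` chooses 1 when noise is detected, else 0.
#' @return a `ptx_b1set` of relative maps with `validity_mask` and
#'   `reference_label = "channel_sum"`.
#' @export
estimate_relative_maps <- function(stack, noise_floor_factor = 3,
                                   smooth_vox = NULL) {
  if (!inherits(stack, "ptx_calstack")) stop("stack must be a ptx_calstack")
  need <- c("all_on", "all_off", paste0("ch_", seq_len(stack$n_channels)))
  missing <- setdiff(need, stack$scheme)
  if (length(missing))
    stop(sprintf("calibration stack is missing measurements: %s",
                 paste(missing, collapse = ", ")))
  off <- stack$images[, match("all_off", stack$scheme)]
  bias <- mean(off)
  sigma_hat <- sqrt(0.5 * mean(Mod(off - bias)^2))

  chn <- stack$images[, match(paste0("ch_", seq_len(stack$n_channels)),
                              stack$scheme), drop = FALSE]
  chn <- chn - bias
  den <- rowSums(chn)
  validity <- Mod(den) >= noise_floor_factor * sigma_hat
  if (sigma_hat == 0) validity <- Mod(den) > 0
  if (!any(validity)) stop("no valid voxels: channel-sum everywhere below the noise floor")

  maps <- chn / den          # recycled column-wise division by a vector
  maps[!validity, ] <- 0 + 0i
  smooth_vox <- smooth_vox %||% (if (sigma_hat > 0) 1L else 0L)
  if (smooth_vox > 0L)
    maps <- box_smooth_masked(maps, validity, stack$phantom$grid_shape, smooth_vox)
  new_b1set(maps, stack$phantom,
            active_mask = rep(TRUE, stack$n_channels),
            validity_mask = validity, reference_label = "channel_sum")
}

## Boxcar average of per-channel maps over valid voxels only (invalid
## voxels contribute neither as sources nor to the kernel weight). A
## normalized kernel maps a constant field to itself, so channel sums are
## preserved wherever any valid neighbour exists.
box_smooth_masked <- function(maps, valid, grid_shape, h = 1L) {
  gs <- as.integer(grid_shape)
  lin <- array(seq_len(prod(gs)), dim = gs)
  v <- as.numeric(valid)
  acc <- matrix(0 + 0i, nrow = prod(gs), ncol = ncol(maps))
  wsum <- numeric(prod(gs))
  for (dx in -h:h) for (dy in -h:h) for (dz in -h:h) {
    sx <- seq_len(gs[1]) + dx; sy <- seq_len(gs[2]) + dy; sz <- seq_len(gs[3]) + dz
    okx <- sx >= 1L & sx <= gs[1]; oky <- sy >= 1L & sy <= gs[2]; okz <- sz >= 1L & sz <= gs[3]
    src <- as.vector(lin[sx[okx], sy[oky], sz[okz]])
    tgt <- as.vector(lin[which(okx), which(oky), which(okz)])
    vs <- v[src]
    wsum[tgt] <- wsum[tgt] + vs
    acc[tgt, ] <- acc[tgt, ] + maps[src, ] * vs
  }
  keep <- wsum > 0
  acc[keep, ] <- acc[keep, ] / wsum[keep]
  acc
}

#' Root-sum-of-squares image across channels
#'
#' The anatomical reference image on which the liver ROI is drawn.
#'
#' @param x a `ptx_b1set`, a `ptx_calstack` (its single-channel images), or
#'   a complex matrix with one column per channel.
#' @return non-negative numeric vector over voxels.
#' @export
rsos_map <- function(x) {
  maps <- if (inherits(x, "ptx_b1set")) x$maps
          else if (inherits(x, "ptx_calstack"))
            x$images[, match(paste0("ch_", seq_len(x$n_channels)), x$scheme),
                     drop = FALSE]
          else x
  if (is.null(dim(maps)) || ncol(maps) < 1L) stop("at least one channel is required")
  sqrt(rowSums(Mod(maps)^2))
}

#' Detect dead transmit channels from relative maps
#'
#' Channels whose median magnitude over the valid ROI falls below
#' `rel_threshold` times the across-channel median are flagged — the route
#' by which unstable channels are identified before pulse optimization.
#'
#' @param relmaps a `ptx_b1set` of relative maps (with `validity_mask`).
#' @param roi logical mask over voxels (defaults to the phantom ROI).
#' @param rel_threshold fraction of the across-channel median magnitude.
#' @return integer vector of suspect channel indices (1-based).
#' @export
detect_dead_channels <- function(relmaps, roi = NULL, rel_threshold = 0.1) {
  roi <- roi %||% as.vector(relmaps$phantom$roi_mask)
  keep <- roi & (relmaps$validity_mask %||% rep(TRUE, nrow(relmaps$maps)))
  if (!any(keep)) stop("no valid ROI voxels")
  med <- apply(Mod(relmaps$maps[keep, , drop = FALSE]), 2, stats::median)
  which(med < rel_threshold * stats::median(med))
}
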