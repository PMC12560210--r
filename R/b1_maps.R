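## Channel-wise complex transmit (B1+) sensitivity synthesis for a remote
## three-ring loop array. The field model is geometric decay plus a complex
## propagation exponential at the RF wavelength in tissue; it is a stand-in
## for measured maps that reproduces the interference structure (zero-phase
## dropouts, channel-count benefit) the downstream analysis exercises, not a
## full-wave EM simulation.

#' Default three-ring remote array layout
#'
#' Two outer rings of 10 elements and an inner ring of 12 (32 elements
#' total), on a remote cylinder well outside the body. The inner ring is
#' azimuthally staggered by half an element pitch.
#'
#' @param n_elements integer per-ring element counts.
#' @param z_mm ring axial offsets in mm.
#' @param radius_mm ring radius in mm (remote: larger than the body extent).
#' @return list with the ring layout plus an `elements` matrix of element
#'   positions (metres), one row per element, numbered ring by ring (1-based).
#' @export
ring_spec_default <- function(n_elements = c(10L, 12L, 10L),
                              z_mm = c(-120, 0, 120),
                              radius_mm = 300) {
  if (length(n_elements) != length(z_mm)) stop("one z offset per ring is required")
  pos <- do.call(rbind, lapply(seq_along(n_elements), function(r) {
    n <- n_elements[r]
    th <- 2 * pi * (seq_len(n) - 1) / n + if (r %% 2 == 0) pi / n else 0
    cbind(radius_mm * cos(th), radius_mm * sin(th), rep(z_mm[r], n)) / 1000
  }))
  list(n_elements = as.integer(n_elements), z_mm = z_mm, radius_mm = radius_mm,
       elements = pos)
}

#' Synthesize channel-wise complex B1+ maps
#'
#' Per element e at position p_e the map is
#' `(d_ref/d)^gamma_decay * exp(-d/attenuation) * exp(-i 2 pi d / lambda + i phi_e)`
#' with d the voxel-element distance, lambda the RF wavelength in tissue and
#' phi_e a seeded random per-element phase offset (cable/feed phase). Maps
#' are zero outside the body (no signal from air).
#'
#' The default wavelength of 130 mm (tissue at 297 MHz / 7 T) makes the
#' equal-phase ("zero-phase") channel combination exhibit destructive-
#' interference dropouts inside a liver-sized ROI.
#'
#' @param phantom a `ptx_phantom`.
#' @param ring_spec array layout, see [ring_spec_default()].
#' @param rf_wavelength_mm RF wavelength in tissue, mm (> 0).
#' @param attenuation_mm amplitude attenuation length, mm (`Inf` disables).
#' @param gamma_decay geometric decay exponent (0 disables distance decay).
#' @param seed integer seed for the per-element phase offsets.
#' @return a `ptx_b1set`: list with `maps` (complex `n_vox x n_channels`
#'   matrix, voxels in array order), `n_channels`, `active_mask`, `phantom`,
#'   `element_pos`.
#' @export
generate_b1_maps <- function(phantom,
                             ring_spec = ring_spec_default(),
                             rf_wavelength_mm = 130,
                             attenuation_mm = 150,
                             gamma_decay = 1,
                             seed = 1L) {
  if (!inherits(phantom, "ptx_phantom")) stop("phantom must be a ptx_phantom")
  if (rf_wavelength_mm <= 0) stop("rf_wavelength_mm must be positive")
  pos <- ring_spec$elements
  n_ch <- nrow(pos)
  if (is.null(n_ch) || n_ch < 1L) stop("at least one array element is required")

  phi <- with_seed(seed, stats::runif(n_ch, 0, 2 * pi))
  rc <- phantom_coords(phantom)
  body <- as.vector(phantom$body_mask)
  lam <- rf_wavelength_mm / 1000
  att <- attenuation_mm / 1000
  dref <- ring_spec$radius_mm / 1000

  maps <- matrix(0 + 0i, nrow = nrow(rc), ncol = n_ch)
  for (e in seq_len(n_ch)) {
    d <- sqrt((rc[, 1] - pos[e, 1])^2 + (rc[, 2] - pos[e, 2])^2 +
                (rc[, 3] - pos[e, 3])^2)
    amp <- (dref / d)^gamma_decay
    if (is.finite(att)) amp <- amp * exp(-d / att)
    m <- amp * exp(complex(imaginary = -2 * pi * d / lam + phi[e]))
    m[!body] <- 0 + 0i
    maps[, e] <- m
  }
  new_b1set(maps, phantom, active_mask = rep(TRUE, n_ch),
            element_pos = pos)
}

new_b1set <- function(maps, phantom, active_mask, element_pos = NULL,
                      validity_mask = NULL, reference_label = NULL) {
  structure(list(maps = maps, n_channels = ncol(maps),
                 active_mask = active_mask, phantom = phantom,
                 element_pos = element_pos,
                 validity_mask = validity_mask,
                 reference_label = reference_label),
            class = "ptx_b1set")
}

#' @export
print.ptx_b1set <- function(x, ...) {
  cat(sprintf("<ptx_b1set> %d channels (%d active) on %s grid%s\n",
              x$n_channels, sum(x$active_mask),
              paste(x$phantom$grid_shape, collapse = "x"),
              if (!is.null(x$reference_label))
                sprintf(" | relative (ref: %s)", x$reference_label) else ""))
  invisible(x)
}

#' Zero out failed transmit channels
#'
#' Channels with RF instabilities are excluded from pulse optimization by
#' zeroing their maps and clearing their active flag; all other channels are
#' returned bit-identically. Channel indices are 1-based.
#'
#' @param b1 a `ptx_b1set`.
#' @param channels integer vector of failed channel indices (may be empty).
#' @return the modified `ptx_b1set`.
#' @export
apply_channel_failures <- function(b1, channels) {
  if (!inherits(b1, "ptx_b1set")) stop("b1 must be a ptx_b1set")
  channels <- as.integer(channels)
  if (length(channels) == 0L) return(b1)
  if (any(channels < 1L | channels > b1$n_channels))
    stop(sprintf("channel index out of range 1..%d", b1$n_channels))
  channels <- unique(channels)
  b1$maps[, channels] <- 0 + 0i
  b1$active_mask[channels] <- FALSE
  if (!any(b1$active_mask)) stop("no active channels remain after failures")
  b1
}

#' Combined complex field for given channel weights
#'
#' @param b1 a `ptx_b1set`.
#' @param weights complex vector, one weight per channel (defaults to the
#'   zero-phase shim: equal unit weights on active channels).
#' @return complex vector over all voxels.
#' @export
combine_channels <- function(b1, weights = NULL) {
  if (is.null(weights)) weights <- as.complex(b1$active_mask)
  if (length(weights) != b1$n_channels) stop("one weight per channel required")
  as.vector(b1$maps %*% weights)
}
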