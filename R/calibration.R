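## Forward simulation of the relative-mapping calibration acquisition:
## n_channels + 2 small-flip-angle GRE images (all channels on with equal
## magnitude and zero phase, all channels off, then one channel at a time),
## sharing one receive profile and complex Gaussian noise.

#' Default smooth receive profile
#'
#' A strictly positive, smoothly varying surrogate for the combined local
#' receive arrays: stronger anteriorly/posteriorly, falling off towards the
#' centre of the body.
#'
#' @param phantom a `ptx_phantom`.
#' @return positive numeric vector over all voxels.
#' @export
default_receive_profile <- function(phantom) {
  rc <- phantom_coords(phantom)
  0.4 + exp(-((rc[, 2] - 0.10)^2) / (2 * 0.08^2)) +
    exp(-((rc[, 2] + 0.10)^2) / (2 * 0.08^2))
}

#' Flip scale giving a requested peak flip angle for the all-on combination
#'
#' @param b1 a `ptx_b1set`.
#' @param peak_deg requested peak flip angle of the all-on image, degrees.
#' @return scalar: radians of flip per unit of relative field magnitude.
#' @export
flip_scale_for_peak <- function(b1, peak_deg = 5) {
  allon <- Mod(combine_channels(b1))
  mx <- max(allon)
  if (mx <= 0) stop("all-on combination is identically zero")
  deg2rad(peak_deg) / mx
}

#' Simulate the calibration image stack
#'
#' Image model per measurement m:
#' `I_m(r) = R(r) * sin(flip_scale * |B_m(r)|) * exp(i arg B_m(r)) + n(r)`
#' where `B_m` is the all-on channel sum, zero, or a single channel map, and
#' `n` is complex Gaussian noise with per-component standard deviation
#' `noise_sigma`. Measurements are ordered all_on, all_off, ch_1 .. ch_N.
#'
#' @param b1 a `ptx_b1set` (ground-truth channel maps).
#' @param receive_profile positive vector over voxels, or `NULL` for
#'   [default_receive_profile()].
#' @param flip_scale radians of flip per unit field magnitude; `NULL` picks
#'   the scale giving a 5 degree all-on peak (small-flip regime).
#' @param noise_sigma per-component noise standard deviation (>= 0).
#' @param seed integer seed for the noise draws.
#' @return a `ptx_calstack`: list with `images` (complex `n_vox x n_meas`),
#'   `scheme` (labels), `noise_sigma`, `receive_profile`, `flip_scale`,
#'   `phantom`, `n_channels`.
#' @export
simulate_calibration_stack <- function(b1, receive_profile = NULL,
                                       flip_scale = NULL, noise_sigma = 0,
                                       seed = 1L) {
  if (!inherits(b1, "ptx_b1set")) stop("b1 must be a ptx_b1set")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  receive_profile <- receive_profile %||% default_receive_profile(b1$phantom)
  if (any(receive_profile <= 0)) stop("receive_profile must be strictly positive")
  flip_scale <- flip_scale %||% flip_scale_for_peak(b1, 5)

  n_ch <- b1$n_channels
  n_vox <- nrow(b1$maps)
  scheme <- c("all_on", "all_off", paste0("ch_", seq_len(n_ch)))
  images <- matrix(0 + 0i, nrow = n_vox, ncol = n_ch + 2L)

  fwd <- function(field) {
    m <- Mod(field)
    out <- receive_profile * sin(flip_scale * m) * exp(complex(imaginary = Arg(field)))
    out[m == 0] <- 0 + 0i
    out
  }
  images[, 1] <- fwd(combine_channels(b1))
  for (ch in seq_len(n_ch)) images[, ch + 2L] <- fwd(b1$maps[, ch])
  if (noise_sigma > 0) {
    images <- images + with_seed(seed,
      matrix(rcnorm(n_vox * (n_ch + 2L), sd = noise_sigma), nrow = n_vox))
  }
  structure(list(images = images, scheme = scheme, noise_sigma = noise_sigma,
                 receive_profile = receive_profile, flip_scale = flip_scale,
                 phantom = b1$phantom, n_channels = n_ch),
            class = "ptx_calstack")
}

#' @export
print.ptx_calstack <- function(x, ...) {
  cat(sprintf("<ptx_calstack> %d measurements (%d channels), sigma = %g\n",
              length(x$scheme), x$n_channels, x$noise_sigma))
  invisible(x)
}
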