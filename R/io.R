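## Readers and writers for every artifact: complex map sets as paired
## magnitude/phase NIfTI volumes with a JSON sidecar, masks as uint8 NIfTI,
## shims/pulses as JSON, L-curves as CSV, VOP sets as JSON, configuration
## as YAML. All angles are degrees at interfaces and radians internally;
## k in rad/m; durations integer microseconds.

nifti_write <- function(arr, path, voxel_size_mm) {
  img <- RNifti::asNifti(arr, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
}

nifti_read <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi   # wrap to (-pi, pi]
  y
}

#' Write a B1 map set as NIfTI volumes plus a JSON sidecar
#'
#' One magnitude and one phase volume per channel (phase in radians,
#' wrapped to (-pi, pi]), the body/ROI (and validity) masks as uint8, and a
#' `b1_sidecar.json` carrying the channel table, active mask, units and
#' grid metadata. The sidecar's channel table — not the file names — defines
#' the channel order on reload.
#'
#' @param b1 a `ptx_b1set`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_b1_dataset <- function(b1, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- b1$phantom$grid_shape
  vs <- b1$phantom$voxel_size_mm
  files <- lapply(seq_len(b1$n_channels), function(ch) {
    m <- array(Mod(b1$maps[, ch]), dim = gs)
    p <- array(wrap_pi(Arg(b1$maps[, ch])), dim = gs)
    fm <- sprintf("b1_ch%02d_mag.nii.gz", ch)
    fp <- sprintf("b1_ch%02d_phase.nii.gz", ch)
    nifti_write(m, file.path(dir, fm), vs)
    nifti_write(p, file.path(dir, fp), vs)
    list(channel = ch, mag = fm, phase = fp)
  })
  nifti_write(array(as.integer(b1$phantom$body_mask), dim = gs),
              file.path(dir, "body_mask.nii.gz"), vs)
  nifti_write(array(as.integer(b1$phantom$roi_mask), dim = gs),
              file.path(dir, "roi_mask.nii.gz"), vs)
  if (!is.null(b1$validity_mask))
    nifti_write(array(as.integer(b1$validity_mask), dim = gs),
                file.path(dir, "validity_mask.nii.gz"), vs)
  sidecar <- list(n_channels = b1$n_channels,
                  active_mask = b1$active_mask,
                  channels = files,
                  grid_shape = gs, voxel_size_mm = vs,
                  units = "relative", phase_units = "radians",
                  reference_label = b1$reference_label,
                  roi_spec = b1$phantom$roi_spec,
                  body_semiaxes_mm = b1$phantom$body_semiaxes_mm)
  jsonlite::write_json(sidecar, file.path(dir, "b1_sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a B1 map set written by [write_b1_dataset()]
#'
#' Channel order is taken from the sidecar, so shuffled directory listings
#' are harmless; grid mismatches and missing volumes are reported by
#' channel.
#'
#' @param dir dataset directory.
#' @return a `ptx_b1set`.
#' @export
load_b1_dataset <- function(dir) {
  sc_path <- file.path(dir, "b1_sidecar.json")
  if (!file.exists(sc_path)) stop(sprintf("missing sidecar: %s", sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  gs <- as.integer(sc$grid_shape)
  n_vox <- prod(gs)
  chans <- sc$channels
  if (nrow(chans) != sc$n_channels)
    stop(sprintf("sidecar lists %d channels but %d channel entries present",
                 sc$n_channels, nrow(chans)))
  maps <- matrix(0 + 0i, nrow = n_vox, ncol = sc$n_channels)
  for (i in seq_len(nrow(chans))) {
    ch <- chans$channel[i]
    fm <- file.path(dir, chans$mag[i]); fp <- file.path(dir, chans$phase[i])
    if (!file.exists(fm) || !file.exists(fp))
      stop(sprintf("missing volume(s) for channel %d: %s", ch,
                   paste(basename(c(fm, fp))[!file.exists(c(fm, fp))], collapse = ", ")))
    m <- nifti_read(fm); p <- nifti_read(fp)
    if (!identical(dim(m), gs) || !identical(dim(p), gs))
      stop(sprintf("grid mismatch for channel %d: expected %s", ch,
                   paste(gs, collapse = "x")))
    maps[, ch] <- as.vector(m) * exp(complex(imaginary = as.vector(p)))
  }
  body <- array(nifti_read(file.path(dir, "body_mask.nii.gz")) > 0, dim = gs)
  roi <- array(nifti_read(file.path(dir, "roi_mask.nii.gz")) > 0, dim = gs)
  phantom <- structure(list(grid_shape = gs,
                            voxel_size_mm = as.numeric(sc$voxel_size_mm),
                            body_mask = body, roi_mask = roi,
                            body_semiaxes_mm = sc$body_semiaxes_mm,
                            roi_spec = sc$roi_spec, seed = NA_integer_),
                       class = "ptx_phantom")
  vfile <- file.path(dir, "validity_mask.nii.gz")
  validity <- if (file.exists(vfile)) as.vector(nifti_read(vfile) > 0) else NULL
  new_b1set(maps, phantom, active_mask = as.logical(sc$active_mask),
            validity_mask = validity, reference_label = sc$reference_label)
}

#' Serialize shim weights to JSON
#'
#' Per-channel magnitude and phase (radians), mode and power normalization.
#'
#' @param shim a `ptx_shim`.
#' @param path output file.
#' @param provenance optional named list recorded verbatim.
#' @export
write_shim_json <- function(shim, path, provenance = NULL) {
  jsonlite::write_json(
    list(mode = shim$mode, power_norm = shim$power_norm,
         magnitude = Mod(shim$weights),
         phase_rad = wrap_pi(Arg(shim$weights)),
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_shim_json
#' @export
read_shim_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = x$magnitude * exp(complex(imaginary = x$phase_rad)),
                 mode = x$mode, power_norm = x$power_norm),
            class = "ptx_shim")
}

#' Serialize a kT-point pulse to JSON
#'
#' Complex weights are stored as `[re, im]` pairs per channel and subpulse;
#' k-locations in rad/m, durations in integer microseconds.
#'
#' @param pulse a `ptx_ktpulse`.
#' @param path output file.
#' @param provenance optional named list (seed, beta, config hash).
#' @export
write_pulse_json <- function(pulse, path, provenance = NULL) {
  jsonlite::write_json(
    list(n_kt = pulse$n_kt, blip_us = pulse$blip_us,
         subpulse_us = pulse$subpulse_us,
         k_locations_rad_per_m = unname(as.matrix(pulse$k_locations)),
         weights_re = unname(Re(pulse$weights)),
         weights_im = unname(Im(pulse$weights)),
         nominal_fa_deg = pulse$nominal_fa_deg,
         deg_scale = pulse$deg_scale,
         provenance = provenance %||% list(seed = pulse$seed, beta = pulse$beta)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pulse_json
#' @export
read_pulse_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_kt = x$n_kt,
                 k_locations = matrix(x$k_locations_rad_per_m, ncol = 3),
                 weights = matrix(complex(real = x$weights_re,
                                          imaginary = x$weights_im),
                                  nrow = nrow(x$weights_re)),
                 subpulse_us = as.integer(x$subpulse_us),
                 blip_us = as.integer(x$blip_us),
                 nominal_fa_deg = x$nominal_fa_deg,
                 deg_scale = x$deg_scale,
                 beta = x$provenance$beta, seed = x$provenance$seed,
                 fit = NULL),
            class = "ptx_ktpulse")
}

#' Write / read an L-curve as CSV (`beta,power,cv`)
#'
#' @param lcurve a `ptx_lcurve`.
#' @param path CSV path.
#' @export
write_lcurve_csv <- function(lcurve, path) {
  utils::write.csv(as.data.frame(lcurve)[, c("beta", "power", "cv")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_lcurve_csv
#' @export
read_lcurve_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("ptx_lcurve", "data.frame")
  out
}

#' Serialize a VOP set to JSON
#'
#' Matrices stored as real/imaginary parts with scaling metadata.
#'
#' @param vops a `ptx_vops`.
#' @param path output file.
#' @export
write_vops_json <- function(vops, path) {
  jsonlite::write_json(
    list(n_channels = vops$n_channels, count = vops$count,
         units = "relative (median unit-norm quadratic form = 1)",
         matrices = lapply(vops$matrices, function(Q)
           list(re = unname(Re(Q)), im = unname(Im(Q))))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vops_json
#' @export
read_vops_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- x$n_channels
  ## JSON stores row-major nested lists; rebuild row by row
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r)))
  mats <- lapply(x$matrices, function(m)
    matrix(complex(real = as_mat(m$re), imaginary = as_mat(m$im)), nrow = n))
  structure(list(matrices = mats, count = x$count, n_channels = n),
            class = "ptx_vops")
}
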