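## Digital body/liver phantom: elliptic-cylinder torso cross-section with a
## right-offset ellipsoidal region of interest standing in for a manually
## drawn whole-liver ROI.

#' Voxel-centre coordinate axes of a grid (metres, isocentre at grid centre)
#'
#' @param grid_shape integer length-3 vector of voxel counts.
#' @param voxel_size_mm positive length-3 voxel size in mm.
#' @return list of three numeric vectors (x, y, z positions in metres).
#' @keywords internal
voxel_axes <- function(grid_shape, voxel_size_mm) {
  lapply(1:3, function(d) {
    (seq_len(grid_shape[d]) - (grid_shape[d] + 1) / 2) * voxel_size_mm[d] / 1000
  })
}

#' Voxel-centre coordinates of every voxel on a phantom grid
#'
#' @param phantom a `ptx_phantom`.
#' @return numeric matrix `n_vox x 3` in metres, voxels in column-major
#'   (array flattening) order.
#' @export
phantom_coords <- function(phantom) {
  ax <- voxel_axes(phantom$grid_shape, phantom$voxel_size_mm)
  n <- phantom$grid_shape
  cbind(
    rep(ax[[1]], times = n[2] * n[3]),
    rep(rep(ax[[2]], each = n[1]), times = n[3]),
    rep(ax[[3]], each = n[1] * n[2])
  )
}

#' Generate a torso phantom with a liver-like ROI
#'
#' The body is an elliptic cylinder (axial ellipse extruded along z) and the
#' ROI a right-offset ellipsoid, both voxelised on an isocentre-centred grid.
#' Coordinates are metres, right-handed, voxel centres.
#'
#' @param grid_shape integer 3-vector of voxel counts (default 48 x 48 x 40).
#' @param voxel_size_mm voxel size in mm (default 4 mm isotropic, the
#'   resolution used for relative B1+ mapping).
#' @param body_semiaxes_mm in-plane semiaxes (x, y) of the body ellipse, mm.
#' @param roi_spec list with `center_mm` (3-vector) and `semiaxes_mm`
#'   (3-vector) describing the ROI ellipsoid.
#' @param seed integer seed (kept for interface uniformity; the masks are
#'   deterministic functions of the geometry).
#' @return a `ptx_phantom`: list with `grid_shape`, `voxel_size_mm`,
#'   `body_mask`, `roi_mask` (logical arrays), `body_semiaxes_mm`, `roi_spec`.
#' @export
generate_phantom <- function(grid_shape = c(48L, 48L, 40L),
                             voxel_size_mm = c(4, 4, 4),
                             body_semiaxes_mm = c(80, 60),
                             roi_spec = list(center_mm = c(26, 4, 0),
                                             semiaxes_mm = c(48, 40, 60)),
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  if (any(body_semiaxes_mm <= 0)) stop("body_semiaxes_mm must be positive")
  sa <- roi_spec$semiaxes_mm
  if (is.null(sa) || length(sa) != 3L) stop("roi_spec$semiaxes_mm must have length 3")
  if (any(sa <= 0)) stop("empty ROI: roi_spec semiaxes must all be positive")
  ctr <- roi_spec$center_mm %||% c(0, 0, 0)

  ## analytic containment: extreme points of the ROI ellipsoid must lie
  ## inside the body cylinder (x/y) and the grid (z)
  half_extent <- grid_shape * voxel_size_mm / 2
  for (d in 1:2) {
    for (s in c(-1, 1)) {
      p <- ctr[1:2]
      p[d] <- p[d] + s * sa[d]
      if (sum((p / body_semiaxes_mm)^2) > 1)
        stop(sprintf("ROI outside body: semiaxis %s (%.0f mm) extends beyond the body ellipse",
                     c("x", "y")[d], sa[d]))
    }
  }
  if (abs(ctr[3]) + sa[3] > half_extent[3])
    stop(sprintf("ROI outside body: semiaxis z (%.0f mm) extends beyond the grid", sa[3]))

  ax <- voxel_axes(grid_shape, voxel_size_mm)
  xm <- ax[[1]] * 1000; ym <- ax[[2]] * 1000; zm <- ax[[3]] * 1000
  bx <- outer((xm / body_semiaxes_mm[1])^2, (ym / body_semiaxes_mm[2])^2, `+`)
  body <- array(rep(bx <= 1, times = grid_shape[3]), dim = grid_shape)

  r2 <- outer(outer(((xm - ctr[1]) / sa[1])^2, ((ym - ctr[2]) / sa[2])^2, `+`),
              ((zm - ctr[3]) / sa[3])^2, `+`)
  roi <- r2 <= 1
  roi <- roi & body
  if (!any(roi)) stop("empty ROI: no voxels inside the ROI ellipsoid")

  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 body_mask = body, roi_mask = roi,
                 body_semiaxes_mm = as.numeric(body_semiaxes_mm),
                 roi_spec = list(center_mm = as.numeric(ctr), semiaxes_mm = as.numeric(sa)),
                 seed = as.integer(seed)),
            class = "ptx_phantom")
}

#' @export
print.ptx_phantom <- function(x, ...) {
  cat(sprintf("<ptx_phantom> %s grid @ %s mm | body %d vox | ROI %d vox\n",
              paste(x$grid_shape, collapse = "x"),
              paste(format(x$voxel_size_mm, trim = TRUE), collapse = "x"),
              sum(x$body_mask), sum(x$roi_mask)))
  invisible(x)
}
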