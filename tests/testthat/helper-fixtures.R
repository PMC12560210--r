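## Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

## A desk-sized phantom: 20x20x16 at 8 mm, liver-like ROI of ~220 voxels.
small_phantom <- function() memo("small_phantom", {
  generate_phantom(grid_shape = c(20L, 20L, 16L), voxel_size_mm = c(8, 8, 8),
                   body_semiaxes_mm = c(64, 48),
                   roi_spec = list(center_mm = c(16, 0, 0),
                                   semiaxes_mm = c(28, 24, 40)),
                   seed = 1L)
})

small_rings <- function() ring_spec_default(c(4L, 4L, 4L), c(-80, 0, 80), 200)

small_b1 <- function(seed = 7L) memo(paste0("small_b1_", seed), {
  generate_b1_maps(small_phantom(), small_rings(), seed = seed)
})

## A two-voxel map set with prescribed superposed magnitudes, for
## hand-computable statistics.
toy_b1 <- function(mags = c(1, 3)) {
  n <- length(mags)
  phantom <- structure(list(grid_shape = c(n, 1L, 1L), voxel_size_mm = c(1, 1, 1),
                            body_mask = array(TRUE, c(n, 1L, 1L)),
                            roi_mask = array(TRUE, c(n, 1L, 1L))),
                       class = "ptx_phantom")
  maps <- matrix(as.complex(mags), ncol = 1)
  structure(list(maps = maps, n_channels = 1L, active_mask = TRUE,
                 phantom = phantom, validity_mask = NULL),
            class = "ptx_b1set")
}

## Random complex map set on the small phantom grid (for oracle comparisons).
random_b1 <- function(n_channels = 5L, seed = 3L) {
  phantom <- small_phantom()
  n_vox <- prod(phantom$grid_shape)
  set.seed(seed)
  maps <- matrix(complex(real = rnorm(n_vox * n_channels),
                         imaginary = rnorm(n_vox * n_channels)),
                 ncol = n_channels)
  structure(list(maps = maps, n_channels = n_channels,
                 active_mask = rep(TRUE, n_channels),
                 phantom = phantom, validity_mask = NULL),
            class = "ptx_b1set")
}
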