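## The full-scale study configuration (default phantom, 32-channel remote
## array, fixed seed), built lazily and shared across test files.

study_seed <- 1L

study <- function() memo("study", {
  phantom <- generate_phantom(seed = study_seed)
  b1 <- generate_b1_maps(phantom, seed = study_seed)
  roi <- as.vector(phantom$roi_mask)
  list(phantom = phantom, b1 = b1, roi = roi)
})

## Phase-only shim on the study maps (trade-off cost), memoized.
study_phase_shim <- function() memo("study_phase_shim", {
  s <- study()
  optimize_static_shim(s$b1, n_starts = 100L, seed = study_seed)
})

## Reference integrated power: the phase shim rescaled to a 10 degree mean
## flip angle over the ROI.
study_reference <- function() memo("study_reference", {
  s <- study()
  reference_power_phase_shim(s$b1, shim = study_phase_shim()$weights)
})

study_lcurve <- function(n_kt) memo(paste0("study_lcurve_", n_kt), {
  s <- study()
  sweep_lcurve(s$b1, n_kt = n_kt, beta_grid = lcurve_beta_grid(27L),
               seed = study_seed)
})
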