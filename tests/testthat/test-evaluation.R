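uniform_b1 <- function(value = 1 + 0i, n_channels = 1L) {
  ph <- small_phantom()
  structure(list(maps = matrix(value, prod(ph$grid_shape), n_channels),
                 n_channels = n_channels, active_mask = rep(TRUE, n_channels),
                 phantom = ph, validity_mask = NULL), class = "ptx_b1set")
}

make_pulse <- function(weights, kmat, tau_us, deg_scale = 1) {
  structure(list(n_kt = nrow(kmat), k_locations = kmat,
                 weights = weights, subpulse_us = rep(as.integer(tau_us),
                                                      length.out = nrow(kmat)),
                 blip_us = 80L, nominal_fa_deg = NA_real_,
                 deg_scale = deg_scale, fit = NULL),
            class = "ptx_ktpulse")
}

test_that("small-tip prediction has the closed-form value for a uniform field", {
  bu <- uniform_b1()
  p <- make_pulse(matrix(4 + 0i, 1, 1), matrix(0, 1, 3), 500, deg_scale = 3)
  fa <- predict_fa_smalltip(p, bu)
  expect_equal(unique(round(fa$fa_deg, 12)), 3 * 4 * 0.5)
  z <- predict_fa_smalltip(make_pulse(matrix(0 + 0i, 1, 1), matrix(0, 1, 3), 500), bu)
  expect_true(all(z$fa_deg == 0))
})

test_that("Bloch oracle reproduces hard-pulse closed forms and subpulse composition", {
  bu <- uniform_b1()
  vox <- which(as.vector(bu$phantom$roi_mask))[1:10]
  ## constant on-resonant RF: FA = (rate x duration) exactly
  p <- make_pulse(matrix(30 + 0i, 1, 1), matrix(0, 1, 3), 1000)
  fb <- bloch_oracle(p, bu, voxels = vox)
  expect_equal(fb$fa_deg, rep(30, 10), tolerance = 1e-9)
  ## two consecutive equal subpulses at k = 0 behave as one of summed duration
  p2 <- make_pulse(matrix(30 + 0i, 1, 2), matrix(0, 2, 3), 500)
  fb2 <- bloch_oracle(p2, bu, voxels = vox)
  expect_equal(fb2$fa_deg, fb$fa_deg, tolerance = 1e-9)
  ## 90 deg: the linear prediction relates to the oracle transverse
  ## magnetization through sin(theta)
  p90 <- make_pulse(matrix(90 + 0i, 1, 1), matrix(0, 1, 3), 1000)
  f90 <- bloch_oracle(p90, bu, voxels = vox)
  st90 <- predict_fa_smalltip(p90, bu, voxels = vox)
  expect_lt(max(abs(attr(f90, "mxy") - sin(ktptx:::deg2rad(st90$fa_deg)))), 0.005)
  expect_error(bloch_oracle(p, bu, voxels = vox, raster_us = 2000), "raster")
})

test_that("small-tip and Bloch agree within 1% at 10 deg and 5% at 30 deg", {
  b1 <- small_b1()
  d <- design_kt_pulse(b1, n_kt = 2, beta = 1e-3, n_starts = 2, seed = 8,
                       refine_sweeps = 1)
  for (case in list(list(scale = 1, tol = 0.01), list(scale = 3, tol = 0.05))) {
    p <- d$pulse
    p$weights <- p$weights * case$scale
    st <- predict_fa_smalltip(p, b1)
    bl <- bloch_oracle(p, b1)
    err <- abs(st$fa_deg - bl$fa_deg) / pmax(bl$fa_deg, 1e-9)
    expect_lt(median(err), case$tol)
  }
})

test_that("integrated power follows its definition and is phase invariant", {
  z <- make_pulse(matrix(0 + 0i, 3, 2), matrix(0, 2, 3), 420)
  expect_equal(integrated_rf_power(z), 0)
  one <- make_pulse(matrix(1 + 0i, 1, 1), matrix(0, 1, 3), 1000)
  expect_equal(integrated_rf_power(one), 1e-3)
  set.seed(3)
  W <- matrix(complex(real = rnorm(6), imaginary = rnorm(6)), 3, 2)
  p <- make_pulse(W, rbind(c(1, 2, 3), c(0, 0, 0)), 420)
  p2 <- p; p2$weights <- p2$weights * exp(0.7i)
  expect_equal(integrated_rf_power(p2), integrated_rf_power(p), tolerance = 1e-12)
})

test_that("peak local SAR matches a brute-force loop and its invariances", {
  set.seed(11)
  v <- generate_vops(3L, 7L, rank = 2L, seed = 4)
  W <- matrix(complex(real = rnorm(6), imaginary = rnorm(6)), 3, 2)
  p <- make_pulse(W, rbind(c(5, 0, 0), c(0, 0, 0)), 420)
  ## brute force
  tau <- p$subpulse_us * 1e-6
  brute <- max(vapply(v$matrices, function(Q) {
    acc <- 0
    for (j in 1:2) {
      val <- 0 + 0i
      for (a in 1:3) for (b in 1:3) val <- val + Conj(W[a, j]) * Q[a, b] * W[b, j]
      acc <- acc + tau[j] * Re(val)
    }
    acc / sum(tau)
  }, numeric(1)))
  expect_equal(peak_local_sar(p, v), brute, tolerance = 1e-12)
  ## identity VOP reduces to mean power per unit time
  id <- structure(list(matrices = list(diag(3) + 0i), count = 1L, n_channels = 3L),
                  class = "ptx_vops")
  expect_equal(peak_local_sar(p, id),
               integrated_rf_power(p) / sum(tau), tolerance = 1e-12)
  ## global phase invariance and degree-2 homogeneity
  p2 <- p; p2$weights <- p2$weights * exp(1.3i)
  expect_equal(peak_local_sar(p2, v), peak_local_sar(p, v), tolerance = 1e-12)
  p3 <- p; p3$weights <- p3$weights * 2
  expect_equal(peak_local_sar(p3, v), 4 * peak_local_sar(p, v), tolerance = 1e-12)
  expect_equal(peak_local_sar(make_pulse(matrix(0 + 0i, 3, 1), matrix(0, 1, 3), 100), v), 0)
  expect_error(peak_local_sar(p, generate_vops(5L, 2L, seed = 1)), "channel count")
})

test_that("channel grouping is the exact complex sum and identity-safe", {
  b1 <- small_b1()
  ident <- group_channels(b1, list(mapping = 1:12, n_groups = 12L))
  expect_identical(ident$maps, b1$maps)
  pair <- group_channels(b1, list(mapping = rep(1:6, each = 2), n_groups = 6L))
  expect_equal(pair$maps[, 1], b1$maps[, 1] + b1$maps[, 2], tolerance = 0)
  ## grouping two identical channels doubles the map
  b2 <- b1; b2$maps[, 2] <- b2$maps[, 1]
  g <- group_channels(b2, list(mapping = c(1, 1, 2:11), n_groups = 11L))
  expect_equal(g$maps[, 1], 2 * b2$maps[, 1], tolerance = 0)
  ## empty group after dead-channel removal
  dead <- apply_channel_failures(b1, c(1L, 2L))
  expect_error(group_channels(dead, list(mapping = rep(1:6, each = 2), n_groups = 6L)),
               "group 1 is empty")
})

test_that("default groupings partition the 32 elements into the advertised counts", {
  for (n in c(8L, 16L, 20L, 32L)) {
    g <- default_grouping(n)
    expect_equal(length(g$mapping), 32L)
    expect_setequal(unique(g$mapping), seq_len(n))
  }
  expect_error(default_grouping(7), "one of")
})

test_that("per-channel power compliance flags over-limit channels", {
  W <- matrix(c(1, 10) + 0i, 2, 1)
  p <- make_pulse(W, matrix(0, 1, 3), 1000)
  chk <- check_channel_power(p, limit_w = 6.6, tr_s = 0.01, watt_per_unit = 1)
  expect_equal(chk$avg_w, c(0.1, 10))
  expect_identical(chk$ok, c(TRUE, FALSE))
  expect_false(attr(chk, "compliant"))
})

test_that("configuration comparison reduces to its parts and self-ratios are one", {
  b1 <- small_b1()
  schemes <- list("12" = list(mapping = 1:12, n_groups = 12L),
                  "6" = list(mapping = rep(1:6, each = 2), n_groups = 6L))
  bg <- lcurve_beta_grid(3L, 1e-6, 1e0)
  cc <- compare_configurations(b1, n_kt_list = 1L, schemes = schemes,
                               beta_grid = bg, seed = 4,
                               reference_power = 0.5)
  expect_equal(dim(cc$summary)[1], 2L)
  expect_equal(cc$summary$cv_ratio_vs_ref[cc$summary$scheme == "12"], 1)
  ## single scheme x single n_kt collapses to a plain L-curve sweep
  lc <- sweep_lcurve(group_channels(b1, schemes[["12"]]), n_kt = 1L,
                     beta_grid = bg, seed = 4, target_fa_deg = 10)
  expect_equal(cc$lcurves[["12"]][["1"]]$cv, lc$cv, tolerance = 1e-10)
  expect_true(all(is.finite(cc$summary$cv_at_ref_power)))
})

test_that("stronger SAR regularization lowers the peak local SAR of the solve", {
  b1 <- small_b1()
  sm <- build_system_matrix(b1, k_locations = matrix(0, 1, 3), subpulse_us = 1000)
  v <- generate_vops(12L, 10L, seed = 3)
  lo <- solve_weights_sar(sm, v, sar_weight = 1e-6, max_iter = 20)
  hi <- solve_weights_sar(sm, v, sar_weight = 10, max_iter = 20)
  expect_lt(hi$peak_sar, lo$peak_sar)
  expect_gt(hi$residual, lo$residual)
})
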