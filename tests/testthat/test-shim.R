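test_that("CV matches the hand-computed two-voxel example and a brute-force oracle", {
  expect_equal(compute_cv(toy_b1(c(1, 3)), weights = 1 + 0i), 0.5)
  expect_equal(compute_cv(toy_b1(c(2, 2)), weights = 1 + 0i), 0)

  b1 <- random_b1()
  set.seed(8)
  w <- complex(real = rnorm(5), imaginary = rnorm(5))
  roi <- as.vector(b1$phantom$roi_mask)
  ## independent per-voxel loop oracle
  idx <- which(roi)
  m <- numeric(length(idx))
  for (i in seq_along(idx)) {
    f <- 0 + 0i
    for (ch in 1:5) f <- f + b1$maps[idx[i], ch] * w[ch]
    m[i] <- Mod(f)
  }
  cv_oracle <- sqrt(mean((m - mean(m))^2)) / mean(m)
  expect_equal(compute_cv(b1, weights = w), cv_oracle, tolerance = 1e-12)

  eta_oracle <- mean(vapply(seq_along(idx), function(i) {
    f <- sum(b1$maps[idx[i], ] * w)
    Mod(f) / sum(Mod(b1$maps[idx[i], ] * w))
  }, numeric(1)))
  expect_equal(compute_efficiency(b1, weights = w), eta_oracle, tolerance = 1e-12)
})

test_that("efficiency is 1 for a single active channel and 0 under exact cancellation", {
  b1 <- small_b1()
  w <- rep(0 + 0i, 12); w[4] <- 2i
  expect_equal(compute_efficiency(b1, weights = w), 1, tolerance = 1e-12)
  ## two equal channels with opposite phase cancel at every voxel
  b2 <- toy_b1(c(1, 2))
  b2$maps <- cbind(b2$maps, -b2$maps)
  b2$n_channels <- 2L; b2$active_mask <- c(TRUE, TRUE)
  expect_error(compute_cv(b2, weights = c(1 + 0i, 1 + 0i)), "all-destructive")
  expect_equal(compute_efficiency(b2, weights = c(1 + 0i, 1 + 0i)), 0)
})

test_that("analytic cost gradients agree with finite differences", {
  b1 <- random_b1(n_channels = 4L, seed = 12)
  roi <- as.vector(b1$phantom$roi_mask)
  B <- b1$maps[roi, ]
  for (mode in c("phase_only", "mag_phase")) {
    for (w_eff in c(0, 1)) {
      cost <- ktptx:::shim_cost_fn(B, mode, w_eff)
      npar <- if (mode == "mag_phase") 8L else 4L
      set.seed(31)
      par <- runif(npar, -1, 1)
      g <- cost$gr(par)
      gn <- vapply(seq_len(npar), function(k) {
        h <- 1e-6; e <- rep(0, npar); e[k] <- h
        (cost$fn(par + e) - cost$fn(par - e)) / (2 * h)
      }, numeric(1))
      expect_equal(g, gn, tolerance = 1e-5)
    }
  }
})

test_that("uniform identical maps give a perfectly homogeneous, fully constructive optimum", {
  ph <- small_phantom()
  n_vox <- prod(ph$grid_shape)
  b1 <- structure(list(maps = matrix(0.5 + 0i, n_vox, 4), n_channels = 4L,
                       active_mask = rep(TRUE, 4), phantom = ph,
                       validity_mask = NULL), class = "ptx_b1set")
  res <- optimize_static_shim(b1, n_starts = 5, seed = 2)
  expect_lt(res$metrics$cv, 1e-8)
  expect_gt(res$metrics$efficiency, 0.999)
})

test_that("cv and efficiency are invariant to global phase and positive scaling", {
  b1 <- small_b1()
  set.seed(5)
  w <- complex(real = rnorm(12), imaginary = rnorm(12))
  for (tr in list(w * exp(1.2i), w * 3.7)) {
    expect_equal(compute_cv(b1, weights = tr), compute_cv(b1, weights = w),
                 tolerance = 1e-12)
    expect_equal(compute_efficiency(b1, weights = tr),
                 compute_efficiency(b1, weights = w), tolerance = 1e-12)
  }
})

test_that("optimized shim beats the zero-phase baseline and is seed-reproducible", {
  b1 <- small_b1()
  res <- optimize_static_shim(b1, n_starts = 10, seed = 9)
  cv0 <- compute_cv(b1, weights = zero_phase_shim(b1))
  expect_lt(res$metrics$cv, cv0)
  res2 <- optimize_static_shim(b1, n_starts = 10, seed = 9)
  expect_identical(res$weights$weights, res2$weights$weights)
  expect_equal(sum(Mod(res$weights$weights)^2), 1, tolerance = 1e-12)
  ## phase-only invariant: equal magnitudes on active channels
  mags <- Mod(res$weights$weights)
  expect_lt(diff(range(mags)), 1e-12)
})

test_that("magnitude+phase seeded from the phase-only solution never does worse", {
  b1 <- small_b1()
  ph <- optimize_static_shim(b1, n_starts = 10, cost_weight = 0, seed = 3)
  mp <- optimize_static_shim(b1, mode = "mag_phase", n_starts = 10,
                             cost_weight = 0, seed = 3,
                             init_weights = ph$weights)
  expect_lte(mp$metrics$cv, ph$metrics$cv + 1e-12)
})

test_that("fewer than two active channels is an error", {
  b1 <- small_b1()
  b1$active_mask[2:12] <- FALSE
  expect_error(optimize_static_shim(b1), "at least 2 active channels")
})
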