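test_that("noiseless stacks invert to the channel-sum-normalized ground truth", {
  b1 <- small_b1()
  ## linear (very small flip) regime so the forward model is exactly a ratio
  st <- simulate_calibration_stack(b1, flip_scale = flip_scale_for_peak(b1, 0.1),
                                   noise_sigma = 0)
  est <- estimate_relative_maps(st)
  truth <- b1$maps / rowSums(b1$maps)
  v <- est$validity_mask
  rel <- sqrt(sum(Mod(est$maps[v, ] - truth[v, ])^2) / sum(Mod(truth[v, ])^2))
  expect_lt(rel, 1e-6)
})

test_that("a common complex receive profile cancels from the estimate", {
  b1 <- small_b1()
  st <- simulate_calibration_stack(b1, noise_sigma = 0)
  est0 <- estimate_relative_maps(st)
  set.seed(4)
  rc <- phantom_coords(b1$phantom)
  prof <- (1 + 0.5 * sin(40 * rc[, 1]) + 0.3 * cos(30 * rc[, 2])) *
    exp(complex(imaginary = 2 * rc[, 3] * 10 + 0.5))
  st2 <- st
  st2$images <- st$images * prof
  est2 <- estimate_relative_maps(st2)
  expect_equal(est2$maps, est0$maps, tolerance = 1e-12)
})

test_that("channel sums equal one at every valid voxel", {
  st <- simulate_calibration_stack(small_b1(), noise_sigma = 0.005, seed = 2)
  est <- estimate_relative_maps(st)
  sums <- rowSums(est$maps[est$validity_mask, , drop = FALSE])
  expect_lt(max(Mod(sums - 1)), 1e-9)
})

test_that("missing scheme entries and all-invalid stacks are rejected", {
  st <- simulate_calibration_stack(small_b1(), noise_sigma = 0)
  st_bad <- st
  st_bad$scheme[3] <- "bogus"
  expect_error(estimate_relative_maps(st_bad), "ch_1")
})

test_that("dead channels come out near zero and are detected", {
  b1 <- apply_channel_failures(small_b1(), c(3L, 9L))
  st <- simulate_calibration_stack(b1, noise_sigma = 0.002, seed = 6)
  est <- estimate_relative_maps(st)
  expect_setequal(detect_dead_channels(est), c(3L, 9L))
})

test_that("RSoS reduces correctly for one and two channels and is permutation-symmetric", {
  b1 <- small_b1()
  one <- b1$maps[, 1, drop = FALSE]
  expect_equal(rsos_map(one), Mod(b1$maps[, 1]))
  two <- cbind(b1$maps[, 1], b1$maps[, 1])
  expect_equal(rsos_map(two), sqrt(2) * Mod(b1$maps[, 1]))
  expect_equal(rsos_map(b1$maps), rsos_map(b1$maps[, sample(12)]))
  expect_error(rsos_map(b1$maps[, 0, drop = FALSE]), "at least one channel")
  ## a calibration stack contributes its single-channel images
  st <- simulate_calibration_stack(b1, noise_sigma = 0)
  expect_equal(rsos_map(st), rsos_map(st$images[, 3:14]))
})
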