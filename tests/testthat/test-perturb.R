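test_that("perturbation sets draw from the stated parameter sets", {
  ps <- sample_perturbation_set(123, k = 40)
  expect_length(ps$specs, 40L)
  tx <- vapply(ps$specs, function(s) s$rigid$tx, 0)
  ty <- vapply(ps$specs, function(s) s$rigid$ty, 0)
  th <- vapply(ps$specs, function(s) s$rigid$theta, 0)
  expect_true(all(tx %in% c(0, 0.4, 0.8)))
  expect_true(all(ty %in% c(0, 0.4, 0.8)))
  expect_true(all(th %in% c(-20, 0, 20)))
  ps2 <- sample_perturbation_set(123, k = 40)
  expect_identical(ps, ps2)
  expect_error(sample_perturbation_set(1, k = 1), "parameter error")
})

test_that("identity rigid perturbation is bit-exact; centre is a fixed point", {
  v <- test_volume(c(21, 21, 3))
  m <- ellipsoid_mask(c(21, 21, 3), radius_frac = c(0.3, 0.3, 0.6))
  out <- apply_rigid(v, m, rigid_perturbation(0, 0, 0))
  expect_identical(out$volume$voxels, v$voxels)
  expect_identical(out$mask$voxels, m$voxels)

  # single bright voxel at the exact centre survives any rotation
  v2 <- image_volume(array(0, c(21, 21, 3)))
  v2$voxels[11, 11, 2] <- 1000
  out2 <- apply_rigid(v2, m, rigid_perturbation(0, 0, 20))
  expect_equal(out2$volume$voxels[11, 11, 2], 1000, tolerance = 1e-12)
})

test_that("opposite rotations nearly invert each other on a convex mask", {
  m <- ellipsoid_mask(c(32, 32, 4), radius_frac = c(0.35, 0.3, 0.8))
  expect_gte(sum(m$voxels), 1000)
  v <- test_volume(c(32, 32, 4))
  a <- apply_rigid(v, m, rigid_perturbation(0, 0, 20))
  b <- apply_rigid(a$volume, a$mask, rigid_perturbation(0, 0, -20))
  expect_gte(dice(b$mask, m), 0.95)
})

test_that("displacement fields have zero z component and unit RMS before smoothing", {
  f0 <- make_displacement_field(c(20, 20, 5), seed = 8, sigma_smooth = 0)
  expect_true(all(f0$dz == 0))
  rms <- sqrt(mean(f0$dx^2 + f0$dy^2 + f0$dz^2))
  expect_lt(abs(rms - 1), 1e-9)
  f5 <- make_displacement_field(c(20, 20, 5), seed = 8, sigma_smooth = 5)
  expect_true(all(f5$dz == 0))
  expect_lt(sqrt(mean(f5$dx^2 + f5$dy^2)), 1)   # smoothing shrinks the RMS
  expect_identical(make_displacement_field(c(20, 20, 5), 8, 5), f5)
})

test_that("field smoothing matches a direct-convolution oracle", {
  set.seed(31)
  arr <- array(runif(64^3, -1, 1), dim = c(64, 64, 64))
  sm <- perturbrad:::smooth_gaussian(arr, 5)
  k1 <- perturbrad:::gauss_kernel(5)
  kern3 <- outer(outer(k1, k1), k1)
  oracle <- fft_convolve_reflect(arr, kern3)
  expect_lt(max(abs(sm - oracle)), 1e-6)
})

test_that("contour randomization: identity at amplitude 0, slice-wise locality", {
  m <- ellipsoid_mask(c(24, 24, 6), radius_frac = c(0.3, 0.3, 0.35))
  f <- make_displacement_field(c(24, 24, 6), seed = 2)
  expect_identical(randomize_contour(m, f, amplitude = 0)$voxels, m$voxels)

  # dz == 0 makes each output slice depend only on its own input slice
  w1 <- randomize_contour(m, f, amplitude = 3)
  m2 <- m
  m2$voxels[, , 6] <- 0L
  m2$voxels[10:14, 10:14, 6] <- 1L          # change only the last slice
  w2 <- randomize_contour(m2, f, amplitude = 3)
  expect_identical(w1$voxels[, , 1:5], w2$voxels[, , 1:5])
})

test_that("default amplitude produces realistic contour variation on a 2000-voxel ellipsoid", {
  m <- ellipsoid_mask(c(32, 32, 8), radius_frac = c(0.4, 0.4, 0.42))
  expect_gt(sum(m$voxels), 1900)
  dices <- vapply(1:25, function(s) {
    f <- make_displacement_field(c(32, 32, 8), seed = s)
    dice(randomize_contour(m, f, amplitude = 3), m)
  }, 0)
  expect_true(all(dices >= 0.80 & dices <= 0.99))
})

test_that("larger amplitude lowers the mean Dice (monotone contour variation)", {
  m <- ellipsoid_mask(c(24, 24, 6), radius_frac = c(0.32, 0.32, 0.4))
  mean_dice <- vapply(c(1, 3, 6), function(a) {
    mean(vapply(1:20, function(s) {
      f <- make_displacement_field(c(24, 24, 6), seed = 100 + s)
      dice(randomize_contour(m, f, amplitude = a), m)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_dice) < 0))
})

test_that("perturb_subject applies one transform chain to both modalities", {
  cfg <- plain_config(shape = c(24, 24, 6), seed = 4, dose_noise_sd = 0)
  masks <- list(A = ellipsoid_mask(c(24, 24, 6), c(0.35, 0.5, 0.5),
                                   c(0.18, 0.2, 0.3), roi_name = "A"),
                B = ellipsoid_mask(c(24, 24, 6), c(0.72, 0.5, 0.5),
                                   c(0.15, 0.16, 0.3), roi_name = "B"))
  ct <- make_ct_phantom(cfg)
  dose <- make_dose_phantom(cfg, masks$A)
  pset <- sample_perturbation_set(99, k = 3)
  out <- perturb_subject(ct, dose, masks, pset, amplitude = 2)
  expect_length(out, 3L)
  expect_named(out[[1]]$masks, c("A", "B"))
  # identical final mask shared by the CT and dose arms by construction;
  # re-running is deterministic
  out2 <- perturb_subject(ct, dose, masks, pset, amplitude = 2)
  expect_identical(out[[2]]$masks$A$voxels, out2[[2]]$masks$A$voxels)
  expect_identical(out[[3]]$ct$voxels, out2[[3]]$ct$voxels)

  # all-identity specs at amplitude 0 reproduce the originals
  id_spec <- list(rigid = rigid_perturbation(0, 0, 0), field_seed = 1L)
  pset0 <- structure(list(specs = list(id_spec), k = 1L),
                     class = "perturbation_set")
  out0 <- perturb_subject(ct, dose, masks, pset0, amplitude = 0)
  expect_identical(out0[[1]]$ct$voxels, ct$voxels)
  expect_identical(out0[[1]]$dose$voxels, dose$voxels)
  expect_identical(out0[[1]]$masks$B$voxels, masks$B$voxels)
})

test_that("first-order statistics of a symmetric phantom barely move under rigid perturbation", {
  # spherically symmetric blob: rotation-invariant first-order stats should
  # change by < 2% (interpolation only)
  shape <- c(33, 33, 5)
  cx <- (shape - 1) / 2
  x <- (seq_len(shape[1]) - 1 - cx[1]); y <- (seq_len(shape[2]) - 1 - cx[2])
  z <- (seq_len(shape[3]) - 1 - cx[3]) * 3
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  vol <- image_volume(1000 * exp(-r2 / 60), spacing = c(1, 1, 3))
  m <- ellipsoid_mask(shape, radius_frac = c(0.4, 0.4, 0.8), spacing = c(1, 1, 3))
  base <- c(mean(vol$voxels[m$voxels == 1]), sd(vol$voxels[m$voxels == 1]))
  for (p in list(rigid_perturbation(0.8, 0.4, 20), rigid_perturbation(0.4, 0, -20))) {
    out <- apply_rigid(vol, m, p)
    cur <- c(mean(out$volume$voxels[out$mask$voxels == 1]),
             sd(out$volume$voxels[out$mask$voxels == 1]))
    expect_lt(max(abs(cur - base) / base), 0.02)
  }
})
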