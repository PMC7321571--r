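test_that("registering a volume to itself yields the identity", {
  ph <- generate_phantom(textured_spec(shape = c(48, 48, 48),
                                       seed = 13L))
  r <- register_rigid(ph$volume, ph$volume, max_rotation = 0)
  expect_identical(r$transform$translation, c(0, 0, 0))
  expect_identical(r$transform$rotation, c(0, 0, 0))
  expect_equal(as.numeric(r$resampled), as.numeric(ph$volume))
})

test_that("integer translations are recovered exactly", {
  ph <- generate_phantom(textured_spec(shape = c(48, 48, 48),
                                       seed = 13L))
  mov <- apply_rigid_transform(ph$volume,
                               rigid_transform(translation = c(4, 0, -3)))
  r <- register_rigid(ph$volume, mov, max_rotation = 0)
  expect_identical(r$transform$translation, c(-4, 0, 3))
  expect_identical(r$transform$rotation, c(0, 0, 0))
})

test_that("a half-voxel Lanczos shift is recovered within 0.1 voxel", {
  v <- speckle_volume(c(64, 64, 64), grain_sigma = 2, seed = 13)
  mov <- apply_rigid_transform(v, rigid_transform(translation = c(0.5, 0, 0)),
                               interp = "lanczos")
  r <- register_rigid(v, mov, max_rotation = 0)
  expect_lt(max(abs(r$transform$translation - c(-0.5, 0, 0))), 0.1)
})

test_that("a combined rotation-translation is recovered to tolerance", {
  v <- speckle_volume(c(64, 64, 64), grain_sigma = 2, seed = 17)
  tr <- rigid_transform(rotation = c(0, 0, 3 * pi / 180),
                        translation = c(2, -1, 1))
  mov <- apply_rigid_transform(v, tr, interp = "lanczos")
  r <- register_rigid(v, mov)
  inv <- invert_rigid_transform(tr)
  expect_lt(max(abs(r$transform$translation - inv$translation)), 0.1)
  expect_lt(max(abs(r$transform$rotation - inv$rotation)),
            0.2 * pi / 180)
  # NMI of the aligned pair is no worse than of the unaligned pair
  nmi_before <- cartidvc:::nmi_value(as.numeric(v), as.numeric(mov), 64L)
  expect_gte(r$nmi, nmi_before)
})

test_that("registration rejects degenerate inputs", {
  const <- vol3d(array(5, c(16, 16, 16)))
  v <- speckle_volume(c(16, 16, 16), seed = 1)
  expect_error(register_rigid(const, const), "registration failure")
  expect_error(register_rigid(v, vol3d(unclass(v), voxel_size = 2)),
               "voxel sizes")
})

test_that("rigid transforms compose with their inverse to identity", {
  tr <- rigid_transform(rotation = c(0.02, -0.04, 0.05),
                        translation = c(1.5, -2, 0.5))
  inv <- invert_rigid_transform(tr)
  R <- cartidvc:::rotation_matrix(tr$rotation)
  Ri <- cartidvc:::rotation_matrix(inv$rotation)
  expect_equal(Ri %*% R, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(Ri %*% tr$translation + inv$translation),
               c(0, 0, 0), tolerance = 1e-12)
})

test_that("anisotropic diffusion smooths noise but conserves the mean", {
  const <- vol3d(array(7, c(24, 24, 24)))
  out <- denoise_anisotropic_diffusion(const, iterations = 5, kappa = 10)
  expect_equal(as.numeric(out), as.numeric(const), tolerance = 1e-12)

  noisy <- add_noise(vol3d(array(100, c(32, 32, 32))), 10, seed = 5)
  den <- denoise_anisotropic_diffusion(noisy, iterations = 10, kappa = 30)
  expect_lt(var(as.numeric(den)), var(as.numeric(noisy)))
  expect_equal(mean(as.numeric(den)), mean(as.numeric(noisy)),
               tolerance = 1e-3 * abs(mean(as.numeric(noisy))))

  expect_identical(denoise_anisotropic_diffusion(noisy, iterations = 0),
                   noisy)
  expect_error(denoise_anisotropic_diffusion(noisy, kappa = 0), "kappa")
  expect_error(denoise_anisotropic_diffusion(noisy, iterations = -1),
               "iterations")
})

test_that("diffusion leaves a noiseless step edge essentially in place", {
  d <- c(16, 16, 64)
  v <- array(50, d)
  v[, , 33:64] <- 150
  vol <- vol3d(v)
  den <- denoise_anisotropic_diffusion(vol, iterations = 10, kappa = 20)
  # half-maximum crossing along z, before and after
  half_cross <- function(vv) {
    prof <- apply(unclass(vv), 3, mean)
    approx(prof, seq_along(prof), xout = 100, ties = mean)$y
  }
  expect_lt(abs(half_cross(den) - half_cross(vol)), 1)
})

test_that("watershed labels a noiseless two-level phantom exactly", {
  ph <- generate_phantom(flat_slab_spec(shape = c(32, 32, 32)))
  lab <- segment_regions(ph$volume)
  expect_identical(unclass(lab), unclass(ph$labels))
})

test_that("explicit markers keep their labels through the flood", {
  ph <- generate_phantom(flat_slab_spec(shape = c(24, 24, 24)))
  markers <- array(0L, c(24, 24, 24))
  markers[12, 12, 3] <- 1L
  markers[12, 12, 22] <- 2L
  lab <- segment_regions(ph$volume, markers = markers)
  expect_identical(unclass(lab)[12, 12, 3], 1L)
  expect_identical(unclass(lab)[12, 12, 22], 2L)
  expect_true(all(unclass(lab) %in% 1:2))
})

test_that("noisy phantom segments with high Dice after denoising", {
  spec <- phantom_spec(shape = c(64, 64, 64), noise_sd = 4.5,
                       psf_sigma = 0.7, seed = 19L)  # 5% of the 90-contrast
  ph <- generate_phantom(spec)
  den <- denoise_anisotropic_diffusion(ph$volume, iterations = 8,
                                       kappa = 25)
  lab <- segment_regions(den)
  for (reg in 1:2) {
    dice <- dice_coefficient(unclass(lab) == reg,
                             unclass(ph$labels) == reg)
    expect_gte(dice, 0.95)
  }
})

test_that("single-mode volumes cannot be auto-segmented", {
  flat <- vol3d(array(3, c(16, 16, 16)))
  expect_error(segment_regions(flat), "markers")
})

test_that("zeroing marrow touches only label-0 voxels", {
  v <- speckle_volume(c(16, 16, 16), seed = 3)
  all0 <- region_labels(array(0L, c(16, 16, 16)))
  expect_identical(max(abs(as.numeric(zero_marrow(v, all0)))), 0)
  all1 <- region_labels(array(1L, c(16, 16, 16)))
  expect_identical(as.numeric(zero_marrow(v, all1)), as.numeric(v))
  mixed <- array(0L, c(16, 16, 16)); mixed[1:8, , ] <- 1L
  ml <- region_labels(mixed)
  out <- zero_marrow(v, ml)
  expect_equal(sum(as.numeric(out)), sum(as.numeric(v)[mixed == 1L]))
  expect_error(zero_marrow(v, region_labels(array(0L, c(8, 8, 8)))),
               "shape")
})

test_that("VOI cropping follows the floor-centering convention", {
  v <- vol3d(array(seq_len(64^3), c(64, 64, 64)))
  expect_identical(as.numeric(crop_voi(v, 64)), as.numeric(v))
  ramp <- vol3d(array(rep(1:128, each = 128 * 128), c(128, 128, 128)))
  cr <- crop_voi(ramp, 64)
  expect_identical(dim(cr), c(64L, 64L, 64L))
  expect_equal(unclass(cr)[1, 1, 1], 33)   # z starts at voxel 33
  small <- vol3d(array(1:64, c(4, 4, 4)))
  s3 <- crop_voi(small, 3)
  expect_equal(unclass(s3)[1, 1, 1], unclass(small)[1, 1, 1])
  expect_error(crop_voi(small, 5), "exceeds")
})
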