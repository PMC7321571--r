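test_that("grid layout follows the tiling arithmetic", {
  g <- build_grid(c(96, 96, 96), 48, 0)
  expect_identical(g$n, c(2L, 2L, 2L))
  expect_identical(nrow(g$centers), 8L)
  g2 <- build_grid(c(96, 96, 96), 48, 0.5)   # spacing 24
  expect_identical(g2$n, c(3L, 3L, 3L))
  g3 <- build_grid(c(64, 64, 64), 64, 0)
  expect_identical(g3$n, c(1L, 1L, 1L))
  expect_equal(g3$centers[1, ], c(32.5, 32.5, 32.5))
  expect_error(build_grid(c(32, 32, 32), 48), "exceeds")
  # symmetry about the image center
  expect_equal(mean(g2$axes[[1]]), 48.5)
})

test_that("identical volumes give zero displacement and unit cc", {
  v <- speckle_volume(c(48, 48, 48), seed = 3)
  f <- correlate_pass(v, v, build_grid(dim(v), 16, 0))
  expect_true(all(f$valid))
  expect_identical(max(abs(f$u)), 0)
  expect_equal(min(f$cc), 1, tolerance = 1e-9)
})

test_that("integer circular shifts are recovered exactly in the interior", {
  v <- speckle_volume(c(64, 64, 64), seed = 4)
  s <- c(3L, -2L, 5L)
  def <- circshift3(v, s)
  f <- correlate_pass(v, def, build_grid(dim(v), 16, 0))
  cen <- f$grid$centers
  # nodes whose true match (template box shifted by s) stays in the image
  interior <- apply(cen, 1, function(p)
    all(p - 7.5 + s >= 1 & p + 7.5 + s <= 64))
  expect_true(all(f$valid[interior]))
  uu <- unique(f$u[interior, , drop = FALSE])
  expect_equal(nrow(uu), 1L)
  expect_identical(as.numeric(uu), as.numeric(s))
})

test_that("translation invariance: shifting the deformed shifts every u", {
  v <- speckle_volume(c(48, 48, 48), seed = 6)
  def <- circshift3(v, c(1L, 0L, -2L))
  def2 <- circshift3(def, c(2L, 1L, 0L))
  g <- build_grid(dim(v), 16, 0)
  f1 <- correlate_pass(v, def, g)
  f2 <- correlate_pass(v, def2, g)
  cen <- g$centers
  interior <- apply(cen, 1, function(p) all(p > 13 & p < 35))
  ok <- interior & f1$valid & f2$valid
  expect_gt(sum(ok), 0)
  expect_equal(f2$u[ok, , drop = FALSE] - f1$u[ok, , drop = FALSE],
               matrix(rep(c(2, 1, 0), each = sum(ok)), ncol = 3),
               tolerance = 1e-9)
})

test_that("sub-voxel shifts are recovered to the stated accuracy", {
  ph <- generate_phantom(textured_spec(shape = c(64, 64, 64)))
  tr <- rigid_transform(translation = c(0, 0, 0.3))
  def <- apply_rigid_transform(ph$volume, tr, interp = "lanczos")
  f <- correlate_pass(ph$volume, def, build_grid(c(64, 64, 64), 32, 0.5))
  ok <- interior_nodes(f$grid) & f$valid
  expect_gt(sum(ok), 0)
  expect_lt(abs(mean(f$u[ok, 3]) - 0.3), 0.05)
  expect_lt(mean(abs(f$u[ok, 1:2])), 0.05)
})

test_that("FFT correlation equals the brute-force spatial oracle", {
  set.seed(12)
  for (case in 1:3) {
    tdim <- sample(6:10, 1)
    v <- array(rnorm(20^3), c(20, 20, 20))
    tmpl <- v[6:(5 + tdim), 6:(5 + tdim), 6:(5 + tdim)]
    window <- v[2:19, 2:19, 2:19]
    oracle <- brute_zncc(tmpl, window)
    t0 <- tmpl - mean(tmpl)
    fftmap <- cartidvc:::zncc_map(t0, sum(t0^2), window, tdim)
    expect_equal(dim(fftmap), dim(oracle))
    expect_lt(max(abs(fftmap - oracle)), 1e-10)
    expect_identical(which.max(fftmap), which.max(oracle))
  }
})

test_that("flat sub-volumes are invalidated, not an error", {
  v <- vol3d(array(0, c(32, 32, 32)))
  vv <- unclass(v)
  vv[1:16, , ] <- array(rnorm(16 * 32 * 32), c(16, 32, 32))
  v <- vol3d(vv)
  f <- correlate_pass(v, v, build_grid(c(32, 32, 32), 16, 0))
  expect_true(any(!f$valid))   # flat half invalid
  expect_true(any(f$valid))
})

test_that("multipass on identical volumes returns a zero field", {
  v <- speckle_volume(c(64, 64, 64), seed = 8)
  fit <- dvc(v, v, sizes = 48)
  expect_identical(max(abs(fit$field$u)), 0)
  expect_error(dvc(v, v, sizes = integer(0)), "empty")
  expect_error(dvc(v, v, sizes = c(32, 48)), "descending")
})

test_that("multipass recovers a 1% axial compression", {
  ph <- generate_phantom(textured_spec(shape = c(96, 96, 96)))
  pair <- make_synthetic_pair(ph$volume, 0.01)
  fit <- dvc(pair$reference, pair$deformed, sizes = c(48, 32),
             overlap = 0.5, truth = pair$deformation)
  r <- residuals(fit)
  ok <- interior_nodes(fit) & fit$field$valid
  expect_gt(sum(ok), 4)
  rms <- sqrt(mean(r[ok, ]^2))
  expect_lt(rms, 0.1)
})

test_that("the predictor keeps at least as many interior nodes valid", {
  ph <- generate_phantom(textured_spec(shape = c(96, 96, 96),
                                       noise_sd = 10))
  v1 <- ph$volume
  v2 <- add_noise(generate_phantom(textured_spec(shape = c(96, 96, 96),
                                                 noise_sd = 0))$volume,
                  10, seed = 21L)
  multi <- dvc(v1, v2, sizes = c(80, 64, 48), overlap = 0.5)
  single <- dvc(v1, v2, sizes = 48, overlap = 0.5)
  int <- interior_nodes(multi)
  expect_gte(sum(multi$field$valid[int]), sum(single$field$valid[int]))
})

test_that("region masking enforces strict sub-volume inclusion", {
  spec <- flat_slab_spec(shape = c(96, 96, 96), zf = 0.5)
  ph <- generate_phantom(spec)
  v <- speckle_volume(c(96, 96, 96), seed = 5)
  g <- build_grid(c(96, 96, 96), 48, 0)
  f <- correlate_pass(v, v, g)
  # uniform map: all nodes kept
  all1 <- region_labels(array(1L, c(96, 96, 96)))
  expect_identical(mask_by_region(f, all1, 1L)$valid, f$valid)
  # half slab, sub-volume 48, z starts at 1 and 49, interface at z = 48:
  # the low-z layer is entirely cartilage, the high-z layer mineralized
  m1 <- mask_by_region(f, ph$labels, 1L)
  m2 <- mask_by_region(f, ph$labels, 2L)
  zc <- g$centers[, 3]
  expect_identical(m1$valid, f$valid & zc < 48)
  expect_identical(m2$valid, f$valid & zc > 48)
  expect_identical(sum(m1$valid), 4L)
  expect_identical(sum(m2$valid), 4L)
  # a node straddling the interface belongs to neither region
  g2 <- build_grid(c(96, 96, 96), 48, 0.5)
  f2 <- correlate_pass(v, v, g2)
  m1b <- mask_by_region(f2, ph$labels, 1L)
  m2b <- mask_by_region(f2, ph$labels, 2L)
  straddle <- abs(g2$centers[, 3] - 48.5) < 24
  expect_false(any(m1b$valid[straddle]))
  expect_false(any(m2b$valid[straddle]))
  expect_error(mask_by_region(f, ph$labels, 7L), "unknown region")
})

test_that("fitted object methods are coherent", {
  ph <- generate_phantom(textured_spec(shape = c(64, 64, 64)))
  pair <- make_synthetic_pair(ph$volume, 0.01)
  fit <- dvc(pair$reference, pair$deformed, sizes = c(32, 16),
             overlap = 0.5, truth = pair$deformation)
  expect_s3_class(fit, "dvc")
  expect_output(print(fit), "Multipass")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.dvc")
  expect_output(print(sm), "valid")
  # predict at node centers reproduces the fitted u on valid nodes
  p <- predict(fit)
  ok <- fit$field$valid
  expect_equal(unname(p[ok, ]), unname(fit$field$u[ok, ]),
               tolerance = 1e-9)
  # microns conversion uses the voxel size
  pum <- predict(fit, units = "um")
  expect_equal(unname(pum[ok, ]), unname(p[ok, ]) * voxel_size(ph$volume),
               tolerance = 1e-9)
  cf <- coef(fit)
  expect_named(cf, c("exx", "eyy", "ezz", "exy", "exz", "eyz"))
  expect_lt(cf[["ezz"]], 0)   # compression
  st <- strain(fit)
  expect_s3_class(st, "strain_field")
})
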