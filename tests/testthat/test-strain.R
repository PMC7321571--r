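# build a displacement field on a regular grid from an analytic function
analytic_field <- function(shape = c(96, 96, 96), size = 24, overlap = 0.5,
                           ufun) {
  g <- build_grid(shape, size, overlap)
  u <- t(apply(g$centers, 1L, ufun))
  cartidvc:::new_dvc_field(g, u, cc = rep(1, nrow(u)),
                           valid = rep(TRUE, nrow(u)))
}

test_that("rigid translation produces zero strain", {
  f <- analytic_field(ufun = function(p) c(1.25, -0.5, 3))
  st <- compute_strain(f)
  expect_true(all(st$valid))
  expect_equal(max(abs(st$eps)), 0)
})

test_that("linear axial field recovers its strain exactly everywhere", {
  a <- -0.01
  cen <- c(48.5, 48.5, 48.5)
  f <- analytic_field(ufun = function(p) c(0, 0, a * (p[3] - cen[3])))
  st <- compute_strain(f)
  expect_true(all(st$valid))
  expect_equal(unname(st$eps[, "ezz"]), rep(a * 1e6, nrow(st$eps)),
               tolerance = 1e-9)
  expect_equal(max(abs(st$eps[, c("exx", "eyy", "exy", "exz", "eyz")])), 0,
               tolerance = 1e-9)
})

test_that("small rigid rotation yields only O(theta^2) strain", {
  theta <- 0.001
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  cen <- c(48.5, 48.5, 48.5)
  f <- analytic_field(ufun = function(p) as.numeric(R %*% (p - cen)) -
                        (p - cen))
  st <- compute_strain(f)
  expect_lt(max(abs(st$eps)), 1)   # < 1 microstrain
})

test_that("equivalent strain matches hand-evaluated closed forms", {
  expect_equal(equivalent_strain(c(0, 0, -10000, 0, 0, 0)),
               20000 / 3, tolerance = 1e-6)
  expect_equal(equivalent_strain(c(5000, 5000, 5000, 0, 0, 0)), 0,
               tolerance = 1e-9)
  expect_equal(equivalent_strain(c(0, 0, 0, 500, 0, 0)),
               1000 / sqrt(3), tolerance = 1e-6)
  dev <- deviatoric_strain(matrix(c(0, 0, -10000, 0, 0, 0), 1))
  expect_equal(as.numeric(dev[1, 1:3]),
               c(10000 / 3, 10000 / 3, -20000 / 3), tolerance = 1e-9)
})

test_that("equivalent strain is hydrostatic-invariant and 1-homogeneous", {
  set.seed(7)
  for (rep in 1:20) {
    eps <- matrix(rnorm(6, sd = 3000), 1)
    base <- equivalent_strain(eps)
    shifted <- eps + c(1234.5, 1234.5, 1234.5, 0, 0, 0)
    expect_equal(equivalent_strain(matrix(shifted, 1)), base,
                 tolerance = 1e-9)
    k <- runif(1, -3, 3)
    expect_equal(equivalent_strain(eps * k), abs(k) * base,
                 tolerance = 1e-9)
    # deviatoric trace vanishes; engineering shears are exactly doubled
    dev <- deviatoric_strain(eps)
    expect_lt(abs(sum(dev[1, 1:3])), 1e-9 * max(1, max(abs(eps))))
    expect_identical(as.numeric(dev[1, 4:6]), as.numeric(2 * eps[1, 4:6]))
  }
})

test_that("strain of an affine fit equals the affine's strain", {
  d <- affine_deformation(matrix(c(1.002, 5e-4, 0,
                                   5e-4, 0.999, 2e-4,
                                   0, 2e-4, 0.995), 3, 3, byrow = TRUE),
                          center = c(48.5, 48.5, 48.5))
  f <- analytic_field(ufun = function(p)
    as.numeric(affine_displacement(d, matrix(p, 1))))
  st <- compute_strain(f)
  truth <- affine_strain(d) * 1e6
  for (k in 1:6)
    expect_equal(unname(st$eps[, k]), rep(unname(truth[k]), nrow(st$eps)),
                 tolerance = 1e-6)
})

test_that("degenerate grids and invalid neighbors are handled", {
  g <- build_grid(c(32, 32, 32), 32, 0)   # single node per axis
  f <- cartidvc:::new_dvc_field(g, matrix(0, 1, 3), 1, TRUE)
  expect_error(compute_strain(f), "degenerate")

  # invalid node: neighbors switch to one-sided differences, linear field
  # still exact; the invalid node itself carries no strain
  fa <- analytic_field(ufun = function(p) c(0, 0, -0.01 * (p[3] - 48.5)))
  kill <- 14L
  fa$valid[kill] <- FALSE
  st <- compute_strain(fa)
  expect_false(st$valid[kill])
  expect_true(all(is.na(st$eps[kill, ])))
  ok <- st$valid
  expect_equal(unname(st$eps[ok, "ezz"]), rep(-1e4, sum(ok)),
               tolerance = 1e-9)
})

test_that("interpolation onto the image grid reproduces nodal structure", {
  f <- analytic_field(shape = c(48, 48, 48), size = 16, overlap = 0.5,
                      ufun = function(p) c(0, 0, -0.01 * (p[3] - 24.5)))
  st <- compute_strain(f)
  # uniform field interpolates to the constant everywhere in the hull
  m <- interpolate_to_image(st, component = "ezz")
  inhull <- !is.na(unclass(m))
  expect_gt(sum(inhull), 0)
  expect_equal(unique(round(unclass(m)[inhull], 6)), -1e4)

  # knot reproduction: value at a node's voxel equals the nodal value
  g <- st$grid
  node_vox <- round(g$centers[1, ] + 0.01)  # centers are x.5 here
  # knot reproduction and linear reproduction between adjacent nodes
  g2 <- st$grid
  za <- g2$axes[[3]]
  uz <- array(st$u[, 3], g2$n)
  nodal <- array(compute_strain(f)$eps[, "ezz"], g2$n)
  mzz <- unclass(interpolate_to_image(st, component = "ezz"))
  xz <- round(g2$axes[[1]][2] + 0.01)   # a voxel on a node column
  for (k in seq_along(za)) {
    zv <- za[k]
    if (zv == round(zv))
      expect_equal(mzz[xz, xz, zv], nodal[2, 2, k], tolerance = 1e-9)
  }
  # exact linear blend halfway between two node planes (centers are x.5,
  # so pick the voxel at the midpoint of node planes 2 and 3)
  mid_z <- (za[2] + za[3]) / 2
  if (mid_z == round(mid_z)) {
    w <- (mid_z - za[2]) / (za[3] - za[2])
    expect_equal(mzz[xz, xz, mid_z],
                 (1 - w) * nodal[2, 2, 2] + w * nodal[2, 2, 3],
                 tolerance = 1e-9)
  }

  expect_error(interpolate_to_image(st, component = "bogus"), "component")
})
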