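#' Specification of a synthetic cartilage-bone phantom
#'
#' The phantom emulates the texture a propagation-based phase-contrast
#' micro-CT scan of an osteochondral plug presents to volume correlation:
#' a two-region slab (articular cartilage over mineralized tissue) with a
#' rough interface, dark ellipsoidal lacunae in both regions (chondrocyte
#' lacunae in cartilage; osteocyte and hypertrophic-chondrocyte lacunae in
#' mineralized tissue), additive Gaussian acquisition noise and optional
#' bright/dark edge-enhancement fringes at gray-level boundaries.
#'
#' Default densities and radii are literature-scale values for adult
#' bovine tissue (tens of thousands of lacunae per cubic millimetre,
#' micron-scale semi-axes); they are stated assumptions, not calibrated
#' values — the source imaging study does not quantify them.
#'
#' @param shape voxels per axis (3 integers); z (third axis) is the
#'   compression axis.
#' @param voxel_size isotropic voxel size, micrometres.
#' @param interface_z_fraction fraction of the height (z) at which
#'   cartilage meets mineralized tissue; cartilage occupies the lower z
#'   indices.
#' @param interface_roughness_amp amplitude (SD, micrometres) of the
#'   smooth random relief added to the interface.
#' @param lacunae_density lacunae per cubic millimetre for the two tissue
#'   regions, named `cartilage` and `mineralized`.
#' @param lacunae_radii range (min, max) of ellipsoid semi-axes,
#'   micrometres.
#' @param gray_levels mean gray values, named `background`, `cartilage`,
#'   `mineralized`, `lacuna`.
#' @param noise_sd SD of additive zero-mean Gaussian gray-value noise.
#' @param edge_enhancement_amp amplitude of the phase-contrast-like fringe
#'   added at region boundaries (0 disables).
#' @param psf_sigma SD (voxels) of the isotropic Gaussian point-spread
#'   function applied to the noiseless structure, modeling the finite
#'   resolution of the source/detector system; tomograms are band-limited,
#'   never voxel-sharp (0 disables).
#' @param seed integer RNG seed; identical spec and seed give bit-identical
#'   phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(240L, 240L, 240L),
                         voxel_size = 2,
                         interface_z_fraction = 0.5,
                         interface_roughness_amp = 10,
                         lacunae_density = c(cartilage = 5e4,
                                             mineralized = 4e4),
                         lacunae_radii = c(2, 6),
                         gray_levels = c(background = 20, cartilage = 90,
                                         mineralized = 180, lacuna = 40),
                         noise_sd = 5,
                         edge_enhancement_amp = 0,
                         psf_sigma = 0.7,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("invalid phantom spec: `shape` must be 3 positive integers")
  if (any(lacunae_density < 0))
    stop("invalid phantom spec: lacunae densities must be >= 0")
  if (interface_z_fraction <= 0 || interface_z_fraction >= 1)
    stop("invalid phantom spec: `interface_z_fraction` must be in (0, 1)")
  if (noise_sd < 0) stop("invalid phantom spec: `noise_sd` must be >= 0")
  if (psf_sigma < 0) stop("invalid phantom spec: `psf_sigma` must be >= 0")
  if (length(lacunae_radii) != 2L || any(lacunae_radii <= 0) ||
      diff(lacunae_radii) < 0)
    stop("invalid phantom spec: `lacunae_radii` must be an increasing pair")
  structure(list(shape = shape, voxel_size = voxel_size,
                 interface_z_fraction = interface_z_fraction,
                 interface_roughness_amp = interface_roughness_amp,
                 lacunae_density = lacunae_density,
                 lacunae_radii = lacunae_radii,
                 gray_levels = gray_levels, noise_sd = noise_sd,
                 edge_enhancement_amp = edge_enhancement_amp,
                 psf_sigma = psf_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic cartilage-bone phantom
#'
#' Builds the volume and its ground-truth region label map from a
#' [phantom_spec()]. All randomness derives from `spec$seed`; the caller's
#' RNG state is preserved.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `cb_phantom` with elements `volume` (a [vol3d]),
#'   `labels` (a [region_labels()]), `n_lacunae` (ellipsoids drawn per
#'   region) and the echoed `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 7))
#' ph$volume
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  d <- spec$shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  amp_vox <- spec$interface_roughness_amp / spec$voxel_size

  # rough interface: smooth random relief r(x, y) around the nominal cut
  r <- if (amp_vox > 0) smooth_field2d(nx, ny, spacing = 16L, sd = amp_vox)
       else matrix(0, nx, ny)
  zcut <- spec$interface_z_fraction * nz + r  # cartilage where z - 0.5 < zcut
  zmax_cart <- pmin(nz, pmax(0, ceiling(zcut - 0.5)))

  zindex <- slice.index(array(0L, d), 3L)
  labels <- array(2L, d)
  labels[zindex <= array(rep(zmax_cart, nz), d)] <- 1L

  g <- spec$gray_levels
  vol <- array(g[["mineralized"]], d)
  vol[labels == 1L] <- g[["cartilage"]]

  # lacunae: Poisson number per region, uniform centers within the region,
  # random-orientation ellipsoids clipped to their host region
  rr_vox <- spec$lacunae_radii / spec$voxel_size
  vox_mm3 <- (spec$voxel_size * 1e-3)^3
  n_lacunae <- c(cartilage = 0L, mineralized = 0L)
  for (reg in 1:2) {
    dens <- spec$lacunae_density[[if (reg == 1L) "cartilage" else "mineralized"]]
    if (dens <= 0) next
    in_reg <- which(labels == reg)
    n_lac <- stats::rpois(1L, dens * length(in_reg) * vox_mm3)
    n_lacunae[reg] <- n_lac
    if (n_lac == 0L) next
    centers_idx <- sample(in_reg, n_lac, replace = TRUE)
    ci <- arrayInd(centers_idx, d) + matrix(stats::runif(3L * n_lac, -0.5, 0.5),
                                            ncol = 3L)
    gray_lac <- g[["lacuna"]]
    n12 <- d[1] * d[2]
    for (q in seq_len(n_lac)) {
      semi <- stats::runif(3L, rr_vox[1], rr_vox[2])
      R <- random_rotation()
      cen <- ci[q, ]
      rmax <- max(semi)
      lo <- pmax(1L, floor(cen - rmax))
      hi <- pmin(d, ceiling(cen + rmax))
      if (any(lo > hi)) next
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      gx <- rep(xs, times = length(ys) * length(zs))
      gy <- rep(rep(ys, each = length(xs)), times = length(zs))
      gz <- rep(zs, each = length(xs) * length(ys))
      p <- cbind(gx - cen[1], gy - cen[2], gz - cen[3]) %*% R
      inside <- (p[, 1] / semi[1])^2 + (p[, 2] / semi[2])^2 +
                (p[, 3] / semi[3])^2 <= 1
      if (!any(inside)) next
      lin <- gx[inside] + (gy[inside] - 1L) * d[1] + (gz[inside] - 1L) * n12
      lin <- lin[labels[lin] == reg]   # clip to the host region
      vol[lin] <- gray_lac             # in-place: vol has a single binding
    }
  }

  if (spec$edge_enhancement_amp != 0) {
    # propagation-fringe surrogate: z-derivative of the blurred
    # mineralized-phase indicator, bright above / dark below the interface
    ind <- blur3d(array(as.numeric(labels == 2L), d), sigma = 2)
    vol <- vol + spec$edge_enhancement_amp * diff_axis(ind, 3L)
  }

  # acquisition blur precedes detector noise
  if (spec$psf_sigma > 0) vol <- blur3d(vol, spec$psf_sigma)

  if (spec$noise_sd > 0)
    vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), d)

  structure(list(volume = vol3d(vol, voxel_size = spec$voxel_size),
                 labels = region_labels(labels,
                                        voxel_size = spec$voxel_size),
                 n_lacunae = n_lacunae, spec = spec),
            class = "cb_phantom")
}

#' @export
print.cb_phantom <- function(x, ...) {
  cat("<cb_phantom>\n")
  print(x$volume)
  print(x$labels)
  invisible(x)
}

#' Add acquisition noise to a volume
#'
#' Adds independent zero-mean Gaussian gray-value noise, emulating the
#' difference between two consecutively acquired tomograms of an
#' undeformed specimen (the zero-strain pair).
#'
#' @param vol a [vol3d] volume.
#' @param sd noise standard deviation in gray units (0 returns the input
#'   unchanged).
#' @param seed integer RNG seed.
#' @return noisy [vol3d].
#' @export
add_noise <- function(vol, sd, seed = 1L) {
  stopifnot(inherits(vol, "vol3d"))
  if (sd < 0) stop("`sd` must be >= 0")
  if (sd == 0) return(vol)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- vol3d(unclass(vol) + array(stats::rnorm(length(vol), 0, sd),
                                    dim(vol)),
               voxel_size = voxel_size(vol))
  attr(out, "outside") <- attr(vol, "outside")   # keep resampling flags
  out
}

#' Smooth speckle test volume
#'
#' Gaussian-filtered white noise, rescaled to zero mean and unit SD: a
#' band-limited speckle pattern useful for exercising sub-voxel
#' displacement recovery where a smooth, feature-dense texture is wanted.
#'
#' @param shape voxels per axis (3 integers).
#' @param grain_sigma Gaussian filter SD in voxels (speckle grain size).
#' @param seed integer RNG seed.
#' @param voxel_size voxel size in micrometres.
#' @return a [vol3d].
#' @export
speckle_volume <- function(shape, grain_sigma = 2, seed = 1L,
                           voxel_size = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  v <- array(stats::rnorm(prod(shape)), dim = shape)
  v <- blur3d(v, grain_sigma)
  vol3d((v - mean(v)) / stats::sd(v), voxel_size = voxel_size)
}

# ---- internal helpers -------------------------------------------------

# smooth 2D Gaussian field: iid normals on a coarse grid, bilinear upsample
smooth_field2d <- function(nx, ny, spacing, sd) {
  cx <- seq(1, nx + spacing, by = spacing)
  cy <- seq(1, ny + spacing, by = spacing)
  coarse <- matrix(stats::rnorm(length(cx) * length(cy), 0, sd),
                   length(cx), length(cy))
  ix <- pmin((seq_len(nx) - 1) / spacing + 1, length(cx) - 1e-9)
  iy <- pmin((seq_len(ny) - 1) / spacing + 1, length(cy) - 1e-9)
  i0 <- floor(ix); fx <- ix - i0
  j0 <- floor(iy); fy <- iy - j0
  a <- coarse[cbind(rep(i0, ny), rep(j0, each = nx))]
  b <- coarse[cbind(rep(i0 + 1, ny), rep(j0, each = nx))]
  cc <- coarse[cbind(rep(i0, ny), rep(j0 + 1, each = nx))]
  dd <- coarse[cbind(rep(i0 + 1, ny), rep(j0 + 1, each = nx))]
  fxr <- rep(fx, ny); fyr <- rep(fy, each = nx)
  matrix((a * (1 - fxr) + b * fxr) * (1 - fyr) +
         (cc * (1 - fxr) + dd * fxr) * fyr, nx, ny)
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# separable Gaussian blur along all three axes (edge-replicated boundaries)
blur3d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  for (ax in 1:3) v <- conv_axis(v, k, ax)
  v
}

# convolve a 3D array with a 1D kernel along axis `ax` (edge replication)
conv_axis <- function(v, k, ax) {
  rad <- (length(k) - 1L) / 2L
  out <- array(0, dim(v))
  n <- dim(v)[ax]
  for (m in seq_along(k)) {
    off <- m - 1L - rad
    src <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[m] * index_axis(v, src, ax)
  }
  out
}

index_axis <- function(v, idx, ax) {
  switch(ax,
         v[idx, , , drop = FALSE],
         v[, idx, , drop = FALSE],
         v[, , idx, drop = FALSE])
}

# central difference along axis `ax` (one-sided at the ends)
diff_axis <- function(v, ax) {
  n <- dim(v)[ax]
  fwd <- c(2:n, n)
  bwd <- c(1L, 1:(n - 1L))
  den <- rep(2, n); den[1] <- 1; den[n] <- 1
  dv <- index_axis(v, fwd, ax) - index_axis(v, bwd, ax)
  sweep_axis(dv, den, ax, `/`)
}

sweep_axis <- function(v, vec, ax, op) {
  d <- dim(v)
  rep_vec <- switch(ax,
                    rep(vec, times = d[2] * d[3]),
                    rep(rep(vec, each = d[1]), times = d[3]),
                    rep(vec, each = d[1] * d[2]))
  array(op(as.numeric(v), rep_vec), d)
}
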