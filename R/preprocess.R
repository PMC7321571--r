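#' Rigid transform (rotation angles + translation)
#'
#' Maps a moving volume onto a reference: the aligned volume at voxel `x`
#' samples the moving volume at `R^-1 (x - c - t) + c`, where `R` is the
#' rotation (intrinsic x-y-z angles, radians) about the image center `c`
#' and `t` the translation in voxels.
#'
#' @param rotation length-3 numeric, radians.
#' @param translation length-3 numeric, voxels.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0),
                            translation = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation (deg): %s | translation (vox): %s\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", ")))
  invisible(x)
}

#' Rigidly register a moving volume to a reference
#'
#' Maximizes normalized mutual information (NMI) over translation and
#' rotation: an FFT cross-correlation supplies the integer-translation
#' start, then multi-start Nelder-Mead refinement runs coarse-to-fine over
#' a two-level pyramid. NMI is computed on a 64-bin joint histogram of the
#' overlapping voxels. Near-integer solutions are snapped to the integer
#' grid when that does not reduce NMI.
#'
#' @param reference,moving [vol3d] volumes with equal voxel size.
#' @param max_translation search bound for the initial integer translation
#'   (voxels).
#' @param max_rotation bound for rotation starts (radians).
#' @param bins joint-histogram bins for NMI.
#' @return list with `transform` (a [rigid_transform()]), `resampled`
#'   (moving resampled onto the reference grid) and `nmi` (final value).
#' @export
register_rigid <- function(reference, moving, max_translation = 8,
                           max_rotation = 5 * pi / 180, bins = 64L) {
  stopifnot(inherits(reference, "vol3d"), inherits(moving, "vol3d"))
  if (!isTRUE(all.equal(voxel_size(reference), voxel_size(moving))))
    stop("registration failure: voxel sizes differ")
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("registration failure: constant image has no registerable content")
  if (!all(dim(reference) == dim(moving)))
    stop("registration failure: volumes must share a shape")

  t0 <- -integer_shift_ncc(reference, moving, max_shift = max_translation)

  # coarse-to-fine NMI refinement, multi-start in rotation at the coarse
  # level; NMI landscapes have local optima under rotation
  factor <- if (min(dim(reference)) >= 64) 2L else 1L
  ref_c <- downsample2(reference, factor)
  mov_c <- downsample2(moving, factor)
  starts <- list(c(t0 / factor, 0, 0, 0))
  if (max_rotation > 0) {
    for (ax in 1:3) for (sgn in c(-1, 1)) {
      rot <- c(0, 0, 0); rot[ax] <- sgn * max_rotation / 2
      starts <- c(starts, list(c(t0 / factor, rot)))
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, nmi_objective, ref = ref_c, mov = mov_c,
                        bins = bins, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- best$par
  par[1:3] <- par[1:3] * factor
  fit <- stats::optim(par, nmi_objective, ref = reference, mov = moving,
                      bins = bins, method = "Nelder-Mead",
                      control = list(maxit = 250, reltol = 1e-9))
  par <- fit$par
  val <- -nmi_objective(par, reference, moving, bins)

  snapped <- c(round(par[1:3]), round(par[4:6] / (pi / 2)) * (pi / 2))
  if (max(abs(par[1:3] - snapped[1:3])) < 0.1 &&
      max(abs(par[4:6] - snapped[4:6])) < 1e-3) {
    val_s <- -nmi_objective(snapped, reference, moving, bins)
    # interpolation mixing can inflate NMI ~1% off-grid on low-entropy
    # images; prefer the exact-grid solution when within 5%. The snap is
    # gated to 0.1 voxel, so accuracy is bounded either way.
    if (val_s >= val - 5e-2 * abs(val)) { par <- snapped; val <- val_s }
  }

  tr <- rigid_transform(rotation = par[4:6], translation = par[1:3])
  resampled <- rigid_resample(moving, tr$rotation, tr$translation,
                              interp = 0L)
  list(transform = tr, resampled = resampled, nmi = val)
}

#' Apply or invert a rigid transform
#' @param vol a [vol3d] volume.
#' @param transform a [rigid_transform()].
#' @param interp `"linear"` or `"lanczos"`.
#' @return resampled [vol3d].
#' @export
apply_rigid_transform <- function(vol, transform,
                                  interp = c("linear", "lanczos")) {
  interp <- match.arg(interp)
  rigid_resample(vol, transform$rotation, transform$translation,
                 interp = if (interp == "lanczos") 1L else 0L)
}

#' @rdname apply_rigid_transform
#' @export
invert_rigid_transform <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  Rinv <- t(R)
  rigid_transform(rotation = euler_angles(Rinv),
                  translation = as.numeric(-Rinv %*%
                                             transform$translation))
}

# intrinsic x-y-z (Rz Ry Rx) angles of a rotation matrix
euler_angles <- function(R) {
  c(atan2(R[3, 2], R[3, 3]), asin(-R[3, 1]), atan2(R[2, 1], R[1, 1]))
}

#' Anisotropic-diffusion denoising (Perona-Malik)
#'
#' Conservative (flux-form) 3D Perona-Malik diffusion with the exponential
#' conductance `g(d) = exp(-(d / kappa)^2)` and zero-flux boundaries; the
#' gray-value mean is conserved exactly.
#'
#' @param vol a [vol3d] volume.
#' @param iterations number of explicit time steps (0 returns the input).
#' @param kappa gradient scale in gray units; gradients well above `kappa`
#'   are treated as edges and preserved.
#' @param lambda time step; stability requires `lambda <= 1/6` in 3D.
#' @return denoised [vol3d].
#' @export
denoise_anisotropic_diffusion <- function(vol, iterations = 10L,
                                          kappa = 20, lambda = 1 / 6) {
  stopifnot(inherits(vol, "vol3d"))
  if (iterations < 0) stop("`iterations` must be >= 0")
  if (kappa <= 0) stop("`kappa` must be positive")
  v <- unclass(vol); attributes(v) <- list(dim = dim(vol))
  for (it in seq_len(iterations)) {
    acc <- array(0, dim(v))
    for (ax in 1:3) {
      n <- dim(v)[ax]
      fwd <- index_axis(v, c(2:n, n), ax) - v     # face flux, 0 at far end
      flux <- exp(-(fwd / kappa)^2) * fwd
      acc <- acc + flux - index_axis(flux, c(1L, 1:(n - 1L)), ax) *
        sweep_mask(dim(v), ax)
    }
    v <- v + lambda * acc
  }
  vol3d(v, voxel_size = voxel_size(vol))
}

# mask that zeroes the wrapped backward flux at the first slice of axis ax
sweep_mask <- function(d, ax) {
  m <- rep(1, d[ax]); m[1] <- 0
  sweep_axis(array(1, d), m, ax, `*`)
}

#' Label tissue regions by marker-controlled watershed
#'
#' Floods the gradient-magnitude image from markers. When markers are not
#' supplied they are derived from multi-level Otsu thresholds: voxels
#' whose gray value lies in the core of a class (between the class mean
#' and halfway to the neighboring threshold) seed that class.
#'
#' @param vol a [vol3d] volume.
#' @param markers optional integer array of marker seeds (0 = unlabeled;
#'   positive values are kept as labels).
#' @param classes 2 for cartilage/mineralized labeling (labels 1, 2) or 3
#'   to also separate a dark background/marrow phase (labels 0, 1, 2).
#' @return a [region_labels()] map.
#' @export
segment_regions <- function(vol, markers = NULL, classes = 2L) {
  stopifnot(inherits(vol, "vol3d"))
  v <- unclass(vol); attributes(v) <- list(dim = dim(vol))
  if (is.null(markers)) {
    thr <- otsu_thresholds(as.numeric(v), k = classes - 1L)
    if (any(!is.finite(thr)) || anyDuplicated(thr))
      stop("volume has fewer gray modes than requested classes; ",
           "supply explicit markers")
    bounds <- c(-Inf, thr, Inf)
    markers <- array(0L, dim(v))
    for (cl in seq_len(classes)) {
      sel <- v >= bounds[cl] & v < bounds[cl + 1L]
      if (!any(sel))
        stop("no voxels in gray class ", cl, "; supply explicit markers")
      mu <- mean(v[sel])
      lo <- if (is.finite(bounds[cl])) (mu + bounds[cl]) / 2 else -Inf
      hi <- if (is.finite(bounds[cl + 1L])) (mu + bounds[cl + 1L]) / 2
            else Inf
      markers[sel & v >= lo & v <= hi] <- cl
    }
    if (length(unique(markers[markers > 0L])) < 2L)
      stop("could not derive two marker classes; supply explicit markers")
  } else {
    markers <- array(as.integer(markers), dim(v))
  }
  grad <- gradient_magnitude(v)
  ws <- cpp_watershed(as.numeric(grad), as.integer(markers), dim(v))
  lab <- array(ws, dim(v))
  # class index -> region coding: darkest class is background only when
  # three classes were requested
  if (classes == 3L) lab <- lab - 1L
  region_labels(lab, voxel_size = voxel_size(vol))
}

gradient_magnitude <- function(v) {
  g <- array(0, dim(v))
  for (ax in 1:3) g <- g + diff_axis(v, ax)^2
  sqrt(g)
}

# exhaustive multi-level Otsu on a 256-bin histogram
otsu_thresholds <- function(x, k = 1L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(NA_real_, k))
  nb <- 256L
  b <- pmin(nb, 1L + floor((x - rng[1]) / diff(rng) * nb))
  h <- tabulate(b, nbins = nb)
  w <- cumsum(h)
  m <- cumsum(h * seq_len(nb))
  wt <- w[nb]; mt <- m[nb]
  centers <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  seg_stat <- function(i, j) {        # between-class weight * mean^2 term
    cw <- w[j] - if (i > 0) w[i] else 0
    cm <- m[j] - if (i > 0) m[i] else 0
    if (cw == 0) 0 else cm^2 / cw
  }
  if (k == 1L) {
    best <- -Inf; bi <- NA_integer_
    for (t1 in 1:(nb - 1L)) {
      s <- seg_stat(0L, t1) + seg_stat(t1, nb)
      if (s > best) { best <- s; bi <- t1 }
    }
    return(centers[bi])
  }
  best <- -Inf; bi <- c(NA_integer_, NA_integer_)
  for (t1 in 1:(nb - 2L)) {
    s1 <- seg_stat(0L, t1)
    for (t2 in (t1 + 1L):(nb - 1L)) {
      s <- s1 + seg_stat(t1, t2) + seg_stat(t2, nb)
      if (s > best) { best <- s; bi <- c(t1, t2) }
    }
  }
  centers[bi]
}

#' Zero the marrow/background voxels of a volume
#'
#' @param vol a [vol3d] volume.
#' @param labels a [region_labels()] map of the same shape.
#' @return [vol3d] with label-0 voxels set to exactly 0 and labeled voxels
#'   unchanged.
#' @export
zero_marrow <- function(vol, labels) {
  stopifnot(inherits(vol, "vol3d"), inherits(labels, "region_labels"))
  if (!all(dim(vol) == dim(labels))) stop("shape mismatch")
  v <- unclass(vol); attributes(v) <- list(dim = dim(vol))
  v[unclass(labels) == 0L] <- 0
  vol3d(v, voxel_size = voxel_size(vol))
}

#' Crop a cubic volume of interest from the middle of a volume
#'
#' Uses floor-based centering for even remainders: the VOI starts at
#' `floor((dim - side) / 2) + 1` on each axis.
#'
#' @param vol a [vol3d] volume (or a [region_labels()] map).
#' @param side VOI edge length in voxels.
#' @param center optional VOI center (voxel coordinates); defaults to the
#'   image center.
#' @return cropped object of the same class.
#' @export
crop_voi <- function(vol, side, center = NULL) {
  d <- dim(vol)
  side <- as.integer(side)
  if (any(side > d)) stop("`side` exceeds an image dimension")
  start <- if (is.null(center)) floor((d - side) / 2) + 1L
           else as.integer(round(center - (side - 1) / 2))
  if (any(start < 1L) || any(start + side - 1L > d))
    stop("VOI does not fit inside the volume")
  out <- unclass(vol)[start[1]:(start[1] + side - 1L),
                      start[2]:(start[2] + side - 1L),
                      start[3]:(start[3] + side - 1L), drop = FALSE]
  if (inherits(vol, "region_labels"))
    region_labels(out, voxel_size = voxel_size(vol))
  else vol3d(out, voxel_size = voxel_size(vol))
}

# ---- registration internals ------------------------------------------

# integer shift s maximizing circular NCC: moving(x) ~ reference(x - s)
integer_shift_ncc <- function(reference, moving, max_shift = 8) {
  a <- unclass(reference); attributes(a) <- list(dim = dim(reference))
  b <- unclass(moving); attributes(b) <- list(dim = dim(moving))
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)),
                      inverse = TRUE)) / length(a)
  d <- dim(a)
  off <- lapply(d, function(n) {
    o <- 0:(n - 1L); o[o > n / 2] <- o[o > n / 2] - n; o
  })
  keep <- lapply(seq_len(3L), function(ax) abs(off[[ax]]) <= max_shift)
  cc_sub <- cc[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  idx <- arrayInd(which.max(cc_sub), dim(cc_sub))
  vapply(seq_len(3L), function(ax) off[[ax]][keep[[ax]]][idx[ax]],
         numeric(1))
}

downsample2 <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- dim(vol)
  dn <- d %/% factor
  v <- unclass(vol)[seq_len(dn[1] * factor), seq_len(dn[2] * factor),
                    seq_len(dn[3] * factor), drop = FALSE]
  dim(v) <- c(factor, dn[1], factor, dn[2], factor, dn[3])
  v <- apply(v, c(2L, 4L, 6L), mean)
  vol3d(v, voxel_size = voxel_size(vol) * factor)
}

nmi_objective <- function(par, ref, mov, bins, interp = 0L) {
  res <- rigid_resample(mov, par[4:6], par[1:3], interp = interp)
  inside <- !attr(res, "outside")
  -nmi_value(as.numeric(ref)[inside], as.numeric(res)[inside], bins)
}

# NMI on a partial-volume (linearly weighted) joint histogram; hard
# binning makes the metric jagged under sub-voxel shifts
nmi_value <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ca <- (a - ra[1]) / diff(ra) * (bins - 1L) + 1
  cb <- (b - rb[1]) / diff(rb) * (bins - 1L) + 1
  ia <- pmin(floor(ca), bins - 1L); fa <- ca - ia
  ib <- pmin(floor(cb), bins - 1L); fb <- cb - ib
  idx <- c(ia + bins * (ib - 1L), ia + 1L + bins * (ib - 1L),
           ia + bins * ib, ia + 1L + bins * ib)
  w <- c((1 - fa) * (1 - fb), fa * (1 - fb), (1 - fa) * fb, fa * fb)
  jt <- rowsum(w, idx)
  p <- as.numeric(jt) / sum(jt)
  pm <- matrix(0, bins, bins)
  pm[as.integer(rownames(jt))] <- p
  pa <- rowSums(pm)
  pb <- colSums(pm)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (ent(pa) + ent(pb)) / max(ent(p), 1e-12)
}
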