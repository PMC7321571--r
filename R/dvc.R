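#' Sub-volume interrogation grid
#'
#' Lays out cubic sub-volumes of a given edge length over a volume,
#' symmetric about the image center. Node spacing is
#' `size * (1 - overlap)` voxels; every sub-volume fits entirely inside
#' the image.
#'
#' @param shape volume dimensions in voxels (3 integers).
#' @param size sub-volume edge length in voxels.
#' @param overlap overlap fraction in `[0, 1)`; 0 tiles sub-volumes edge
#'   to edge.
#' @return object of class `dvc_grid` with per-axis sub-volume start
#'   indices and node centers (voxel coordinates, x fastest).
#' @examples
#' g <- build_grid(c(96, 96, 96), size = 48, overlap = 0)
#' g$n  # 2 x 2 x 2 nodes
#' @export
build_grid <- function(shape, size, overlap = 0) {
  shape <- as.integer(shape)
  size <- as.integer(size)
  if (length(shape) != 3L) stop("`shape` must have length 3")
  if (size > min(shape)) stop("sub-volume size exceeds an image dimension")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  spacing <- max(1L, as.integer(round(size * (1 - overlap))))
  n <- pmax(1L, (shape - size) %/% spacing + 1L)
  extent <- (n - 1L) * spacing + size
  start0 <- (shape - extent) %/% 2L + 1L
  starts <- lapply(1:3, function(ax)
    start0[ax] + (seq_len(n[ax]) - 1L) * spacing)
  axes <- lapply(1:3, function(ax) starts[[ax]] + (size - 1) / 2)
  centers <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]],
                                   z = axes[[3]]))
  dimnames(centers) <- NULL
  structure(list(shape = shape, size = size, spacing = spacing,
                 overlap = overlap, n = n, starts = starts, axes = axes,
                 centers = centers),
            class = "dvc_grid")
}

#' @export
print.dvc_grid <- function(x, ...) {
  cat(sprintf("<dvc_grid> %d x %d x %d nodes, sub-volume %d vox, spacing %d vox\n",
              x$n[1], x$n[2], x$n[3], x$size, x$spacing))
  invisible(x)
}

new_dvc_field <- function(grid, u, cc, valid) {
  structure(list(grid = grid, u = u, cc = cc, valid = valid),
            class = "dvc_field")
}

#' @export
print.dvc_field <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<dvc_field> %d nodes (%d valid), sub-volume %d vox\n",
              nrow(x$u), nv, x$grid$size))
  if (nv > 0)
    cat(sprintf("  mean |u| (vox): %.4f | mean cc: %.4f\n",
                mean(sqrt(rowSums(x$u[x$valid, , drop = FALSE]^2))),
                mean(x$cc[x$valid])))
  invisible(x)
}

#' Single correlation pass over a sub-volume grid
#'
#' For each grid node, the reference sub-volume is matched in the deformed
#' volume by zero-normalized cross-correlation (ZNCC), computed over a
#' search window centered on the (interpolated and rounded) predictor
#' displacement. The integer peak is located FFT-accelerated, then refined
#' per axis by a 3-point Gaussian fit of the correlation peak (log-parabola
#' fallback when a neighboring value is non-positive). Nodes whose peak
#' lies on the search-window border, whose sub-volume has zero variance, or
#' whose peak ZNCC falls below `cc_min` are flagged invalid.
#'
#' @param reference,deformed [vol3d] volumes of equal shape.
#' @param grid a [build_grid()] layout.
#' @param predictor optional `dvc_field` from a coarser pass; its
#'   displacements seed the search-window centers.
#' @param search search radius in voxels; defaults to half the sub-volume
#'   size without a predictor and 4 voxels with one.
#' @param cc_min validity threshold on the peak correlation coefficient.
#'
#' @details Volumes carrying an `outside` attribute (set by
#' [apply_affine_deformation()] for voxels resampled from outside the
#' input domain) are masked automatically: a node whose sub-volume
#' overlaps a flagged voxel in either volume is invalidated rather than
#' correlated against padding.
#'
#' @return a `dvc_field` (per-node displacement `u` in voxels, correlation
#'   coefficient `cc`, validity flag).
#' @export
correlate_pass <- function(reference, deformed, grid, predictor = NULL,
                           search = NULL, cc_min = 0.1) {
  stopifnot(inherits(reference, "vol3d"), inherits(deformed, "vol3d"))
  if (!all(dim(reference) == dim(deformed)))
    stop("reference and deformed volumes must share a shape")
  ex_ref <- attr(reference, "outside")
  ex_def <- attr(deformed, "outside")
  ex_ref_sat <- if (!is.null(ex_ref) && any(ex_ref))
    integral_image(ex_ref) else NULL
  ex_def_sat <- if (!is.null(ex_def) && any(ex_def))
    integral_image(ex_def) else NULL
  if (is.null(search))
    search <- if (is.null(predictor)) grid$size %/% 2L else 4L
  search <- max(1L, as.integer(search))
  s <- grid$size
  d <- dim(reference)
  nn <- prod(grid$n)
  pred_u <- predictor_at(predictor, grid)

  ref <- unclass(reference); attributes(ref) <- list(dim = d)
  def <- unclass(deformed); attributes(def) <- list(dim = d)

  u <- matrix(NA_real_, nn, 3L)
  cc <- rep(NA_real_, nn)
  valid <- rep(FALSE, nn)

  node <- 0L
  for (kz in seq_len(grid$n[3])) for (ky in seq_len(grid$n[2]))
    for (kx in seq_len(grid$n[1])) {
      node <- node + 1L
      st <- c(grid$starts[[1]][kx], grid$starts[[2]][ky],
              grid$starts[[3]][kz])
      tmpl <- ref[st[1]:(st[1] + s - 1L), st[2]:(st[2] + s - 1L),
                  st[3]:(st[3] + s - 1L)]
      mt <- mean(tmpl)
      t0 <- tmpl - mt
      ssq <- sum(t0 * t0)
      # flat sub-volume: invalid, not an error. The floor is a relative
      # contrast of 1e-4 of the local gray level -- patterns below it are
      # indistinguishable from arithmetic ripple and carry no signal
      if (ssq <= s^3 * (1e-4 * (abs(mt) + 1))^2) next

      p <- round(pred_u[node, ])
      p <- pmin(pmax(p, 1L - st), d - s + 1L - st)  # keep template window inside
      # mask sub-volumes overlapping out-of-domain (flagged) voxels
      if (!is.null(ex_ref_sat) && box_count(ex_ref_sat, st, s) > 0) next
      if (!is.null(ex_def_sat) && box_count(ex_def_sat, st + p, s) > 0)
        next
      m_lo <- pmin(search, st + p - 1L)
      m_hi <- pmin(search, d - (st + p + s - 1L))
      ws <- st + p - m_lo
      L <- s + m_lo + m_hi
      W <- def[ws[1]:(ws[1] + L[1] - 1L), ws[2]:(ws[2] + L[2] - 1L),
               ws[3]:(ws[3] + L[3] - 1L)]

      ncc <- zncc_map(t0, ssq, W, s)
      pk <- peak_select(ncc, m_lo, p)
      if (is.null(pk)) next
      peak_cc <- ncc[pk[1], pk[2], pk[3]]
      if (!is.finite(peak_cc) || peak_cc < cc_min) next
      # a peak on the border of the *requested* search range is unreliable
      # (the true peak may lie beyond); a peak against the image boundary
      # is the physical measurement limit and is kept
      on_border <- any((pk == 1L & m_lo == search) |
                       (pk == dim(ncc) & m_hi == search))
      if (on_border) next

      delta <- c(0, 0, 0)
      if (peak_cc < 1 - 1e-9) {
        for (ax in 1:3) {
          if (pk[ax] <= 1L || pk[ax] >= dim(ncc)[ax]) next
          idx <- pk; idx[ax] <- pk[ax] - 1L
          cm1 <- ncc[idx[1], idx[2], idx[3]]
          idx[ax] <- pk[ax] + 1L
          cp1 <- ncc[idx[1], idx[2], idx[3]]
          delta[ax] <- subvoxel_offset(cm1, peak_cc, cp1)
        }
      }
      u[node, ] <- p + (pk - 1L - m_lo) + delta
      cc[node] <- peak_cc
      valid[node] <- TRUE
    }
  new_dvc_field(grid, u, cc, valid)
}

#' Multipass digital volume correlation
#'
#' The central estimator: tracks cubic sub-volumes between a reference and
#' a deformed volume through a sequence of strictly decreasing sub-volume
#' sizes, each pass seeded by trilinear interpolation of the previous
#' pass's displacement field (the multipass predictor scheme). The default
#' size sequence reaches a final 48-voxel sub-volume via 80-72-64-56
#' predictors. Returns a fitted object with the final displacement field;
#' use [strain()] for the strain tensor field, and the usual
#' `print`/`summary`/`plot`/`predict`/`residuals` methods.
#'
#' @param reference,deformed [vol3d] volumes of equal shape.
#' @param sizes strictly decreasing sub-volume edge lengths in voxels; a
#'   single size gives a single-pass analysis.
#' @param overlap node overlap fraction of the final pass (and all
#'   passes).
#' @param cc_min validity threshold on the correlation coefficient.
#' @param search_coarse search radius of the first pass (default: half the
#'   first sub-volume size).
#' @param search_fine search radius of predictor-seeded passes (voxels).
#' @param truth optional [affine_deformation()] ground truth; stored for
#'   [residuals.dvc()].
#' @return object of class `dvc`.
#' @examples
#' \donttest{
#' ref <- speckle_volume(c(64, 64, 64), seed = 1)
#' def <- apply_affine_deformation(ref,
#'   affine_deformation(diag(c(1, 1, 0.99)), image_center(ref)))
#' fit <- dvc(ref, def, sizes = c(48, 32), overlap = 0.5)
#' summary(fit)
#' }
#' @export
dvc <- function(reference, deformed, sizes = c(80L, 72L, 64L, 56L, 48L),
                overlap = 0, cc_min = 0.1, search_coarse = NULL,
                search_fine = 4L, truth = NULL) {
  if (length(sizes) == 0L) stop("`sizes` must not be empty")
  sizes <- as.integer(sizes)
  if (length(sizes) > 1L && any(diff(sizes) >= 0L))
    stop("`sizes` must be strictly descending")
  if (max(sizes) > min(dim(reference)))
    stop("largest sub-volume exceeds an image dimension")
  field <- NULL
  n_valid <- integer(length(sizes))
  for (i in seq_along(sizes)) {
    grid <- build_grid(dim(reference), sizes[i], overlap)
    field <- correlate_pass(reference, deformed, grid, predictor = field,
                            search = if (i == 1L) search_coarse
                                     else search_fine,
                            cc_min = cc_min)
    n_valid[i] <- sum(field$valid)
  }
  structure(list(field = field, sizes = sizes, overlap = overlap,
                 cc_min = cc_min, n_valid_per_pass = n_valid,
                 voxel_size = voxel_size(reference), truth = truth,
                 call = match.call()),
            class = "dvc")
}

#' Restrict a displacement field to one tissue region
#'
#' Keeps only the nodes whose entire sub-volume lies within voxels of the
#' given label (strict inclusion); all other nodes are invalidated. Nodes
#' straddling the cartilage-mineralized interface therefore belong to
#' neither region.
#'
#' @param field a `dvc_field` (or a fitted `dvc` object, whose final field
#'   is used).
#' @param labels a [region_labels()] map covering the field's image.
#' @param region label value: 0 background/marrow, 1 articular cartilage,
#'   2 mineralized tissue.
#' @return the field with the validity mask intersected with strict
#'   region inclusion.
#' @export
mask_by_region <- function(field, labels, region) {
  if (inherits(field, "dvc")) field <- field$field
  stopifnot(inherits(field, "dvc_field"), inherits(labels, "region_labels"))
  if (!region %in% c(0L, 1L, 2L)) stop("unknown region label: ", region)
  if (!all(dim(labels) == field$grid$shape))
    stop("label map does not cover the field's image")
  g <- field$grid
  sat <- integral_image(unclass(labels) == as.integer(region))
  s <- g$size
  inside <- rep(FALSE, nrow(field$u))
  node <- 0L
  for (kz in seq_len(g$n[3])) for (ky in seq_len(g$n[2]))
    for (kx in seq_len(g$n[1])) {
      node <- node + 1L
      st <- c(g$starts[[1]][kx], g$starts[[2]][ky], g$starts[[3]][kz])
      cnt <- box_count(sat, st, s)
      inside[node] <- (cnt == s^3)
    }
  new_dvc_field(g, field$u, field$cc, field$valid & inside)
}

# ---- internal ---------------------------------------------------------

# ZNCC map over all window offsets: t0 is the mean-subtracted template
# (sum of squares ssq), W the search window, s the template edge length.
zncc_map <- function(t0, ssq, W, s) {
  L <- dim(W)
  W <- W - mean(W)      # zero-mean window tames cancellation in the sums
  tp <- array(0, L)
  tp[1:s, 1:s, 1:s] <- t0
  num <- Re(stats::fft(stats::fft(W) * Conj(stats::fft(tp)),
                       inverse = TRUE)) / prod(L)
  nf <- L - s + 1L
  num <- num[1:nf[1], 1:nf[2], 1:nf[3], drop = FALSE]
  S1 <- running_box_sum(W, s)
  S2 <- running_box_sum(W * W, s)
  varw <- pmax(S2 - S1 * S1 / s^3, 0)
  den <- sqrt(ssq * varw)
  ncc <- num / pmax(den, 1e-300)
  # windows with vanishing texture relative to the template carry no
  # correlation information
  ncc[varw < 1e-6 * ssq] <- 0
  array(pmin(pmax(ncc, -1), 1), nf)
}

# integer peak with the documented tie-break: among equal maxima choose the
# smallest displacement magnitude, then lexicographic order
peak_select <- function(ncc, m_lo, p) {
  mx <- max(ncc)
  if (!is.finite(mx)) return(NULL)
  cand <- which(ncc >= mx - 0)          # exact ties
  if (length(cand) > 1L) {
    ci <- arrayInd(cand, dim(ncc))
    disp <- sweep(ci, 2L, 1L + m_lo) + matrix(p, length(cand), 3L,
                                              byrow = TRUE)
    mag <- rowSums(disp^2)
    ord <- order(mag, disp[, 1], disp[, 2], disp[, 3])
    ci[ord[1L], ]
  } else {
    as.integer(arrayInd(cand, dim(ncc)))
  }
}

# 3-point sub-voxel peak: Gaussian fit on log-values, parabola fallback
subvoxel_offset <- function(cm1, c0, cp1) {
  if (is.finite(cm1) && is.finite(cp1) && cm1 > 0 && cp1 > 0 && c0 > 0) {
    den <- log(cm1) + log(cp1) - 2 * log(c0)
    if (den >= 0) return(0)
    delta <- 0.5 * (log(cm1) - log(cp1)) / den
  } else {
    den <- cm1 + cp1 - 2 * c0
    if (den >= 0) return(0)
    delta <- 0.5 * (cm1 - cp1) / den
  }
  max(-1, min(1, delta))
}

# sliding box sums of edge s along all axes: output dims = dim(v) - s + 1
running_box_sum <- function(v, s) {
  for (ax in 1:3) {
    n <- dim(v)[ax]
    cs <- apply_cumsum0(v, ax)               # leading zero slab
    hi <- index_axis(cs, (s:n) + 1L, ax)
    lo <- index_axis(cs, (0:(n - s)) + 1L, ax)
    v <- hi - lo
  }
  v
}

integral_image <- function(mask) {
  v <- array(as.numeric(mask), dim(mask))
  for (ax in 1:3) v <- apply_cumsum0(v, ax)
  v
}

# cumulative sum with a leading zero slab along axis ax
apply_cumsum0 <- function(v, ax) {
  d <- dim(v)
  perm <- c(ax, setdiff(1:3, ax))
  vp <- aperm(v, perm)
  m <- matrix(vp, d[ax])
  m <- rbind(0, apply(m, 2L, cumsum))
  vp <- array(m, c(d[ax] + 1L, dim(vp)[2], dim(vp)[3]))
  aperm(vp, order(perm))
}

# count of TRUE voxels in the box [st, st + s - 1] from an integral image
box_count <- function(sat, st, s) {
  a <- st; b <- st + s
  sat[b[1], b[2], b[3]] - sat[a[1], b[2], b[3]] - sat[b[1], a[2], b[3]] -
    sat[b[1], b[2], a[3]] + sat[a[1], a[2], b[3]] +
    sat[a[1], b[2], a[3]] + sat[b[1], a[2], a[3]] -
    sat[a[1], a[2], a[3]]
}

# interpolate a (possibly coarser) predictor field onto grid node centers
predictor_at <- function(predictor, grid) {
  nn <- prod(grid$n)
  if (is.null(predictor)) return(matrix(0, nn, 3L))
  stopifnot(inherits(predictor, "dvc_field"))
  pu <- predictor$u
  if (any(!predictor$valid)) {
    # predictor-only infill: invalid coarse nodes take the valid mean
    if (any(predictor$valid)) {
      fill <- colMeans(pu[predictor$valid, , drop = FALSE])
    } else fill <- c(0, 0, 0)
    pu[!predictor$valid, ] <- matrix(fill, sum(!predictor$valid), 3L,
                                     byrow = TRUE)
  }
  out <- matrix(0, nn, 3L)
  for (comp in 1:3) {
    va <- array(pu[, comp], predictor$grid$n)
    out[, comp] <- trilinear_nodes(predictor$grid$axes, va, grid$centers)
  }
  out
}

# trilinear interpolation of nodal values at points, clamped to the hull
trilinear_nodes <- function(axes, values, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  np <- nrow(pts)
  i0 <- matrix(1L, np, 3L)
  f <- matrix(0, np, 3L)
  for (ax in 1:3) {
    a <- axes[[ax]]
    if (length(a) == 1L) next
    x <- pmin(pmax(pts[, ax], a[1]), a[length(a)])
    i <- findInterval(x, a, rightmost.closed = TRUE)
    i <- pmax(1L, pmin(i, length(a) - 1L))
    i0[, ax] <- i
    f[, ax] <- (x - a[i]) / (a[i + 1L] - a[i])
  }
  n <- dim(values)
  out <- numeric(np)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ii <- pmin(i0[, 1] + dx, n[1]); jj <- pmin(i0[, 2] + dy, n[2])
    kk <- pmin(i0[, 3] + dz, n[3])
    term <- w * values[cbind(ii, jj, kk)]
    term[w == 0] <- 0      # zero-weight corners must not propagate NA
    out <- out + term
  }
  out
}
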