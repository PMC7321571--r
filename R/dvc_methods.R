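#' Strain tensor field of a fitted DVC object
#'
#' @param x a fitted [dvc()] object or a `dvc_field`.
#' @param ... unused.
#' @return a `strain_field`; see [compute_strain()].
#' @export
strain <- function(x, ...) UseMethod("strain")

#' @export
strain.dvc <- function(x, ...) compute_strain(x$field)

#' @export
strain.dvc_field <- function(x, ...) compute_strain(x)

#' @export
print.dvc <- function(x, ...) {
  cat("Multipass digital volume correlation\n")
  cat(sprintf("  passes (sub-volume vox): %s | overlap %.2f | cc_min %.2f\n",
              paste(x$sizes, collapse = "-"), x$overlap, x$cc_min))
  print(x$field)
  invisible(x)
}

#' @export
summary.dvc <- function(object, ...) {
  f <- object$field
  v <- f$valid
  st <- compute_strain(f)
  out <- list(sizes = object$sizes, n_valid_per_pass = object$n_valid_per_pass,
              n_nodes = length(v), n_valid = sum(v),
              cc = if (any(v)) summary(f$cc[v]) else NULL,
              u_mean = if (any(v)) colMeans(f$u[v, , drop = FALSE]) else NULL,
              voxel_size = object$voxel_size,
              strain = summary(st))
  class(out) <- "summary.dvc"
  out
}

#' @export
print.summary.dvc <- function(x, ...) {
  cat("Multipass DVC fit\n")
  cat(sprintf("  sizes: %s (valid nodes per pass: %s)\n",
              paste(x$sizes, collapse = "-"),
              paste(x$n_valid_per_pass, collapse = "-")))
  cat(sprintf("  final grid: %d nodes, %d valid\n", x$n_nodes, x$n_valid))
  if (!is.null(x$u_mean)) {
    cat(sprintf("  mean displacement (vox): %s\n",
                paste(signif(x$u_mean, 4), collapse = ", ")))
    cat("  correlation coefficient:\n")
    print(x$cc)
  }
  print(x$strain)
  invisible(x)
}

#' Predict displacement at arbitrary voxel coordinates
#'
#' Trilinear interpolation of the fitted nodal displacement field.
#' Invalid nodes propagate NA.
#'
#' @param object a fitted [dvc()] object.
#' @param coords n x 3 matrix of voxel coordinates (default: the grid
#'   node centers).
#' @param units `"voxels"` or `"um"`.
#' @param ... unused.
#' @return n x 3 matrix of displacements.
#' @export
predict.dvc <- function(object, coords = NULL,
                        units = c("voxels", "um"), ...) {
  units <- match.arg(units)
  f <- object$field
  if (is.null(coords)) coords <- f$grid$centers
  coords <- matrix(as.numeric(coords), ncol = 3L)
  u <- f$u
  u[!f$valid, ] <- NA_real_
  out <- vapply(1:3, function(comp)
    trilinear_nodes(f$grid$axes, array(u[, comp], f$grid$n), coords),
    numeric(nrow(coords)))
  out <- matrix(out, ncol = 3L, dimnames = list(NULL, c("ux", "uy", "uz")))
  if (units == "um") out <- out * object$voxel_size
  out
}

#' Displacement residuals against a known deformation
#'
#' Subtracts the analytic displacement of the ground-truth affine map
#' (stored at fit time or supplied here) from the measured nodal
#' displacements.
#'
#' @param object a fitted [dvc()] object.
#' @param truth an [affine_deformation()]; defaults to the one stored in
#'   the fit (zero displacement if none).
#' @param ... unused.
#' @return n x 3 matrix of residuals in voxels (NA on invalid nodes).
#' @export
residuals.dvc <- function(object, truth = NULL, ...) {
  f <- object$field
  if (is.null(truth)) truth <- object$truth
  expected <- if (is.null(truth)) matrix(0, nrow(f$u), 3L)
              else affine_displacement(truth, f$grid$centers)
  r <- f$u - expected
  r[!f$valid, ] <- NA_real_
  colnames(r) <- c("ux", "uy", "uz")
  r
}

#' Mean strain-tensor components of a fitted DVC object
#'
#' @param object a fitted [dvc()] object.
#' @param ... unused.
#' @return named length-6 vector: mean of each strain component over the
#'   valid nodes, in microstrain.
#' @export
coef.dvc <- function(object, ...) {
  st <- compute_strain(object$field)
  colMeans(st$eps[st$valid, , drop = FALSE])
}

#' Plot a mid-grid slice of a fitted DVC field
#'
#' @param x a fitted [dvc()] object.
#' @param what `"uz"`, `"ux"`, `"uy"` or `"cc"`.
#' @param slice node-grid z index (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.dvc <- function(x, what = c("uz", "ux", "uy", "cc"), slice = NULL,
                     ...) {
  what <- match.arg(what)
  f <- x$field
  g <- f$grid
  if (is.null(slice)) slice <- max(1L, g$n[3] %/% 2L)
  vals <- switch(what, ux = f$u[, 1], uy = f$u[, 2], uz = f$u[, 3],
                 cc = f$cc)
  vals[!f$valid] <- NA_real_
  va <- array(vals, g$n)[, , slice]
  graphics::image(g$axes[[1]], g$axes[[2]], va,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  main = sprintf("%s, node slice z = %g vox", what,
                                 g$axes[[3]][slice]), ...)
  invisible(x)
}

#' Plot a mid-grid slice of a strain field
#'
#' @param x a `strain_field`.
#' @param component tensor component or `"eq"`.
#' @param slice node-grid z index (default: middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.strain_field <- function(x, component = "eq", slice = NULL, ...) {
  g <- x$grid
  if (is.null(slice)) slice <- max(1L, g$n[3] %/% 2L)
  vals <- if (component == "eq") equivalent_strain(x)
          else x$eps[, component]
  va <- array(vals, g$n)[, , slice]
  graphics::image(g$axes[[1]], g$axes[[2]], va,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (voxel)", ylab = "y (voxel)",
                  main = sprintf("%s (microstrain), node slice z = %g vox",
                                 component, g$axes[[3]][slice]), ...)
  invisible(x)
}

#' Interior nodes of a measurement grid
#'
#' Nodes that are not on the boundary of the node grid on any axis;
#' boundary nodes rely on one-sided gradients and partially framed search
#' windows, so summary statistics are usually restricted to the interior.
#'
#' @param grid a `dvc_grid` (or a `dvc`/`dvc_field`/`strain_field`
#'   object).
#' @return logical vector over the grid nodes (x fastest).
#' @export
interior_nodes <- function(grid) {
  if (inherits(grid, "dvc")) grid <- grid$field$grid
  if (inherits(grid, "dvc_field") || inherits(grid, "strain_field"))
    grid <- grid$grid
  stopifnot(inherits(grid, "dvc_grid"))
  idx <- expand.grid(x = seq_len(grid$n[1]), y = seq_len(grid$n[2]),
                     z = seq_len(grid$n[3]))
  ok <- rep(TRUE, nrow(idx))
  for (ax in 1:3) {
    if (grid$n[ax] >= 3L)
      ok <- ok & idx[[ax]] > 1L & idx[[ax]] < grid$n[ax]
  }
  ok
}
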