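#' Affine deformation of a volume
#'
#' Describes the linear map `y = A (x - c) + c` about a fixed point `c`
#' (in voxel coordinates). The axial virtual-compression protocol uses
#' `A = diag(1, 1, 1 - s)` about the image center, which imposes a uniform
#' nominal strain of `-s` along the third (z, compression) axis.
#'
#' @param matrix invertible 3x3 linear map (dimensionless).
#' @param center fixed point, voxel coordinates (length 3). Use
#'   [image_center()] for the symmetric convention.
#' @return object of class `affine_deformation`.
#' @examples
#' d <- affine_deformation(diag(c(1, 1, 0.99)), center = c(120.5, 120.5, 120.5))
#' @export
affine_deformation <- function(matrix, center) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3L, 3L))) stop("`matrix` must be 3x3")
  if (abs(det(matrix)) < 1e-12) stop("`matrix` is singular")
  if (length(center) != 3L) stop("`center` must have length 3")
  structure(list(matrix = matrix, center = as.numeric(center)),
            class = "affine_deformation")
}

#' @export
print.affine_deformation <- function(x, ...) {
  cat("<affine_deformation> about center (",
      paste(signif(x$center, 6), collapse = ", "), ")\n", sep = "")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Center of a volume in voxel coordinates
#'
#' Returns `(dim + 1) / 2`, the point equidistant from the first and last
#' voxel centers; deformations about this point are symmetric with respect
#' to the image.
#'
#' @param vol a [vol3d] volume (or any object with a 3D `dim`).
#' @return numeric length-3 voxel coordinate.
#' @export
image_center <- function(vol) (dim(vol) + 1) / 2

#' Inverse of an affine deformation
#' @param d an [affine_deformation()].
#' @return the inverse deformation (same fixed point).
#' @export
invert_deformation <- function(d) {
  affine_deformation(solve(d$matrix), d$center)
}

#' Ground-truth displacement of voxel coordinates under an affine map
#'
#' For the map `y = A (x - c) + c` the displacement is
#' `u(x) = (A - I) (x - c)`; this is the analytic reference the synthetic
#' deformation protocol validates against.
#'
#' @param d an [affine_deformation()].
#' @param coords n x 3 matrix of voxel coordinates.
#' @return n x 3 matrix of displacements in voxels.
#' @export
affine_displacement <- function(d, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  sweep(coords, 2L, d$center) %*% t(d$matrix - diag(3))
}

#' Small-strain tensor of an affine deformation
#'
#' @param d an [affine_deformation()].
#' @return named length-6 vector (exx, eyy, ezz, exy, exz, eyz),
#'   dimensionless; the symmetric part of `A - I`.
#' @export
affine_strain <- function(d) {
  E <- (d$matrix + t(d$matrix)) / 2 - diag(3)
  c(exx = E[1, 1], eyy = E[2, 2], ezz = E[3, 3],
    exy = E[1, 2], exz = E[1, 3], eyz = E[2, 3])
}

#' Resample a volume under an affine deformation
#'
#' The output at voxel `y` is sampled from the input at
#' `x = A^-1 (y - c) + c` (inverse mapping of voxel centers), by Lanczos
#' interpolation with kernel order a = 3 or trilinear interpolation.
#' Voxels whose source point falls outside the input domain are set to 0
#' and flagged in the `outside` attribute (a logical array) so downstream
#' correlation can mask them.
#'
#' @param vol a [vol3d] volume.
#' @param d an [affine_deformation()].
#' @param interp `"lanczos"` (order 3) or `"linear"`.
#' @return deformed [vol3d] of the same shape, with an `outside` attribute.
#' @export
apply_affine_deformation <- function(vol, d, interp = c("lanczos", "linear")) {
  stopifnot(inherits(vol, "vol3d"), inherits(d, "affine_deformation"))
  interp <- match.arg(interp)
  res <- cpp_affine_resample(as.numeric(vol), dim(vol),
                             solve(d$matrix), d$center, c(0, 0, 0),
                             if (interp == "lanczos") 1L else 0L)
  out <- array(res$values, dim = dim(vol))
  out <- vol3d(out, voxel_size = voxel_size(vol))
  attr(out, "outside") <- array(!res$inside, dim = dim(vol))
  out
}

# rigid resample: y = R (x - c) + c + t; used by the registration stage
rigid_resample <- function(vol, rotation, translation, interp = 0L) {
  cen <- image_center(vol)
  R <- rotation_matrix(rotation)
  res <- cpp_affine_resample(as.numeric(vol), dim(vol), solve(R), cen,
                             as.numeric(translation), as.integer(interp))
  out <- vol3d(array(res$values, dim = dim(vol)), voxel_size = voxel_size(vol))
  attr(out, "outside") <- array(!res$inside, dim = dim(vol))
  out
}

# intrinsic rotations about x, y, z axes composed as Rz Ry Rx
rotation_matrix <- function(angles) {
  a <- as.numeric(angles)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}
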