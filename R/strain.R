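#' Small-strain tensor field from a displacement field
#'
#' Computes `eps_ij = (du_i/dx_j + du_j/dx_i) / 2` by central differences
#' on the node grid, falling back to one-sided differences at grid borders
#' and beside invalid nodes; nodes without enough valid neighbors along
#' some axis are invalidated. Strains are reported in microstrain.
#'
#' Because the scheme is linear-exact, an affine displacement field is
#' recovered with zero discretization error.
#'
#' @param field a `dvc_field` (or fitted `dvc` object).
#' @return object of class `strain_field`: per-node tensor components
#'   `exx, eyy, ezz, exy, exz, eyz` in microstrain plus a validity flag on
#'   the same grid.
#' @export
compute_strain <- function(field) {
  if (inherits(field, "dvc")) field <- field$field
  stopifnot(inherits(field, "dvc_field"))
  g <- field$grid
  if (any(g$n < 2L))
    stop("degenerate grid: need at least 2 nodes per axis for gradients")
  h <- g$spacing
  vmask <- array(field$valid, g$n)
  grads <- vector("list", 9L)   # du_i/dx_j, i fast
  for (i in 1:3) {
    ui <- array(field$u[, i], g$n)
    ui[!vmask] <- NA_real_
    for (j in 1:3) {
      grads[[(j - 1L) * 3L + i]] <- grad_axis(ui, j, h)
    }
  }
  gv <- function(i, j) grads[[(j - 1L) * 3L + i]]
  eps <- cbind(exx = as.numeric(gv(1, 1)),
               eyy = as.numeric(gv(2, 2)),
               ezz = as.numeric(gv(3, 3)),
               exy = as.numeric((gv(1, 2) + gv(2, 1)) / 2),
               exz = as.numeric((gv(1, 3) + gv(3, 1)) / 2),
               eyz = as.numeric((gv(2, 3) + gv(3, 2)) / 2)) * 1e6
  valid <- field$valid & apply(is.finite(eps), 1L, all)
  eps[!valid, ] <- NA_real_
  structure(list(grid = g, eps = eps, valid = valid,
                 cc = field$cc, u = field$u),
            class = "strain_field")
}

# gradient along axis ax with spacing h: central where both neighbors are
# finite, one-sided otherwise, NA when no finite neighbor exists
grad_axis <- function(ua, ax, h) {
  n <- dim(ua)[ax]
  up <- index_axis(ua, pmin(seq_len(n) + 1L, n), ax)
  um <- index_axis(ua, pmax(seq_len(n) - 1L, 1L), ax)
  at_hi <- sweep_axis(array(0, dim(ua)), as.numeric(seq_len(n) == n), ax,
                      `+`) > 0
  at_lo <- sweep_axis(array(0, dim(ua)), as.numeric(seq_len(n) == 1L), ax,
                      `+`) > 0
  up[at_hi] <- NA_real_   # neighbor beyond the border does not exist
  um[at_lo] <- NA_real_
  central <- (up - um) / (2 * h)
  fwd <- (up - ua) / h
  bwd <- (ua - um) / h
  out <- central
  use_fwd <- !is.finite(central) & is.finite(fwd)
  out[use_fwd] <- fwd[use_fwd]
  use_bwd <- !is.finite(out) & is.finite(bwd)
  out[use_bwd] <- bwd[use_bwd]
  out
}

#' Deviatoric components and engineering shears of a strain field
#'
#' The deviatoric normal components are
#' `e_ii = (2/3) eps_ii - (1/3) eps_jj - (1/3) eps_kk` and the engineering
#' shears `gamma_ij = 2 eps_ij`.
#'
#' @param strain a `strain_field` (or its `eps` matrix, microstrain).
#' @return matrix with columns `e_xx, e_yy, e_zz, g_xy, g_xz, g_yz`
#'   (microstrain).
#' @export
deviatoric_strain <- function(strain) {
  eps <- if (inherits(strain, "strain_field")) strain$eps else strain
  eps <- matrix(eps, ncol = 6L)
  tr3 <- (eps[, 1] + eps[, 2] + eps[, 3]) / 3
  cbind(e_xx = eps[, 1] - tr3,
        e_yy = eps[, 2] - tr3,
        e_zz = eps[, 3] - tr3,
        g_xy = 2 * eps[, 4],
        g_xz = 2 * eps[, 5],
        g_yz = 2 * eps[, 6])
}

#' Von Mises equivalent strain
#'
#' `eps_eq = (2/3) sqrt( 3 (e_xx^2 + e_yy^2 + e_zz^2) / 2
#'  + 3 (g_xy^2 + g_xz^2 + g_yz^2) / 4 )`, a nonnegative scalar built from
#' the deviatoric normal components and engineering shears; hydrostatic
#' strain states map to zero.
#'
#' @param strain a `strain_field`, or an n x 6 matrix / length-6 vector of
#'   tensor components `(exx, eyy, ezz, exy, exz, eyz)` in microstrain.
#' @return per-node equivalent strain in microstrain (NA on invalid
#'   nodes).
#' @examples
#' equivalent_strain(c(0, 0, -10000, 0, 0, 0))  # 6666.7 microstrain
#' @export
equivalent_strain <- function(strain) {
  dev <- deviatoric_strain(strain)
  unname((2 / 3) * sqrt(3 * (dev[, 1]^2 + dev[, 2]^2 + dev[, 3]^2) / 2 +
                        3 * (dev[, 4]^2 + dev[, 5]^2 + dev[, 6]^2) / 4))
}

#' Interpolate a nodal strain component onto the voxel grid
#'
#' Trilinear interpolation from the measurement grid onto voxel centers;
#' voxels outside the convex hull of the nodes, or whose surrounding nodes
#' are invalid, carry NA.
#'
#' @param strain a `strain_field`.
#' @param shape output voxel dimensions (default: the field's image
#'   shape).
#' @param component one of `"exx", "eyy", "ezz", "exy", "exz", "eyz",
#'   "eq"`.
#' @return a [vol3d] scalar map in microstrain with NA as no-data.
#' @export
interpolate_to_image <- function(strain, shape = NULL, component = "eq") {
  stopifnot(inherits(strain, "strain_field"))
  g <- strain$grid
  if (is.null(shape)) shape <- g$shape
  vals <- if (component == "eq") equivalent_strain(strain)
          else if (component %in% colnames(strain$eps))
            strain$eps[, component]
          else stop("unknown component name: ", component)
  va <- array(vals, g$n)
  pts <- as.matrix(expand.grid(x = seq_len(shape[1]),
                               y = seq_len(shape[2]),
                               z = seq_len(shape[3])))
  out <- trilinear_nodes(g$axes, va, pts)
  hull <- rep(TRUE, nrow(pts))
  for (ax in 1:3) {
    a <- g$axes[[ax]]
    hull <- hull & pts[, ax] >= a[1] & pts[, ax] <= a[length(a)]
  }
  out[!hull] <- NA_real_
  vol3d(array(out, shape), voxel_size = 1)
}

#' @export
print.strain_field <- function(x, ...) {
  nv <- sum(x$valid)
  cat(sprintf("<strain_field> %d nodes (%d valid)\n", nrow(x$eps), nv))
  if (nv > 0) {
    m <- colMeans(x$eps[x$valid, , drop = FALSE])
    cat("  mean components (microstrain):\n")
    print(round(m, 1))
    cat(sprintf("  mean eps_eq: %.1f microstrain\n",
                mean(equivalent_strain(x)[x$valid])))
  }
  invisible(x)
}

#' @export
summary.strain_field <- function(object, ...) {
  v <- object$valid
  eq <- equivalent_strain(object)
  out <- list(n_nodes = length(v), n_valid = sum(v),
              mean = colMeans(object$eps[v, , drop = FALSE]),
              sd = apply(object$eps[v, , drop = FALSE], 2L, stats::sd),
              eq_mean = mean(eq[v]), eq_peak = max(eq[v]))
  class(out) <- "summary.strain_field"
  out
}

#' @export
print.summary.strain_field <- function(x, ...) {
  cat(sprintf("Strain field: %d/%d valid nodes\n", x$n_valid, x$n_nodes))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 1))
  cat(sprintf("eps_eq mean %.1f, max %.1f microstrain\n",
              x$eq_mean, x$eq_peak))
  invisible(x)
}
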