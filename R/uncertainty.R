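#' Zero-strain uncertainty test
#'
#' Correlates two repeated volumes of an undeformed specimen at each
#' requested sub-volume size and summarizes the apparent (error) strain
#' per tissue region. For each valid node `k` the scalar
#' `a_k = mean(|eps_c(k)|)` over the six strain components is formed;
#' MAER is the mean and SDER the standard deviation of `a_k` over the
#' nodes of a region (strict sub-volume inclusion). Any nonzero value is
#' measurement error, since the true strain is identically zero.
#'
#' @param vol1,vol2 registered [vol3d] volumes of the same shape (e.g.
#'   two consecutively acquired tomograms).
#' @param labels a [region_labels()] map.
#' @param sizes sub-volume edge lengths to sweep (voxels); each size runs
#'   as an independent single-pass analysis.
#' @param regions label values to report (default cartilage and
#'   mineralized).
#' @param overlap,cc_min passed to the correlation engine.
#' @param search search radius in voxels. The protocol operates on
#'   registered pairs whose displacements are at most a few voxels, so
#'   the default is a fixed 8-voxel window rather than the engine's
#'   half-sub-volume default.
#' @return an `uncertainty_report` data frame: one row per (region, size)
#'   with MAER, SDER (microstrain), `n_valid` and per-component mean/SD.
#'   Sizes at which a region has no valid node carry NA (absent), not
#'   zero.
#' @export
zero_strain_test <- function(vol1, vol2, labels, sizes = c(16, 32, 48, 64, 80),
                             regions = c(1L, 2L), overlap = 0,
                             cc_min = 0.1, search = 8L) {
  protocol_test(vol1, vol2, labels, sizes, regions, overlap, cc_min,
                search, truth = NULL, protocol = "zero_strain")
}

#' Create a synthetically deformed volume pair
#'
#' Applies the virtual axial compression protocol: an affine map
#' `diag(1, 1, 1 - strain_level)` symmetric about the image center,
#' resampled with Lanczos interpolation. The imposed nodal strain is
#' exactly `eps_zz = -strain_level` everywhere (e.g. -10000 microstrain at
#' the 1% level), giving a known analytic ground truth.
#'
#' @param vol a [vol3d] volume (the "second scan").
#' @param strain_level nominal compressive strain, in `(0, 0.05)`;
#'   default 1%.
#' @param interp interpolation for the virtual deformation.
#' @return list with `reference` (the input), `deformed` (the virtually
#'   compressed copy) and `deformation` (the [affine_deformation()]).
#' @export
make_synthetic_pair <- function(vol, strain_level = 0.01,
                                interp = c("lanczos", "linear")) {
  stopifnot(inherits(vol, "vol3d"))
  if (!(strain_level > 0 && strain_level < 0.05))
    stop("`strain_level` must lie in (0, 0.05)")
  interp <- match.arg(interp)
  d <- affine_deformation(diag(c(1, 1, 1 - strain_level)),
                          center = image_center(vol))
  deformed <- apply_affine_deformation(vol, d, interp = interp)
  list(reference = vol, deformed = deformed, deformation = d)
}

#' Synthetic-deformation uncertainty test
#'
#' As [zero_strain_test()], but correlating a volume against a copy
#' deformed by a known affine map; per-node errors are taken against the
#' analytic strain of that map, and the mean recovered axial strain
#' `eps_zz` per region is reported alongside MAER/SDER.
#'
#' @inheritParams zero_strain_test
#' @param vol2_deformed the virtually deformed copy (see
#'   [make_synthetic_pair()]).
#' @param truth the [affine_deformation()] used to create
#'   `vol2_deformed`.
#' @return an `uncertainty_report`; see [zero_strain_test()].
#' @export
synthetic_deformation_test <- function(vol1, vol2_deformed, truth, labels,
                                       sizes = c(16, 32, 48, 64, 80),
                                       regions = c(1L, 2L), overlap = 0,
                                       cc_min = 0.1, search = 8L) {
  stopifnot(inherits(truth, "affine_deformation"))
  protocol_test(vol1, vol2_deformed, labels, sizes, regions, overlap,
                cc_min, search, truth = truth, protocol = "synthetic")
}

protocol_test <- function(vol1, vol2, labels, sizes, regions, overlap,
                          cc_min, search, truth, protocol) {
  stopifnot(inherits(vol1, "vol3d"), inherits(vol2, "vol3d"),
            inherits(labels, "region_labels"))
  if (!all(dim(vol1) == dim(vol2))) stop("volumes must share a shape")
  if (length(sizes) == 0L) stop("`sizes` must not be empty")
  eps_true <- if (is.null(truth)) rep(0, 6L)
              else affine_strain(truth) * 1e6
  rows <- list()
  for (s in sort(as.integer(sizes))) {
    entry <- tryCatch({
      fit <- dvc(vol1, vol2, sizes = s, overlap = overlap,
                 cc_min = cc_min, search_coarse = search)
      st <- compute_strain(fit$field)
      lapply(regions, function(reg) {
        masked <- mask_by_region(fit$field, labels, reg)
        keep <- masked$valid & st$valid
        region_row(protocol, reg, s, st, keep, eps_true, truth)
      })
    }, error = function(e) {
      lapply(regions, function(reg)
        region_row(protocol, reg, s, NULL, logical(0), eps_true, truth))
    })
    rows <- c(rows, entry)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("uncertainty_report", "data.frame")
  rep
}

region_row <- function(protocol, region, size, st, keep, eps_true, truth) {
  region_name <- c("background", "cartilage", "mineralized")[region + 1L]
  base <- data.frame(protocol = protocol, region = region,
                     region_name = region_name, size = size,
                     MAER = NA_real_, SDER = NA_real_, n_valid = 0L)
  comp <- c("exx", "eyy", "ezz", "exy", "exz", "eyz")
  for (cn in comp) {
    base[[paste0("mean_", cn)]] <- NA_real_
    base[[paste0("sd_", cn)]] <- NA_real_
  }
  if (!is.null(truth)) base$mean_recovered_ezz <- NA_real_
  if (is.null(st) || !any(keep)) return(base)
  err <- sweep(st$eps[keep, , drop = FALSE], 2L, eps_true)
  a <- rowMeans(abs(err))
  base$MAER <- mean(a)
  base$SDER <- if (length(a) > 1L) stats::sd(a) else 0
  base$n_valid <- sum(keep)
  for (i in seq_along(comp)) {
    base[[paste0("mean_", comp[i])]] <- mean(st$eps[keep, i])
    base[[paste0("sd_", comp[i])]] <-
      if (sum(keep) > 1L) stats::sd(st$eps[keep, i]) else 0
  }
  if (!is.null(truth)) base$mean_recovered_ezz <- mean(st$eps[keep, 3L])
  base
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("Strain uncertainty report (%s protocol)\n",
              paste(unique(x$protocol), collapse = "/")))
  cols <- c("region_name", "size", "MAER", "SDER", "n_valid")
  if ("mean_recovered_ezz" %in% names(x))
    cols <- c(cols, "mean_recovered_ezz")
  df <- as.data.frame(x)[, cols]
  num <- vapply(df, is.numeric, TRUE) & names(df) != "size"
  df[num] <- lapply(df[num], function(v) round(v, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normalized frequency distribution of equivalent strain
#'
#' Histogram of equivalent-strain values with frequencies normalized to
#' sum to one; the peak is the center of the modal bin.
#'
#' @param values equivalent-strain values in microstrain (NAs dropped).
#' @param bin_width bin width in microstrain.
#' @return object of class `strain_histogram` with `mids`, `freq`,
#'   `peak` and `bin_width`.
#' @export
strain_histogram <- function(values, bin_width = 100) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to histogram")
  if (bin_width <= 0) stop("`bin_width` must be positive")
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(values) >= breaks[length(breaks)])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      right = FALSE)
  freq <- h$counts / sum(h$counts)
  structure(list(mids = h$mids, freq = freq,
                 peak = h$mids[which.max(h$counts)],
                 bin_width = bin_width, n = length(values)),
            class = "strain_histogram")
}

#' @export
print.strain_histogram <- function(x, ...) {
  cat(sprintf("<strain_histogram> %d values, bin %g microstrain, peak at %g\n",
              x$n, x$bin_width, x$peak))
  invisible(x)
}

#' @export
plot.strain_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$freq, type = "h", lwd = 3,
                 xlab = "eps_eq (microstrain)",
                 ylab = "normalized frequency", ...)
  invisible(x)
}
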