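#' 3D grayscale volume with voxel size
#'
#' A `vol3d` is a numeric 3D array carrying its isotropic voxel size in
#' micrometres. It is the unit every pipeline stage consumes and produces:
#' phantom generation, preprocessing, digital volume correlation and the
#' uncertainty protocols all operate on `vol3d` objects.
#'
#' @param data numeric 3D array of gray values.
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @return object of class `vol3d` (a 3D array with a `voxel_size`
#'   attribute).
#' @examples
#' v <- vol3d(array(0, dim = c(8, 8, 8)), voxel_size = 2)
#' dim(v)
#' @export
vol3d <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  storage.mode(data) <- "double"
  structure(data, voxel_size = as.numeric(voxel_size),
            class = c("vol3d", "array"))
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vol3d> %d x %d x %d voxels, voxel size %g um\n",
              d[1], d[2], d[3], voxel_size(x)))
  cat(sprintf("  gray range [%g, %g], mean %g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' Voxel size of a volume or label map
#' @param x a `vol3d` or `region_labels` object.
#' @return voxel edge length in micrometres.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) 1 else vs
}

as_vol3d <- function(x, like = NULL) {
  vs <- if (is.null(like)) 1 else voxel_size(like)
  vol3d(x, voxel_size = vs)
}

#' Read a volume from a multi-page TIFF stack with sidecar metadata
#'
#' The sidecar (`<path>.meta`, plain-text `key=value`) must provide
#' `voxel_size_um`; `scale` and `dtype` are written by [write_volume()] and
#' used to restore gray values. Integer volumes round-trip bit-identically.
#'
#' @param path path to a multi-page TIFF file.
#' @return a [vol3d] volume.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path))
    stop("missing sidecar metadata file: ", meta_path)
  meta <- read_config(meta_path)
  if (is.null(meta$voxel_size_um))
    stop("sidecar metadata is missing required key 'voxel_size_um'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  scale <- if (is.null(meta$scale)) 1 else as.numeric(meta$scale)
  dtype <- if (is.null(meta$dtype)) "double" else meta$dtype
  if (dtype == "integer") {
    arr <- round(arr * scale)
  } else {
    offset <- if (is.null(meta$offset)) 0 else as.numeric(meta$offset)
    arr <- arr * scale + offset
  }
  vol3d(arr, voxel_size = as.numeric(meta$voxel_size_um))
}

#' Write a volume as a multi-page TIFF stack with sidecar metadata
#'
#' Nonnegative integer-valued volumes are stored losslessly at 8 or 16
#' bits per sample; other volumes are stored as min-max scaled 16-bit with
#' the scale recorded in the sidecar.
#'
#' @param vol a [vol3d] volume.
#' @param path output TIFF path; the sidecar goes to `<path>.meta`.
#' @param extra named list of additional sidecar entries (e.g. a seed or a
#'   parameter echo).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, extra = list()) {
  stopifnot(inherits(vol, "vol3d"))
  v <- unclass(vol)
  attributes(v) <- list(dim = dim(vol))
  integerish <- all(v >= 0) && all(v == round(v))
  if (integerish && max(v) <= 65535) {
    bits <- if (max(v) <= 255) 8L else 16L
    scale <- 2^bits - 1
    dtype <- "integer"
    pages <- lapply(seq_len(dim(vol)[3]), function(k) v[, , k] / scale)
    meta <- c(list(voxel_size_um = voxel_size(vol), dtype = dtype,
                   scale = scale,
                   dims = paste(dim(vol), collapse = "x")), extra)
  } else {
    # min-max scaled 16-bit: lossy at ~1.5e-5 of the dynamic range
    bits <- 16L
    lo <- min(v); hi <- max(v)
    vn <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
    pages <- lapply(seq_len(dim(vol)[3]), function(k) vn[, , k])
    meta <- c(list(voxel_size_um = voxel_size(vol), dtype = "double",
                   scale = hi - lo, offset = lo,
                   dims = paste(dim(vol), collapse = "x")), extra)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  write_config(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read or write a region label map as 8-bit TIFF
#'
#' Labels use the fixed coding 0 = background/marrow, 1 = articular
#' cartilage, 2 = mineralized tissue.
#'
#' @param labels a `region_labels` object (integer 3D array of 0/1/2).
#' @param path TIFF path.
#' @return for `read_labels`, a `region_labels` object.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "region_labels"))
  v <- unclass(labels)
  attributes(v) <- list(dim = dim(labels))
  pages <- lapply(seq_len(dim(labels)[3]), function(k) v[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  write_config(list(voxel_size_um = voxel_size(labels),
                    dims = paste(dim(labels), collapse = "x")),
               paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- read_config(paste0(path, ".meta"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 255))
  region_labels(arr, voxel_size = as.numeric(meta$voxel_size_um))
}

#' Voxelwise region label map
#'
#' @param labels integer 3D array with values in \{0, 1, 2\}
#'   (0 background/marrow, 1 articular cartilage, 2 mineralized tissue).
#' @param voxel_size voxel edge length in micrometres.
#' @return object of class `region_labels`.
#' @export
region_labels <- function(labels, voxel_size = 1) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (!all(labels %in% c(0L, 1L, 2L)))
    stop("labels must take values in {0, 1, 2}")
  storage.mode(labels) <- "integer"
  structure(labels, voxel_size = as.numeric(voxel_size),
            class = c("region_labels", "array"))
}

#' @export
print.region_labels <- function(x, ...) {
  d <- dim(x)
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf("<region_labels> %d x %d x %d voxels, voxel size %g um\n",
              d[1], d[2], d[3], voxel_size(x)))
  cat(sprintf("  background/marrow %d | articular cartilage %d | mineralized %d\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}
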