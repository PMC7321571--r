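#' Split a raw indentation record into loading / hold / unloading phases
#'
#' The loading phase rises to the first sample within `plateau_tol` of
#' the maximum load, the hold phase is the remaining contiguous samples
#' within that band, and unloading is everything after. A triangle-wave
#' load therefore splits at the apex with an empty hold.
#'
#' @param curve data frame with numeric columns `time` (s), `load` (mN)
#'   and `depth` (um).
#' @param plateau_tol fraction of the maximum load defining the hold
#'   plateau band.
#' @param location_id,replicate_id optional identifiers carried along.
#' @return the curve with a `phase` factor column
#'   (`loading`/`hold`/`unloading`), class `indentation_curve`.
#' @export
segment_phases <- function(curve, plateau_tol = 0.01, location_id = NA,
                           replicate_id = NA) {
  req <- c("time", "load", "depth")
  if (!all(req %in% names(curve)))
    stop("curve needs columns: ", paste(req, collapse = ", "))
  if (nrow(curve) < 3L) stop("need at least 3 samples")
  if (is.unsorted(curve$time, strictly = TRUE))
    stop("time must be strictly increasing")
  pmax_ <- max(curve$load)
  band <- which(curve$load >= pmax_ * (1 - plateau_tol))
  i1 <- min(band)
  i2 <- max(band)
  phase <- rep("unloading", nrow(curve))
  phase[seq_len(i1)] <- "loading"
  if (i2 > i1) phase[(i1 + 1L):i2] <- "hold"
  curve$phase <- factor(phase, levels = c("loading", "hold", "unloading"))
  attr(curve, "location_id") <- location_id
  attr(curve, "replicate_id") <- replicate_id
  class(curve) <- c("indentation_curve", "data.frame")
  curve
}

#' Contact stiffness from the initial unloading slope
#'
#' `S = dP/dh`, the least-squares slope of load versus depth over the top
#' `fit_fraction` of the unloading load range (the initial stage of the
#' unloading from maximum load).
#'
#' @param curve an [segment_phases()] `indentation_curve`.
#' @param fit_fraction fraction of the unloading load range to fit,
#'   in `(0, 1]`; default the top 20%.
#' @return contact stiffness in mN/um.
#' @export
contact_stiffness <- function(curve, fit_fraction = 0.2) {
  stopifnot(inherits(curve, "indentation_curve"))
  if (!(fit_fraction > 0 && fit_fraction <= 1))
    stop("`fit_fraction` must be in (0, 1]")
  un <- curve[curve$phase == "unloading", ]
  if (nrow(un) == 0L) stop("curve has no unloading phase")
  p_hi <- max(un$load); p_lo <- min(un$load)
  win <- un[un$load >= p_hi - fit_fraction * (p_hi - p_lo), ]
  if (nrow(win) < 2L)
    stop("fewer than 2 unloading samples in the fit window")
  unname(stats::coef(stats::lm(load ~ depth, data = win))[2L])
}

#' Indentation hardness of a flat punch
#'
#' Maximum force over the contact area. For a flat punch the contact area
#' is the nominal tip base area (default 2500 um^2, a 50 um x 50 um tip)
#' unless a calibrated area is supplied.
#'
#' @param curve an `indentation_curve` (or any data frame with a `load`
#'   column in mN).
#' @param tip_area contact area in um^2.
#' @return hardness in MPa.
#' @export
hardness <- function(curve, tip_area = 2500) {
  if (tip_area <= 0) stop("`tip_area` must be positive")
  # mN / um^2 = GPa, hence the factor 1000 to MPa
  max(curve$load) / tip_area * 1000
}

#' Summarize indentation metrics over locations and replicates
#'
#' Averages replicates within each location, then reports the mean and SD
#' across locations (the triplicate-by-location protocol).
#'
#' @param metrics data frame with columns `location`, `replicate` and one
#'   or more numeric metric columns (e.g. `S`, `hardness`).
#' @return list with `per_location` (replicate means) and `summary`
#'   (across-location mean and SD per metric).
#' @export
summarize_locations <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no metrics to summarize")
  if (!all(c("location", "replicate") %in% names(metrics)))
    stop("metrics need `location` and `replicate` columns")
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                      c("location", "replicate"))
  per_loc <- stats::aggregate(metrics[num_cols],
                              by = list(location = metrics$location),
                              FUN = mean)
  summ <- data.frame(metric = num_cols,
                     mean = vapply(num_cols,
                                   function(cn) mean(per_loc[[cn]]),
                                   numeric(1)),
                     sd = vapply(num_cols,
                                 function(cn) stats::sd(per_loc[[cn]]),
                                 numeric(1)),
                     n_locations = nrow(per_loc))
  rownames(summ) <- NULL
  list(per_location = per_loc, summary = summ)
}

#' Stress-strain reduction of an unconfined compression record
#'
#' Nominal stress is force over the plug cross-section
#' (`F / (pi d^2 / 4)`, MPa for N and mm), nominal strain is displacement
#' over cartilage thickness. The stress relaxation is the stress drop over
#' the displacement hold (first to last sample at maximum displacement).
#'
#' @param force force in N.
#' @param displacement displacement in mm (compression positive).
#' @param diameter specimen diameter in mm.
#' @param thickness nominal articular cartilage thickness in mm.
#' @param hold_tol displacement tolerance (fraction of the maximum)
#'   defining the hold plateau.
#' @return list with `stress` (MPa), `strain` (dimensionless),
#'   `max_stress`, `relaxation` and the input geometry.
#' @export
compression_stress_strain <- function(force, displacement, diameter,
                                      thickness, hold_tol = 1e-6) {
  if (diameter <= 0 || thickness <= 0)
    stop("diameter and thickness must be positive")
  if (length(force) != length(displacement))
    stop("force and displacement must have equal length")
  area <- pi * diameter^2 / 4          # mm^2; N / mm^2 = MPa
  stress <- force / area
  strain <- displacement / thickness
  hold <- which(displacement >= max(displacement) * (1 - hold_tol))
  relaxation <- if (length(hold) >= 2L)
    stress[min(hold)] - stress[max(hold)] else 0
  list(stress = stress, strain = strain, max_stress = max(stress),
       relaxation = relaxation, diameter = diameter,
       thickness = thickness)
}

#' Simulate a flat-punch indentation curve
#'
#' Trapezoidal load program (ramp to the load setpoint, hold, unload)
#' with a power-law loading response and linear unloading of slope
#' `S_true`; used as a ground-truth generator for the indentation
#' metrics.
#'
#' @param P_max load setpoint in mN.
#' @param S_true unloading contact stiffness in mN/um.
#' @param n_load,n_hold,n_unload samples per phase.
#' @param noise_sd load noise SD in mN.
#' @param seed RNG seed.
#' @return data frame with `time`, `load`, `depth`; phase sample counts
#'   in attributes `n_load`, `n_hold`, `n_unload`.
#' @export
simulate_indentation_curve <- function(P_max = 45, S_true = 2,
                                       n_load = 50L, n_hold = 20L,
                                       n_unload = 50L, noise_sd = 0,
                                       seed = 1L) {
  h_max <- 1.5 * P_max / S_true        # power-law P = c h^2 hits P_max
  tl <- seq_len(n_load)
  h_l <- h_max * sqrt(tl / n_load)
  p_l <- P_max * (h_l / h_max)^2
  h_h <- h_max + cumsum(rep(0.001 * h_max, n_hold))
  p_h <- rep(P_max, n_hold)
  # unloading starts just below the plateau band so the hold/unloading
  # boundary is unambiguous at the default 1% plateau tolerance
  p_u <- seq(0.98 * P_max, 0.05 * P_max, length.out = n_unload)
  h_u <- h_max + (p_u - P_max) / S_true
  load <- c(p_l, p_h, p_u)
  depth <- c(h_l, h_h, h_u)
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    load <- load + stats::rnorm(length(load), 0, noise_sd)
  }
  out <- data.frame(time = seq_along(load), load = load, depth = depth)
  attr(out, "n_load") <- as.integer(n_load)
  attr(out, "n_hold") <- as.integer(n_hold)
  attr(out, "n_unload") <- as.integer(n_unload)
  out
}

#' Read an indentation record from delimited text
#'
#' @param path file path.
#' @param col_map named character vector mapping file column names to
#'   `time`, `load`, `depth` (e.g. `c(time = "t_s", load = "P_mN",
#'   depth = "h_um")`).
#' @param ... passed to [utils::read.table()] (e.g. `sep`, `header`).
#' @return data frame with `time`, `load`, `depth`.
#' @export
read_indentation <- function(path, col_map = c(time = "time",
                                               load = "load",
                                               depth = "depth"), ...) {
  raw <- utils::read.table(path, header = TRUE, ...)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols) > 0L)
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  data.frame(time = raw[[col_map[["time"]]]],
             load = raw[[col_map[["load"]]]],
             depth = raw[[col_map[["depth"]]]])
}
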