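# Voxel-grid containers for signal series and fitted parameter maps.

#' 4-D signal volume
#'
#' A 3-D voxel grid with the measurement axis (b-values or DCE frames) as
#' the 4th dimension, plus voxel spacing and the acquisition that indexes
#' the series. Concentration volumes (which may dip below zero under
#' Gaussian noise) set `nonneg = FALSE`.
#'
#' @param data 4-D numeric array `(x, y, z, measurement)`.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm; `dz` is the
#'   slice-to-slice distance (thickness + gap).
#' @param acq The matching [diffusion_acquisition()] or [dce_acquisition()].
#' @param nonneg Enforce non-negative signals (default `TRUE`).
#' @return An object of class `signal_volume`.
#' @export
signal_volume <- function(data, spacing, acq, nonneg = TRUE) {
  if (length(dim(data)) != 4) stop("data must be a 4-D array")
  n_meas <- if (inherits(acq, "diffusion_acquisition")) length(acq$b_values)
            else if (inherits(acq, "dce_acquisition")) length(acq$frame_times)
            else stop("acq must be a diffusion or DCE acquisition")
  if (dim(data)[4] != n_meas)
    stop("4th dimension must match the acquisition length")
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (nonneg && any(data < 0, na.rm = TRUE)) stop("signals must be non-negative")
  structure(list(data = data, spacing = as.numeric(spacing), acq = acq),
            class = "signal_volume")
}

#' @export
print.signal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<signal_volume> %d x %d x %d voxels, %d measurements, spacing %s mm\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Fitted parameter map
#'
#' One fitted parameter on a voxel grid, with the mask of successfully
#' fitted voxels, the reporting scale (see [report_scale()]) and a per-voxel
#' residual norm as the fit-quality measure. Values are stored in natural
#' units; [map_values()] converts to the reporting scale.
#'
#' @param parameter Parameter name (e.g. `"adc"`).
#' @param values 3-D array of fitted values in natural units.
#' @param mask 3-D logical array of fitted voxels.
#' @param scale Reporting scale factor; defaults to [report_scale()] of
#'   `parameter`.
#' @param residual Optional 3-D array of residual norms.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(parameter, values, mask,
                          scale = report_scale(parameter), residual = NULL) {
  if (!identical(dim(values), dim(mask))) stop("values and mask dims differ")
  if (scale <= 0) stop("scale must be positive")
  if (any(!is.finite(values[mask])))
    stop("values must be finite inside the mask")
  structure(list(parameter = parameter, values = values,
                 mask = mask, scale = scale, residual = residual),
            class = "parameter_map")
}

#' Extract map values
#'
#' @param map A [parameter_map()].
#' @param reported Return reporting-scale values (default) or natural units.
#' @param masked_only Return only the fitted voxels as a vector.
#' @return Array (or vector if `masked_only`) of values.
#' @export
map_values <- function(map, reported = TRUE, masked_only = FALSE) {
  stopifnot(inherits(map, "parameter_map"))
  v <- if (reported) map$values / map$scale else map$values
  if (masked_only) v[map$mask] else v
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s: %d fitted voxels, reporting scale %g\n",
              x$parameter, sum(x$mask), x$scale))
  invisible(x)
}

# Flatten the masked voxels of a 4-D volume into an (nvox x nmeas) matrix.
# Returns the matrix plus the linear indices used, so fitted vectors can be
# scattered back into 3-D maps.
flatten_volume <- function(vol, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stop("mask dims must match the volume grid")
  idx <- which(mask)
  nmeas <- d[4]
  Y <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nmeas)[idx, , drop = FALSE]
  list(Y = Y, idx = idx, dim = d[1:3])
}

# Scatter per-voxel fitted values back into a parameter_map.
scatter_map <- function(parameter, est, ok, flat, residual = NULL,
                        scale = report_scale(parameter)) {
  vals <- array(NA_real_, flat$dim)
  mk <- array(FALSE, flat$dim)
  vals[flat$idx] <- ifelse(ok, est, NA_real_)
  mk[flat$idx] <- ok
  res <- NULL
  if (!is.null(residual)) {
    res <- array(NA_real_, flat$dim)
    res[flat$idx] <- ifelse(ok, residual, NA_real_)
  }
  parameter_map(parameter, vals, mk, scale = scale, residual = res)
}
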