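#' Diffusion acquisition description
#'
#' Holds the diffusion weightings (b-values) that index a DWI/DKI/IVIM
#' signal series. The b-value grid must start at 0 and be strictly
#' increasing; model-specific minima (>= 4 b-values spanning >= 1500 s/mm^2
#' for kurtosis fitting, >= 6 for IVIM) are enforced by the fitters.
#'
#' @param b_values Numeric vector of b-values in s/mm^2.
#' @return An object of class `diffusion_acquisition`.
#' @examples
#' diffusion_acquisition(c(0, 600))
#' @export
diffusion_acquisition <- function(b_values) {
  b <- as.numeric(b_values)
  if (length(b) < 2) stop("need at least two b-values")
  if (anyNA(b) || any(b < 0)) stop("b-values must be non-negative")
  if (is.unsorted(b, strictly = TRUE)) stop("b-values must be strictly increasing")
  if (b[1] != 0) stop("the acquisition must include b = 0")
  structure(list(b_values = b), class = "diffusion_acquisition")
}

#' Dynamic contrast-enhanced acquisition description
#'
#' Frame times of a DCE series together with the number of pre-contrast
#' (baseline) frames. Contrast arrival is taken at the first post-baseline
#' frame.
#'
#' @param frame_times Numeric vector of frame acquisition times in seconds,
#'   strictly increasing.
#' @param n_baseline Number of pre-contrast frames (>= 1, < number of frames).
#' @return An object of class `dce_acquisition`.
#' @examples
#' dce_acquisition(seq(0, by = 8.1, length.out = 35), n_baseline = 4)
#' @export
dce_acquisition <- function(frame_times, n_baseline) {
  t <- as.numeric(frame_times)
  if (length(t) < 2) stop("need at least two frames")
  if (anyNA(t) || is.unsorted(t, strictly = TRUE))
    stop("frame times must be strictly increasing")
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1 || n_baseline >= length(t))
    stop("n_baseline must be >= 1 and smaller than the number of frames")
  structure(list(frame_times = t, n_baseline = n_baseline),
            class = "dce_acquisition")
}

#' Onset time (s) of contrast arrival for a DCE acquisition
#' @param acq A [dce_acquisition()].
#' @return Time in seconds of the first post-baseline frame.
#' @export
dce_onset <- function(acq) {
  stopifnot(inherits(acq, "dce_acquisition"))
  acq$frame_times[acq$n_baseline + 1L]
}

#' Default acquisition set
#'
#' The acquisition grids used throughout the synthetic cohort: two-point DWI
#' (b = 0/600), a five-point kurtosis series to b = 2000, a twelve-point
#' IVIM series dense at low b, and a 35-frame DCE series (4 baseline frames,
#' 8.1 s spacing, about 4 min 44 s total).
#'
#' @return A named list with elements `dwi`, `dki`, `ivim`
#'   ([diffusion_acquisition()]) and `dce` ([dce_acquisition()]).
#' @export
default_acquisitions <- function() {
  list(
    dwi  = diffusion_acquisition(c(0, 600)),
    dki  = diffusion_acquisition(c(0, 500, 1000, 1500, 2000)),
    ivim = diffusion_acquisition(c(0, 10, 20, 30, 50, 80, 100, 150, 200, 400, 600, 800)),
    dce  = dce_acquisition(seq(0, by = 8.1, length.out = 35), n_baseline = 4)
  )
}

#' Tissue parameter set
#'
#' Ground-truth (or fitted) per-voxel parameters for the four signal models,
#' in natural units: diffusivities in mm^2/s, rate constants in 1/min,
#' fractions dimensionless. `ve` is derived as `ktrans/kep` when not given.
#'
#' @param s0 Baseline signal (a.u.), > 0.
#' @param adc Apparent diffusion coefficient (mm^2/s).
#' @param d Kurtosis-corrected diffusivity MD (mm^2/s).
#' @param k Mean kurtosis MK (dimensionless, >= 0).
#' @param f Perfusion fraction (0..1).
#' @param dslow True diffusion coefficient (mm^2/s).
#' @param dfast Pseudo-diffusion coefficient (mm^2/s), >= `dslow`.
#' @param ktrans Transfer constant (1/min).
#' @param kep Rate constant (1/min).
#' @param ve Extravascular-extracellular fraction; defaults to `ktrans/kep`.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(s0 = 100, adc = 1238.43e-6)
#' @export
tissue_params <- function(s0 = 100, adc = NA_real_, d = NA_real_, k = NA_real_,
                          f = NA_real_, dslow = NA_real_, dfast = NA_real_,
                          ktrans = NA_real_, kep = NA_real_, ve = NULL) {
  if (any(s0 <= 0)) stop("s0 must be positive")
  chk_nonneg <- function(x, nm) {
    if (!all(is.na(x)) && any(x[!is.na(x)] < 0))
      stop(sprintf("%s must be non-negative", nm))
  }
  chk_nonneg(adc, "adc"); chk_nonneg(d, "d"); chk_nonneg(k, "k")
  chk_nonneg(dslow, "dslow"); chk_nonneg(dfast, "dfast")
  chk_nonneg(ktrans, "ktrans"); chk_nonneg(kep, "kep")
  if (!all(is.na(f)) && any(f[!is.na(f)] < 0 | f[!is.na(f)] > 1))
    stop("f must lie in [0, 1]")
  if (!all(is.na(dfast)) && !all(is.na(dslow)) &&
      any(stats::na.omit(dfast - dslow) < 0))
    stop("dfast must be >= dslow")
  if (is.null(ve)) {
    ve <- ifelse(!is.na(kep) & kep > 0, ktrans / kep, NA_real_)
  } else {
    if (any(!is.na(ve) & (ve < 0 | ve > 1))) stop("ve must lie in [0, 1]")
    ok <- !is.na(kep) & kep > 0 & !is.na(ktrans) & !is.na(ve)
    if (any(ok & abs(ve - ktrans / kep) > 1e-8 * pmax(1, ve)))
      stop("ve must equal ktrans/kep when kep > 0")
  }
  structure(list(s0 = s0, adc = adc, d = d, k = k, f = f, dslow = dslow,
                 dfast = dfast, ktrans = ktrans, kep = kep, ve = ve),
            class = "tissue_params")
}
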