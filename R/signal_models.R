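# Forward signal models: the ground truth for every fitting routine.

#' Mono-exponential diffusion signal
#'
#' `S(b) = S0 * exp(-b * ADC)`, the conventional DWI model of Gaussian
#' diffusion.
#'
#' @param params A [tissue_params()] (uses `s0`, `adc`).
#' @param b Non-negative b-value(s) in s/mm^2.
#' @return Signal in the units of `s0`.
#' @examples
#' p <- tissue_params(s0 = 100, adc = 1238.43e-6)
#' dwi_signal(p, c(0, 600))
#' @export
dwi_signal <- function(params, b) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(b < 0)) stop("b must be non-negative")
  params$s0 * exp(-b * params$adc)
}

#' Diffusion kurtosis signal
#'
#' `S(b) = S0 * exp(-b * D + (1/6) * b^2 * D^2 * K)`. With `K = 0` this is
#' the mono-exponential model with `ADC = D`. The quadratic term is a
#' truncated cumulant expansion: it is only a decaying signal model while
#' the exponent's derivative stays negative over the b range, which the
#' fitting bounds (`K <= 3`, `D <= 4e-3`) maintain for clinical b grids.
#'
#' @param params A [tissue_params()] (uses `s0`, `d`, `k`).
#' @param b Non-negative b-value(s) in s/mm^2.
#' @return Signal in the units of `s0`.
#' @examples
#' dki_signal(tissue_params(s0 = 1, d = 1e-3, k = 1), 1000)  # exp(-5/6)
#' @export
dki_signal <- function(params, b) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(b < 0)) stop("b must be non-negative")
  params$s0 * exp(-b * params$d + (1 / 6) * b^2 * params$d^2 * params$k)
}

#' Bi-exponential intravoxel incoherent motion signal
#'
#' `S(b)/S0 = (1 - f) * exp(-b * Dslow) + f * exp(-b * (Dslow + Dfast))`:
#' the tissue compartment decays at the true diffusion rate `Dslow`, the
#' perfusing blood compartment (fraction `f`) at the faster pseudo-diffusion
#' rate `Dslow + Dfast`.
#'
#' @param params A [tissue_params()] (uses `s0`, `f`, `dslow`, `dfast`).
#' @param b Non-negative b-value(s) in s/mm^2.
#' @return Signal in the units of `s0`.
#' @examples
#' p <- tissue_params(s0 = 1, f = 0.2, dslow = 0.8e-3, dfast = 40e-3)
#' ivim_signal(p, 800)
#' @export
ivim_signal <- function(params, b) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(b < 0)) stop("b must be non-negative")
  f <- params$f
  if (any(is.na(f)) || any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  params$s0 * ((1 - f) * exp(-b * params$dslow) +
                 f * exp(-b * (params$dslow + params$dfast)))
}

# ---- Arterial input functions -------------------------------------------

#' Arterial input function models
#'
#' An AIF is the plasma contrast concentration over time that drives the
#' Tofts convolution. `aif_step` is a constant concentration switched on at
#' `onset_s` (used for closed-form testing); `aif_parker` is the standard
#' population-average AIF (two Gaussians plus a sigmoid-modulated
#' exponential washout) shifted to `onset_s`. Both are zero before onset
#' and non-negative everywhere.
#'
#' @param amplitude Plateau concentration in mM (step AIF).
#' @param onset_s Contrast-arrival time in seconds.
#' @return An object of class `aif_model` with fields `name`, `parameters`
#'   and an evaluator used by [aif_eval()].
#' @examples
#' aif <- aif_step(1, onset_s = 0)
#' aif_eval(aif, c(0, 30, 60))
#' @export
aif_step <- function(amplitude = 1, onset_s = 0) {
  stopifnot(amplitude >= 0)
  structure(list(
    name = "step",
    parameters = list(amplitude = amplitude, onset_s = onset_s),
    fun = function(t_s) ifelse(t_s >= onset_s, amplitude, 0)
  ), class = "aif_model")
}

#' @rdname aif_step
#' @export
aif_parker <- function(onset_s = 0) {
  # Population AIF coefficients (concentration in mM, time in minutes).
  p <- list(A1 = 0.809, A2 = 0.330, T1 = 0.17046, T2 = 0.365,
            s1 = 0.0563, s2 = 0.132, alpha = 1.050, beta = 0.1685,
            s = 38.078, tau = 0.483, onset_s = onset_s)
  structure(list(
    name = "parker",
    parameters = p,
    fun = function(t_s) {
      tm <- (t_s - onset_s) / 60
      out <- numeric(length(tm))
      pos <- tm > 0
      t <- tm[pos]
      g1 <- p$A1 / (p$s1 * sqrt(2 * pi)) * exp(-(t - p$T1)^2 / (2 * p$s1^2))
      g2 <- p$A2 / (p$s2 * sqrt(2 * pi)) * exp(-(t - p$T2)^2 / (2 * p$s2^2))
      wash <- p$alpha * exp(-p$beta * t) / (1 + exp(-p$s * (t - p$tau)))
      out[pos] <- pmax(0, g1 + g2 + wash)
      out
    }
  ), class = "aif_model")
}

#' Evaluate an AIF at given times
#' @param aif An `aif_model`.
#' @param t_s Times in seconds.
#' @return Plasma concentration (mM) at `t_s`.
#' @export
aif_eval <- function(aif, t_s) {
  stopifnot(inherits(aif, "aif_model"))
  aif$fun(t_s)
}

# ---- Tofts two-compartment model ----------------------------------------

# Exact convolution of a piecewise-linear Cp with exp(-kep * t):
# tissue_conc_series() advances G(t) = int Cp(tau) exp(-kep (t - tau)) dtau
# frame by frame with the closed-form update for a linear segment, so the
# only approximation is the linear interpolation of Cp between frames.
# Vectorized over kep (one value per voxel). Times in minutes, rates 1/min.
exp_conv_grid <- function(cp, t_min, kep) {
  nt <- length(t_min)
  nv <- length(kep)
  G <- matrix(0, nrow = nv, ncol = nt)
  for (i in seq_len(nt - 1)) {
    h <- t_min[i + 1] - t_min[i]
    m <- (cp[i + 1] - cp[i]) / h
    E <- exp(-kep * h)
    incr <- cp[i + 1] * (1 - E) / kep - m * (1 - E - kep * h * E) / kep^2
    G[, i + 1] <- G[, i] * E + incr
  }
  G
}

#' Tofts model tissue concentration
#'
#' Standard (two-parameter) Tofts model:
#' `Ct(t) = Ktrans * int_0^t Cp(tau) exp(-Kep (t - tau)) dtau`, with
#' `Ve = Ktrans / Kep` the extravascular-extracellular fraction. The
#' convolution is evaluated exactly for the piecewise-linear interpolant of
#' the AIF between frame times.
#'
#' @param params A [tissue_params()] (uses `ktrans`, `kep`, both 1/min).
#' @param aif An `aif_model` ([aif_step()] or [aif_parker()]).
#' @param acq A [dce_acquisition()].
#' @return Tissue concentration (mM) at the acquisition's frame times.
#' @examples
#' acq <- dce_acquisition(0:120, n_baseline = 1)
#' p <- tissue_params(ktrans = 0.1, kep = 0.5)
#' ct <- tofts_concentration(p, aif_step(1, onset_s = 0), acq)
#' @export
tofts_concentration <- function(params, aif, acq) {
  stopifnot(inherits(params, "tissue_params"), inherits(acq, "dce_acquisition"))
  kt <- params$ktrans
  kep <- params$kep
  if (is.na(kt)) stop("ktrans is required")
  if (kt == 0) return(numeric(length(acq$frame_times)))
  if (is.na(kep) || kep <= 0) stop("kep must be > 0 when ktrans > 0")
  cp <- aif_eval(aif, acq$frame_times)
  t_min <- acq$frame_times / 60
  as.numeric(kt * exp_conv_grid(cp, t_min, kep))
}

# ---- Measurement noise ---------------------------------------------------

#' Add measurement noise to a signal series
#'
#' Rician noise models magnitude-reconstructed MRI: the noisy value is
#' `sqrt((s + e1)^2 + e2^2)` with independent Gaussian `e1, e2` of scale
#' `sigma`, hence non-negative and positively biased at low SNR. Gaussian
#' noise is appropriate for derived concentration series.
#'
#' @param series Numeric vector/array of true values.
#' @param sigma Noise scale (same units as `series`), >= 0; `sigma = 0`
#'   returns the input unchanged without touching the RNG.
#' @param model `"rician"` or `"gaussian"`.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is restored afterwards.
#' @return Noisy series with the shape of `series`.
#' @examples
#' add_noise(c(100, 50), sigma = 2, model = "rician", seed = 1)
#' @export
add_noise <- function(series, sigma, model = c("rician", "gaussian"),
                      seed = NULL) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(series)
  local_seed(seed, {
    n <- length(series)
    out <- if (model == "rician") {
      sqrt((series + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    } else {
      series + stats::rnorm(n, 0, sigma)
    }
    if (is.array(series)) array(out, dim = dim(series)) else out
  })
}
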