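# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' stream afterwards, so seeded simulation helpers do not perturb user code.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-patient sub-seed kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# Reporting scale factors: stored (natural) value = reported value * scale.
# Diffusivities are mm^2/s, rates 1/min, fractions dimensionless.
.report_scales <- c(
  adc = 1e-6, md = 1e-6, mk = 1e-3, dslow = 1e-6, dfast = 1e-4,
  pf = 1e-4, ktrans = 1e-3, kep = 1e-3, ve = 1e-3, s0 = 1
)

#' Reporting scale factor for a parameter
#'
#' Parameter maps and cohort tables carry values on the conventional
#' reporting scale (e.g. ADC in units of 1e-6 mm^2/s, so a typical tumour
#' value prints as 1238 rather than 0.001238). The scale factor converts a
#' reported value back to natural units: `natural = reported * scale`.
#'
#' @param parameter One of `"adc","md","mk","dslow","dfast","pf","ktrans",
#'   "kep","ve","s0"`.
#' @return A positive scalar scale factor.
#' @export
report_scale <- function(parameter) {
  parameter <- match.arg(tolower(parameter), names(.report_scales))
  unname(.report_scales[[parameter]])
}
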