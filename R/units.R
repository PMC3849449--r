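# Internal unit system: cm, min, kPa, mmol, mole fraction.
# Permeability is stored in cm^2; 1 Darcy = 9.869e-9 cm^2 is used for all
# laboratory-unit conversions.

#' Unit-conversion constants
#'
#' Named constants used throughout the package to convert between laboratory
#' units (Darcy, micrometre, mPa s, m^2/s) and the internal unit system
#' (cm, min, kPa, mmol, mole fraction).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{darcy_cm2}{cm^2 per Darcy (9.869e-9).}
#'   \item{um2_cm2}{cm^2 per square micrometre (1e-8).}
#'   \item{um_cm}{cm per micrometre (1e-4).}
#'   \item{mPas_kPamin}{kPa min per mPa s (1e-6 / 60).}
#'   \item{m2s_cm2min}{cm^2/min per m^2/s (6e5).}
#' }
#' @export
lobule_units <- list(
  darcy_cm2   = 9.869e-9,
  um2_cm2     = 1e-8,
  um_cm       = 1e-4,
  mPas_kPamin = 1e-6 / 60,
  m2s_cm2min  = 6e5
)

# viscosity mPa.s -> kPa.min (internal)
.mu_internal <- function(mu_mPas) mu_mPas * lobule_units$mPas_kPamin

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a finite numeric scalar", name)
  invisible(x)
}
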