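# Lamp and culture parameters for the fluence model.

#' Convert optical density to transmittance
#'
#' Beer-Lambert conversion \eqn{T = 10^{-OD}}: the fraction of incident light
#' transmitted through a culture whose absorbance (typically at 600 nm) is
#' `od600`.  An OD600 of 1.2 gives 6.3\% transmittance.
#'
#' @param od600 Non-negative absorbance (dimensionless).
#' @return Transmittance as a fraction in (0, 1].
#' @examples
#' od_to_transmittance(0)    # 1: no absorbance
#' od_to_transmittance(1.2)  # 0.0631
#' @export
od_to_transmittance <- function(od600) {
  if (!is.numeric(od600) || length(od600) != 1L || !is.finite(od600))
    validation_error("'od600' must be a single finite number")
  if (od600 < 0)
    validation_error("'od600' must be non-negative")
  10^(-od600)
}

#' Lamp and culture configuration for irradiance experiments
#'
#' Bundles the parameters of the fluence model: lamp wavelength, fluence rate
#' (intensity) \eqn{H_0}, spectral bandwidth \eqn{b}, and the culture's
#' transmittance \eqn{T} (supplied directly or derived from OD600 via
#' [od_to_transmittance()]).  Defaults describe a 302 nm lamp at 70 W/m2 with
#' 10 nm bandwidth and a stationary-phase culture of OD600 = 1.2
#' (transmittance 6.3\%).
#'
#' If both `od600` and `transmittance` are given they must agree under
#' \eqn{T = 10^{-OD}} to within `tol`; the explicit transmittance is then the
#' value used.
#'
#' @param wavelength_nm Lamp wavelength in nm (> 0).
#' @param intensity_wm2 Fluence rate \eqn{H_0} in W/m2 (> 0).
#' @param bandwidth_nm Spectral bandwidth \eqn{b} in nm (> 0).
#' @param od600 Optional culture absorbance at 600 nm (>= 0).
#' @param transmittance Optional transmittance in (0, 1]; derived from
#'   `od600` when absent.
#' @param tol Agreement tolerance between `transmittance` and
#'   \eqn{10^{-od600}} when both are supplied.
#' @return An object of class `"irradiance_config"`.
#' @examples
#' irradiance_config()                 # paper-style defaults
#' irradiance_config(od600 = 2)        # T = 0.01
#' @export
irradiance_config <- function(wavelength_nm = 302, intensity_wm2 = 70,
                              bandwidth_nm = 10, od600 = 1.2,
                              transmittance = NULL, tol = 1e-9) {
  check_scalar_number(wavelength_nm, "wavelength_nm", 0, strict_lower = TRUE)
  check_scalar_number(intensity_wm2, "intensity_wm2", 0, strict_lower = TRUE)
  check_scalar_number(bandwidth_nm, "bandwidth_nm", 0, strict_lower = TRUE)
  if (is.null(od600) && is.null(transmittance))
    validation_error("one of 'od600' or 'transmittance' is required")
  if (!is.null(od600)) {
    check_scalar_number(od600, "od600", 0)
    derived <- od_to_transmittance(od600)
  } else derived <- NULL
  if (!is.null(transmittance)) {
    check_scalar_number(transmittance, "transmittance", 0, 1,
                        strict_lower = TRUE)
    if (!is.null(derived) && abs(transmittance - derived) > tol)
      validation_error(sprintf(
        "transmittance %.10g inconsistent with od600 %.10g (10^-od600 = %.10g)",
        transmittance, od600, derived))
  } else transmittance <- derived
  structure(
    list(wavelength_nm = wavelength_nm, intensity_wm2 = intensity_wm2,
         bandwidth_nm = bandwidth_nm, od600 = od600,
         transmittance = transmittance),
    class = "irradiance_config")
}

#' @export
print.irradiance_config <- function(x, ...) {
  cat("Irradiance configuration\n")
  cat(sprintf("  lamp: %g nm, %g W/m2, bandwidth %g nm\n",
              x$wavelength_nm, x$intensity_wm2, x$bandwidth_nm))
  cat(sprintf("  culture: transmittance %.4g (%.2f%%)%s\n",
              x$transmittance, 100 * x$transmittance,
              if (!is.null(x$od600)) sprintf(", OD600 %g", x$od600) else ""))
  invisible(x)
}

#' Total fluence delivered after an exposure time
#'
#' The total fluence is proportional to transmittance x bandwidth x intensity
#' x time, \eqn{H = T b H_0 t}, with the proportionality constant fixed at 1
#' (units W m^-2 nm min).  Linear and non-decreasing in `t`, zero at `t = 0`.
#'
#' @param config An [irradiance_config()].
#' @param t Exposure time in minutes (>= 0); may be a vector.
#' @return Fluence value(s), same length as `t`.
#' @examples
#' cfg <- irradiance_config(transmittance = 0.063, od600 = NULL)
#' total_fluence(cfg, 1)  # 0.063 * 10 * 70 = 44.1
#' @export
total_fluence <- function(config, t) {
  if (!inherits(config, "irradiance_config"))
    validation_error("'config' must be an irradiance_config")
  if (!is.numeric(t) || any(!is.finite(t)))
    validation_error("'t' must be finite numeric")
  if (any(t < 0))
    validation_error("exposure time 't' must be non-negative")
  config$transmittance * config$bandwidth_nm * config$intensity_wm2 * t
}

# Per-minute fluence factor T*b*H0: converts a per-minute survival constant to
# the per-fluence-unit scale and back.
fluence_factor <- function(config) {
  config$transmittance * config$bandwidth_nm * config$intensity_wm2
}
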