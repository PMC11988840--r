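# Intensity corrections for oriented-film lamellar diffraction in
# reflection geometry. All angles are the half scattering angle theta in
# degrees; corrections multiply the integrated intensity before the square
# root that yields |F_h|.

deg2rad <- function(x) x * pi / 180

check_theta <- function(theta) {
  if (!is.numeric(theta) || any(theta <= 0) || any(theta >= 90)) {
    stop("theta must lie strictly inside (0, 90) degrees")
  }
}

#' Neutron absorption correction
#'
#' `C_abs = alpha / (1 - exp(-alpha))` with `alpha = 2*mu*t / sin(theta)`,
#' the self-attenuation factor for a thin film of attenuation-thickness
#' product mu*t measured in reflection: at grazing angles the in-plane path
#' grows as 1/sin(theta). `C_abs >= 1` always and tends to 1 as
#' `mu*t -> 0` (handled explicitly to avoid 0/0).
#'
#' An alternative reading of the attenuation factor as
#' `alpha = 2*mu*t*sin(theta)` is available via `geometry = "times_sin"`
#' for comparison; the default reflection geometry divides by sin(theta).
#'
#' @param ctx A correction context ([instrument_config()] or
#'   [correction_context()]) supplying `mu_t`.
#' @param theta Half scattering angle, degrees, in (0, 90).
#' @param geometry `"over_sin"` (default) or `"times_sin"`.
#' @return The multiplicative correction factor, >= 1.
#' @export
absorption_correction <- function(ctx, theta, geometry = c("over_sin",
                                                           "times_sin")) {
  geometry <- match.arg(geometry)
  check_theta(theta)
  mu_t <- ctx$mu_t
  if (mu_t < 0) stop("mu_t must be >= 0")
  if (mu_t == 0) return(rep(1, length(theta))[seq_along(theta)])
  s <- sin(deg2rad(theta))
  alpha <- if (geometry == "over_sin") 2 * mu_t / s else 2 * mu_t * s
  ifelse(alpha < 1e-12, 1, alpha / (1 - exp(-alpha)))
}

#' Lorentz correction
#'
#' `C_Lor = sin(2*theta)`: the geometric factor accounting for the time a
#' reciprocal-lattice point spends in reflecting condition in a
#' one-dimensional powder-like stack. Maximal (= 1) at theta = 45 degrees
#' and symmetric about it.
#'
#' @param theta Half scattering angle, degrees, in (0, 90).
#' @return `sin(2*theta)`, in (0, 1].
#' @export
lorentz_correction <- function(theta) {
  check_theta(theta)
  sin(deg2rad(2 * theta))
}

#' Neutron flux correction
#'
#' `C_flux = 1 / erf(L*sin(theta) / (sqrt(8)*delta))`: at grazing incidence
#' the beam footprint overfills a sample of length L, so only the error-
#' function fraction of a Gaussian beam of width 2*delta is intercepted.
#' `C_flux >= 1`, tending to 1 once the sample intercepts the whole beam.
#' The denominator convention is configurable (`flux_denominator` field of
#' the context): `"sqrt8"` (default) or `"eight"`.
#'
#' @param ctx A correction context supplying `sample_length_L`,
#'   `beam_half_width_delta` and `flux_denominator`.
#' @param theta Half scattering angle, degrees, in (0, 90).
#' @return The multiplicative correction factor, >= 1.
#' @export
flux_correction <- function(ctx, theta) {
  check_theta(theta)
  denom <- switch(ctx$flux_denominator %||% "sqrt8",
                  sqrt8 = sqrt(8) * ctx$beam_half_width_delta,
                  eight = 8 * ctx$beam_half_width_delta,
                  stop("flux_denominator must be 'sqrt8' or 'eight'"))
  arg <- ctx$sample_length_L * sin(deg2rad(theta)) / denom
  e <- erf(arg)
  if (any(e < 1e-6)) {
    stop("flux correction diverges: the sample intercepts essentially no ",
         "beam at this geometry (L*sin(theta) << beam width)")
  }
  1 / e
}

# Gauss error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a
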