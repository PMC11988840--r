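#' Sample environment for a diffraction measurement
#'
#' Records the environmental state of an oriented multilayer film during a
#' measurement: temperature, relative humidity and the D2O fraction of the
#' vapour used for contrast variation. An 8% D2O mixture ("null water") has
#' zero net neutron scattering length density, so water is invisible and the
#' lipid headgroups dominate the profile; 100% D2O highlights the
#' inter-bilayer water layer.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param relative_humidity Relative humidity in percent, in (0, 100].
#' @param d2o_fraction D2O fraction of the hydration water, in [0, 1].
#' @return An object of class `sample_condition`.
#' @examples
#' sample_condition(70, 95, 0.08)
#' @export
sample_condition <- function(temperature, relative_humidity, d2o_fraction = 0.08) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (!is.numeric(relative_humidity) || relative_humidity <= 0 ||
      relative_humidity > 100) {
    stop("relative_humidity must lie in (0, 100], got ", relative_humidity)
  }
  if (!is.numeric(d2o_fraction) || d2o_fraction < 0 || d2o_fraction > 1) {
    stop("d2o_fraction must lie in [0, 1], got ", d2o_fraction)
  }
  structure(
    list(temperature = as.numeric(temperature),
         relative_humidity = as.numeric(relative_humidity),
         d2o_fraction = as.numeric(d2o_fraction)),
    class = "sample_condition"
  )
}

#' @export
print.sample_condition <- function(x, ...) {
  cat(sprintf("<sample_condition> %g degC, %g%% RH, %g%% D2O\n",
              x$temperature, x$relative_humidity, 100 * x$d2o_fraction))
  invisible(x)
}

#' Instrument and sample geometry configuration
#'
#' Holds the quantities needed both to render synthetic diffraction patterns
#' and to apply the intensity corrections: neutron wavelength, the
#' attenuation-thickness product mu*t of the film, the sample length along
#' the beam footprint, the beam half-width delta (the beam is 2*delta wide),
#' the rendered Gaussian peak width in 2-theta, a linear background and the
#' counts scale (expected counts for unit integrated intensity).
#'
#' The same object serves as the correction context for
#' [absorption_correction()] and [flux_correction()].
#'
#' @param wavelength Incident neutron wavelength in Angstrom (default
#'   4.487 Angstrom, the D16 cold-neutron value).
#' @param mu_t Dimensionless attenuation x thickness product, >= 0.
#' @param sample_length_L Sample length along the beam, mm.
#' @param beam_half_width_delta Beam half width delta, mm (beam width is
#'   2*delta).
#' @param peak_width_2theta Gaussian sigma of rendered Bragg peaks, degrees
#'   2-theta.
#' @param background Numeric length-2 vector `c(slope, intercept)` of the
#'   linear background in counts per bin versus 2-theta (degrees).
#' @param counts_scale Expected counts for a peak of unit integrated
#'   intensity.
#' @param flux_denominator Either `"sqrt8"` (default) or `"eight"`: the
#'   denominator convention in the flux-correction error function argument
#'   `L*sin(theta) / (sqrt(8)*delta)` versus `L*sin(theta) / (8*delta)`.
#' @return An object of class `instrument_config`.
#' @examples
#' instrument_config(mu_t = 0.1)
#' @export
instrument_config <- function(wavelength = 4.487,
                              mu_t = 0.1,
                              sample_length_L = 50,
                              beam_half_width_delta = 1,
                              peak_width_2theta = 0.15,
                              background = c(slope = 0, intercept = 20),
                              counts_scale = 1e5,
                              flux_denominator = c("sqrt8", "eight")) {
  flux_denominator <- match.arg(flux_denominator)
  if (wavelength <= 0) stop("wavelength must be positive")
  if (mu_t < 0) stop("mu_t must be >= 0")
  if (beam_half_width_delta <= 0) stop("beam_half_width_delta must be positive")
  if (sample_length_L <= 0) stop("sample_length_L must be positive")
  if (peak_width_2theta <= 0) stop("peak_width_2theta must be positive")
  background <- as.numeric(background)
  if (length(background) != 2L) stop("background must be c(slope, intercept)")
  structure(
    list(wavelength = wavelength, mu_t = mu_t,
         sample_length_L = sample_length_L,
         beam_half_width_delta = beam_half_width_delta,
         peak_width_2theta = peak_width_2theta,
         background = c(slope = background[[1L]], intercept = background[[2L]]),
         counts_scale = counts_scale,
         flux_denominator = flux_denominator),
    class = "instrument_config"
  )
}

#' Correction context for intensity corrections
#'
#' A thin constructor exposing only the fields consumed by the absorption
#' and flux corrections. Any object with these fields (in particular an
#' [instrument_config()]) is accepted wherever a correction context is
#' required.
#'
#' @param mu_t Attenuation x thickness product (dimensionless, >= 0).
#' @param sample_length_L Sample length along the beam, mm.
#' @param beam_half_width_delta Beam half width, mm.
#' @param wavelength Neutron wavelength, Angstrom.
#' @param flux_denominator `"sqrt8"` or `"eight"`, see [instrument_config()].
#' @return An `instrument_config` restricted to correction fields.
#' @export
correction_context <- function(mu_t = 0, sample_length_L = 50,
                               beam_half_width_delta = 1,
                               wavelength = 4.487,
                               flux_denominator = c("sqrt8", "eight")) {
  instrument_config(wavelength = wavelength, mu_t = mu_t,
                    sample_length_L = sample_length_L,
                    beam_half_width_delta = beam_half_width_delta,
                    flux_denominator = match.arg(flux_denominator))
}

#' Gaussian density component of a membrane profile
#'
#' One moiety of the parametric membrane model. A component with
#' `center_z > 0` stands for a mirrored pair at +/- `center_z` so that the
#' resulting profile is even; a component with `center_z = 0` is a single
#' midplane Gaussian. Amplitudes are in arbitrary neutron scattering length
#' density units (the analysis never fixes an absolute scale); at 8% D2O
#' contrast aliphatic chains have negative density, so CH3 components must
#' carry `amplitude < 0` (or 0 for lipids lacking midplane methyl termini).
#'
#' @param moiety One of `"water"`, `"headgroup"`, `"CH2"`, `"CH3"`.
#' @param center_z Center position in Angstrom, >= 0 (mirrored at
#'   `-center_z` unless zero).
#' @param width_sigma Gaussian sigma in Angstrom, > 0.
#' @param amplitude Signed peak amplitude, arbitrary NSLD units.
#' @return An object of class `gaussian_component`.
#' @export
gaussian_component <- function(moiety, center_z, width_sigma, amplitude) {
  moiety <- match.arg(moiety, c("water", "headgroup", "CH2", "CH3"))
  if (width_sigma <= 0) stop("width_sigma must be positive")
  if (center_z < 0) stop("center_z must be >= 0 (mirroring is implicit)")
  structure(
    list(moiety = moiety, center_z = as.numeric(center_z),
         width_sigma = as.numeric(width_sigma),
         amplitude = as.numeric(amplitude)),
    class = "gaussian_component"
  )
}

#' Parametric membrane profile specification
#'
#' Ground truth for the forward simulator: a lamellar period, a set of
#' mirrored Gaussian components, the number of diffraction orders the
#' rendered pattern should exhibit, an archetype label and the sample
#' condition.
#'
#' @param period_d Lamellar repeat distance d, Angstrom (> 0).
#' @param components List of [gaussian_component()] objects.
#' @param n_orders Number of diffraction orders to render, in 1..8.
#' @param label Archetype tag: `"D"` (diether bilayer), `"T"` (tetraether
#'   monolayer), `"DT11"` or `"DT21"` (1:1 and 2:1 diether/tetraether
#'   mixtures), or a free-form tag.
#' @param condition A [sample_condition()].
#' @return An object of class `membrane_profile_spec`.
#' @export
membrane_profile_spec <- function(period_d, components, n_orders,
                                  label = "custom",
                                  condition = sample_condition(70, 95, 0.08)) {
  if (period_d <= 0) stop("period_d must be positive")
  if (n_orders < 1 || n_orders > 8) stop("n_orders must lie in 1..8")
  stopifnot(is.list(components))
  for (cmp in components) {
    if (!inherits(cmp, "gaussian_component")) {
      stop("components must be gaussian_component objects")
    }
    if (cmp$center_z >= period_d / 2) {
      stop(sprintf("component '%s' center (%.3g A) lies beyond the half-period %.3g A",
                   cmp$moiety, cmp$center_z, period_d / 2))
    }
    if (cmp$moiety == "CH3" && cmp$center_z != 0) {
      stop("CH3 components must sit at the midplane (center_z = 0)")
    }
  }
  structure(
    list(period_d = as.numeric(period_d), components = components,
         n_orders = as.integer(n_orders), label = label,
         condition = condition),
    class = "membrane_profile_spec"
  )
}

#' @export
print.membrane_profile_spec <- function(x, ...) {
  cat(sprintf("<membrane_profile_spec> %s: d = %.2f A, %d orders, %d components\n",
              x$label, x$period_d, x$n_orders, length(x$components)))
  for (cmp in x$components) {
    cat(sprintf("  %-9s center %6.2f A  sigma %5.2f A  amplitude %+.3f\n",
                cmp$moiety, cmp$center_z, cmp$width_sigma, cmp$amplitude))
  }
  invisible(x)
}

#' One-dimensional diffractogram
#'
#' Intensity versus scattering angle 2-theta with Poisson counting errors;
#' the unit of peak analysis. Produced by [integrate_roi()] from a
#' reciprocal-space map, by [synth_diffractogram()], or read from disk with
#' [read_diffractogram()].
#'
#' @param two_theta Strictly increasing scattering angles, degrees.
#' @param counts Nonnegative counts per bin.
#' @param sigma Counting error per bin; defaults to `sqrt(counts)`
#'   (floored at 1 where counts are positive but tiny is not needed;
#'   sigma must be > 0 wherever counts > 0).
#' @param metadata Named list of provenance (instrument, condition, seed,
#'   warnings, ...).
#' @return An object of class `diffractogram`.
#' @export
diffractogram <- function(two_theta, counts, sigma = NULL, metadata = list()) {
  two_theta <- as.numeric(two_theta)
  counts <- as.numeric(counts)
  if (any(diff(two_theta) <= 0)) stop("two_theta must be strictly increasing")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(sigma)) sigma <- sqrt(counts)
  sigma <- as.numeric(sigma)
  if (length(two_theta) != length(counts) || length(counts) != length(sigma)) {
    stop("two_theta, counts and sigma must have equal length")
  }
  if (any(sigma[counts > 0] <= 0)) {
    stop("sigma must be > 0 wherever counts > 0")
  }
  structure(
    list(two_theta = two_theta, counts = counts, sigma = sigma,
         metadata = metadata),
    class = "diffractogram"
  )
}

#' @export
print.diffractogram <- function(x, ...) {
  cat(sprintf("<diffractogram> %d bins, 2theta in [%.3f, %.3f] deg, total %.4g counts\n",
              length(x$two_theta), min(x$two_theta), max(x$two_theta),
              sum(x$counts)))
  invisible(x)
}

#' Reciprocal-space map from an omega scan
#'
#' A 2D intensity grid over sample rotation Omega (rows) and scattering
#' angle 2-theta (columns), as produced by stacking rocking-curve scans.
#'
#' @param omega_axis Omega values, degrees (rows of `intensity`).
#' @param two_theta_axis 2-theta values, degrees (columns of `intensity`).
#' @param intensity Nonnegative matrix, `length(omega_axis)` x
#'   `length(two_theta_axis)`.
#' @param metadata Named list of provenance.
#' @return An object of class `reciprocal_map`.
#' @export
reciprocal_map <- function(omega_axis, two_theta_axis, intensity,
                           metadata = list()) {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(omega_axis) ||
      ncol(intensity) != length(two_theta_axis)) {
    stop(sprintf("intensity grid is %d x %d but axes imply %d x %d",
                 nrow(intensity), ncol(intensity),
                 length(omega_axis), length(two_theta_axis)))
  }
  if (any(intensity < 0)) stop("intensities must be nonnegative")
  structure(
    list(omega_axis = as.numeric(omega_axis),
         two_theta_axis = as.numeric(two_theta_axis),
         intensity = intensity, metadata = metadata),
    class = "reciprocal_map"
  )
}

#' @export
print.reciprocal_map <- function(x, ...) {
  cat(sprintf("<reciprocal_map> %d Omega steps x %d 2theta bins\n",
              length(x$omega_axis), length(x$two_theta_axis)))
  invisible(x)
}

#' Set of structure factors of a lamellar stack
#'
#' Amplitudes |F_h| (and, once phased, signs V_h) of the cosine Fourier
#' coefficients of the repeat-unit scattering length density, indexed by
#' diffraction order h. Orders are contiguous from 1; an undetected order is
#' carried as amplitude 0 with a `missing` flag so the band limit stays
#' explicit.
#'
#' @param d_spacing Lamellar period d, Angstrom.
#' @param amplitudes Nonnegative |F_h| for h = 1..n.
#' @param signs Optional integer vector of +1/-1 phases V_h (NA until
#'   phased).
#' @param sigma_amplitudes Optional uncertainties of the amplitudes.
#' @param missing Logical vector flagging orders recorded as absent.
#' @param metadata Named list of provenance.
#' @return An object of class `structure_factor_set`.
#' @export
structure_factor_set <- function(d_spacing, amplitudes, signs = NULL,
                                 sigma_amplitudes = NULL, missing = NULL,
                                 metadata = list()) {
  if (d_spacing <= 0) stop("d_spacing must be positive")
  amplitudes <- as.numeric(amplitudes)
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  n <- length(amplitudes)
  if (is.null(signs)) signs <- rep(NA_integer_, n)
  if (length(signs) != n) stop("signs must match amplitudes in length")
  ok <- is.na(signs) | signs %in% c(-1L, 1L)
  if (!all(ok)) stop("signs must be -1, +1 or NA")
  if (is.null(sigma_amplitudes)) sigma_amplitudes <- rep(NA_real_, n)
  if (is.null(missing)) missing <- rep(FALSE, n)
  structure(
    list(d_spacing = as.numeric(d_spacing), orders = seq_len(n),
         amplitudes = amplitudes, signs = as.integer(signs),
         sigma_amplitudes = as.numeric(sigma_amplitudes),
         missing = as.logical(missing), metadata = metadata),
    class = "structure_factor_set"
  )
}

#' @export
print.structure_factor_set <- function(x, ...) {
  cat(sprintf("<structure_factor_set> d = %.3f A, %d orders\n",
              x$d_spacing, length(x$orders)))
  sgn <- ifelse(is.na(x$signs), "?", ifelse(x$signs < 0, "-", "+"))
  for (i in x$orders) {
    cat(sprintf("  h = %d  |F| = %8.4f  sign %s%s\n", i, x$amplitudes[i],
                sgn[i], if (x$missing[i]) "  (missing order)" else ""))
  }
  invisible(x)
}

#' Neutron scattering length density profile
#'
#' A periodic, centrosymmetric density rho(z) sampled on a uniform grid over
#' one lamellar repeat, z in [-d/2, +d/2).
#'
#' @param z_grid Uniform grid of z values, Angstrom.
#' @param rho Density values, arbitrary units.
#' @param d_spacing Lamellar period, Angstrom.
#' @param n_orders Band limit (number of cosine orders represented; NA for
#'   analytic ground-truth profiles).
#' @param contrast_d2o D2O fraction of the measurement the profile refers to.
#' @param metadata Named list of provenance (signs used, flags, ...).
#' @return An object of class `nsld_profile`.
#' @export
nsld_profile <- function(z_grid, rho, d_spacing, n_orders = NA_integer_,
                         contrast_d2o = 0.08, metadata = list()) {
  z_grid <- as.numeric(z_grid)
  rho <- as.numeric(rho)
  if (length(z_grid) != length(rho)) stop("z_grid and rho length mismatch")
  dz <- diff(z_grid)
  if (length(dz) && max(abs(dz - dz[1L])) > 1e-9 * abs(dz[1L])) {
    stop("z_grid must be uniform")
  }
  structure(
    list(z_grid = z_grid, rho = rho, d_spacing = as.numeric(d_spacing),
         n_orders = n_orders, contrast_d2o = contrast_d2o,
         metadata = metadata),
    class = "nsld_profile"
  )
}

#' @export
print.nsld_profile <- function(x, ...) {
  cat(sprintf("<nsld_profile> d = %.3f A, %d grid points%s, max|rho| = %.4g\n",
              x$d_spacing, length(x$z_grid),
              if (is.na(x$n_orders)) "" else sprintf(", %d orders", x$n_orders),
              max(abs(x$rho))))
  invisible(x)
}

# Internal: check evenness of a profile sampled on the standard grid
# z_j = -d/2 + j*d/n. Index of -z for j (0-based) is (n - j) mod n.
profile_even_error <- function(profile) {
  n <- length(profile$z_grid)
  j <- seq_len(n) - 1L
  mirror <- ((n - j) %% n) + 1L
  max(abs(profile$rho - profile$rho[mirror]))
}
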