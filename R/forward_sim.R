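# Forward simulator: parametric ground-truth profiles -> structure factors
# -> raw integrated intensities (corrections inverted) -> rendered patterns.

# Internal: evaluate the periodic, even density implied by a spec at z.
# Each component contributes its Gaussian plus, when center_z > 0, the
# mirror at -center_z; periodic images over k = -2..2 repeats make the
# result properly periodic (Gaussian tails beyond 2 periods are < 1e-300
# for any physically sensible width).
eval_profile_spec <- function(spec, z) {
  d <- spec$period_d
  rho <- numeric(length(z))
  for (cmp in spec$components) {
    centers <- if (cmp$center_z > 0) c(-cmp$center_z, cmp$center_z) else 0
    for (ctr in centers) {
      for (k in -2:2) {
        rho <- rho + cmp$amplitude *
          exp(-((z - ctr - k * d)^2) / (2 * cmp$width_sigma^2))
      }
    }
  }
  rho
}

#' Sample a membrane profile specification on a grid
#'
#' Realizes the parametric ground-truth density: the sum of all Gaussian
#' components and their mirror images, periodically continued, sampled on
#' `n_grid` evenly spaced points spanning one repeat `[-d/2, +d/2)`. The
#' result is even (rho(z) = rho(-z)) by construction.
#'
#' @param spec A [membrane_profile_spec()].
#' @param n_grid Number of grid points, >= 64. The default 512 oversamples a
#'   4-order band limit by more than 60x.
#' @return An [nsld_profile()] with `n_orders = NA` (analytic profile, not
#'   band limited).
#' @examples
#' spec <- fixture_preset("D", sample_condition(60, 95, 0.08))
#' prof <- build_profile(spec)
#' @export
build_profile <- function(spec, n_grid = 512L) {
  stopifnot(inherits(spec, "membrane_profile_spec"))
  if (n_grid < 64L) stop("n_grid must be >= 64")
  d <- spec$period_d
  z <- -d / 2 + d * (seq_len(n_grid) - 1L) / n_grid
  nsld_profile(z, eval_profile_spec(spec, z), d_spacing = d,
               n_orders = NA_integer_,
               contrast_d2o = spec$condition$d2o_fraction,
               metadata = list(label = spec$label,
                               condition = unclass(spec$condition)))
}

#' Cosine structure factors of an even periodic profile
#'
#' Computes the signed cosine moments
#' `F_h = integral over one repeat of rho(z) * cos(2*pi*h*z/d) dz`
#' for h = 1..n_orders by the rectangle rule on the profile's uniform grid
#' (spectrally accurate for smooth periodic integrands, and exactly the
#' discrete-orthogonality inverse of [synthesize_profile()]).
#'
#' @param profile An even, periodic [nsld_profile()].
#' @param n_orders Number of orders to compute.
#' @param tol Relative evenness tolerance; an asymmetric profile beyond it
#'   is rejected because the cosine-only (centrosymmetric) model is invalid.
#' @return A [structure_factor_set()] carrying amplitudes |F_h| and the true
#'   signs V_h = sign(F_h).
#' @export
structure_factors_from_profile <- function(profile, n_orders, tol = 1e-8) {
  stopifnot(inherits(profile, "nsld_profile"))
  if (n_orders < 1) stop("n_orders must be >= 1")
  scale <- max(abs(profile$rho), .Machine$double.xmin)
  if (profile_even_error(profile) > tol * scale) {
    stop("profile is not even within tolerance; the cosine-only ",
         "(centrosymmetric) structure-factor model does not apply")
  }
  d <- profile$d_spacing
  f <- vapply(seq_len(n_orders), function(h) {
    d * mean(profile$rho * cos(2 * pi * h * profile$z_grid / d))
  }, numeric(1))
  sgn <- ifelse(f == 0, 1L, as.integer(sign(f)))
  structure_factor_set(d, abs(f), signs = sgn,
                       metadata = c(profile$metadata, list(source = "profile")))
}

# Internal: Bragg angles theta_h (deg) for orders h at period d.
bragg_theta_deg <- function(d, orders, wavelength) {
  s <- orders * wavelength / (2 * d)   # sin(theta) from q_h = 2*pi*h/d
  if (any(s >= 1)) stop("order beyond the accessible angular range")
  asin(s) * 180 / pi
}

#' Raw integrated intensities from structure factors
#'
#' Inverts the intensity corrections of the analysis chain: given signed or
#' unsigned structure factors, returns the uncorrected integrated Bragg
#' intensities `I_h = F_h^2 / (C_abs * C_Lor * C_flux)` at the supplied peak
#' angles. This is the exact inverse of [structure_factor_amplitudes()], so
#' rendered synthetic data feed the analysis chain with a consistent
#' ground truth.
#'
#' @param sf A [structure_factor_set()].
#' @param instrument An [instrument_config()] (or [correction_context()]).
#' @param peak_thetas Optional half scattering angles theta_h in degrees,
#'   one per order; by default derived from `q_h = 2*pi*h/d`.
#' @return Numeric vector of intensities I_h (area units).
#' @export
intensities_from_factors <- function(sf, instrument, peak_thetas = NULL) {
  stopifnot(inherits(sf, "structure_factor_set"))
  if (is.null(peak_thetas)) {
    peak_thetas <- bragg_theta_deg(sf$d_spacing, sf$orders,
                                   instrument$wavelength)
  }
  if (length(peak_thetas) != length(sf$orders)) {
    stop("need one theta per order")
  }
  if (any(peak_thetas <= 0 | peak_thetas >= 90)) {
    stop("theta must lie in (0, 90) degrees")
  }
  corr <- vapply(peak_thetas, function(th) {
    absorption_correction(instrument, th) * lorentz_correction(th) *
      flux_correction(instrument, th)
  }, numeric(1))
  sf$amplitudes^2 / corr
}

#' Render a synthetic 1D diffractogram
#'
#' Draws Gaussian Bragg peaks with integrated areas proportional to the raw
#' intensities implied by `sf` (corrections inverted), on top of a linear
#' background, optionally with Poisson counting noise. Expected counts per
#' bin are `counts_scale * sum_h I_h * dnorm(2theta; 2theta_h, w) * bin` plus
#' the background evaluated at the bin centre.
#'
#' @param sf A [structure_factor_set()].
#' @param instrument An [instrument_config()]; supplies peak width,
#'   background, counts scale and the corrections to invert.
#' @param noise `"none"` (expected counts, continuous) or `"poisson"`.
#' @param seed Integer seed used when `noise = "poisson"`; recorded in
#'   metadata.
#' @param two_theta_range Rendered angular range, degrees.
#' @param step Bin width, degrees.
#' @return A [diffractogram()]. If two orders are closer than twice the peak
#'   width a `"overlapping_orders"` warning string is recorded in the
#'   metadata.
#' @export
synth_diffractogram <- function(sf, instrument, noise = c("none", "poisson"),
                                seed = 0L, two_theta_range = c(1, 26),
                                step = 0.02) {
  noise <- match.arg(noise)
  stopifnot(inherits(sf, "structure_factor_set"))
  two_theta <- seq(two_theta_range[1L], two_theta_range[2L], by = step)
  keep <- !sf$missing & sf$amplitudes > 0
  orders <- sf$orders[keep]
  warnings <- character()
  expected <- instrument$background[["intercept"]] +
    instrument$background[["slope"]] * two_theta
  if (length(orders)) {
    th <- bragg_theta_deg(sf$d_spacing, sf$orders, instrument$wavelength)
    if (any(2 * th[keep] > two_theta_range[2L])) {
      stop("orders fall outside the rendered angular range; widen two_theta_range")
    }
    intens <- intensities_from_factors(sf, instrument, th)
    w <- instrument$peak_width_2theta
    pos <- 2 * th[keep]
    if (length(pos) > 1L && min(diff(sort(pos))) < 2 * w) {
      warnings <- c(warnings, "overlapping_orders")
    }
    for (i in seq_along(orders)) {
      h <- orders[i]
      expected <- expected + instrument$counts_scale * intens[h] *
        stats::dnorm(two_theta, mean = pos[i], sd = w) * step
    }
  }
  expected <- pmax(expected, 0)
  if (noise == "poisson") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    counts <- stats::rpois(length(expected), expected)
    sigma <- sqrt(pmax(counts, 1))
  } else {
    counts <- expected
    sigma <- sqrt(pmax(counts, 1))
  }
  diffractogram(two_theta, counts, sigma,
                metadata = list(seed = if (noise == "poisson") as.integer(seed) else NA_integer_,
                                noise = noise,
                                instrument = unclass(instrument),
                                warnings = warnings,
                                truth = list(d_spacing = sf$d_spacing,
                                             signs = sf$signs,
                                             amplitudes = sf$amplitudes)))
}

# Save/restore .Random.seed so simulator seeding never perturbs the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Render a synthetic omega-scan reciprocal-space map
#'
#' Each Bragg order contributes a Gaussian ridge in Omega centred at the
#' specular condition Omega = theta_h with width `mosaic_sigma` (the mosaic
#' / rocking spread of the multilayer). The Omega weights are normalised to
#' sum to one over the scanned rows, and the flat background is spread
#' evenly across rows, so vertical ROI integration recovers the paired 1D
#' diffractogram exactly.
#'
#' @param sf A [structure_factor_set()].
#' @param instrument An [instrument_config()].
#' @param mosaic_sigma Mosaic spread (Gaussian sigma in Omega), degrees, > 0.
#' @param seed Seed for `noise = "poisson"`.
#' @param noise `"none"` or `"poisson"`.
#' @param omega_range Scanned Omega range, degrees (default -1 to 13).
#' @param omega_step Omega step, degrees (default 0.05).
#' @param two_theta_range,step Passed through to the 2-theta axis.
#' @return A [reciprocal_map()].
#' @export
synth_omega_map <- function(sf, instrument, mosaic_sigma = 0.4, seed = 0L,
                            noise = c("none", "poisson"),
                            omega_range = c(-1, 13), omega_step = 0.05,
                            two_theta_range = c(1, 26), step = 0.02) {
  noise <- match.arg(noise)
  if (mosaic_sigma <= 0) stop("mosaic_sigma must be positive")
  base <- synth_diffractogram(sf, instrument, noise = "none", seed = seed,
                              two_theta_range = two_theta_range, step = step)
  omega <- seq(omega_range[1L], omega_range[2L], by = omega_step)
  n_om <- length(omega)
  two_theta <- base$two_theta
  bg <- instrument$background[["intercept"]] +
    instrument$background[["slope"]] * two_theta
  bg <- pmax(bg, 0)
  peaks_only <- base$counts - bg   # per-bin peak signal
  # Ridge weights per order; bins are attributed to the nearest order so
  # overlapping tails keep the column sums identical to the 1D pattern.
  keep <- !sf$missing & sf$amplitudes > 0
  th <- if (any(keep)) {
    bragg_theta_deg(sf$d_spacing, sf$orders, instrument$wavelength)[keep]
  } else numeric()
  grid <- matrix(rep(bg / n_om, each = n_om), nrow = n_om)
  if (length(th)) {
    owner <- vapply(two_theta, function(tt) which.min(abs(tt / 2 - th)),
                    integer(1))
    for (i in seq_along(th)) {
      w <- stats::dnorm(omega, mean = th[i], sd = mosaic_sigma)
      if (sum(w) <= 0) w <- as.numeric(abs(omega - th[i]) ==
                                         min(abs(omega - th[i])))
      w <- w / sum(w)
      cols <- owner == i
      grid[, cols] <- grid[, cols] + outer(w, peaks_only[cols])
    }
  }
  grid <- pmax(grid, 0)
  if (noise == "poisson") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    grid <- matrix(stats::rpois(length(grid), grid), nrow = n_om)
  }
  reciprocal_map(omega, two_theta, grid,
                 metadata = c(base$metadata,
                              list(mosaic_sigma = mosaic_sigma,
                                   omega_step = omega_step)))
}
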