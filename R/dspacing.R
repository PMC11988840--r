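# Lamellar repeat distance from Bragg peak positions.

#' Scattering vector from scattering angle
#'
#' `q_z = 4*pi*sin(theta)/lambda` with `theta = two_theta/2`. Angles in
#' degrees, wavelength in Angstrom, q in inverse Angstrom.
#'
#' @param two_theta Scattering angle 2-theta, degrees, in (0, 180).
#' @param wavelength Neutron wavelength, Angstrom.
#' @return Scattering vector q_z, inverse Angstrom.
#' @examples
#' q_from_theta(10, 4.487)
#' @export
q_from_theta <- function(two_theta, wavelength = 4.487) {
  if (any(two_theta <= 0 | two_theta >= 180)) {
    stop("two_theta must lie in (0, 180) degrees")
  }
  if (wavelength <= 0) stop("wavelength must be positive")
  4 * pi * sin(deg2rad(two_theta / 2)) / wavelength
}

#' Scattering angle from scattering vector
#'
#' Inverse of [q_from_theta()]: `two_theta = 2*asin(q*lambda/(4*pi))`.
#'
#' @param q Scattering vector, inverse Angstrom, with `q*lambda/(4*pi) < 1`.
#' @param wavelength Neutron wavelength, Angstrom.
#' @return Scattering angle 2-theta, degrees.
#' @export
theta_from_q <- function(q, wavelength = 4.487) {
  s <- q * wavelength / (4 * pi)
  if (any(s <= 0 | s >= 1)) stop("q outside the accessible range")
  2 * asin(s) * 180 / pi
}

new_lamellar_fit <- function(d, sigma_d, slope, sigma_slope, intercept,
                             sigma_intercept, n_orders_used, method,
                             flags = character()) {
  structure(
    list(d_spacing = d, sigma_d = sigma_d,
         slope_q_per_order = slope, sigma_slope = sigma_slope,
         intercept_q = intercept, sigma_intercept = sigma_intercept,
         n_orders_used = as.integer(n_orders_used), method = method,
         flags = flags),
    class = "lamellar_fit"
  )
}

#' @export
print.lamellar_fit <- function(x, ...) {
  cat(sprintf("<lamellar_fit> d = %.3f +/- %.3g A (%s, %d orders)%s\n",
              x$d_spacing, x$sigma_d, x$method, x$n_orders_used,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' d-spacing from a linear fit of peak positions versus order
#'
#' Converts each fitted peak position to `q_h = 4*pi*sin(theta_h)/lambda`
#' and fits `q_h = slope * h + intercept` by weighted least squares
#' (inverse-variance weights from the fitted position uncertainties,
#' unweighted when absent). The repeat distance is `d = 2*pi/slope` and its
#' uncertainty propagates from the slope standard error,
#' `sigma_d = 2*pi*sigma_slope/slope^2`. The intercept is free: it absorbs
#' a small zero-angle misalignment and is flagged (`"nonzero_intercept"`)
#' when it exceeds three times its standard error.
#'
#' Peaks flagged as non-lamellar by [fit_peaks()] are excluded.
#'
#' @param peaks A `bragg_peak_set` from [fit_peaks()], or a data frame with
#'   columns `order`, `position` (degrees 2-theta) and optionally
#'   `position_se`.
#' @param wavelength Neutron wavelength, Angstrom.
#' @return A `lamellar_fit` with `method = "linear_fit"`.
#' @export
dspacing_linear <- function(peaks, wavelength = 4.487) {
  pk <- as.data.frame(peaks)
  if ("lamellar" %in% names(pk)) pk <- pk[pk$lamellar, ]
  if (nrow(pk) < 2L) {
    stop("need >= 2 peaks with distinct orders for a linear fit; ",
         "use dspacing_single() for a lone first-order peak")
  }
  if (anyDuplicated(pk$order)) stop("peak orders must be distinct")
  q <- q_from_theta(pk$position, wavelength)
  # Propagate position uncertainty into q: dq/d(2theta) in rad then deg.
  have_se <- "position_se" %in% names(pk) && all(is.finite(pk$position_se)) &&
    all(pk$position_se > 0)
  w <- if (have_se) {
    dq <- (2 * pi / wavelength) * cos(deg2rad(pk$position / 2)) *
      deg2rad(pk$position_se)
    1 / dq^2
  } else rep(1, nrow(pk))
  fit <- stats::lm(q ~ order, data = data.frame(q = q, order = pk$order),
                   weights = w)
  # summary.lm warns on an exactly collinear ("perfect") fit; exact
  # arithmetic progressions are a legitimate input here.
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- cf["order", "Estimate"]
  if (!is.finite(slope) || slope <= 0) stop("non-positive slope: peak positions do not increase with order")
  sigma_slope <- cf["order", "Std. Error"]
  intercept <- cf["(Intercept)", "Estimate"]
  sigma_intercept <- cf["(Intercept)", "Std. Error"]
  # With exact input the residuals vanish and lm reports zero standard
  # errors; keep them (they are honest) but guard against NaN.
  if (!is.finite(sigma_slope)) sigma_slope <- 0
  if (!is.finite(sigma_intercept)) sigma_intercept <- 0
  flags <- character()
  if (sigma_intercept > 0 && abs(intercept) > 3 * sigma_intercept &&
      abs(intercept) > 1e-4) {   # q offsets below 1e-4 1/A are numerical
    flags <- c(flags, "nonzero_intercept")
  }
  new_lamellar_fit(2 * pi / slope, 2 * pi * sigma_slope / slope^2,
                   slope, sigma_slope, intercept, sigma_intercept,
                   nrow(pk), "linear_fit", flags)
}

#' d-spacing from a single first-order peak
#'
#' When only one Bragg reflection is observed the repeat distance follows
#' directly from `d = 2*pi/q_1`, with the uncertainty propagated from the
#' fitted position uncertainty.
#'
#' @param peak One row of a `bragg_peak_set` (or a list with `position`,
#'   optionally `position_se`), taken to be the first-order reflection.
#' @param wavelength Neutron wavelength, Angstrom.
#' @return A `lamellar_fit` with `method = "single_peak"`.
#' @export
dspacing_single <- function(peak, wavelength = 4.487) {
  pk <- as.data.frame(peak)
  if (nrow(pk) != 1L) stop("dspacing_single expects exactly one peak")
  q1 <- q_from_theta(pk$position, wavelength)
  if (q1 <= 0) stop("non-positive q")
  d <- 2 * pi / q1
  sigma_d <- if ("position_se" %in% names(pk) && is.finite(pk$position_se)) {
    dq <- (2 * pi / wavelength) * cos(deg2rad(pk$position / 2)) *
      deg2rad(pk$position_se)
    2 * pi * dq / q1^2
  } else NA_real_
  new_lamellar_fit(d, sigma_d, q1, NA_real_, 0, NA_real_, 1L, "single_peak")
}
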