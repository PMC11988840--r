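# Shared fixtures: everything is generated in code at test time.

std_inst <- function(...) instrument_config(...)

# Render a preset archetype into (spec, structure factors, diffractogram).
render_preset <- function(label, temp = 70, rh = 95, d2o = 0.08,
                          noise = "none", seed = 0L,
                          inst = std_inst(), n_grid = 512L) {
  cond <- sample_condition(temp, rh, d2o)
  spec <- fixture_preset(label, cond)
  sf <- structure_factors_from_profile(build_profile(spec, n_grid),
                                       spec$n_orders)
  dg <- synth_diffractogram(sf, inst, noise = noise, seed = seed)
  list(spec = spec, sf = sf, dg = dg, cond = cond, inst = inst)
}

sign_string <- function(v) paste(ifelse(v < 0, "-", "+"), collapse = "")

# Independent high-resolution quadrature oracle for cosine moments of a
# membrane_profile_spec (adaptive integrate() per component, closed over
# the analytic Gaussian sum).
oracle_moments <- function(spec, n_orders) {
  d <- spec$period_d
  f <- function(z, h) {
    rho <- numeric(length(z))
    for (cmp in spec$components) {
      centers <- if (cmp$center_z > 0) c(-cmp$center_z, cmp$center_z) else 0
      for (ctr in centers) for (k in -2:2) {
        rho <- rho + cmp$amplitude *
          exp(-((z - ctr - k * d)^2) / (2 * cmp$width_sigma^2))
      }
    }
    rho * cos(2 * pi * h * z / d)
  }
  vapply(seq_len(n_orders), function(h) {
    stats::integrate(f, -d / 2, d / 2, h = h, rel.tol = 1e-12,
                     subdivisions = 2000L)$value
  }, numeric(1))
}
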