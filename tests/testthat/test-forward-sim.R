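# Forward simulator: profiles, cosine moments, intensity inversion,
# rendered diffractograms and omega maps, archetype presets.

test_that("build_profile realizes even, periodic component sums", {
  cond <- sample_condition(70, 95, 0.08)
  empty <- membrane_profile_spec(50, list(), 3, "empty", cond)
  expect_true(all(build_profile(empty)$rho == 0))

  pair <- membrane_profile_spec(
    50, list(gaussian_component("headgroup", 20, 2, 1)), 3, "pair", cond)
  prof <- build_profile(pair, 1000)
  # exactly two equal maxima at +/- 20 A
  r <- prof$rho
  imax <- which(diff(sign(diff(r))) == -2) + 1L
  expect_length(imax, 2L)
  expect_equal(abs(prof$z_grid[imax]), c(20, 20), tolerance = 0.1)
  expect_equal(r[imax[1]], r[imax[2]], tolerance = 1e-12)

  # evenness for every preset (property, all archetypes x conditions)
  for (lab in c("D", "T", "DT11", "DT21")) for (rh in c(80, 95)) {
    p <- build_profile(fixture_preset(lab, sample_condition(70, rh, 0.08)))
    expect_lt(lamellar:::profile_even_error(p), 1e-12 * max(abs(p$rho)))
  }

  # midplane trough of the diether archetype (analytic ground truth)
  pd <- build_profile(fixture_preset("D", cond))
  i0 <- which.min(abs(pd$z_grid))
  expect_lt(pd$rho[i0], pd$rho[i0 - 1L])
  expect_lt(pd$rho[i0], pd$rho[i0 + 1L])

  # component beyond the half-period is rejected by name
  expect_error(
    membrane_profile_spec(40, list(gaussian_component("CH2", 25, 3, 1)),
                          3, "bad", cond),
    "CH2.*half-period")
})

test_that("structure_factors_from_profile computes signed cosine moments", {
  d <- 50
  z <- -d / 2 + d * (0:511) / 512
  # constant profile: all moments vanish
  flat <- nsld_profile(z, rep(3, 512), d)
  expect_true(all(structure_factors_from_profile(flat, 4)$amplitudes < 1e-12))
  # pure cosine: F_1 = d/2 exactly, higher orders zero
  pure <- nsld_profile(z, cos(2 * pi * z / d), d)
  sf <- structure_factors_from_profile(pure, 3)
  expect_equal(sf$amplitudes[1], d / 2, tolerance = 1e-12)
  expect_lt(max(sf$amplitudes[2:3]), 1e-12)
  expect_equal(sf$signs[1], 1L)
  # D archetype against the adaptive-quadrature oracle
  spec <- fixture_preset("D", sample_condition(60, 95, 0.08))
  got <- structure_factors_from_profile(build_profile(spec), 4)
  want <- oracle_moments(spec, 4)
  expect_equal(got$signs * got$amplitudes, want, tolerance = 1e-6)
  # asymmetric profile is rejected
  odd <- nsld_profile(z, sin(2 * pi * z / d), d)
  expect_error(structure_factors_from_profile(odd, 2), "not even")
})

test_that("intensities_from_factors inverts the corrections exactly", {
  sf <- structure_factor_set(50, c(4, 0, 1), signs = c(-1L, 1L, 1L))
  # zero amplitude -> zero intensity
  inst <- std_inst()
  expect_equal(intensities_from_factors(sf, inst)[2], 0)
  # identity limit: no absorption, fully illuminated, theta = 45 deg
  ideal <- instrument_config(mu_t = 0, sample_length_L = 1e5,
                             beam_half_width_delta = 1e-3)
  expect_equal(intensities_from_factors(sf, ideal, peak_thetas = rep(45, 3)),
               sf$amplitudes^2, tolerance = 1e-9)
  # algebraic round trip intensities -> amplitudes -> intensities
  intens <- intensities_from_factors(sf, inst)
  th <- lamellar:::bragg_theta_deg(sf$d_spacing, sf$orders, inst$wavelength)
  pk <- data.frame(order = 1:3, position = 2 * th,
                   area = intens * inst$counts_scale)
  back <- structure_factor_amplitudes(pk, inst, 50)
  expect_equal(back$amplitudes, sf$amplitudes, tolerance = 1e-9)
  expect_error(intensities_from_factors(sf, inst, peak_thetas = c(1, 2, 95)),
               "theta")
})

test_that("synth_diffractogram renders calibrated Gaussian peaks", {
  fx <- render_preset("DT11")
  inst0 <- instrument_config(background = c(0, 0))
  dg <- synth_diffractogram(fx$sf, inst0, noise = "none")
  total <- sum(dg$counts)
  expect_equal(total,
               sum(intensities_from_factors(fx$sf, inst0)) * inst0$counts_scale,
               tolerance = 1e-6)
  # no orders -> flat background
  empty <- structure_factor_set(50, numeric(0))
  flat <- synth_diffractogram(empty, std_inst(), noise = "none")
  expect_true(all(flat$counts == flat$counts[1]))
  # overlapping orders recorded as a warning in metadata
  wide <- instrument_config(peak_width_2theta = 3)
  dgw <- synth_diffractogram(fx$sf, wide, noise = "none")
  expect_true("overlapping_orders" %in% dgw$metadata$warnings)
  # Poisson noise: nonnegative integer counts, reproducible by seed
  d1 <- synth_diffractogram(fx$sf, std_inst(), noise = "poisson", seed = 7)
  d2 <- synth_diffractogram(fx$sf, std_inst(), noise = "poisson", seed = 7)
  expect_identical(d1$counts, d2$counts)
  expect_true(all(d1$counts >= 0) && all(d1$counts == round(d1$counts)))
})

test_that("synth_omega_map reduces back to the 1D diffractogram", {
  fx <- render_preset("T")
  map <- synth_omega_map(fx$sf, fx$inst, mosaic_sigma = 0.4)
  # dimensions of the standard scan: -1 to 13 deg in 0.05 steps
  expect_length(map$omega_axis, 281L)
  expect_equal(map$omega_axis[2] - map$omega_axis[1], 0.05)
  red <- integrate_roi(map)
  expect_equal(red$counts, fx$dg$counts, tolerance = 1e-6)
  # near-zero mosaic: intensity concentrated on single Omega rows
  tight <- synth_omega_map(fx$sf, fx$inst, mosaic_sigma = 1e-4)
  col <- which.max(colSums(tight$intensity))
  profile_om <- tight$intensity[, col]
  expect_gt(max(profile_om) / sum(profile_om), 0.99)
})

test_that("fixture presets encode the archetype facts", {
  cond <- sample_condition(70, 95, 0.08)
  hg_amp <- function(lab) {
    sp <- fixture_preset(lab, cond)
    vapply(sp$components, function(cc)
      if (cc$moiety == "headgroup") cc$amplitude else NA_real_,
      numeric(1)) |> (\(x) x[!is.na(x)])()
  }
  expect_equal(hg_amp("T") / hg_amp("D"), 5, tolerance = 0.01) # 1 : 0.2
  # DT21 midplane trough deeper than DT11 (analytic profiles)
  t21 <- trough_depth(build_profile(fixture_preset("DT21", cond)))
  t11 <- trough_depth(build_profile(fixture_preset("DT11", cond)))
  expect_gt(t21, t11)
  expect_gt(t11, 0)
  # every preset at 8% D2O has ~zero water amplitude
  for (lab in c("D", "T", "DT11", "DT21")) {
    sp <- fixture_preset(lab, cond)
    wamp <- vapply(sp$components, function(cc)
      if (cc$moiety == "water") abs(cc$amplitude) else 0, numeric(1))
    expect_lt(max(wamp), 1e-12)
  }
  expect_error(fixture_preset("X", cond), "unknown preset")
})
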