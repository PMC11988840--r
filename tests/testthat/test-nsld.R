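# Intensity corrections, structure-factor amplitudes, sign search,
# Fourier synthesis, contrast-variation water profile.

test_that("correction factors match closed forms and limits", {
  ctx <- correction_context(mu_t = 0)
  # no absorption
  expect_equal(absorption_correction(ctx, 10), 1)
  # alpha = 2 evaluated independently: C = 2 / (1 - exp(-2))
  ctx2 <- correction_context(mu_t = 1)           # alpha = 2 at theta = 90-eps
  th <- 89.999999
  expect_equal(absorption_correction(ctx2, th), 2 / (1 - exp(-2)),
               tolerance = 1e-6)
  # monotone increase toward grazing incidence
  cc <- absorption_correction(correction_context(mu_t = 0.1),
                              c(1, 2, 5, 10, 30, 60))
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc >= 1))

  expect_equal(lorentz_correction(45), 1)
  expect_equal(lorentz_correction(30), sin(60 * pi / 180))
  expect_equal(lorentz_correction(20), lorentz_correction(70))

  # fully illuminated limit and the erf oracle via pnorm
  big <- correction_context(sample_length_L = 1e6)
  expect_equal(flux_correction(big, 30), 1, tolerance = 1e-12)
  # L sin(theta) / (sqrt(8) delta) = 1  =>  C = 1 / erf(1)
  erf1 <- 2 * pnorm(sqrt(2)) - 1
  delta <- 1
  L <- sqrt(8) * delta / sin(30 * pi / 180)
  expect_equal(flux_correction(correction_context(
    sample_length_L = L, beam_half_width_delta = delta), 30),
    1 / erf1, tolerance = 1e-12)
  fl <- flux_correction(std_inst(), c(1, 2, 5, 10, 45, 80))
  expect_true(all(diff(fl) <= 0) && all(fl >= 1))
  # geometry failure is named
  expect_error(flux_correction(correction_context(
    sample_length_L = 1e-9), 1), "beam")
})

test_that("structure_factor_amplitudes applies sqrt of corrected intensity", {
  ctx <- instrument_config(mu_t = 0, sample_length_L = 1e5,
                           beam_half_width_delta = 1e-3, counts_scale = 1)
  pk <- data.frame(order = 1:2, position = c(90, 90), area = c(16, 0))
  sf <- structure_factor_amplitudes(pk, ctx, 50)
  expect_equal(sf$amplitudes, c(4, 0), tolerance = 1e-9)
  # missing order recorded as zero amplitude with a flag
  pk2 <- data.frame(order = c(1, 3), position = c(5, 15), area = c(9, 4))
  expect_warning(sf2 <- structure_factor_amplitudes(pk2, std_inst(), 50),
                 "missing order")
  expect_equal(sf2$amplitudes[2], 0)
  expect_true(sf2$missing[2])
  expect_error(structure_factor_amplitudes(
    data.frame(order = 1, position = 5, area = -1), std_inst(), 50),
    "negative")
})

test_that("full-chain amplitudes match the forward model", {
  fx <- render_preset("T")
  pk <- fit_peaks(fx$dg, detect_peaks(fx$dg))
  sf <- structure_factor_amplitudes(pk, fx$inst,
                                    dspacing_linear(pk)$d_spacing)
  expect_lt(max(abs(sf$amplitudes - fx$sf$amplitudes)),
            1e-3 * max(fx$sf$amplitudes))
})

test_that("phase_search recovers the generator signs on every preset", {
  for (lab in c("D", "T", "DT11", "DT21")) for (rh in c(80, 95)) {
    fx <- render_preset(lab, temp = 70, rh = rh)
    if (length(fx$sf$orders) < 3L) {
      expect_error(phase_search(fx$sf), "3 diffraction orders")
      next
    }
    ps <- phase_search(fx$sf)
    expect_true(ps$pass[1L])
    expect_equal(attr(ps, "top"), fx$sf$signs,
                 label = paste(lab, rh))
  }
  # D archetype evaluated at 4 orders: the printed vector [-, -, +, -]
  spec <- fixture_preset("D", sample_condition(60, 95, 0.08))
  sf4 <- structure_factors_from_profile(build_profile(spec), 4)
  expect_equal(sign_string(attr(phase_search(sf4), "top")), "--+-")
  # dominant first order: leading sign forced negative by rho(0) <= 0
  sfd <- structure_factor_set(50, c(10, 0.3, 0.2))
  ps <- suppressWarnings(phase_search(sfd))
  expect_true(all(substr(ps$signs, 1, 1) == "-"))
})

test_that("phase_search ranking equals an independent brute-force rescoring", {
  fx <- render_preset("DT21")
  ps <- phase_search(fx$sf)
  d <- fx$sf$d_spacing
  n <- length(fx$sf$orders)
  z <- -d / 2 + d * (0:511) / 512
  oracle <- do.call(rbind, lapply(seq_len(2^n) - 1L, function(code) {
    v <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, 1L, -1L)
    rho <- as.numeric(sapply(1:n, function(h) cos(2 * pi * h * z / d)) %*%
                        (v * fx$sf$amplitudes))
    rho <- rho / max(abs(rho))
    rho0 <- rho[257L]
    if (rho0 > 0) return(NULL)
    central <- abs(z) <= d / 8
    pa <- rho0 <= min(rho[central]) + 1e-12
    zm <- abs(z[rho >= max(rho) - 1e-9]) / (d / 2)
    pb <- all(zm >= 0.5 & zm <= 0.95)
    data.frame(signs = sign_string(v), gap = rho[1L], pass = pa && pb)
  }))
  oracle <- oracle[order(-oracle$pass, oracle$gap), ]
  expect_equal(ps$signs, oracle$signs)
  expect_equal(ps$pass, oracle$pass)
  # scale invariance of the whole ranking
  sf_scaled <- structure_factor_set(d, fx$sf$amplitudes * 123)
  expect_equal(phase_search(sf_scaled)$signs, ps$signs)
})

test_that("synthesize_profile is the exact inverse of the cosine analysis", {
  # closed form: single negative order
  sf1 <- structure_factor_set(40, 1, signs = -1L)
  prof <- synthesize_profile(sf1, 256)
  expect_equal(prof$rho,
               -(2 / 40) * cos(2 * pi * prof$z_grid / 40), tolerance = 1e-12)
  expect_equal(prof$z_grid[which.min(prof$rho)], 0)
  # all zero
  sf0 <- structure_factor_set(40, c(0, 0), signs = c(1L, 1L))
  expect_true(all(synthesize_profile(sf0)$rho == 0))
  # unphased input refuses
  expect_error(synthesize_profile(structure_factor_set(40, c(1, 2))),
               "unphased")
  # discrete orthogonality round trip < 1e-10 (property over presets)
  for (lab in c("D", "T", "DT21")) {
    fx <- render_preset(lab)
    prof <- synthesize_profile(fx$sf, 512)
    back <- structure_factors_from_profile(prof, length(fx$sf$orders))
    expect_equal(back$signs * back$amplitudes,
                 fx$sf$signs * fx$sf$amplitudes,
                 tolerance = 1e-10)
  }
  # band-limited synthesis equals the truncated cosine series of the truth
  fx <- render_preset("DT11")
  prof <- synthesize_profile(fx$sf, 512)
  z <- prof$z_grid
  series <- Reduce(`+`, lapply(fx$sf$orders, function(h) {
    (2 / fx$sf$d_spacing) * fx$sf$signs[h] * fx$sf$amplitudes[h] *
      cos(2 * pi * h * z / fx$sf$d_spacing)
  }))
  expect_equal(prof$rho, series, tolerance = 1e-12)
})

test_that("water profile by contrast isolates the gap water", {
  cond8 <- sample_condition(70, 95, 0.08)
  cond100 <- sample_condition(70, 95, 1.00)
  p8 <- build_profile(fixture_preset("T", cond8), 512)
  p100 <- build_profile(fixture_preset("T", cond100), 512)
  # identical inputs -> zero water
  expect_true(all(abs(water_profile_by_contrast(p8, p8)$rho) < 1e-12))
  w <- water_profile_by_contrast(p100, p8)
  d <- p8$d_spacing
  # recovered water curve peaks where the generating component sum does
  # (the mirrored pair at +/- 0.48 d merges at the gap edge); oracle is
  # the analytic component sum evaluated directly
  water_true <- local({
    z <- w$z_grid
    out <- numeric(length(z))
    for (ctr in c(-0.48 * d, 0.48 * d)) for (k in -2:2) {
      out <- out + exp(-((z - ctr - k * d)^2) / (2 * 3.5^2))
    }
    out * (1 - 0.08) / 0.92
  })
  gap <- abs(w$z_grid) > d / 4
  zc <- w$z_grid[gap][which.max(w$rho[gap])]
  zc_true <- w$z_grid[gap][which.max(water_true[gap])]
  expect_lt(abs(zc - zc_true), 0.5)
  # recovered area within 5% of the generating Gaussian mass
  dz <- w$z_grid[2] - w$z_grid[1]
  mass <- sum(w$rho) * dz
  truth <- 2 * 1.0 * (1 - 0.08) / 0.92 * 3.5 * sqrt(2 * pi)
  expect_equal(mass, truth, tolerance = 0.05)
  # mismatched periods refuse
  bad <- nsld_profile(p8$z_grid * 1.2, p8$rho, d * 1.2)
  expect_error(water_profile_by_contrast(bad, p8), "1%")
  # 8% contrast preset alone carries a ~zero water component
  w8 <- Filter(function(cc) cc$moiety == "water",
               fixture_preset("T", cond8)$components)[[1]]
  expect_lt(abs(w8$amplitude), 1e-12)
})
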