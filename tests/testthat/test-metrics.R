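# Profile metrics: bilayer thickness, water layer, trough, hump,
# component decomposition, condition-grid batch analysis.

test_that("bilayer_thickness refines head peaks to sub-grid precision", {
  d <- 50
  z <- -d / 2 + d * (0:511) / 512
  rho <- exp(-((z - 21.5)^2) / 8) + exp(-((z + 21.5)^2) / 8)
  prof <- nsld_profile(z, rho, d)
  expect_equal(bilayer_thickness(prof), 43.0, tolerance = 1e-3)
  # the DT11 archetype at 60 C / 95% RH carries the printed 43 A
  pa <- build_profile(fixture_preset("DT11", sample_condition(60, 95, 0.08)))
  expect_equal(bilayer_thickness(pa), 43, tolerance = 0.5)
  # parabolic interpolation agrees with argmax on a 100x denser synthesis
  fx <- render_preset("T")
  prof_c <- synthesize_profile(fx$sf, 512)
  dense <- synthesize_profile(fx$sf, 51200)
  db_dense <- 2 * dense$z_grid[dense$z_grid > 0][
    which.max(dense$rho[dense$z_grid > 0])]
  expect_equal(bilayer_thickness(prof_c), db_dense, tolerance = 0.02)
  # monotone profile: no head peaks
  mono <- nsld_profile(z, -cos(2 * pi * z / d), d)
  expect_error(bilayer_thickness(mono), "no head peaks")
})

test_that("water_thickness is exact subtraction with guards", {
  expect_identical(water_thickness(55, 43), 12)
  expect_identical(water_thickness(51, 41), 10)
  expect_equal(water_thickness(50, 50 - 1e-6), 1e-6, tolerance = 1e-6)
  expect_error(water_thickness(40, 43), "exceed")
  expect_error(water_thickness(40, -1), "positive")
})

test_that("trough_depth measures the central dip only when a shoulder exists", {
  d <- 50
  z <- -d / 2 + d * (0:511) / 512
  # pure first-order profile: monotone central region, no trough
  expect_equal(trough_depth(nsld_profile(z, -cos(2 * pi * z / d), d)), 0)
  # archetype ordering: more diether -> deeper trough (both humidities)
  for (rh in c(80, 95)) {
    cond <- sample_condition(60, rh, 0.08)
    t21 <- trough_depth(build_profile(fixture_preset("DT21", cond)))
    t11 <- trough_depth(build_profile(fixture_preset("DT11", cond)))
    expect_gt(t21, t11)
    expect_gt(t11, 0)
  }
  # equals brute-force max-minus-center on the same (dense) grid
  cond <- sample_condition(70, 95, 0.08)
  prof <- build_profile(fixture_preset("DT21", cond), 512)
  dense <- build_profile(fixture_preset("DT21", cond), 65536)
  rn <- dense$rho / max(abs(dense$rho))
  brute <- max(rn[abs(dense$z_grid) <= dense$d_spacing / 8]) -
    rn[which.min(abs(dense$z_grid))]
  expect_equal(trough_depth(dense), brute, tolerance = 1e-6)
  expect_equal(trough_depth(prof), brute, tolerance = 0.02)
  # scale invariance
  big <- nsld_profile(prof$z_grid, 5 * prof$rho, prof$d_spacing)
  expect_equal(trough_depth(big), trough_depth(prof), tolerance = 1e-9)
})

test_that("hump_metric locates the hydrocarbon shoulder", {
  d <- 50
  z <- -d / 2 + d * (0:511) / 512
  # two-order profile without interior extremum between d/8 and head
  two <- nsld_profile(z, -cos(2 * pi * z / d) - 0.3 * cos(4 * pi * z / d), d)
  expect_equal(hump_metric(two)$amplitude, 0)
  # T archetype at 95% RH: hump at the CH2 center (analytic profile)
  spec <- fixture_preset("T", sample_condition(70, 95, 0.08))
  hm <- hump_metric(build_profile(spec, 2048))
  ch2 <- Filter(function(cc) cc$moiety == "CH2", spec$components)[[1]]
  expect_gt(hm$amplitude, 0)
  expect_lt(abs(hm$position - ch2$center_z), 2)
  # agrees with an exhaustive local-extremum scan on a dense grid
  dense <- build_profile(spec, 65536)
  rn <- dense$rho / max(abs(dense$rho))
  zd <- dense$z_grid
  zh <- bilayer_thickness(dense) / 2
  m <- length(rn)
  locmax <- which(rn[2:(m - 1)] > rn[1:(m - 2)] &
                    rn[2:(m - 1)] > rn[3:m]) + 1L
  locmax <- locmax[zd[locmax] > dense$d_spacing / 8 &
                     zd[locmax] < zh - 0.5]
  i <- locmax[which.max(rn[locmax])]
  expect_equal(hm$position, zd[i], tolerance = 0.05)
})

test_that("component_decomposition recovers the generating moieties", {
  fx <- render_preset("DT11")
  prof <- synthesize_profile(fx$sf, 512)
  db <- bilayer_thickness(prof)
  dec <- component_decomposition(prof, d_b = db)
  par <- dec$parameters
  truth <- fx$spec$components
  hg_t <- truth[[1]]; ch2_t <- truth[[2]]; ch3_t <- truth[[3]]
  expect_lt(abs(par$center[par$moiety == "headgroup"] - hg_t$center_z), 1)
  expect_lt(abs(par$center[par$moiety == "CH2"] - ch2_t$center_z), 1)
  expect_equal(par$amplitude[par$moiety == "headgroup"], hg_t$amplitude,
               tolerance = 0.05)
  expect_equal(par$amplitude[par$moiety == "CH2"], ch2_t$amplitude,
               tolerance = 0.05)
  # CH3 strictly negative for diether-containing samples; absolute
  # tolerance (the CH3 share of 4 cosine moments is weakly determined)
  ch3_amp <- par$amplitude[par$moiety == "CH3"]
  expect_lt(ch3_amp, 0)
  expect_lt(abs(ch3_amp - ch3_t$amplitude), 0.05)
  expect_length(dec$flags, 0)

  # tetraether: CH3 component collapses to ~0
  ft <- render_preset("T")
  pt <- synthesize_profile(ft$sf, 512)
  dt <- component_decomposition(pt, d_b = bilayer_thickness(pt))
  expect_gt(dt$parameters$amplitude[dt$parameters$moiety == "CH3"], -0.05)
})

test_that("analyze_condition_grid isolates failures per row", {
  inst <- std_inst()
  inputs <- list()
  for (lab in c("D", "T", "DT11", "DT21")) for (rh in c(80, 95)) {
    for (temp in c(60, 80)) {
      fx <- render_preset(lab, temp = temp, rh = rh)
      inputs[[length(inputs) + 1L]] <-
        list(diff = fx$dg, instrument = inst, condition = fx$cond,
             label = lab)
    }
  }
  tab <- analyze_condition_grid(inputs)
  expect_equal(nrow(tab), 16L)
  expect_true(all(is.na(tab$error)))
  # d_w + d_b = d exactly wherever both are present
  has <- !is.na(tab$d_b)
  expect_identical(tab$d_spacing[has] - tab$d_b[has], tab$d_w[has])
  # 80% RH diether: 2 orders, d-spacing present, NSLD metrics refused
  drow <- tab[tab$label == "D" & tab$relative_humidity == 80, ]
  expect_true(all(drow$n_orders == 2L))
  expect_true(all(grepl("insufficient_orders", drow$flags)))
  expect_true(all(!is.na(drow$d_spacing)) && all(is.na(drow$d_b)))
  # all >= 3-order rows carry clean metrics
  expect_true(all(!is.na(tab$d_b[tab$n_orders >= 3])))

  # one corrupted diffractogram does not poison the grid
  bad <- inputs[[1]]
  bad$diff <- diffractogram(c(1, 2, 3), c(0, 0, 0))
  tab2 <- analyze_condition_grid(c(list(bad), inputs[2:3]))
  expect_equal(sum(!is.na(tab2$error)), 1L)
  expect_true(all(is.na(tab2$error[-which(!is.na(tab2$error))])))
})

test_that("metrics are invariant under amplitude rescaling and reflection", {
  fx <- render_preset("DT21")
  prof <- synthesize_profile(fx$sf, 512)
  n <- length(prof$z_grid)
  mirror_idx <- ((n - (seq_len(n) - 1L)) %% n) + 1L   # index of -z
  scaled <- nsld_profile(prof$z_grid, prof$rho * 13, prof$d_spacing)
  mirrored <- nsld_profile(prof$z_grid, prof$rho[mirror_idx],
                           prof$d_spacing)
  for (p in list(scaled, mirrored)) {
    expect_equal(bilayer_thickness(p), bilayer_thickness(prof),
                 tolerance = 1e-6)
    expect_equal(trough_depth(p), trough_depth(prof), tolerance = 1e-9)
  }
})
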