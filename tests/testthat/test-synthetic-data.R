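test_that("dissolution kinetics match their closed forms", {
  sol <- species_definition("s", 1e4, 10, solubility_class = "soluble",
                            kinetics = c(tau_fast = 10))
  expect_equal(elution_kinetics(sol, 0), 1.0)
  expect_equal(elution_kinetics(sol, 30), exp(-3))
  expect_error(elution_kinetics(sol, -1), "t must be")

  mem <- species_definition("m", 1e4, 10,
                            solubility_class = "membrane_associated",
                            kinetics = c(tau_rise = 30))
  tt <- seq(0, 200, by = 0.01)
  expect_equal(tt[which.max(elution_kinetics(mem, tt))], 30,
               tolerance = 1e-3)
  expect_equal(max(elution_kinetics(mem, tt)), 1.0, tolerance = 1e-8)

  tm <- species_definition("t", 1e4, 10,
                           solubility_class = "transmembrane",
                           kinetics = c(tau_rise = 30, tau_slow = 120))
  # unit peak, located where the grid-search maximum sits
  expect_equal(max(elution_kinetics(tm, tt)), 1.0, tolerance = 1e-8)
  t_peak_grid <- tt[which.max(elution_kinetics(tm, tt))]
  expect_equal(t_peak_grid, 30 * log(1 + 120 / 30), tolerance = 1e-2)
})

test_that("synthesized spectra put charge-state peaks where the mass says", {
  sp <- species_definition("v", 30668.0, 10)
  grid <- seq(2400, 4000, 0.25)
  s <- synth_spectrum(list(list(species = sp, abundance = 100)), grid)
  expect_equal(s$mz[which.max(s$intensity)], (30668.0 + 10 * 1.00728) / 10,
               tolerance = 0.3)

  # VDAC1-like: all four printed charge-state peaks within +/- 0.35 Th
  vd <- species_definition("vdac", 30668.0, 8:11,
                           solubility_class = "transmembrane")
  s2 <- synth_spectrum(list(list(species = vd, abundance = 100)), grid)
  printed <- c(2788.9, 3067.9, 3408.5, 3834.6)
  for (p in printed) {
    near <- abs(s2$mz - p) <= 0.35
    expect_gt(max(s2$intensity[near]), 0.5 * max(s2$intensity))
  }

  # zero abundance with zero noise -> identically baseline
  s3 <- synth_spectrum(list(list(species = sp, abundance = 0)), grid,
                       noise = c(2.5, 0))
  expect_true(all(s3$intensity == 2.5))
  s4 <- synth_spectrum(list(), grid)
  expect_true(all(s4$intensity == 0))
})

test_that("identical seeds give bit-identical simulated streams", {
  ph <- two_region_phantom(2, 2, 1)
  sp <- default_species()[c(1, 6)]
  sched <- acquisition_schedule(dwell_s = 13)
  a <- simulate_discrete_run(ph, sp, sched, seed = 123, snr = 10)
  b <- simulate_discrete_run(ph, sp, sched, seed = 123, snr = 10)
  expect_identical(a$scans, b$scans)
  expect_identical(a$truth, b$truth)
  c <- simulate_discrete_run(ph, sp, sched, seed = 124, snr = 10)
  expect_false(identical(a$scans, c$scans))
})

test_that("discrete runs emit floor(dwell/dt) scans and honest ground truth", {
  ph <- two_region_phantom(2, 1, 1)
  sp <- list(
    default_species()$sod1_like,
    species_definition("ghost", 25000, 9, abundance_map = c(0, 0)))
  sched <- acquisition_schedule()  # dwell 90 s, dt 2.6 s
  run <- simulate_discrete_run(ph, sp, sched, seed = 1)
  expect_equal(length(run$scans), 2 * floor(90 / 2.6))
  expect_equal(floor(90 / 2.6), 34)

  # zero-abundance species has all-zero ground truth
  expect_true(all(run$truth$intensity[run$truth$species == "ghost"] == 0))

  # per-pixel summed truth equals abundance x midpoint quadrature of the
  # kinetics, computed independently here
  mid <- (seq_len(34) - 0.5) * 2.6
  quad <- sum(exp(-mid / 10))
  for (p in 0:1) {
    tr <- run$truth[run$truth$pixel == p & run$truth$species == "SOD1_like", ]
    region <- ph$region_labels[1, p + 1]
    ab <- sp[[1]]$abundance_map[region + 1] * 100
    expect_equal(sum(tr$intensity), ab * quad, tolerance = 1e-6)
  }

  expect_error(
    simulate_discrete_run(ph, sp, acquisition_schedule(dwell_s = 1),
                          seed = 1),
    "no-scan pixel")
})

test_that("continuous mode sees one effective exposure per location", {
  ph <- two_region_phantom(4, 1, 2)
  tm <- species_definition("tm", 30668, 9:10,
                           solubility_class = "transmembrane",
                           kinetics = c(tau_rise = 30, tau_slow = 120),
                           abundance_map = c(1, 1))
  schedC <- acquisition_schedule("continuous", junction_diameter_um = 100,
                                 raster_speed_um_s = 5)
  expect_equal(transit_time(schedC), 20)

  run <- simulate_continuous_run(ph, list(tm), schedC, seed = 1)
  # single exposure of 20 s on a curve peaking much later: continuous-mode
  # amplitude sits below the discrete-mode peak amplitude
  cont_amp <- max(run$truth$intensity)
  expect_equal(cont_amp, 100 * elution_kinetics(tm, 20))
  expect_lt(cont_amp, 100 * 1.0)  # discrete reaches the unit peak

  # speed -> infinity: exposure -> 0, a soluble species reaches full
  # abundance (kinetics at t = 0 is 1)
  sol <- species_definition("sol", 30000, 10, abundance_map = c(1, 1))
  fast <- acquisition_schedule("continuous", raster_speed_um_s = 1e4,
                               scan_period_s = 1e-3)
  run2 <- simulate_continuous_run(ph, list(sol), fast, seed = 1)
  expect_equal(max(run2$truth$intensity), 100 * 1.0, tolerance = 1e-3)

  expect_error(simulate_continuous_run(ph, list(sol),
                                       acquisition_schedule(), seed = 1))
})
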