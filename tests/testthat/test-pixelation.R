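baseline_then_signal <- function(n_base, n_sig, base_level = 1,
                                 sig_level = 100) {
  grid <- seq(2400, 2500, 1)
  lapply(seq_len(n_base + n_sig) - 1L, function(i) {
    lev <- if (i < n_base) base_level else sig_level
    mass_spectrum(i, i * 2.6, grid, rep(lev, length(grid)))
  })
}

test_that("contact detection finds the TIC jump", {
  scans <- baseline_then_signal(5, 4)
  expect_identical(detect_contact(scans, c(2400, 2500), 5), 5L)
  expect_identical(detect_contact(scans, c(2400, 2500), 0), 0L)
  flat <- baseline_then_signal(8, 0)
  expect_error(detect_contact(flat, c(2400, 2500), 5), "no-contact")
  expect_error(detect_contact(flat[1:2], c(2400, 2500), 5), "3 scans")
})

test_that("contact alignment re-zeroes times, leaving pre-contact negative", {
  scans <- baseline_then_signal(3, 3)
  al <- align_to_contact(scans, 3L)
  times <- vapply(al, `[[`, numeric(1), "time_s")
  expect_equal(times, ((0:5) - 3) * 2.6)
  expect_true(all(times[1:3] < 0))
})

test_that("spot sampling fills each pixel's dwell and re-zeroes per pixel", {
  ph <- two_region_phantom(2, 1, 1)
  sched <- acquisition_schedule()  # 90 s dwell, 12.9 s overhead
  run <- simulate_discrete_run(ph, default_species()[1], sched, seed = 3,
                               mz_step = 5, overhead_scans = TRUE)
  img <- spot_sample(run$scans, sched, run$pixel_order)
  for (p in img$pixels) {
    expect_length(p$spectra, 34)
    expect_equal(p$spectra[[1]]$time_s, 0)
  }
  # audit reconciles: every input scan assigned or explicitly discarded
  audit <- img$metadata$scan_audit
  expect_equal(audit$assigned + audit$pre_contact + audit$overhead,
               length(run$scans))
  expect_equal(audit$overhead, sum(run$scan_roles == "overhead"))
})

test_that("spot sampling recovers the simulator's pixel assignment exactly", {
  ph <- two_region_phantom(3, 2, 2)
  sched <- acquisition_schedule(dwell_s = 26)
  for (seed in c(1, 7, 19)) {
    run <- simulate_discrete_run(ph, default_species()[c(1, 6)], sched,
                                 seed = seed, mz_step = 2,
                                 overhead_scans = TRUE)
    img <- spot_sample(run$scans, sched, run$pixel_order)
    tr <- run$truth
    for (p in unique(tr$pixel)) {
      sub <- tr[tr$pixel == p, ]
      px <- get_pixel(img, sub$col[1], sub$row[1])
      # first assigned stream scan and scan count both match ground truth
      expect_identical(px$contact_scan, min(sub$scan_global))
      expect_length(px$spectra, length(unique(sub$scan_global)))
    }
  }
})

test_that("spot sampling degenerate inputs behave", {
  sched <- acquisition_schedule()
  scans <- baseline_then_signal(0, 10)
  empty <- spot_sample(scans, sched, matrix(numeric(0), ncol = 2,
                                            dimnames = list(NULL,
                                                            c("col", "row"))))
  expect_length(empty$pixels, 0)
  # stream far too short for 4 pixels
  po <- cbind(col = c(0L, 1L, 0L, 1L), row = c(0L, 0L, 1L, 1L))
  expect_error(spot_sample(scans, sched, po), "truncation error")
})

test_that("time binning subdivides linescans by stage position", {
  ph <- two_region_phantom(8, 4, 6)
  sp <- default_species()[c("cah2_like", "vdac1_like")]
  schedC <- acquisition_schedule("continuous", pitch_x_um = 94,
                                 raster_speed_um_s = 5)
  run <- simulate_continuous_run(ph, sp, schedC, seed = 2)
  img <- time_bin(run$scans, schedC,
                  list(n_cols = 8, n_rows = 4,
                       line_start_s = run$line_start_s))
  expect_length(img$pixels, 32)
  expect_length(img$pixels[[1]]$spectra, 1)

  # noiseless per-pixel intensity map tracks the phantom abundance map
  ii <- ion_image(img, species_targets(sp)$VDAC1_like)
  ab <- matrix(sp$vdac1_like$abundance_map[ph$region_labels + 1],
               nrow = ph$n_rows)
  expect_gt(cor(as.vector(ii$grid), as.vector(ab)), 0.95)

  # single scan per bin: averaging is the identity
  # (13 um pixels at 5 um/s = 2.6 s per pixel = exactly one scan)
  grid <- seq(2400, 2450, 1)
  scans3 <- lapply(0:2, function(i) {
    mass_spectrum(i, i * 2.6, grid, rep(i + 1, length(grid)))
  })
  one <- time_bin(scans3,
                  acquisition_schedule("continuous", pitch_x_um = 13,
                                       raster_speed_um_s = 5),
                  list(n_cols = 3, n_rows = 1, line_start_s = 0))
  for (i in 0:2) {
    expect_identical(get_pixel(one, i, 0)$spectra[[1]]$intensity,
                     scans3[[i + 1]]$intensity)
  }
  expect_error(time_bin(run$scans[1:2], schedC,
                        list(n_cols = 8, n_rows = 4,
                             line_start_s = run$line_start_s)),
               "short-line")
})

test_that("acquisition planning reproduces total-time arithmetic", {
  sched <- acquisition_schedule(dwell_s = 90, per_pixel_overhead_s = 12.9)
  plan <- plan_acquisition(30, 13, sched)
  expect_equal(plan$n_pixels, 390)
  expect_equal(plan$raster_time_s, 390 * 90)
  expect_equal(plan$dead_time_s, 390 * 12.9)
  expect_equal(plan$total_time_s / 3600, 11.15, tolerance = 0.01)

  # halving the pitch in both axes quadruples pixels and time
  fine <- plan_acquisition(60, 26, sched)
  expect_equal(fine$n_pixels, 4 * plan$n_pixels)
  expect_equal(fine$total_time_s, 4 * plan$total_time_s)

  one <- plan_acquisition(1, 1, sched)
  expect_equal(one$total_time_s, 90 + 12.9)
})

test_that("junction transit time is diameter over speed", {
  expect_equal(transit_time(acquisition_schedule(
    "continuous", junction_diameter_um = 100, raster_speed_um_s = 5)), 20)
  expect_equal(transit_time(acquisition_schedule(
    "continuous", junction_diameter_um = 100, raster_speed_um_s = 100)), 1)
  expect_equal(transit_time(acquisition_schedule(
    "continuous", junction_diameter_um = 200, raster_speed_um_s = 5)), 40)
  bad <- acquisition_schedule("continuous")
  bad$raster_speed_um_s <- 0
  expect_error(transit_time(bad), "positive")
})
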