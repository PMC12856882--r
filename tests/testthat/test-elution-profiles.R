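test_that("XIC extraction captures peaks inside the tolerance window", {
  s <- peak_spectrum(3067.81, 100)
  tg <- xic_target("v10", 3067.9, 10, 0.15, "mz")
  x <- extract_xic(list(s), tg)
  expect_gt(x$intensity, 0)

  # zero spectra -> zero XIC
  z <- mass_spectrum(0, 0, seq(3000, 3100, 0.25), numeric(401))
  expect_equal(extract_xic(list(z), tg)$intensity, 0)

  # windows fully outside the scanned range: zeros plus a warning flag
  far <- xic_target("far", 9000, 5, 0.15, "mz")
  expect_warning(x2 <- extract_xic(list(s), far), "outside")
  expect_true(attr(x2, "out_of_range"))
  expect_equal(x2$intensity, 0)
})

test_that("XICs are additive over disjoint m/z windows", {
  s <- peak_spectrum(c(2788.9, 3067.9, 3408.5), c(50, 100, 75))
  t1 <- xic_target("a", 2788.9, 11, 0.15)
  t2 <- xic_target("b", c(3067.9, 3408.5), c(10, 9), 0.15)
  both <- xic_target("ab", c(2788.9, 3067.9, 3408.5), c(11, 10, 9), 0.15)
  expect_identical(extract_xic(list(s), both)$intensity,
                   extract_xic(list(s), t1)$intensity +
                     extract_xic(list(s), t2)$intensity)
})

test_that("profile averaging across identical pixels has zero SD", {
  s1 <- peak_spectrum(3067.9, 100, time_s = 0)
  s2 <- peak_spectrum(3067.9, 40, time_s = 2.6)
  s2$scan_index <- 1L
  px <- lapply(0:3, function(i) {
    pixel_record(i %% 2, i %/% 2, spectra = list(s1, s2))
  })
  img <- image4d(px, 2, 2, acquisition_schedule(), c(0, 2.6))
  pr <- average_profiles(img, xic_target("t", 3067.9, 10, 0.15))
  expect_equal(pr$sd, c(0, 0))
  expect_equal(pr$n_pixels, 4)
  # with identical pixels the mean equals any single pixel's normalized XIC
  single <- extract_xic(list(s1, s2), xic_target("t", 3067.9, 10, 0.15))
  expect_equal(pr$mean_intensity, single$intensity / max(single$intensity))
})

test_that("recovered mean profiles match the generating kinetics", {
  fx <- small_discrete_fixture()
  for (key in c("sod1_like", "rab3a_like", "vdac1_like", "mal_like")) {
    sp <- fx$species[[key]]
    pr <- average_profiles(fx$image, fx$targets[[sp$name]])
    kin <- elution_kinetics(sp, pr$time_s + fx$schedule$scan_period_s / 2)
    kin <- kin / max(kin)
    rmse <- sqrt(mean((pr$mean_intensity / max(pr$mean_intensity) - kin)^2))
    expect_lt(rmse, 0.05)
  }
})

test_that("a soluble profile peaks immediately and is depleted by 30 s", {
  fx <- small_discrete_fixture()
  pr <- average_profiles(fx$image, fx$targets$SOD1_like)
  norm <- pr$mean_intensity / max(pr$mean_intensity)
  expect_equal(which.max(norm), 1L)           # slot 0
  expect_lt(norm[which(pr$time_s >= 30)[1]], 0.1)
})

test_that("profile features handle canonical shapes", {
  delta <- list(time_s = (0:9) * 2.6, mean_intensity = c(1, rep(0, 9)))
  f <- profile_features(delta)
  expect_equal(f$frac_first_30s, 1.0)
  expect_equal(f$t_peak_s, 0)

  unif <- list(time_s = seq(0.5, 89.5, 1), mean_intensity = rep(3, 90))
  f2 <- profile_features(unif)
  expect_equal(f2$frac_first_30s, 1 / 3)
  expect_equal(f2$flatness, 1.0)
  expect_equal(f2$t_half_s, 44.5)

  # gamma-like kinetics peak within one slot of tau_rise on the 2.6 s grid
  tt <- (0:33) * 2.6 + 1.3
  mem <- species_definition("m", 1e4, 10,
                            solubility_class = "membrane_associated",
                            kinetics = c(tau_rise = 30))
  f3 <- profile_features(list(time_s = tt, mean_intensity =
                                elution_kinetics(mem, tt)))
  expect_lt(abs(f3$t_peak_s - 30), 2.6)

  expect_error(profile_features(list(time_s = 1:3,
                                     mean_intensity = c(0, 0, 0))),
               "all-zero")
})

test_that("solubility classes follow elution behavior, not annotation", {
  tt <- (0:33) * 2.6 + 1.3
  feats <- function(sp) profile_features(
    list(time_s = tt, mean_intensity = elution_kinetics(sp, tt)))

  sol <- species_definition("s", 1e4, 10, kinetics = c(tau_fast = 10))
  expect_identical(classify_solubility(feats(sol)), "soluble")

  mal <- species_definition("mal", 1e4, 5,
                            solubility_class = "transmembrane",
                            kinetics = c(tau_rise = 30, tau_slow = 900))
  expect_identical(classify_solubility(feats(mal)), "transmembrane")

  # a soluble protein with membrane-like dissolution kinetics (myelin
  # association) is NOT called soluble: class reflects elution
  sirt2 <- species_definition("sirt2", 1e4, 13,
                              solubility_class = "membrane_associated",
                              kinetics = c(tau_rise = 30))
  expect_false(classify_solubility(feats(sirt2)) == "soluble")
})

test_that("neutral mass estimation inverts the charge-series relation", {
  vdac <- cbind(c(2788.9, 3067.9, 3408.5, 3834.6), c(11, 10, 9, 8))
  est <- neutral_mass_from_series(vdac)
  expect_equal(est$mass_da, 30668, tolerance = 2)
  expect_lte(est$sd_da, 2)
  expect_false(est$flagged)

  one <- neutral_mass_from_series(cbind(2900.3, 11))
  expect_equal(one$mass_da, 11 * (2900.3 - 1.00728))
  expect_equal(one$sd_da, 0)

  # algebraic round trip: (M + z mp)/z back to exactly M
  for (M in c(16695, 30668, 84363)) {
    for (z in c(5L, 10L, 17L)) {
      mz <- (M + z * 1.00728) / z
      expect_equal(neutral_mass_from_series(cbind(mz, z))$mass_da, M)
    }
  }

  # wildly inconsistent series flagged but still returned
  bad <- neutral_mass_from_series(cbind(c(2900, 3500), c(11, 10)))
  expect_true(bad$flagged)
})

test_that("PTM mass-shift matching reproduces the printed assignments", {
  m286 <- match_mass_shift(286, max_copies = 2, tol_da = 1)
  top <- m286[1, ]
  expect_equal(top$geranylgeranylation, 1)
  expect_equal(top$methylation, 1)
  expect_equal(top$shift_da, 272.2504 + 14.0157)

  m558 <- match_mass_shift(558, max_copies = 2, tol_da = 1)
  expect_true(any(m558$geranylgeranylation == 2 & m558$methylation == 1))

  # farnesylation cannot explain a 286 Da shift (alone or with methylation)
  expect_true(all(m286$farnesylation == 0))

  expect_equal(nrow(match_mass_shift(1000, tol_da = 0.5)), 0)
  expect_error(match_mass_shift(-5))
})

test_that("PTM matching agrees with a brute-force enumeration oracle", {
  cat <- ptm_catalog()
  for (delta in c(286, 558, 420.4, 830, 14.02)) {
    got <- match_mass_shift(delta, cat, max_copies = 3, tol_da = 1)
    oracle <- brute_force_ptm(delta, cat$shift_da, 3, 1)
    expect_equal(nrow(got), length(oracle))
    if (nrow(got) > 0) {
      got_keys <- sort(apply(got[, cat$name], 1, paste, collapse = "-"))
      ora_keys <- sort(vapply(oracle, paste, character(1), collapse = "-"))
      expect_identical(got_keys, ora_keys)
    }
  }
})
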