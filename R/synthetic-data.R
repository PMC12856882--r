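#' Define a simulated protein species
#'
#' Ground-truth description of one species in the tissue phantom: neutral
#' mass, charge-state envelope, solubility class with dissolution kinetics,
#' and per-region relative abundance.
#'
#' @param name Species label.
#' @param neutral_mass_da Average neutral mass in Da (> 0). Native SIM of
#'   ~30 kDa proteins does not resolve isotopic fine structure, so a single
#'   average-mass peak per charge state is modeled.
#' @param charges Integer vector of charge states.
#' @param charge_weights Non-negative weights, one per charge; normalized to
#'   sum to 1. Default uniform.
#' @param solubility_class `"soluble"`, `"membrane_associated"` or
#'   `"transmembrane"`; selects the dissolution-kinetics functional form
#'   (see [elution_kinetics()]).
#' @param kinetics Named numeric vector of time constants in seconds:
#'   `tau_fast` (soluble decay), `tau_rise` (dissolution onset), `tau_slow`
#'   (slow depletion). All positive.
#' @param abundance_map Numeric vector of relative abundance per phantom
#'   region, indexed by region label + 1 (region 0 first).
#' @return An object of class `SpeciesDefinition`.
#' @export
species_definition <- function(name, neutral_mass_da, charges,
                               charge_weights = NULL,
                               solubility_class = c("soluble",
                                                    "membrane_associated",
                                                    "transmembrane"),
                               kinetics = c(tau_fast = 10, tau_rise = 30,
                                            tau_slow = 120),
                               abundance_map = c(1, 1)) {
  solubility_class <- match.arg(solubility_class)
  stopifnot(neutral_mass_da > 0, length(charges) >= 1L, all(charges >= 1))
  if (is.null(charge_weights)) charge_weights <- rep(1, length(charges))
  stopifnot(length(charge_weights) == length(charges),
            all(charge_weights >= 0), sum(charge_weights) > 0)
  charge_weights <- charge_weights / sum(charge_weights)
  k <- c(tau_fast = 10, tau_rise = 30, tau_slow = 120)
  k[names(kinetics)] <- kinetics
  if (any(k <= 0)) stop("kinetics time constants must be positive")
  if (any(abundance_map < 0)) stop("abundances must be non-negative")
  structure(
    list(name = as.character(name), neutral_mass_da = neutral_mass_da,
         charges = as.integer(charges), charge_weights = charge_weights,
         solubility_class = solubility_class, kinetics = k,
         abundance_map = as.numeric(abundance_map)),
    class = "SpeciesDefinition")
}

#' m/z of a charge-state series
#'
#' @param neutral_mass_da Neutral mass M in Da.
#' @param charges Charge states z.
#' @return `(M + z * m_proton) / z` for each z.
#' @export
charge_series_mz <- function(neutral_mass_da, charges) {
  (neutral_mass_da + charges * PROTON_MASS_DA) / charges
}

#' Tissue phantom
#'
#' A rectangular grid of pixels with integer region labels (e.g. 0 = gray
#' matter, 1 = white matter) driving species abundance in the simulator.
#'
#' @param region_labels Integer matrix, `n_rows` x `n_cols`, of 0-based
#'   region labels.
#' @return An object of class `Phantom`.
#' @export
phantom <- function(region_labels) {
  region_labels <- as.matrix(region_labels)
  storage.mode(region_labels) <- "integer"
  if (any(region_labels < 0)) stop("region labels must be >= 0")
  structure(
    list(n_cols = ncol(region_labels), n_rows = nrow(region_labels),
         region_labels = region_labels),
    class = "Phantom")
}

#' Two-region phantom emulating gray/white-matter tissue classes
#'
#' Region-1 pixels (white-matter-like, e.g. a corpus-callosum band) form a
#' contiguous row-major block; the rest are region 0 (gray-matter-like).
#' The default 30 x 14 grid with 51 region-1 pixels reproduces the
#' reference segmentation class sizes of 369 and 51 pixels.
#'
#' @param n_cols,n_rows Grid size (default 30 x 14 = 420 pixels).
#' @param n_region1 Number of region-1 pixels (default 51), assigned
#'   row-major from the top-left corner.
#' @return A [phantom()].
#' @export
two_region_phantom <- function(n_cols = 30, n_rows = 14, n_region1 = 51) {
  n <- n_cols * n_rows
  stopifnot(n_region1 >= 1, n_region1 < n)
  lab <- matrix(0L, nrow = n_rows, ncol = n_cols)
  # row-major order: fill along rows
  idx <- cbind(row = rep(seq_len(n_rows), each = n_cols),
               col = rep(seq_len(n_cols), times = n_rows))[seq_len(n_region1), ,
                                                           drop = FALSE]
  lab[idx] <- 1L
  phantom(lab)
}

#' Dissolution kinetics of a species during probe residence
#'
#' Parametric elution-profile model by solubility class, normalized to unit
#' peak:
#' \itemize{
#'   \item soluble: `exp(-t / tau_fast)` -- intense immediately on contact,
#'     rapidly depleted (a 10 s time constant leaves ~5\% of the initial
#'     signal after 30 s);
#'   \item membrane_associated: gamma-like `(t / tau_rise) * exp(1 - t / tau_rise)`,
#'     peaking at `t = tau_rise`;
#'   \item transmembrane: rise-decay `(1 - exp(-t / tau_rise)) * exp(-t / tau_slow)`
#'     scaled to unit maximum -- slow dissolution followed by slow
#'     depletion; with `tau_slow` much larger than the dwell the profile is
#'     nearly flat.
#' }
#'
#' @param species A [species_definition()].
#' @param t Time since tissue contact, seconds (vectorized, all >= 0).
#' @return Relative intensity in \[0, 1\].
#' @export
elution_kinetics <- function(species, t) {
  if (any(t < 0)) stop("t must be >= 0")
  k <- species$kinetics
  switch(species$solubility_class,
    soluble = exp(-t / k[["tau_fast"]]),
    membrane_associated = (t / k[["tau_rise"]]) * exp(1 - t / k[["tau_rise"]]),
    transmembrane = {
      a <- k[["tau_rise"]]; b <- k[["tau_slow"]]
      t_peak <- a * log(1 + b / a)
      peak <- (1 - exp(-t_peak / a)) * exp(-t_peak / b)
      (1 - exp(-t / a)) * exp(-t / b) / peak
    })
}

# Add Gaussian peaks to an intensity vector on mz_grid. FWHM follows an
# Orbitrap-like resolving power law R_eff = r_ref * sqrt(200 / mz), so
# FWHM = mz / R_eff. Only grid points within 6 sigma of a center are touched.
add_gaussian_peaks <- function(intensity, mz_grid, centers, heights,
                               resolving_power_ref) {
  for (i in seq_along(centers)) {
    m <- centers[i]
    r_eff <- resolving_power_ref * sqrt(200 / m)
    sigma <- (m / r_eff) / (2 * sqrt(2 * log(2)))
    lo <- findInterval(m - 6 * sigma, mz_grid) + 1L
    hi <- findInterval(m + 6 * sigma, mz_grid)
    if (lo > hi) next
    idx <- lo:hi
    intensity[idx] <- intensity[idx] +
      heights[i] * exp(-0.5 * ((mz_grid[idx] - m) / sigma)^2)
  }
  intensity
}

#' Synthesize one native SIM spectrum
#'
#' Each species contributes a Gaussian peak at `(M + z * m_p) / z` for every
#' charge state z, with height proportional to abundance times the charge
#' weight and width set by a resolving power of `resolving_power_ref` at m/z
#' 200 falling off as `sqrt(200 / mz)`. Additive Gaussian baseline noise is
#' drawn from the current RNG stream (seed it for reproducibility); negative
#' values are clamped to zero.
#'
#' @param species_mix List of `list(species = <SpeciesDefinition>,
#'   abundance = <scalar>)` entries; an empty list yields a baseline-only
#'   spectrum.
#' @param mz_grid Ascending m/z axis.
#' @param resolving_power_ref Resolving power at m/z 200 (default 7500,
#'   typical of native SIM of intact proteins).
#' @param noise `c(baseline, sd)` of the additive Gaussian baseline.
#' @param scan_index,time_s,ms_level,precursor_window Passed to
#'   [mass_spectrum()].
#' @return A [mass_spectrum()].
#' @export
synth_spectrum <- function(species_mix, mz_grid, resolving_power_ref = 7500,
                           noise = c(0, 0), scan_index = 0L, time_s = 0,
                           ms_level = 1L, precursor_window = NULL) {
  stopifnot(all(diff(mz_grid) > 0))
  intensity <- numeric(length(mz_grid))
  for (entry in species_mix) {
    sp <- entry$species
    ab <- entry$abundance
    if (ab < 0) stop("abundances must be >= 0")
    if (ab == 0) next
    centers <- charge_series_mz(sp$neutral_mass_da, sp$charges)
    intensity <- add_gaussian_peaks(intensity, mz_grid, centers,
                                    ab * sp$charge_weights,
                                    resolving_power_ref)
  }
  intensity <- intensity + noise[1]
  if (noise[2] > 0) {
    intensity <- intensity + rnorm(length(intensity), 0, noise[2])
  }
  intensity[intensity < 0] <- 0
  mass_spectrum(scan_index, time_s, mz_grid, intensity, ms_level,
                precursor_window)
}

#' Reference species panel for the two-region phantom
#'
#' A panel mimicking the behavior of proteins observed in brain tissue:
#' rapidly eluting soluble complexes enriched in region 0 (gray-matter-like),
#' a soluble complex enriched in region 1 (white-matter-like), lipid-anchored
#' membrane-associated proteins with delayed peaks, a transmembrane
#' beta-barrel, and a near-flat myelin-like transmembrane protein. Neutral
#' masses are chosen so the charge series fall in the m/z 2400-4000 native
#' SIM window.
#'
#' @return Named list of [species_definition()] objects.
#' @export
default_species <- function() {
  list(
    sod1_like = species_definition(
      "SOD1_like", 31892.2, charges = 10:12,
      solubility_class = "soluble", kinetics = c(tau_fast = 10),
      abundance_map = c(1.0, 0.35)),
    arf3_like = species_definition(
      "Arf3_like", 21122.3, charges = 6:8,
      solubility_class = "soluble", kinetics = c(tau_fast = 10),
      abundance_map = c(0.9, 0.2)),
    cah2_like = species_definition(
      "CAH2_like", 29093.7, charges = 9:11,
      solubility_class = "soluble", kinetics = c(tau_fast = 12),
      abundance_map = c(0.2, 1.0)),
    rab3a_like = species_definition(
      "Rab3a_like", 25882.9, charges = 8:10,
      solubility_class = "membrane_associated", kinetics = c(tau_rise = 30),
      abundance_map = c(1.0, 0.3)),
    cnp1_like = species_definition(
      "CNP1_like", 47554.0, charges = 12:15,
      solubility_class = "membrane_associated", kinetics = c(tau_rise = 25),
      abundance_map = c(0.25, 1.0)),
    vdac1_like = species_definition(
      "VDAC1_like", 30668.0, charges = 8:11,
      solubility_class = "transmembrane",
      kinetics = c(tau_rise = 30, tau_slow = 120),
      abundance_map = c(0.4, 1.0)),
    mal_like = species_definition(
      "MAL_like", 16695.0, charges = 5:6,
      solubility_class = "transmembrane",
      kinetics = c(tau_rise = 30, tau_slow = 900),
      abundance_map = c(0.15, 1.0))
  )
}

#' XIC targets for a species list
#'
#' @param species List of [species_definition()] objects.
#' @param tolerance,tolerance_unit Extraction tolerance (see [xic_target()]).
#' @return Named list of [xic_target()] objects, one per species.
#' @export
species_targets <- function(species, tolerance = 0.15,
                            tolerance_unit = "mz") {
  out <- lapply(species, function(sp) {
    xic_target(sp$name, charge_series_mz(sp$neutral_mass_da, sp$charges),
               sp$charges, tolerance, tolerance_unit)
  })
  names(out) <- vapply(species, `[[`, character(1), "name")
  out
}

# Shared machinery: given per-scan species amplitudes, build the scan list.
# Two passes so that noise sd can be tied to the tallest noiseless peak
# (snr argument); noise is then drawn in scan order from set.seed(seed),
# giving bit-identical streams for identical seeds.
build_scan_stream <- function(amp, species, times, mz_grid,
                              resolving_power_ref, noise_baseline, noise_sd,
                              snr, seed, ms_level = 1L,
                              precursor_window = NULL) {
  n_scan <- length(times)
  noiseless <- vector("list", n_scan)
  max_height <- 0
  for (j in seq_len(n_scan)) {
    intensity <- numeric(length(mz_grid))
    for (i in seq_along(species)) {
      a <- amp[i, j]
      if (a <= 0) next
      sp <- species[[i]]
      centers <- charge_series_mz(sp$neutral_mass_da, sp$charges)
      intensity <- add_gaussian_peaks(intensity, mz_grid, centers,
                                      a * sp$charge_weights,
                                      resolving_power_ref)
    }
    noiseless[[j]] <- intensity
    if (length(intensity)) max_height <- max(max_height, max(intensity))
  }
  if (!is.null(snr) && is.finite(snr)) {
    if (snr <= 0) stop("snr must be positive")
    noise_sd <- if (max_height > 0) max_height / snr else 0
  }
  set.seed(seed)
  scans <- vector("list", n_scan)
  for (j in seq_len(n_scan)) {
    intensity <- noiseless[[j]] + noise_baseline
    if (noise_sd > 0) {
      intensity <- intensity + rnorm(length(intensity), 0, noise_sd)
    }
    intensity[intensity < 0] <- 0
    # invariants hold by construction (shared ascending grid, clamped
    # intensities), so skip per-scan validation on this hot path
    scans[[j]] <- structure(
      list(scan_index = j - 1L, time_s = times[j], mz = mz_grid,
           intensity = intensity, ms_level = as.integer(ms_level),
           precursor_window = precursor_window),
      class = "MassSpectrum")
  }
  scans
}

#' Simulate a discrete-mode nano-DESI imaging run
#'
#' The probe visits phantom pixels row-major, parking on each for
#' `schedule$dwell_s` and emitting `floor(dwell_s / scan_period_s)` scans at
#' the schedule's scan period; species intensity at each scan is the
#' region abundance times [elution_kinetics()] evaluated at the scan
#' mid-time since pixel contact. Per-pixel overhead gaps (probe lift and
#' reposition) contain no scans unless `overhead_scans = TRUE`, in which
#' case baseline-only scans are emitted there so downstream audits can flag
#' and discard them.
#'
#' @param phantom A [phantom()].
#' @param species List of [species_definition()] objects.
#' @param schedule A discrete-mode [acquisition_schedule()].
#' @param seed Integer seed; identical seeds give bit-identical streams.
#' @param mz_range,mz_step m/z axis of the simulated SIM window (default
#'   2400-4000 Th at 0.25 Th spacing).
#' @param resolving_power_ref Resolving power at m/z 200.
#' @param noise_baseline,noise_sd Additive Gaussian baseline parameters.
#' @param snr If finite, overrides `noise_sd` with (tallest noiseless
#'   peak) / `snr`.
#' @param pre_contact_scans Number of baseline-only scans emitted before the
#'   probe first touches tissue.
#' @param abundance_scale Global intensity scale applied to all species.
#' @param overhead_scans Emit baseline scans during overhead gaps?
#' @return List with `scans` (ordered [mass_spectrum()] stream on a global
#'   clock), `truth` (data.frame: pixel, col, row, species, scan_global,
#'   scan_in_pixel, time_in_pixel_s, noiseless intensity), `schedule`,
#'   `phantom`, `species`, `mz_grid`, `pixel_order`, `pixel_start_s`, and
#'   `scan_roles` (per-scan `"pixel"`, `"pre_contact"` or `"overhead"`).
#' @export
simulate_discrete_run <- function(phantom, species, schedule, seed = 1L,
                                  mz_range = c(2400, 4000), mz_step = 0.25,
                                  resolving_power_ref = 7500,
                                  noise_baseline = 0, noise_sd = 0,
                                  snr = Inf, pre_contact_scans = 0L,
                                  abundance_scale = 100,
                                  overhead_scans = FALSE) {
  stopifnot(inherits(phantom, "Phantom"), schedule$mode == "discrete")
  dt <- schedule$scan_period_s
  n_per_pixel <- floor(schedule$dwell_s / dt)
  if (n_per_pixel < 1L) stop("dwell_s shorter than one scan period: no-scan pixel")
  n_gap <- if (overhead_scans) floor(schedule$per_pixel_overhead_s / dt) else 0L
  mz_grid <- seq(mz_range[1], mz_range[2], by = mz_step)

  pixel_order <- cbind(
    col = rep(seq_len(phantom$n_cols), times = phantom$n_rows) - 1L,
    row = rep(seq_len(phantom$n_rows), each = phantom$n_cols) - 1L)
  n_pixels <- nrow(pixel_order)
  period <- schedule$dwell_s + schedule$per_pixel_overhead_s
  t0 <- pre_contact_scans * dt
  pixel_start <- t0 + (seq_len(n_pixels) - 1L) * period

  mid <- (seq_len(n_per_pixel) - 0.5) * dt   # scan mid-times within a pixel
  kin <- vapply(species, elution_kinetics, numeric(n_per_pixel), t = mid)
  kin <- matrix(kin, nrow = n_per_pixel)     # n_per_pixel x n_species

  times <- numeric(0)
  roles <- character(0)
  amp_cols <- list()
  truth <- vector("list", n_pixels)
  if (pre_contact_scans > 0L) {
    times <- (seq_len(pre_contact_scans) - 1L) * dt
    roles <- rep("pre_contact", pre_contact_scans)
    amp_cols <- rep(list(numeric(length(species))), pre_contact_scans)
  }
  sp_names <- unname(vapply(species, `[[`, character(1), "name"))
  for (p in seq_len(n_pixels)) {
    col <- unname(pixel_order[p, "col"])
    row <- unname(pixel_order[p, "row"])
    region <- phantom$region_labels[row + 1L, col + 1L]
    ab <- vapply(species, function(sp) {
      if (region + 1L > length(sp$abundance_map)) 0 else
        sp$abundance_map[region + 1L]
    }, numeric(1)) * abundance_scale
    amp_px <- unname(t(kin)) * unname(ab)    # n_species x n_per_pixel
    first_global <- length(times)
    times <- c(times, pixel_start[p] + (seq_len(n_per_pixel) - 1L) * dt)
    roles <- c(roles, rep("pixel", n_per_pixel))
    amp_cols <- c(amp_cols, lapply(seq_len(n_per_pixel),
                                   function(j) amp_px[, j]))
    truth[[p]] <- data.frame(
      pixel = p - 1L, col = col, row = row,
      species = rep(sp_names, times = n_per_pixel),
      scan_global = rep(first_global + seq_len(n_per_pixel) - 1L,
                        each = length(species)),
      scan_in_pixel = rep(seq_len(n_per_pixel) - 1L, each = length(species)),
      time_in_pixel_s = rep(mid, each = length(species)),
      intensity = as.vector(amp_px))
    if (n_gap > 0L && p < n_pixels) {
      times <- c(times, pixel_start[p] + schedule$dwell_s +
                   (seq_len(n_gap) - 1L) * dt)
      roles <- c(roles, rep("overhead", n_gap))
      amp_cols <- c(amp_cols, rep(list(numeric(length(species))), n_gap))
    }
  }
  amp <- matrix(unlist(amp_cols), nrow = length(species))
  scans <- build_scan_stream(amp, species, times, mz_grid,
                             resolving_power_ref, noise_baseline, noise_sd,
                             snr, seed)
  list(scans = scans, truth = do.call(rbind, truth), schedule = schedule,
       phantom = phantom, species = species, mz_grid = mz_grid,
       pixel_order = pixel_order, pixel_start_s = pixel_start,
       scan_roles = roles)
}

#' Simulate a continuous-mode nano-DESI imaging run
#'
#' Linescans are rastered row-major at the schedule's stage speed. Because
#' the junction sweeps past each location, every point experiences a single
#' effective exposure equal to the junction transit time
#' (diameter / speed); species intensity at each scan is the local region
#' abundance times [elution_kinetics()] evaluated at that exposure. Species
#' whose kinetics peak well after the transit time are therefore
#' under-sampled relative to discrete mode.
#'
#' @inheritParams simulate_discrete_run
#' @param schedule A continuous-mode [acquisition_schedule()];
#'   `per_pixel_overhead_s` is the dead time between linescans.
#' @return List with `scans`, `truth` (per scan and species: row, col at
#'   scan midpoint, noiseless intensity), `schedule`, `phantom`, `species`,
#'   `mz_grid`, `line_start_s` (per-row linescan start times), and
#'   `scan_roles`.
#' @export
simulate_continuous_run <- function(phantom, species, schedule, seed = 1L,
                                    mz_range = c(2400, 4000), mz_step = 0.25,
                                    resolving_power_ref = 7500,
                                    noise_baseline = 0, noise_sd = 0,
                                    snr = Inf, abundance_scale = 100) {
  stopifnot(inherits(phantom, "Phantom"), schedule$mode == "continuous")
  if (schedule$raster_speed_um_s <= 0) stop("raster speed must be positive")
  dt <- schedule$scan_period_s
  speed <- schedule$raster_speed_um_s
  exposure <- schedule$junction_diameter_um / speed
  mz_grid <- seq(mz_range[1], mz_range[2], by = mz_step)
  line_len <- phantom$n_cols * schedule$pitch_x_um
  line_dur <- line_len / speed
  n_line <- floor(line_dur / dt)
  if (n_line < 1L) stop("linescan shorter than one scan period")
  line_start <- (seq_len(phantom$n_rows) - 1L) *
    (line_dur + schedule$per_pixel_overhead_s)

  kin1 <- vapply(species, elution_kinetics, numeric(1), t = exposure)
  sp_names <- unname(vapply(species, `[[`, character(1), "name"))
  times <- numeric(0); amp_cols <- list(); truth <- list(); roles <- character(0)
  for (r in seq_len(phantom$n_rows)) {
    t_scan <- line_start[r] + (seq_len(n_line) - 1L) * dt
    pos_mid <- speed * (t_scan - line_start[r] + dt / 2)
    col <- pmin(floor(pos_mid / schedule$pitch_x_um), phantom$n_cols - 1L)
    region <- phantom$region_labels[r, col + 1L]
    for (j in seq_len(n_line)) {
      ab <- vapply(species, function(sp) {
        if (region[j] + 1L > length(sp$abundance_map)) 0 else
          sp$abundance_map[region[j] + 1L]
      }, numeric(1)) * abundance_scale
      amp_cols <- c(amp_cols, list(ab * kin1))
      truth[[length(truth) + 1L]] <- data.frame(
        row = r - 1L, col = col[j], species = sp_names,
        scan_global = length(times) + j - 1L,
        intensity = unname(ab * kin1))
    }
    times <- c(times, t_scan)
    roles <- c(roles, rep("pixel", n_line))
  }
  amp <- matrix(unlist(amp_cols), nrow = length(species))
  scans <- build_scan_stream(amp, species, times, mz_grid,
                             resolving_power_ref, noise_baseline, noise_sd,
                             snr, seed)
  list(scans = scans, truth = do.call(rbind, truth), schedule = schedule,
       phantom = phantom, species = species, mz_grid = mz_grid,
       line_start_s = line_start, scan_roles = roles)
}

#' Reference precursor set for chimeric MS2 simulation
#'
#' Two co-isolated precursor families mimicking an eye-lens measurement: a
#' soluble crystallin-like heterotetramer dissociating into three monomer
#' subunit series, and a transmembrane aquaporin-like homotetramer
#' dissociating into monomers and trimers. Both fall inside one quadrupole
#' isolation window (m/z 6281 +/- 15), so their product ions appear in the
#' same MS2 scans and are separable only by elution time.
#'
#' @return List of precursor definitions, each `list(name,
#'   solubility_class, kinetics, series)` where `series` lists product
#'   subunits as `list(label, neutral_mass_da, charges)`.
#' @export
default_ms2_precursors <- function() {
  list(
    list(name = "crystallin_tetramer", solubility_class = "soluble",
         kinetics = c(tau_fast = 10),
         series = list(
           list(label = "gamma_crystallin", neutral_mass_da = 20966,
                charges = 10:13),
           list(label = "betaB2_crystallin", neutral_mass_da = 23249,
                charges = 9:12),
           list(label = "betaA4_crystallin", neutral_mass_da = 22442,
                charges = 10:12))),
    list(name = "aqp0_tetramer", solubility_class = "transmembrane",
         kinetics = c(tau_rise = 30, tau_slow = 120),
         series = list(
           list(label = "aqp0_monomer", neutral_mass_da = 28121,
                charges = 5:11),
           # trimer charges divisible by 3 would land exactly on monomer
           # m/z (trimer mass is 3x monomer mass), so they are skipped
           list(label = "aqp0_trimer", neutral_mass_da = 84363,
                charges = c(13, 14, 16, 17))))
  )
}

#' XIC targets for MS2 product-ion subunit series
#'
#' @param precursors Output of [default_ms2_precursors()] (or same shape).
#' @param tolerance,tolerance_unit Extraction tolerance.
#' @return Named list of [xic_target()] objects, one per subunit series,
#'   with a `precursor` attribute naming the generating precursor.
#' @export
ms2_product_targets <- function(precursors, tolerance = 0.3,
                                tolerance_unit = "mz") {
  out <- list()
  for (pc in precursors) {
    for (s in pc$series) {
      tg <- xic_target(s$label,
                       charge_series_mz(s$neutral_mass_da, s$charges),
                       s$charges, tolerance, tolerance_unit)
      attr(tg, "precursor") <- pc$name
      out[[s$label]] <- tg
    }
  }
  out
}

#' Simulate discrete-mode MS2 acquisition at several tissue locations
#'
#' The instrument continuously fragments one isolation window while the
#' probe dwells on each location; product-ion intensity follows the
#' precursor's dissolution kinetics. Each location yields an independent
#' MS2 scan stream (with optional pre-contact baseline scans).
#'
#' @param precursors See [default_ms2_precursors()].
#' @param schedule Discrete-mode [acquisition_schedule()] (per-run dwell is
#'   always explicit; MS2 residence need not match imaging dwell).
#' @param n_locations Number of sampled locations.
#' @param precursor_window `c(center, half_width)` of the isolation window.
#' @inheritParams simulate_discrete_run
#' @return List with `locations` (list of per-location scan lists), `truth`
#'   (location, precursor, series label, scan, mid-time, noiseless
#'   intensity), `mz_grid`, `schedule`, `precursors`.
#' @export
simulate_ms2_run <- function(precursors = default_ms2_precursors(),
                             schedule = acquisition_schedule(dwell_s = 78),
                             n_locations = 5, seed = 1L,
                             mz_range = c(1200, 6500), mz_step = 0.5,
                             resolving_power_ref = 7500,
                             noise_baseline = 0, noise_sd = 0, snr = Inf,
                             pre_contact_scans = 0L, abundance_scale = 100,
                             precursor_window = c(6281, 15)) {
  stopifnot(schedule$mode == "discrete")
  dt <- schedule$scan_period_s
  n_per_loc <- floor(schedule$dwell_s / dt)
  if (n_per_loc < 1L) stop("dwell_s shorter than one scan period")
  mz_grid <- seq(mz_range[1], mz_range[2], by = mz_step)
  pw <- precursor_window

  # flatten subunit series into pseudo-species with precursor kinetics
  sp <- list(); pc_of <- character(0)
  for (pc in precursors) {
    for (s in pc$series) {
      sp[[s$label]] <- species_definition(
        s$label, s$neutral_mass_da, s$charges,
        solubility_class = pc$solubility_class, kinetics = pc$kinetics,
        abundance_map = c(1))
      pc_of[s$label] <- pc$name
    }
  }
  mid <- (seq_len(n_per_loc) - 0.5) * dt
  kin <- vapply(sp, elution_kinetics, numeric(n_per_loc), t = mid)
  kin <- matrix(kin, nrow = n_per_loc)

  locations <- vector("list", n_locations)
  truth <- list()
  for (loc in seq_len(n_locations)) {
    n_pre <- pre_contact_scans
    times <- (seq_len(n_pre + n_per_loc) - 1L) * dt
    amp <- matrix(0, nrow = length(sp), ncol = n_pre + n_per_loc)
    amp[, n_pre + seq_len(n_per_loc)] <- t(kin) * abundance_scale
    locations[[loc]] <- build_scan_stream(
      amp, sp, times, mz_grid, resolving_power_ref, noise_baseline,
      noise_sd, snr, seed + loc - 1L, ms_level = 2L, precursor_window = pw)
    truth[[loc]] <- data.frame(
      location = loc - 1L,
      precursor = rep(unname(pc_of[names(sp)]), times = n_per_loc),
      series = rep(names(sp), times = n_per_loc),
      scan = rep(n_pre + seq_len(n_per_loc) - 1L, each = length(sp)),
      time_in_location_s = rep(mid, each = length(sp)),
      intensity = as.vector(t(kin) * abundance_scale))
  }
  list(locations = locations, truth = do.call(rbind, truth),
       mz_grid = mz_grid, schedule = schedule, precursors = precursors)
}
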