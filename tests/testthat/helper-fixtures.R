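# Shared fixtures, built in code at test time.

# A flat-grid spectrum with Gaussian peaks at given centers/heights.
peak_spectrum <- function(centers, heights, mz_grid = seq(2400, 4000, 0.25),
                          sigma = 0.7, scan_index = 0L, time_s = 0) {
  inten <- numeric(length(mz_grid))
  for (i in seq_along(centers)) {
    inten <- inten + heights[i] *
      exp(-0.5 * ((mz_grid - centers[i]) / sigma)^2)
  }
  mass_spectrum(scan_index, time_s, mz_grid, inten)
}

# Independent brute-force oracle for PTM multiset matching: depth-first
# enumeration over per-entry copy counts, no shared code with the package.
brute_force_ptm <- function(delta, shifts, max_copies, tol) {
  hits <- list()
  n <- length(shifts)
  recurse <- function(i, counts, total) {
    if (i > n) {
      if (sum(counts) > 0 && abs(total - delta) <= tol) {
        hits[[length(hits) + 1L]] <<- counts
      }
      return(invisible())
    }
    for (k in 0:max_copies) {
      recurse(i + 1L, c(counts, k), total + k * shifts[i])
    }
  }
  recurse(1L, integer(0), 0)
  hits
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small cached discrete-mode run shared across test files (noiseless,
# 3 x 2 phantom, full 90 s dwell).
.fixture_cache <- new.env(parent = emptyenv())
small_discrete_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    ph <- two_region_phantom(3, 2, 2)
    sp <- default_species()
    sched <- acquisition_schedule()
    run <- simulate_discrete_run(ph, sp, sched, seed = 42)
    img <- spot_sample(run$scans, sched, run$pixel_order)
    .fixture_cache$small <- list(phantom = ph, species = sp,
                                 schedule = sched, run = run, image = img,
                                 targets = species_targets(sp))
  }
  .fixture_cache$small
}
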