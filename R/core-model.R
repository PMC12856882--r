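#' nanodims: discrete-mode nano-DESI imaging mass spectrometry
#'
#' Tools for time-resolved ("discrete-mode") nano-DESI mass spectrometry
#' imaging of intact proteins: a forward simulator, raw-stream readers, a 4D
#' (x, y, elution time, m/z) image store, pixelation, elution-profile
#' extraction and solubility classification, elution-time-filtered ion
#' images, PCA/k-means tissue segmentation, and elution-time simplification
#' of chimeric MS2 spectra.
#'
#' @keywords internal
#' @importFrom stats median rnorm sd cor kmeans prcomp setNames
"_PACKAGE"

# Mass of a proton in Da; used for all m/z <-> neutral-mass conversions.
PROTON_MASS_DA <- 1.00728

#' A single mass spectrum (one scan)
#'
#' The atomic record of a scan stream: an m/z axis with intensities, a scan
#' clock time, and (for MS2) the precursor isolation window.
#'
#' @param scan_index 0-based scan index within its stream.
#' @param time_s Scan start time in seconds. In a raw stream this is time
#'   since acquisition start; inside a pixel it is re-zeroed to pixel
#'   contact, so pre-contact scans may carry negative times after alignment.
#' @param mz Strictly ascending numeric vector of m/z values (Th).
#' @param intensity Non-negative numeric vector, same length as `mz`.
#' @param ms_level 1 or 2.
#' @param precursor_window For MS2 scans, `c(center, half_width)` of the
#'   quadrupole isolation window in Th (e.g. `c(6281, 15)`); NULL for MS1.
#' @return An object of class `MassSpectrum`.
#' @export
mass_spectrum <- function(scan_index, time_s, mz, intensity, ms_level = 1L,
                          precursor_window = NULL) {
  scan_index <- as.integer(scan_index)
  stopifnot(length(scan_index) == 1L, scan_index >= 0L)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("mz must be strictly ascending")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (!is.null(precursor_window)) {
    stopifnot(length(precursor_window) == 2L, precursor_window[2] > 0)
    precursor_window <- as.numeric(precursor_window)
  }
  structure(
    list(scan_index = scan_index, time_s = as.numeric(time_s),
         mz = as.numeric(mz), intensity = as.numeric(intensity),
         ms_level = as.integer(ms_level),
         precursor_window = precursor_window),
    class = "MassSpectrum")
}

#' @export
print.MassSpectrum <- function(x, ...) {
  cat(sprintf("<MassSpectrum> scan %d, t = %.2f s, MS%d, %d points",
              x$scan_index, x$time_s, x$ms_level, length(x$mz)))
  if (!is.null(x$precursor_window)) {
    cat(sprintf(", precursor %.1f +/- %.1f", x$precursor_window[1],
                x$precursor_window[2]))
  }
  cat("\n")
  invisible(x)
}

#' A pixel's ordered time-resolved spectra
#'
#' One pixel of a discrete-mode acquisition: the spectra recorded while the
#' probe was parked on that tissue location, ordered by time since contact.
#'
#' @param col,row 0-based grid indices.
#' @param center_um Physical pixel center `c(x, y)` in micrometers.
#' @param spectra List of [mass_spectrum()] objects with strictly increasing
#'   `time_s`, all sharing one `ms_level`.
#' @param contact_scan Scan index (in the originating raw stream) at which
#'   tissue contact was established for this pixel.
#' @return An object of class `PixelRecord`.
#' @export
pixel_record <- function(col, row, center_um = c(NA_real_, NA_real_),
                         spectra = list(), contact_scan = NA_integer_) {
  stopifnot(col >= 0, row >= 0)
  if (length(spectra) > 0L) {
    times <- vapply(spectra, `[[`, numeric(1), "time_s")
    if (length(times) > 1L && any(diff(times) <= 0)) {
      stop("pixel spectra must have strictly increasing time_s")
    }
    lv <- vapply(spectra, `[[`, integer(1), "ms_level")
    if (length(unique(lv)) > 1L) stop("pixel spectra must share one ms_level")
  }
  structure(
    list(col = as.integer(col), row = as.integer(row),
         center_um = as.numeric(center_um), spectra = spectra,
         contact_scan = as.integer(contact_scan)),
    class = "PixelRecord")
}

#' Acquisition schedule
#'
#' Geometry and timing of a nano-DESI imaging run. Discrete mode parks the
#' probe for `dwell_s` per pixel; continuous mode rasters linescans at
#' `raster_speed_um_s`. Defaults reproduce the reference protein-imaging
#' protocol: 100 x 200 um pitch, 1.5 min dwell, 2.6 s scan period, ~100 um
#' liquid junction, and 12.9 s of per-pixel dead time (probe lift,
#' reposition, junction stabilization).
#'
#' @param mode `"discrete"` or `"continuous"`.
#' @param pitch_x_um,pitch_y_um Pixel pitch in micrometers.
#' @param dwell_s Per-pixel residence time in seconds (discrete mode).
#' @param scan_period_s Time between consecutive scan starts, seconds.
#' @param raster_speed_um_s Stage speed in um/s (continuous mode).
#' @param junction_diameter_um Liquid-junction diameter, micrometers.
#' @param per_pixel_overhead_s Dead time per pixel (discrete) or per line
#'   (continuous), seconds.
#' @return An object of class `AcquisitionSchedule`.
#' @export
acquisition_schedule <- function(mode = c("discrete", "continuous"),
                                 pitch_x_um = 100, pitch_y_um = 200,
                                 dwell_s = 90, scan_period_s = 2.6,
                                 raster_speed_um_s = 5,
                                 junction_diameter_um = 100,
                                 per_pixel_overhead_s = 12.9) {
  mode <- match.arg(mode)
  vals <- c(pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
            scan_period_s = scan_period_s,
            junction_diameter_um = junction_diameter_um)
  if (any(vals <= 0)) stop("schedule fields must be positive")
  if (per_pixel_overhead_s < 0) stop("per_pixel_overhead_s must be >= 0")
  if (mode == "discrete") {
    if (is.null(dwell_s) || dwell_s <= 0) stop("discrete mode requires dwell_s > 0")
  } else {
    if (is.null(raster_speed_um_s) || raster_speed_um_s <= 0) {
      stop("continuous mode requires raster_speed_um_s > 0")
    }
  }
  structure(
    list(mode = mode, pitch_x_um = as.numeric(pitch_x_um),
         pitch_y_um = as.numeric(pitch_y_um),
         dwell_s = as.numeric(dwell_s),
         scan_period_s = as.numeric(scan_period_s),
         raster_speed_um_s = as.numeric(raster_speed_um_s),
         junction_diameter_um = as.numeric(junction_diameter_um),
         per_pixel_overhead_s = as.numeric(per_pixel_overhead_s)),
    class = "AcquisitionSchedule")
}

#' Extracted-ion-chromatogram target
#'
#' A species to extract: one m/z center per charge state plus a tolerance.
#' Native intact proteins present as a charge-state series, so XICs here are
#' typically summed over several charge states of one neutral mass.
#'
#' @param label Species label.
#' @param mz_centers Numeric vector of m/z centers (Th), one per charge.
#' @param charges Positive integer vector parallel to `mz_centers`.
#' @param tolerance Positive tolerance value; half-width in Th when
#'   `tolerance_unit = "mz"`, or parts-per-million of each center when
#'   `"ppm"` (half-width = center * tolerance * 1e-6).
#' @param tolerance_unit `"mz"` (absolute +/- Th) or `"ppm"`.
#' @return An object of class `XICTarget`.
#' @export
xic_target <- function(label, mz_centers, charges,
                       tolerance = 0.15, tolerance_unit = c("mz", "ppm")) {
  tolerance_unit <- match.arg(tolerance_unit)
  stopifnot(length(mz_centers) == length(charges), tolerance > 0,
            all(charges >= 1))
  structure(
    list(label = as.character(label), mz_centers = as.numeric(mz_centers),
         charges = as.integer(charges), tolerance = as.numeric(tolerance),
         tolerance_unit = tolerance_unit),
    class = "XICTarget")
}

#' Half-widths of an XIC target's extraction windows
#' @param target An [xic_target()].
#' @return Numeric vector of half-widths (Th), one per charge state.
#' @export
xic_half_widths <- function(target) {
  if (target$tolerance_unit == "ppm") {
    target$mz_centers * target$tolerance * 1e-6
  } else {
    rep(target$tolerance, length(target$mz_centers))
  }
}

#' Map a scan-index window to an elution-time window
#'
#' Scan indices are 0-based and windows half-open: a window covering scans
#' `first_scan` through `last_scan` spans `[first_scan * dt,
#' (last_scan + 1) * dt)` seconds. This is the convention under which a
#' 3-scan window over scans 2-4 at a 2.6 s scan period spans 5.2-13.0 s and
#' scans 19-21 span 49.4-57.2 s.
#'
#' @param first_scan,last_scan 0-based scan indices, `first_scan <= last_scan`.
#' @param scan_period_s Scan period in seconds (> 0).
#' @return Named numeric vector `c(start_s, end_s)`.
#' @examples
#' scan_window_to_time(2, 4, 2.6)   # 5.2 13.0
#' scan_window_to_time(19, 21, 2.6) # 49.4 57.2
#' @export
scan_window_to_time <- function(first_scan, last_scan, scan_period_s) {
  stopifnot(scan_period_s > 0, first_scan >= 0)
  if (first_scan > last_scan) stop("first_scan must be <= last_scan")
  c(start_s = first_scan * scan_period_s,
    end_s = (last_scan + 1) * scan_period_s)
}

#' Width of an n-scan elution window
#'
#' @param n_scans Number of scans in the window (>= 1).
#' @param scan_period_s Scan period in seconds.
#' @return Window width in seconds, `n_scans * scan_period_s`; e.g. 3 scans
#'   at a 2.6 s period give 7.8 s.
#' @export
window_width <- function(n_scans, scan_period_s) {
  if (n_scans < 1) stop("n_scans must be >= 1")
  stopifnot(scan_period_s > 0)
  n_scans * scan_period_s
}
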