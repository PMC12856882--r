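#' Detect tissue contact in a raw scan stream
#'
#' The probe touches tissue some time after acquisition starts; contact is
#' visible as a jump in total ion current. Walking forward through the
#' stream, the first scan whose TIC over `tic_window_mz` exceeds
#' `threshold_factor` times the median TIC of all earlier (pre-signal)
#' scans is declared the contact scan.
#'
#' @param scans Ordered list of [mass_spectrum()] objects (>= 3).
#' @param tic_window_mz `c(lo, hi)` m/z window for the TIC.
#' @param threshold_factor Multiple of the pre-signal median TIC that
#'   signals contact; `<= 0` returns scan 0 (everything qualifies).
#' @return 0-based index of the contact scan.
#' @export
detect_contact <- function(scans, tic_window_mz = c(2400, 4000),
                           threshold_factor = 5) {
  if (length(scans) < 3L) stop("need at least 3 scans")
  if (threshold_factor <= 0) return(0L)
  tic <- vapply(scans, function(s) {
    sel <- s$mz >= tic_window_mz[1] & s$mz <= tic_window_mz[2]
    sum(s$intensity[sel])
  }, numeric(1))
  for (i in 2:length(tic)) {
    if (tic[i] > threshold_factor * median(tic[1:(i - 1)])) {
      return(i - 1L)  # 0-based
    }
  }
  stop("no-contact error: no scan exceeds the contact threshold")
}

#' Re-zero scan times to a contact scan
#'
#' Subtracts the contact scan's start time from every scan; pre-contact
#' scans carry negative times afterwards and are excluded downstream.
#'
#' @param scans Ordered list of [mass_spectrum()] objects.
#' @param contact_index 0-based contact scan index (e.g. from
#'   [detect_contact()]).
#' @return The scan list with shifted `time_s`.
#' @export
align_to_contact <- function(scans, contact_index) {
  stopifnot(contact_index >= 0, contact_index < length(scans))
  t0 <- scans[[contact_index + 1L]]$time_s
  lapply(scans, function(s) {
    s$time_s <- s$time_s - t0
    s
  })
}

#' Spot-sample a discrete-mode stream into a 4D image
#'
#' Each pixel in `pixel_order` occupies the half-open dwell interval
#' `[p * (dwell + overhead), p * (dwell + overhead) + dwell)` on the stream
#' clock (time 0 = first pixel's contact). Scans are assigned to pixels by
#' scan start time, re-zeroed to their pixel's contact, and scans falling
#' in overhead gaps (or before time 0) are flagged and discarded -- the
#' returned metadata reconciles every input scan as assigned or discarded.
#'
#' @param scans Ordered list of [mass_spectrum()] objects whose `time_s` is
#'   0 at the first pixel's contact (see [align_to_contact()]).
#' @param schedule A discrete-mode [acquisition_schedule()].
#' @param pixel_order Matrix or data.frame with columns `col`, `row`
#'   (0-based) in probe visiting order. Empty input gives an empty image.
#' @return An [image4d()]; `metadata$scan_audit` counts assigned,
#'   pre-contact and overhead scans.
#' @export
spot_sample <- function(scans, schedule, pixel_order) {
  stopifnot(schedule$mode == "discrete")
  pixel_order <- as.matrix(pixel_order)
  n_pixels <- nrow(pixel_order)
  if (n_pixels == 0L) {
    return(image4d(list(), 0L, 0L, schedule, numeric(0),
                   metadata = list(scan_audit = list(
                     assigned = 0L, pre_contact = length(scans),
                     overhead = 0L))))
  }
  dt <- schedule$scan_period_s
  period <- schedule$dwell_s + schedule$per_pixel_overhead_s
  times <- vapply(scans, `[[`, numeric(1), "time_s")

  # candidate pixel by scan start time; epsilon guards against a pixel
  # start like 3 * 102.9 s landing one ULP below the boundary
  p_idx <- floor(times / period + 1e-9)
  within <- times - p_idx * period
  role <- rep("overhead", length(scans))
  role[times < 0] <- "pre_contact"
  ok <- times >= 0 & p_idx < n_pixels & within < schedule$dwell_s
  role[ok] <- "pixel"

  assigned <- split(which(ok), p_idx[ok])
  missing_px <- setdiff(as.character(seq_len(n_pixels) - 1L),
                        names(assigned))
  if (length(missing_px) > 0L) {
    stop("truncation error: stream leaves pixels unfilled: ",
         paste(missing_px, collapse = ", "))
  }

  n_cols <- max(pixel_order[, "col"]) + 1L
  n_rows <- max(pixel_order[, "row"]) + 1L
  pixels <- vector("list", n_cols * n_rows)
  max_slots <- 0L
  for (p in seq_len(n_pixels)) {
    sel <- assigned[[as.character(p - 1L)]]
    sp <- lapply(seq_along(sel), function(j) {
      s <- scans[[sel[j]]]
      s$time_s <- s$time_s - (p - 1L) * period  # re-zero to pixel contact
      s$scan_index <- j - 1L
      s
    })
    max_slots <- max(max_slots, length(sp))
    col <- unname(pixel_order[p, "col"])
    row <- unname(pixel_order[p, "row"])
    pixels[[row * n_cols + col + 1L]] <- pixel_record(
      col, row,
      center_um = c((col + 0.5) * schedule$pitch_x_um,
                    (row + 0.5) * schedule$pitch_y_um),
      spectra = sp, contact_scan = sel[1] - 1L)
  }
  if (any(vapply(pixels, is.null, logical(1)))) {
    stop("pixel_order does not cover the full grid")
  }
  image4d(pixels, n_cols, n_rows, schedule,
          time_axis = (seq_len(max_slots) - 1L) * dt,
          metadata = list(scan_audit = list(
            assigned = sum(role == "pixel"),
            pre_contact = sum(role == "pre_contact"),
            overhead = sum(role == "overhead"))))
}

#' Time-bin a continuous-mode stream into a 2D image
#'
#' Linescans are subdivided into pixels post hoc: each scan is mapped to a
#' stage position (speed times elapsed line time, taken at the scan
#' midpoint) and scans whose position falls inside a pixel's x-extent are
#' averaged into that pixel's single spectrum. One bin of width
#' `pitch_x_um` corresponds to `pitch_x_um / raster_speed_um_s` seconds of
#' scanning.
#'
#' @param scans Ordered list of [mass_spectrum()] objects.
#' @param schedule A continuous-mode [acquisition_schedule()].
#' @param line_geometry List with `n_cols`, `n_rows`, and `line_start_s`
#'   (per-row linescan start times on the stream clock).
#' @return An [image4d()] with one averaged spectrum per pixel (single
#'   elution-time slot).
#' @export
time_bin <- function(scans, schedule, line_geometry) {
  stopifnot(schedule$mode == "continuous")
  n_cols <- line_geometry$n_cols
  n_rows <- line_geometry$n_rows
  starts <- line_geometry$line_start_s
  stopifnot(length(starts) == n_rows)
  speed <- schedule$raster_speed_um_s
  dt <- schedule$scan_period_s
  line_len <- n_cols * schedule$pitch_x_um
  line_dur <- line_len / speed
  if (length(scans) * dt < line_dur) {
    stop("short-line error: stream shorter than one linescan")
  }
  times <- vapply(scans, `[[`, numeric(1), "time_s")

  bins <- vector("list", n_cols * n_rows)
  for (i in seq_along(scans)) {
    r <- findInterval(times[i], starts)
    if (r < 1L) next
    pos <- speed * (times[i] + dt / 2 - starts[r])  # midpoint position
    if (pos < 0 || pos >= line_len) next
    col <- floor(pos / schedule$pitch_x_um)
    key <- (r - 1L) * n_cols + col + 1L
    bins[[key]] <- c(bins[[key]], i)
  }
  empty <- which(vapply(bins, is.null, logical(1)))
  if (length(empty) > 0L) {
    stop("short-line error: pixels received no scans: ",
         paste(empty - 1L, collapse = ", "))
  }
  pixels <- vector("list", n_cols * n_rows)
  for (key in seq_along(bins)) {
    idx <- bins[[key]]
    mz <- scans[[idx[1]]]$mz
    for (i in idx[-1]) {
      if (!identical(scans[[i]]$mz, mz)) {
        stop("time_bin requires a shared m/z axis across binned scans")
      }
    }
    inten <- Reduce(`+`, lapply(idx, function(i) scans[[i]]$intensity)) /
      length(idx)
    col <- (key - 1L) %% n_cols
    row <- (key - 1L) %/% n_cols
    pixels[[key]] <- pixel_record(
      col, row,
      center_um = c((col + 0.5) * schedule$pitch_x_um,
                    (row + 0.5) * schedule$pitch_y_um),
      spectra = list(mass_spectrum(0L, 0, mz, inten,
                                   scans[[idx[1]]]$ms_level)),
      contact_scan = idx[1] - 1L)
  }
  image4d(pixels, n_cols, n_rows, schedule, time_axis = 0,
          metadata = list(binned_from = length(scans)))
}

#' Plan (or audit) an acquisition's duration
#'
#' @param n_cols,n_rows Image dimensions in pixels.
#' @param schedule A discrete-mode [acquisition_schedule()].
#' @return List with `n_pixels`, `raster_time_s` (dwell only),
#'   `dead_time_s` (lift/reposition overhead) and `total_time_s`. Halving
#'   the pitch in both axes quadruples `n_pixels` and `total_time_s`.
#' @export
plan_acquisition <- function(n_cols, n_rows, schedule) {
  stopifnot(n_cols >= 1, n_rows >= 1)
  n_pixels <- n_cols * n_rows
  raster <- n_pixels * schedule$dwell_s
  dead <- n_pixels * schedule$per_pixel_overhead_s
  list(n_pixels = n_pixels, raster_time_s = raster, dead_time_s = dead,
       total_time_s = raster + dead)
}

#' Liquid-junction transit time in continuous mode
#'
#' @param schedule A continuous-mode [acquisition_schedule()].
#' @return `junction_diameter_um / raster_speed_um_s` in seconds -- the
#'   effective exposure of any one tissue location (20 s for a 100 um
#'   junction at 5 um/s).
#' @export
transit_time <- function(schedule) {
  stopifnot(schedule$mode == "continuous")
  if (schedule$raster_speed_um_s <= 0) stop("raster speed must be positive")
  schedule$junction_diameter_um / schedule$raster_speed_um_s
}
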