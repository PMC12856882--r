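#' Extracted ion chromatogram for a multi-charge-state target
#'
#' Per scan, sums all intensity falling within the tolerance window of each
#' (m/z center, charge) in the target and adds the windows together --
#' native proteins spread signal over a charge-state series, so the summed
#' XIC is the species-level trace. A ppm tolerance gives a half-width of
#' `center * tol * 1e-6`; overlapping windows are summed as given.
#'
#' @param spectra Time-ordered list of [mass_spectrum()] objects.
#' @param target An [xic_target()].
#' @param background `"none"` sums raw window intensity; `"floor"` applies
#'   per-scan noise suppression before summing: the spectrum's baseline
#'   (median) and noise spread are estimated robustly, only window points
#'   above baseline + 3 sigma are summed, and the baseline is subtracted
#'   from them. Raw sums otherwise accumulate the detector's non-negative
#'   noise into a positive offset that distorts elution-profile shapes.
#'   On noiseless spectra `"floor"` is exactly equivalent to `"none"`.
#' @return data.frame with `time_s` and `intensity`; if every window lies
#'   outside the scanned m/z range the XIC is all zeros and carries
#'   attribute `out_of_range = TRUE` (with a warning).
#' @export
extract_xic <- function(spectra, target, background = c("none", "floor")) {
  background <- match.arg(background)
  hw <- xic_half_widths(target)
  lo <- target$mz_centers - hw
  hi <- target$mz_centers + hw
  times <- vapply(spectra, `[[`, numeric(1), "time_s")
  inten <- vapply(spectra, function(s) {
    thr <- 0; base <- 0
    if (background == "floor") {
      nf <- noise_floor(s$intensity)
      base <- nf$baseline
      thr <- nf$baseline + 3 * nf$sd
    }
    tot <- 0
    for (w in seq_along(lo)) {
      a <- findInterval(lo[w], s$mz) + 1L
      b <- findInterval(hi[w], s$mz)
      if (a <= b) {
        v <- s$intensity[a:b]
        v <- v[v >= thr]
        tot <- tot + sum(v - base)
      }
    }
    tot
  }, numeric(1))
  out <- data.frame(time_s = times, intensity = inten)
  in_range <- any(vapply(spectra, function(s) {
    length(s$mz) > 0 && any(hi >= s$mz[1] & lo <= s$mz[length(s$mz)])
  }, logical(1)))
  if (!in_range) {
    warning("XIC target windows lie outside the scanned m/z range for '",
            target$label, "'")
    attr(out, "out_of_range") <- TRUE
  }
  out
}

# Robust per-scan noise model. Peaks occupy a small minority of a SIM
# spectrum's grid points, so low quantiles are noise-dominated. A positive
# median indicates a symmetric noise baseline (spread via MAD); a zero
# median indicates noise clamped at the detector's zero, whose underlying
# sd follows from the 75th percentile of the half-normal
# (q75 = 0.6745 sd). Both estimates are exactly 0 on noiseless spectra.
noise_floor <- function(intensity) {
  # a substantial mass of exact zeros marks noise clamped at the
  # detector's zero (half-normal); otherwise a symmetric baseline
  if (mean(intensity == 0) > 0.25) {
    q75 <- stats::quantile(intensity, 0.75, names = FALSE)
    list(baseline = 0, sd = q75 / 0.6744898)
  } else {
    q50 <- median(intensity)
    list(baseline = q50, sd = stats::mad(intensity, center = q50))
  }
}

#' Average per-pixel elution profiles for a target
#'
#' Computes every pixel's summed-charge-state XIC on the shared scan-slot
#' grid, optionally scales each pixel's trace to unit maximum, and returns
#' the per-slot mean and standard deviation across pixels -- the averaged
#' elution profile with its +/- 1 SD band.
#'
#' @param image An [image4d()].
#' @param target An [xic_target()].
#' @param normalize Scale each pixel's XIC to unit maximum before averaging
#'   (all-zero pixels are left at zero). Default TRUE.
#' @param pixel_idx Optional integer vector (1-based into `image$pixels`)
#'   restricting the average to a pixel subset, e.g. one segmentation class.
#' @param background Passed to [extract_xic()]; defaults to `"floor"`
#'   (per-scan noise-floor subtraction), which is a no-op on noiseless
#'   data.
#' @return An `ElutionProfile`: list with `target`, `time_s`,
#'   `mean_intensity`, `sd`, `n_pixels`, `normalized`.
#' @export
average_profiles <- function(image, target, normalize = TRUE,
                             pixel_idx = NULL,
                             background = c("floor", "none")) {
  background <- match.arg(background)
  pixels <- if (is.null(pixel_idx)) image$pixels else image$pixels[pixel_idx]
  pixels <- Filter(function(p) length(p$spectra) >= 1L, pixels)
  if (length(pixels) == 0L) stop("no pixels with spectra")
  counts <- vapply(pixels, function(p) length(p$spectra), integer(1))
  n_slot <- min(counts)
  if (n_slot < 2L) stop("need >= 2 scans per pixel")
  if (length(unique(counts)) > 1L) {
    warning("pixels differ in scan count; aligning on the shortest (",
            n_slot, " slots)")
  }
  traces <- vapply(pixels, function(p) {
    x <- extract_xic(p$spectra[seq_len(n_slot)], target,
                     background = background)$intensity
    if (normalize && max(x) > 0) x / max(x) else x
  }, numeric(n_slot))
  traces <- matrix(traces, nrow = n_slot)
  structure(
    list(target = target,
         time_s = image$time_axis[seq_len(n_slot)],
         mean_intensity = rowMeans(traces),
         sd = apply(traces, 1, sd),
         n_pixels = length(pixels), normalized = normalize),
    class = "ElutionProfile")
}

#' @export
print.ElutionProfile <- function(x, ...) {
  cat(sprintf("<ElutionProfile> %s: %d slots, n = %d pixels%s\n",
              x$target$label, length(x$time_s), x$n_pixels,
              if (x$normalized) " (unit-max normalized)" else ""))
  invisible(x)
}

moving_mean3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
}

#' Summary features of an elution profile
#'
#' Quantifies the contrasts that separate solubility classes: soluble
#' species concentrate their signal in the first 30 s of probe residence,
#' membrane proteins peak later, and slow-dissolving transmembrane proteins
#' show near-flat profiles.
#'
#' @param profile An `ElutionProfile` (or any list with `time_s` and
#'   `mean_intensity`).
#' @return A `ProfileFeatures` list: `t_peak_s` (time of maximum),
#'   `frac_first_30s` (share of summed signal at t <= 30 s),
#'   `flatness` (decay flatness: min/max of the 3-slot moving mean taken
#'   from its peak slot onward, in \[0, 1\] -- the rising dissolution onset
#'   is excluded so that species depleting much slower than the dwell read
#'   as flat) and `t_half_s` (time at which cumulative signal reaches half
#'   its total).
#' @export
profile_features <- function(profile) {
  x <- profile$mean_intensity
  t <- profile$time_s
  total <- sum(x)
  if (total <= 0) stop("undefined-features error: all-zero profile")
  sm <- moving_mean3(x)
  peak <- which.max(sm)
  cum <- cumsum(x)
  structure(
    list(t_peak_s = t[which.max(x)],
         frac_first_30s = sum(x[t <= 30]) / total,
         flatness = min(sm[peak:length(sm)]) / max(sm),
         t_half_s = t[which(cum >= total / 2)[1]]),
    class = "ProfileFeatures")
}

#' Classify solubility from elution-profile features
#'
#' Rule cascade on [profile_features()]: a profile with at least
#' `frac30` of its signal in the first 30 s is soluble; otherwise a
#' near-flat profile (flatness >= `flat`) indicates a slow-dissolving
#' transmembrane species; the remainder -- delayed but peaked -- are
#' membrane-associated. The classification reflects elution behavior, not
#' annotation: a soluble protein locked in membrane-rich tissue elutes, and
#' is classified, like a membrane protein.
#'
#' @param features A `ProfileFeatures` object.
#' @param thresholds Named numeric vector `c(frac30 = 0.8, flat = 0.5)`.
#' @return `"soluble"`, `"transmembrane"` or `"membrane_associated"`.
#' @export
classify_solubility <- function(features,
                                thresholds = c(frac30 = 0.8, flat = 0.5)) {
  if (features$frac_first_30s >= thresholds[["frac30"]]) return("soluble")
  if (features$flatness >= thresholds[["flat"]]) return("transmembrane")
  "membrane_associated"
}

#' Neutral mass from a charge-state series
#'
#' Each peak (m/z, z) implies a neutral mass `z * (mz - m_proton)`; a
#' consistent series gives near-identical masses across charge states, so
#' the mean is the mass estimate and the SD a consistency check.
#'
#' @param peaks Two-column matrix/data.frame of `(mz, charge)`, or a list
#'   of such pairs.
#' @param flag_sd_da Series with SD above this (default 5 Da) are flagged
#'   inconsistent but still returned.
#' @return List with `mass_da` (mean), `sd_da` (0 for a single peak), and
#'   `flagged`.
#' @export
neutral_mass_from_series <- function(peaks, flag_sd_da = 5) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- do.call(rbind, lapply(peaks, function(p) c(p[1], p[2])))
  }
  peaks <- as.matrix(peaks)
  stopifnot(nrow(peaks) >= 1L, all(peaks[, 2] >= 1))
  masses <- peaks[, 2] * (peaks[, 1] - PROTON_MASS_DA)
  s <- if (nrow(peaks) > 1L) sd(masses) else 0
  list(mass_da = mean(masses), sd_da = s, flagged = s > flag_sd_da)
}

#' Catalog of lipid post-translational-modification mass shifts
#'
#' Monoisotopic mass additions of the membrane-anchoring PTMs relevant to
#' native protein imaging; `methylation` is the C-terminal methyl ester
#' that accompanies CaaX-motif prenylation.
#'
#' @return data.frame with `name`, `formula`, `shift_da`:
#'   S-geranylgeranylation +272.2504 (C20H32), S-farnesylation +204.1878
#'   (C15H24), N-myristoylation +210.1984 (C14H26O), C-terminal methylation
#'   +14.0157 (CH2).
#' @export
ptm_catalog <- function() {
  data.frame(
    name = c("geranylgeranylation", "farnesylation", "myristoylation",
             "methylation"),
    formula = c("C20H32", "C15H24", "C14H26O", "CH2"),
    shift_da = c(272.2504, 204.1878, 210.1984, 14.0157),
    stringsAsFactors = FALSE)
}

#' Match an observed mass shift to PTM combinations
#'
#' Exhaustively enumerates multisets of catalog entries (at most
#' `max_copies` of each) whose summed monoisotopic shift falls within
#' `tol_da` of the observed mass difference; e.g. a 286 Da shift matches
#' one geranylgeranylation plus one methylation (272.2504 + 14.0157 =
#' 286.27 Da), and ~558 Da matches two geranylgeranylations plus one
#' methylation.
#'
#' @param delta_da Observed positive mass difference in Da.
#' @param catalog A [ptm_catalog()]-shaped data.frame.
#' @param max_copies Maximum copies of each modification (default 2).
#' @param tol_da Matching tolerance in Da (default 1).
#' @return data.frame sorted by `abs(error_da)` with one row per matching
#'   combination: a `combo` description, one count column per catalog
#'   entry, `shift_da` and `error_da`. Zero rows if nothing matches.
#' @export
match_mass_shift <- function(delta_da, catalog = ptm_catalog(),
                             max_copies = 2, tol_da = 1) {
  stopifnot(delta_da > 0, tol_da > 0, max_copies >= 1)
  counts <- do.call(expand.grid, rep(list(0:max_copies), nrow(catalog)))
  names(counts) <- catalog$name
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  shift <- as.matrix(counts) %*% catalog$shift_da
  err <- shift - delta_da
  keep <- abs(err) <= tol_da
  out <- counts[keep, , drop = FALSE]
  out$shift_da <- shift[keep]
  out$error_da <- err[keep]
  out$combo <- if (nrow(out) == 0L) character(0) else {
    apply(out[, catalog$name, drop = FALSE], 1, function(r) {
      nz <- r > 0
      paste(sprintf("%dx %s", r[nz], catalog$name[nz]), collapse = " + ")
    })
  }
  out <- out[order(abs(out$error_da)), c("combo", catalog$name,
                                         "shift_da", "error_da")]
  rownames(out) <- NULL
  out
}
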