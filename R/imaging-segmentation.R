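#' Elution-time-filtered ion image
#'
#' Integrates a target's summed-charge-state XIC over the scans whose
#' elution times fall in a half-open time window, per pixel. Restricting
#' the window to a species' own elution period (e.g. 0.0-0.3 min for
#' soluble, 0.7-1.5 min for slow-dissolving species) improves image
#' specificity and signal-to-noise.
#'
#' @param image An [image4d()].
#' @param target An [xic_target()].
#' @param time_window_s `c(start, end)` in seconds, half-open
#'   `[start, end)`; NULL integrates the full time axis.
#' @param normalization `"none"` or `"max"` (scale the grid to unit
#'   maximum).
#' @return An `IonImage`: list with `grid` (n_rows x n_cols matrix),
#'   `target`, `time_window_s`, `normalization`.
#' @export
ion_image <- function(image, target, time_window_s = NULL,
                      normalization = c("none", "max")) {
  normalization <- match.arg(normalization)
  if (!is.null(time_window_s)) {
    if (time_window_s[1] >= time_window_s[2]) {
      stop("empty time window: start must be < end")
    }
  }
  grid <- matrix(0, nrow = image$n_rows, ncol = image$n_cols)
  for (px in image$pixels) {
    if (length(px$spectra) == 0L) next
    x <- extract_xic(px$spectra, target)
    keep <- if (is.null(time_window_s)) rep(TRUE, nrow(x)) else
      x$time_s >= time_window_s[1] & x$time_s < time_window_s[2]
    grid[px$row + 1L, px$col + 1L] <- sum(x$intensity[keep])
  }
  if (normalization == "max" && max(grid) > 0) grid <- grid / max(grid)
  structure(list(grid = grid, target = target,
                 time_window_s = time_window_s,
                 normalization = normalization),
            class = "IonImage")
}

#' Bin pixel spectra onto a fixed m/z grid
#'
#' Builds the pixel-by-bin feature matrix for multivariate analysis: each
#' pixel's scans (optionally restricted to an elution-time window first)
#' are summed over time, then intensities are accumulated into half-open
#' m/z bins `[lo + i*w, lo + (i+1)*w)`. Total intensity within the range
#' is conserved.
#'
#' @param image An [image4d()].
#' @param bin_width_mz Bin width in Th (default 2).
#' @param mz_range `c(lo, hi)`; bin count is `ceiling((hi - lo) / w)`
#'   (2400-4000 at width 2 gives 800 bins).
#' @param time_window_s Optional half-open elution-time filter applied
#'   before binning.
#' @return Numeric matrix, pixels (row-major) x bins, with bin centers in
#'   `colnames`-free attribute `mz_centers`; all-zero rows are flagged in
#'   attribute `empty_pixels`.
#' @export
bin_spectra <- function(image, bin_width_mz = 2, mz_range = c(2400, 4000),
                        time_window_s = NULL) {
  stopifnot(bin_width_mz > 0, mz_range[2] > mz_range[1])
  lo <- mz_range[1]
  n_bins <- ceiling((mz_range[2] - lo) / bin_width_mz)
  n_px <- length(image$pixels)
  mat <- matrix(0, nrow = n_px, ncol = n_bins)
  bin_add <- function(row, mz, inten) {
    sel <- mz >= lo & mz < mz_range[2]
    if (!any(sel)) return(row)
    b <- floor((mz[sel] - lo) / bin_width_mz) + 1L
    acc <- rowsum(inten[sel], b)
    idx <- as.integer(rownames(acc))
    row[idx] <- row[idx] + acc[, 1]
    row
  }
  for (p in seq_len(n_px)) {
    px <- image$pixels[[p]]
    # scans sharing an m/z axis (the usual case) are summed over time
    # first, so the binning pass runs once per pixel
    mz_ref <- NULL
    total <- NULL
    for (s in px$spectra) {
      if (!is.null(time_window_s)) {
        if (s$time_s < time_window_s[1] || s$time_s >= time_window_s[2]) next
      }
      if (is.null(mz_ref)) {
        mz_ref <- s$mz
        total <- s$intensity
      } else if (identical(s$mz, mz_ref)) {
        total <- total + s$intensity
      } else {
        mat[p, ] <- bin_add(mat[p, ], s$mz, s$intensity)
      }
    }
    if (!is.null(mz_ref)) mat[p, ] <- bin_add(mat[p, ], mz_ref, total)
  }
  empty <- which(rowSums(mat) == 0)
  if (length(empty) > 0L) {
    warning(length(empty), " pixel(s) have no signal in the binned range")
  }
  attr(mat, "mz_centers") <- lo + (seq_len(n_bins) - 0.5) * bin_width_mz
  attr(mat, "empty_pixels") <- empty
  mat
}

#' Segment pixels by PCA and k-means
#'
#' The standard MSI segmentation recipe: per-pixel TIC normalization (scale
#' invariance across pixels), column mean-centering, PCA to
#' `n_components` dimensions, then seeded k-means with `nstart >= 10`
#' restarts. Labels are canonicalized so class 0 is the largest, making
#' runs comparable across seeds.
#'
#' @param matrix Non-negative pixel-by-bin matrix from [bin_spectra()].
#' @param n_components Number of principal components (default 5); reduced
#'   with a warning if the matrix has lower rank.
#' @param k Number of clusters (default 2, e.g. gray vs white matter).
#' @param seed Integer RNG seed for k-means.
#' @param nstart k-means restarts (minimum 10 enforced).
#' @return A `SegmentationResult`: list with `labels` (0-based, per pixel),
#'   `n_components`, `k`, `class_sizes` (decreasing), `scores` (PC
#'   coordinates), `seed`.
#' @export
segment <- function(matrix, n_components = 5, k = 2, seed = 1L,
                    nstart = 10) {
  stopifnot(nrow(matrix) > k, all(matrix >= 0))
  tic <- rowSums(matrix)
  norm <- matrix
  nz <- tic > 0
  norm[nz, ] <- norm[nz, , drop = FALSE] / tic[nz]
  centered <- scale(norm, center = TRUE, scale = FALSE)
  pc <- prcomp(centered, center = FALSE, scale. = FALSE)
  avail <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (avail < n_components) {
    warning("matrix rank ", avail, " < n_components; using ", avail,
            " components")
    n_components <- avail
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = max(nstart, 10))
  sizes <- table(km$cluster)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(k)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(k) - 1L
  labels <- relabel[km$cluster]
  structure(
    list(labels = labels, n_components = n_components, k = k,
         class_sizes = as.integer(sizes[ord]), scores = scores,
         seed = seed),
    class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("<SegmentationResult> k = %d on %d PCs; class sizes: %s\n",
              x$k, x$n_components, paste(x$class_sizes, collapse = ", ")))
  invisible(x)
}

#' Per-class mean spectra and elution profiles
#'
#' Averages the binned spectra of each segmentation class and, if targets
#' are supplied, recomputes each target's averaged elution profile
#' restricted to the class's pixels. Class-restricted profiles have lower
#' SD than whole-image profiles for region-specific species because the
#' other tissue class no longer contributes background.
#'
#' @param image An [image4d()].
#' @param labels Integer vector of 0-based class labels, one per pixel
#'   (row-major), e.g. from [segment()].
#' @param targets Optional list of [xic_target()]s for per-class profiles.
#' @param bin_width_mz,mz_range Passed to [bin_spectra()].
#' @return Named list (one entry per non-empty class, `"class0"`, ...)
#'   with `n_pixels`, `mean_spectrum`, `mz_centers`, and `profiles` (list
#'   of `ElutionProfile` per target). Empty classes are dropped with a
#'   warning.
#' @export
class_mean_spectrum <- function(image, labels, targets = NULL,
                                bin_width_mz = 2, mz_range = c(2400, 4000)) {
  stopifnot(length(labels) == length(image$pixels))
  mat <- bin_spectra(image, bin_width_mz, mz_range)
  out <- list()
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    if (length(idx) == 0L) next
    entry <- list(
      label = lab, n_pixels = length(idx),
      mean_spectrum = colMeans(mat[idx, , drop = FALSE]),
      mz_centers = attr(mat, "mz_centers"))
    if (!is.null(targets)) {
      entry$profiles <- lapply(targets, function(tg)
        average_profiles(image, tg, normalize = TRUE, pixel_idx = idx))
    }
    out[[paste0("class", lab)]] <- entry
  }
  present <- sort(unique(labels))
  if (length(out) < length(present)) warning("empty class excluded")
  out
}
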