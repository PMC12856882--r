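#' Mean MS2 spectrum over an elution-time window
#'
#' Averages the product-ion scans whose (contact-aligned) times fall in the
#' half-open window. Because co-isolated precursors elute at different
#' times, a window placed late in the dwell yields a spectrum free of
#' fast-eluting (soluble) precursors' products -- the chimera is simplified
#' by elution-time filtering rather than by narrower isolation.
#'
#' @param ms2_scans Time-ordered list of MS2 [mass_spectrum()] objects
#'   sharing one m/z axis.
#' @param t_window_s `c(start, end)` seconds, half-open.
#' @return A [mass_spectrum()] whose intensity is the scan mean; `time_s`
#'   is the window start and the precursor window is carried over.
#' @export
window_mean_spectrum <- function(ms2_scans, t_window_s) {
  stopifnot(length(t_window_s) == 2L, t_window_s[1] < t_window_s[2])
  times <- vapply(ms2_scans, `[[`, numeric(1), "time_s")
  idx <- which(times >= t_window_s[1] & times < t_window_s[2])
  if (length(idx) == 0L) stop("no-scans error: window contains no scans")
  mz <- ms2_scans[[idx[1]]]$mz
  for (i in idx[-1]) {
    if (!identical(ms2_scans[[i]]$mz, mz)) {
      stop("window_mean_spectrum requires a shared m/z axis")
    }
  }
  inten <- Reduce(`+`, lapply(idx, function(i) ms2_scans[[i]]$intensity)) /
    length(idx)
  mass_spectrum(0L, t_window_s[1], mz, inten,
                ms2_scans[[idx[1]]]$ms_level,
                ms2_scans[[idx[1]]]$precursor_window)
}

#' Product-ion elution profiles averaged over sampling locations
#'
#' For each product-ion target (a subunit's charge-state series), extracts
#' the summed XIC at every location, aligns locations on the shortest
#' common scan count, averages, and scales to unit maximum. Product-ion
#' profiles track their precursor's dissolution kinetics and are more
#' specific than intact-mass traces.
#'
#' @param ms2_locations List of per-location MS2 scan lists (each
#'   time-ordered and contact-aligned).
#' @param targets List of [xic_target()]s, one per product-ion series.
#' @return List of `ProductIonSeries`: for each target, `label`,
#'   `charges`, `time_s`, `intensity` (unit-max mean), `sd`,
#'   `n_locations`, `source_window` (the shared precursor isolation
#'   window), and any `precursor` attribute carried on the target.
#' @export
product_ion_profiles <- function(ms2_locations, targets) {
  stopifnot(length(ms2_locations) >= 1L)
  keep <- vapply(ms2_locations, function(l) length(l) > 0L, logical(1))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " empty location(s)")
    ms2_locations <- ms2_locations[keep]
  }
  counts <- vapply(ms2_locations, length, integer(1))
  n_slot <- min(counts)
  if (length(unique(counts)) > 1L) {
    warning("locations differ in scan count; aligning on the shortest")
  }
  times <- vapply(ms2_locations[[1]][seq_len(n_slot)], `[[`, numeric(1),
                  "time_s")
  src <- ms2_locations[[1]][[1]]$precursor_window
  lapply(targets, function(tg) {
    traces <- vapply(ms2_locations, function(loc) {
      extract_xic(loc[seq_len(n_slot)], tg)$intensity
    }, numeric(n_slot))
    traces <- matrix(traces, nrow = n_slot)
    m <- rowMeans(traces)
    s <- apply(traces, 1, sd)
    if (max(m) > 0) {
      s <- s / max(m)
      m <- m / max(m)
    }
    structure(
      list(label = tg$label, charges = tg$charges, time_s = times,
           intensity = m, sd = s, n_locations = ncol(traces),
           source_window = src,
           precursor = attr(tg, "precursor")),
      class = "ProductIonSeries")
  })
}

#' Group product ions by elution-profile similarity
#'
#' Single-linkage grouping on the Pearson correlation of normalized
#' product-ion profiles: any pair with `r >= r_threshold` is linked, and
#' connected components form the groups. Product ions of one precursor
#' share its dissolution kinetics, so groups recover the precursor
#' families of a chimeric isolation window automatically (the reference
#' workflow separates them by manually chosen time windows). Constant
#' (zero-variance) profiles cannot be correlated and are assigned their
#' own group with a warning. Output order is deterministic: groups are
#' sorted by their lexicographically smallest member label, members
#' sorted within.
#'
#' @param series List of `ProductIonSeries` (>= 2).
#' @param r_threshold Linking threshold (default 0.8).
#' @return List of character vectors of member labels; attribute
#'   `membership` gives the group index per input series.
#' @export
group_by_profile <- function(series, r_threshold = 0.8) {
  n <- length(series)
  stopifnot(n >= 2L)
  labels <- unname(vapply(series, `[[`, character(1), "label"))
  prof <- lapply(series, `[[`, "intensity")
  variable <- vapply(prof, function(x) sd(x) > 0, logical(1))
  if (!all(variable)) {
    warning("constant product-ion profile(s) assigned to singleton groups: ",
            paste(labels[!variable], collapse = ", "))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!variable[i] || !variable[j]) next
      if (cor(prof[[i]], prof[[j]]) >= r_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(labels, roots)
  comp <- lapply(comp, sort)
  comp <- comp[order(vapply(comp, `[[`, character(1), 1))]
  names(comp) <- NULL
  membership <- vapply(seq_len(n), function(i) {
    which(vapply(comp, function(g) labels[i] %in% g, logical(1)))[1]
  }, integer(1))
  attr(comp, "membership") <- membership
  comp
}
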