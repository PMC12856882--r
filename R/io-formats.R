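#' The 4D image store (x, y, elution time, m/z)
#'
#' Container for a pixelated discrete-mode acquisition: a grid of
#' [pixel_record()]s whose spectra are aligned on a shared elution-time
#' axis. The atom of the store is one spectrum at one (x, y, elution-time)
#' coordinate.
#'
#' @param pixels List of [pixel_record()]s in row-major order (index =
#'   `row * n_cols + col + 1`); coordinates must be unique and consistent
#'   with that order.
#' @param n_cols,n_rows Grid dimensions.
#' @param schedule The [acquisition_schedule()] that produced the image.
#' @param time_axis Strictly increasing per-scan-slot elution times
#'   (seconds since pixel contact); every pixel has at most
#'   `length(time_axis)` scans.
#' @param metadata Free-form provenance list.
#' @return An object of class `Image4D`.
#' @export
image4d <- function(pixels, n_cols, n_rows, schedule, time_axis,
                    metadata = list()) {
  stopifnot(length(pixels) == n_cols * n_rows)
  if (length(time_axis) > 1L && any(diff(time_axis) <= 0)) {
    stop("time_axis must be strictly increasing")
  }
  coords <- vapply(pixels, function(p) c(p$col, p$row), numeric(2))
  key <- coords[2, ] * n_cols + coords[1, ]
  if (anyDuplicated(key)) stop("duplicate pixel coordinates")
  if (!identical(as.integer(key), seq_len(length(pixels)) - 1L)) {
    stop("pixels must be in row-major order matching their (col, row)")
  }
  n_scans <- vapply(pixels, function(p) length(p$spectra), integer(1))
  if (any(n_scans > length(time_axis))) {
    stop("pixel has more scans than time_axis slots")
  }
  structure(
    list(pixels = pixels, n_cols = as.integer(n_cols),
         n_rows = as.integer(n_rows), schedule = schedule,
         time_axis = as.numeric(time_axis), metadata = metadata),
    class = "Image4D")
}

#' @export
print.Image4D <- function(x, ...) {
  cat(sprintf("<Image4D> %d x %d pixels, %d elution-time slots, dt = %g s\n",
              x$n_cols, x$n_rows, length(x$time_axis),
              x$schedule$scan_period_s))
  invisible(x)
}

#' Fetch one pixel from an Image4D
#' @param image An [image4d()].
#' @param col,row 0-based grid indices.
#' @return The [pixel_record()] at that coordinate.
#' @export
get_pixel <- function(image, col, row) {
  stopifnot(col >= 0, col < image$n_cols, row >= 0, row < image$n_rows)
  image$pixels[[row * image$n_cols + col + 1L]]
}

#' Structural equality of two Image4D stores
#'
#' Compares grid shape, schedule, time axis (numeric tolerance), and every
#' pixel's coordinates, contact scan, and spectra (m/z, intensity, times,
#' MS level, precursor windows). Used to verify lossless round trips.
#'
#' @param a,b [image4d()] objects.
#' @param tol Numeric tolerance for times/schedule; m/z and intensity
#'   arrays are compared exactly.
#' @return TRUE or a character description of the first difference.
#' @export
image4d_equal <- function(a, b, tol = 1e-9) {
  if (a$n_cols != b$n_cols || a$n_rows != b$n_rows) return("grid shape differs")
  sa <- a$schedule; sb <- b$schedule
  for (f in names(sa)) {
    if (!isTRUE(all.equal(sa[[f]], sb[[f]], tolerance = tol))) {
      return(paste("schedule field differs:", f))
    }
  }
  if (!isTRUE(all.equal(a$time_axis, b$time_axis, tolerance = tol))) {
    return("time_axis differs")
  }
  for (i in seq_along(a$pixels)) {
    pa <- a$pixels[[i]]; pb <- b$pixels[[i]]
    if (pa$col != pb$col || pa$row != pb$row) return("pixel coords differ")
    if (!identical(is.na(pa$contact_scan), is.na(pb$contact_scan)) ||
        (!is.na(pa$contact_scan) && pa$contact_scan != pb$contact_scan)) {
      return("contact_scan differs")
    }
    if (length(pa$spectra) != length(pb$spectra)) return("scan count differs")
    for (j in seq_along(pa$spectra)) {
      qa <- pa$spectra[[j]]; qb <- pb$spectra[[j]]
      if (!identical(qa$mz, qb$mz)) return("mz arrays differ")
      if (!identical(qa$intensity, qb$intensity)) return("intensity differs")
      if (!isTRUE(all.equal(qa$time_s, qb$time_s, tolerance = tol))) {
        return("spectrum times differ")
      }
      if (qa$ms_level != qb$ms_level) return("ms_level differs")
      if (!isTRUE(all.equal(qa$precursor_window, qb$precursor_window))) {
        return("precursor_window differs")
      }
    }
  }
  TRUE
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
}

# ---- raw scan streams -------------------------------------------------------

#' Read an ordered raw scan stream
#'
#' @param path File path.
#' @param format `"mzml"` (read through mzR), `"jsondump"` (the package's
#'   dependency-free JSON dialect), or `"auto"` to pick by extension.
#' @return List of [mass_spectrum()] objects ordered by time; MS level and
#'   precursor isolation windows are preserved for MS2 scans.
#' @export
read_scan_stream <- function(path, format = c("auto", "mzml", "jsondump")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mzml = "mzml", json = "jsondump",
                     stop("unsupported format: ", tools::file_ext(path)))
  }
  if (file.size(path) == 0) stop("format error: empty file")
  scans <- switch(format,
                  mzml = read_mzml_stream(path),
                  jsondump = read_jsondump_stream(path))
  if (length(scans) == 0L) stop("format error: stream contains no scans")
  times <- vapply(scans, `[[`, numeric(1), "time_s")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("format error: scan times unsorted or duplicated")
  }
  scans
}

read_mzml_stream <- function(path) {
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) stop("format error: ",
                                              conditionMessage(e)))
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) return(list())
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hdr)), function(i) {
    pw <- NULL
    if (hdr$msLevel[i] >= 2L) {
      ctr <- hdr$isolationWindowTargetMZ[i]
      off <- hdr$isolationWindowUpperOffset[i]
      if (is.na(ctr)) ctr <- hdr$precursorMZ[i]
      if (!is.na(ctr)) pw <- c(ctr, if (is.na(off) || off <= 0) 0.5 else off)
    }
    mass_spectrum(i - 1L, hdr$retentionTime[i], pk[[i]][, 1], pk[[i]][, 2],
                  hdr$msLevel[i], pw)
  })
}

read_jsondump_stream <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e) stop("format error: ",
                                           conditionMessage(e)))
  if (is.null(obj$scans)) stop("format error: not a nanodims jsondump")
  lapply(obj$scans, function(s) {
    mass_spectrum(s$scan_index, s$time_s, unlist(s$mz), unlist(s$intensity),
                  s$ms_level,
                  if (is.null(s$precursor_window)) NULL
                  else unlist(s$precursor_window))
  })
}

#' Write a raw scan stream
#'
#' @param scans List of [mass_spectrum()] objects.
#' @param path Output path.
#' @param format `"mzml"` (written through mzR) or `"jsondump"`.
#' @return `path`, invisibly.
#' @export
write_scan_stream <- function(scans, path, format = c("mzml", "jsondump")) {
  format <- match.arg(format)
  stopifnot(length(scans) > 0L)
  if (format == "jsondump") {
    payload <- list(
      format = "nanodims-jsondump", version = 1L,
      scans = lapply(scans, function(s) {
        out <- list(scan_index = s$scan_index, time_s = s$time_s,
                    ms_level = s$ms_level, mz = s$mz,
                    intensity = s$intensity)
        if (!is.null(s$precursor_window)) {
          out$precursor_window <- s$precursor_window
        }
        out
      }))
    json_write(payload, path)
    return(invisible(path))
  }
  n <- length(scans)
  pk <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  lv <- vapply(scans, `[[`, integer(1), "ms_level")
  tm <- vapply(scans, `[[`, numeric(1), "time_s")
  pwc <- vapply(scans, function(s)
    if (is.null(s$precursor_window)) NA_real_ else s$precursor_window[1],
    numeric(1))
  pwh <- vapply(scans, function(s)
    if (is.null(s$precursor_window)) NA_real_ else s$precursor_window[2],
    numeric(1))
  npk <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = tm,
    basePeakMZ = vapply(pk, function(m)
      if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(m)
      if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(lv > 1L, 70, 0), ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = ifelse(is.na(pwc), 0, pwc),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = pwc, isolationWindowLowerOffset = pwh,
    isolationWindowUpperOffset = pwh,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pk, file = path, header = hdr)
  invisible(path)
}

# ---- 4D imzML ---------------------------------------------------------------

# Encoding dialect: standard imzML carries (x, y, z) pixel positions; the
# elution-time slot index is stored in the z slot (1-based), with the
# index -> seconds mapping and the acquisition schedule in a JSON sidecar.
# Processed mode (per-spectrum m/z arrays) is used throughout since scans
# are never resampled onto a common grid. Flagged in metadata$encoding.
IMZML_DIALECT <- "nanodims-4d/elution-time-in-z/v1"

imzml_paths <- function(path) {
  base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"),
       sidecar = paste0(base, ".meta.json"))
}

#' Write an Image4D as 4D imzML
#'
#' Writes processed-mode imzML: an XML index (`.imzML`) whose spectra carry
#' 1-based (x, y, z) positions with the elution-time slot in z, a binary
#' `.ibd` with a shared UUID and little-endian float64 m/z / intensity
#' arrays, and a `.meta.json` sidecar holding the schedule, the elution
#' time axis, per-spectrum clock times and MS metadata. The round trip
#' through [read_imzml4d()] is lossless.
#'
#' @param image An [image4d()].
#' @param path Output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml4d <- function(image, path) {
  stopifnot(inherits(image, "Image4D"))
  p <- imzml_paths(path)
  uuid <- as.raw(sample.int(256, 16, replace = TRUE) - 1L)
  uuid_hex <- paste(sprintf("%02x", as.integer(uuid)), collapse = "")

  con <- file(p$ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  spec_xml <- character(0)
  idx <- 0L
  for (px in image$pixels) {
    for (j in seq_along(px$spectra)) {
      s <- px$spectra[[j]]
      n <- length(s$mz)
      writeBin(s$mz, con, size = 8, endian = "little")
      mz_off <- offset; offset <- offset + 8 * n
      writeBin(s$intensity, con, size = 8, endian = "little")
      int_off <- offset; offset <- offset + 8 * n
      spec_xml <- c(spec_xml, sprintf(
        paste0(
          '   <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
          '    <scanList count="1"><scan>\n',
          '     <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
          '     <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
          '     <cvParam cvRef="IMS" accession="IMS:1000052" name="position z" value="%d"/>\n',
          '    </scan></scanList>\n',
          '    <binaryDataArrayList count="2">\n',
          '     <binaryDataArray encodedLength="0">\n',
          '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
          '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
          '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
          '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
          '      <binary/>\n',
          '     </binaryDataArray>\n',
          '     <binaryDataArray encodedLength="0">\n',
          '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
          '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
          '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
          '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
          '      <binary/>\n',
          '     </binaryDataArray>\n',
          '    </binaryDataArrayList>\n',
          '   </spectrum>'),
        idx, idx, n, px$col + 1L, px$row + 1L, j, mz_off, n, int_off, n))
      idx <- idx + 1L
    }
  }

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    ' <fileDescription>',
    '  <fileContent>',
    '   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            uuid_hex),
    '  </fileContent>',
    ' </fileDescription>',
    sprintf(' <run id="nanodims4d" defaultSourceFileRef="%s">',
            basename(p$ibd)),
    sprintf('  <spectrumList count="%d">', idx),
    spec_xml,
    '  </spectrumList>',
    ' </run>',
    '</mzML>')
  writeLines(xml, p$xml)

  sidecar <- list(
    dialect = IMZML_DIALECT,
    uuid = uuid_hex,
    n_cols = image$n_cols, n_rows = image$n_rows,
    schedule = unclass(image$schedule),
    time_axis = image$time_axis,
    metadata = image$metadata,
    pixels = lapply(image$pixels, function(px) list(
      col = px$col, row = px$row, center_um = px$center_um,
      contact_scan = px$contact_scan,
      spectra = lapply(px$spectra, function(s) {
        out <- list(scan_index = s$scan_index, time_s = s$time_s,
                    ms_level = s$ms_level)
        if (!is.null(s$precursor_window)) {
          out$precursor_window <- s$precursor_window
        }
        out
      }))))
  json_write(sidecar, p$sidecar)
  invisible(path)
}

#' Read a 4D imzML store written by [write_imzml4d()]
#'
#' @param path Path to the `.imzML` file (the `.ibd` and `.meta.json`
#'   companions must sit beside it).
#' @return The reconstructed [image4d()].
#' @export
read_imzml4d <- function(path) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) stop("read error: missing imzML file ", p$xml)
  if (!file.exists(p$ibd)) stop("read error: missing binary file ", p$ibd)
  if (!file.exists(p$sidecar)) stop("read error: missing sidecar ", p$sidecar)

  doc <- xml2::read_xml(p$xml)
  xml2::xml_ns_strip(doc)
  uuid_xml <- xml2::xml_attr(xml2::xml_find_first(
    doc, "//cvParam[@accession='IMS:1000080']"), "value")
  uuid_xml <- gsub("[{}-]", "", tolower(uuid_xml))

  ibd <- file(p$ibd, "rb")
  on.exit(close(ibd), add = TRUE)
  uuid_ibd <- paste(sprintf("%02x", as.integer(readBin(ibd, "raw", 16))),
                    collapse = "")
  if (!identical(uuid_xml, uuid_ibd)) {
    stop("read error: ibd UUID does not match imzML UUID")
  }

  side <- jsonlite::fromJSON(p$sidecar, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(side$dialect, IMZML_DIALECT)) {
    stop("read error: unknown 4D encoding dialect")
  }

  nodes <- xml2::xml_find_all(doc, "//spectrum")
  get_val <- function(node, acc) {
    as.numeric(xml2::xml_attr(xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", acc)), "value"))
  }
  recs <- lapply(nodes, function(node) {
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    kind <- vapply(arrays, function(a) {
      if (length(xml2::xml_find_all(
        a, ".//cvParam[@accession='MS:1000514']")) > 0) "mz" else "intensity"
    }, character(1))
    list(x = get_val(node, "IMS:1000050"), y = get_val(node, "IMS:1000051"),
         z = get_val(node, "IMS:1000052"),
         off = setNames(vapply(arrays, get_val, numeric(1),
                               acc = "IMS:1000102"), kind),
         len = setNames(vapply(arrays, get_val, numeric(1),
                               acc = "IMS:1000103"), kind))
  })
  read_arr <- function(off, len) {
    seek(ibd, where = off, origin = "start")
    readBin(ibd, "double", n = len, size = 8, endian = "little")
  }

  schedule <- do.call(acquisition_schedule, side$schedule[
    c("mode", "pitch_x_um", "pitch_y_um", "dwell_s", "scan_period_s",
      "raster_speed_um_s", "junction_diameter_um", "per_pixel_overhead_s")])
  n_cols <- side$n_cols
  by_pixel <- split(recs, vapply(recs, function(r)
    (r$y - 1) * n_cols + (r$x - 1), numeric(1)))

  pixels <- lapply(side$pixels, function(pm) {
    key <- as.character(pm$row * n_cols + pm$col)
    rs <- by_pixel[[key]]
    if (is.null(rs)) rs <- list()
    rs <- rs[order(vapply(rs, `[[`, numeric(1), "z"))]
    stopifnot(length(rs) == length(pm$spectra))
    spectra <- lapply(seq_along(rs), function(j) {
      r <- rs[[j]]; sm <- pm$spectra[[j]]
      mass_spectrum(sm$scan_index, sm$time_s,
                    read_arr(r$off[["mz"]], r$len[["mz"]]),
                    read_arr(r$off[["intensity"]], r$len[["intensity"]]),
                    sm$ms_level,
                    if (is.null(sm$precursor_window)) NULL
                    else unlist(sm$precursor_window))
    })
    pixel_record(pm$col, pm$row, unlist(pm$center_um), spectra,
                 if (is.null(pm$contact_scan)) NA_integer_
                 else pm$contact_scan)
  })
  image4d(pixels, n_cols, side$n_rows, schedule,
          unlist(side$time_axis),
          if (is.null(side$metadata)) list() else side$metadata)
}
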