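## mzXML MS1 reading and the in-memory ion map -------------------------------

#' Construct a sample ion map
#'
#' A `SampleIonMap` holds the centroided MS1 ion cloud of one sample:
#' one row per centroid peak with retention time (minutes), m/z (Th) and
#' intensity, plus an optional inverse reduced ion mobility column `im`.
#' Ions are stored sorted by RT; a secondary m/z-sorted index makes the
#' rectangular window query ([ions_in_window()]) O(log n + hits).
#'
#' @param ions data.frame/data.table with columns `rt` (minutes), `mz` (Th),
#'   `intensity`, and optionally `im`.
#' @param sample_id opaque sample label.
#' @return object of class `SampleIonMap`.
#' @export
sample_ion_map <- function(ions, sample_id) {
  ions <- as.data.table(ions)
  req <- c("rt", "mz", "intensity")
  miss <- setdiff(req, names(ions))
  if (length(miss))
    stop("ion table misses column(s): ", paste(miss, collapse = ", "))
  if (nrow(ions)) {
    stopifnot(all(ions$rt >= 0), all(ions$mz > 0), all(ions$intensity >= 0))
    if ("im" %in% names(ions) && anyNA(ions$im))
      stop("`im` must be present for all ions of a sample or for none")
  }
  setorder(ions, rt, mz)
  o <- order(ions$mz)
  map <- list(
    sample_id = sample_id,
    ions      = ions,
    # m/z-sorted copies for O(log n + hits) window queries (m/z is by far
    # the more selective dimension)
    mz_s      = ions$mz[o],
    rt_s      = ions$rt[o],
    int_s     = ions$intensity[o],
    im_s      = if ("im" %in% names(ions)) ions$im[o] else NULL,
    rt_range  = if (nrow(ions)) range(ions$rt) else c(NA_real_, NA_real_),
    mz_range  = if (nrow(ions)) range(ions$mz) else c(NA_real_, NA_real_)
  )
  class(map) <- "SampleIonMap"
  map
}

# indices (into the m/z-sorted arrays) of ions inside the closed window
.win_idx <- function(map, rt_lo, rt_hi, mz_lo, mz_hi) {
  if (!length(map$mz_s)) return(integer())
  b <- .mz_bounds(map$mz_s, mz_lo, mz_hi)
  if (b[1] > b[2]) return(integer())
  idx <- b[1]:b[2]
  rt <- map$rt_s[idx]
  idx[rt >= rt_lo & rt <= rt_hi]
}

# fast extraction: c(count, total, signal) given an intensity threshold
.extract_vec <- function(map, rt_lo, rt_hi, mz_lo, mz_hi, thr = -Inf) {
  if (!length(map$mz_s)) return(c(0, 0, 0))
  .extract_window(map$mz_s, map$rt_s, map$int_s, rt_lo, rt_hi,
                  mz_lo, mz_hi, thr)
}

#' @export
print.SampleIonMap <- function(x, ...) {
  cat(sprintf("<SampleIonMap> sample '%s': %d ions", x$sample_id,
              nrow(x$ions)))
  if (nrow(x$ions))
    cat(sprintf(", RT %.2f-%.2f min, m/z %.4f-%.4f",
                x$rt_range[1], x$rt_range[2], x$mz_range[1], x$mz_range[2]))
  cat("\n")
  invisible(x)
}

#' Query ions in a closed RT x m/z window
#'
#' Returns exactly the ions with `rt_lo <= rt <= rt_hi` and
#' `mz_lo <= mz <= mz_hi` (closed on all four boundaries). The result is
#' independent of internal storage order. The m/z bound is applied first via
#' binary search because it is by far the more selective dimension.
#'
#' @param map a [sample_ion_map()].
#' @param rt_lo,rt_hi,mz_lo,mz_hi window bounds (minutes / Th).
#' @param im_lo,im_hi optional ion-mobility bounds, applied only when the
#'   map carries an `im` column.
#' @return data.table of matching ions (rows ordered by m/z).
#' @export
ions_in_window <- function(map, rt_lo, rt_hi, mz_lo, mz_hi,
                           im_lo = NULL, im_hi = NULL) {
  if (!nrow(map$ions)) return(map$ions)
  idx <- .win_idx(map, rt_lo, rt_hi, mz_lo, mz_hi)
  if (!is.null(im_lo) && !is.null(map$im_s)) {
    im <- map$im_s[idx]
    idx <- idx[im >= im_lo & im <= im_hi]
  }
  out <- data.table(rt = map$rt_s[idx], mz = map$mz_s[idx],
                    intensity = map$int_s[idx])
  if (!is.null(map$im_s)) out[, im := map$im_s[idx]]
  out
}

## -- mzXML parsing -----------------------------------------------------------

# ISO8601 duration as used by mzXML retentionTime attributes ("PT1234.5S",
# occasionally "PT12.3M"); returns minutes.
parse_iso_rt <- function(s) {
  m <- regmatches(s, regexec("^PT([0-9.eE+-]+)([SM])$", s))
  vapply(seq_along(s), function(i) {
    mi <- m[[i]]
    if (length(mi) == 3L) {
      v <- as.numeric(mi[2L])
      return(if (mi[3L] == "S") v / 60 else v)
    }
    # bare number: assume seconds (mzXML default unit)
    v <- suppressWarnings(as.numeric(s[i]))
    if (is.na(v)) stop("unparseable retentionTime: ", s[i])
    v / 60
  }, numeric(1))
}

decode_peaks <- function(b64, precision, byte_order = "network",
                         compression = "none") {
  raw <- jsonlite::base64_dec(gsub("[\r\n ]", "", b64))
  if (identical(compression, "zlib"))
    raw <- memDecompress(raw, type = "gzip")
  else if (!compression %in% c("none", ""))
    stop("unsupported peaks compression: ", compression)
  endian <- if (identical(byte_order, "little")) "little" else "big"
  n <- length(raw) %/% (precision %/% 8L)
  readBin(raw, what = "double", n = n, size = precision %/% 8L,
          endian = endian)
}

#' Read the MS1 ion map of one sample from a centroided mzXML file
#'
#' Only scans with `msLevel="1"` contribute; every centroid peak of such a
#' scan becomes one ion carrying the scan's retention time, converted to
#' minutes regardless of the unit recorded in the file. Files whose scans
#' are explicitly marked as profile mode (`centroided="0"`) are rejected.
#'
#' @param path mzXML file.
#' @param sample_id label attached to the resulting map (default: file name
#'   without extension).
#' @return a [sample_ion_map()]. A file without MS1 scans yields an empty
#'   map with a warning.
#' @export
read_ms1_map <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("mzXML parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  scans <- xml2::xml_find_all(doc, "//scan[@msLevel='1']")
  if (!length(scans)) {
    warning("no MS1 scans in ", path, "; returning empty ion map")
    return(sample_ion_map(data.table(rt = numeric(), mz = numeric(),
                                     intensity = numeric()), sample_id))
  }
  cen <- xml2::xml_attr(scans, "centroided")
  if (any(!is.na(cen) & cen == "0"))
    stop("mzXML file ", path, " contains profile-mode MS1 scans; ",
         "requant requires centroided input")
  # vectorized over the scan nodeset: per-scan XPath calls dominate
  # otherwise on files with many scans
  rt_min <- parse_iso_rt(xml2::xml_attr(scans, "retentionTime"))
  npeaks <- suppressWarnings(
    as.integer(xml2::xml_attr(scans, "peaksCount")))
  pks <- xml2::xml_find_first(scans, "peaks")
  prec <- suppressWarnings(as.integer(xml2::xml_attr(pks, "precision")))
  prec[is.na(prec)] <- 32L
  comp <- xml2::xml_attr(pks, "compressionType")
  comp[is.na(comp)] <- "none"
  bo <- xml2::xml_attr(pks, "byteOrder")
  bo[is.na(bo)] <- "network"
  txt <- xml2::xml_text(pks)
  per_scan <- lapply(seq_along(scans), function(i) {
    if (is.na(txt[i]) || identical(npeaks[i], 0L)) return(NULL)
    v <- decode_peaks(txt[i], prec[i], bo[i], comp[i])
    if (!length(v)) return(NULL)
    mzv <- v[seq(1L, length(v), by = 2L)]
    inv <- v[seq(2L, length(v), by = 2L)]
    if (!is.na(npeaks[i]) && length(mzv) != npeaks[i])
      stop("peaksCount mismatch in scan of ", path)
    data.table(rt = rt_min[i], mz = mzv, intensity = inv)
  })
  ions <- rbindlist(per_scan)
  if (!nrow(ions))
    ions <- data.table(rt = numeric(), mz = numeric(), intensity = numeric())
  sample_ion_map(ions, sample_id)
}

#' Write an ion table as a minimal centroided mzXML file
#'
#' Emits the dialect [read_ms1_map()] consumes: one MS1 scan per distinct
#' retention time, peaks base64-encoded as network-order 32-bit floats,
#' retention times in seconds (`PT...S`). Used by the synthetic-data
#' generator; not a general-purpose mzXML exporter.
#'
#' @param ions data.frame with `rt` (minutes), `mz`, `intensity`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(ions, path) {
  ions <- as.data.table(ions)
  setorder(ions, rt, mz)
  rts <- unique(ions$rt)
  grp <- ions[, .(b64 = {
    v <- as.vector(rbind(mz, intensity))
    raw <- writeBin(v, raw(), size = 4L, endian = "big")
    gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)
  }, n = .N), by = rt]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', nrow(grp))), con)
  for (i in seq_len(nrow(grp))) {
    writeLines(sprintf(
      paste0('  <scan num="%d" msLevel="1" centroided="1" peaksCount="%d"',
             ' retentionTime="PT%.6fS">'),
      i, grp$n[i], grp$rt[i] * 60), con)
    writeLines(sprintf(
      paste0('   <peaks precision="32" byteOrder="network"',
             ' contentType="m/z-int" compressionType="none">%s</peaks>'),
      grp$b64[i]), con)
    writeLines("  </scan>", con)
  }
  writeLines(c(" </msRun>", "</mzXML>"), con)
  invisible(path)
}
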