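library(data.table)

# hand-written mzXML text (independent of write_mzxml) ----------------------

# base64 of interleaved (mz, intensity) pairs, big-endian float32
b64_peaks <- function(mz, intensity) {
  v <- as.vector(rbind(mz, intensity))
  gsub("\n", "", jsonlite::base64_enc(
    writeBin(v, raw(), size = 4L, endian = "big")), fixed = TRUE)
}

make_mzxml_text <- function(scans) {
  # scans: list of list(rt_attr, ms_level, mz, intensity, centroided)
  body <- vapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    cen <- if (is.null(sc$centroided)) "1" else sc$centroided
    paste0(
      sprintf('  <scan num="%d" msLevel="%s" centroided="%s" peaksCount="%d" retentionTime="%s">',
              i, sc$ms_level %||% "1", cen, length(sc$mz), sc$rt_attr),
      sprintf('<peaks precision="32" byteOrder="network" contentType="m/z-int" compressionType="none">%s</peaks>',
              b64_peaks(sc$mz, sc$intensity)),
      "</scan>")
  }, character(1))
  paste(c('<?xml version="1.0" encoding="ISO-8859-1"?>',
          '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
          sprintf(' <msRun scanCount="%d">', length(scans)),
          body, " </msRun>", "</mzXML>"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp <- function(text, ext = ".mzXML") {
  f <- tempfile(fileext = ext)
  writeLines(text, f)
  f
}

# small detected-feature table builder ---------------------------------------
make_features <- function(sample_id, sequence, charge, mz, rt,
                          mz_uncal = mz, rt_peak_width = 0.5,
                          intensity = 1e6, resolution = 6e4,
                          modifications = "Unmodified",
                          protein = NA_character_,
                          is_contaminant = FALSE, is_reverse = FALSE) {
  data.table(sample_id = sample_id, sequence = sequence,
             modifications = modifications, charge = as.integer(charge),
             mz_calibrated = mz, mz_uncalibrated = mz_uncal, rt = rt,
             rt_peak_width = rt_peak_width, intensity = intensity,
             resolution = resolution, protein = protein,
             is_contaminant = is_contaminant, is_reverse = is_reverse)
}

# resolved windows without estimation
fixed_windows <- function(rt = 0.5, mz = 0.005) {
  estimate_alignment_windows(
    data.table(), alignment_windows(user_fixed_rt = rt, user_fixed_mz = mz))
}

# ion map from plain vectors
make_map <- function(rt, mz, intensity = rep(1, length(rt)),
                     sample_id = "S1") {
  sample_ion_map(data.table(rt = rt, mz = mz, intensity = intensity),
                 sample_id)
}

# brute-force window scan over all ions of a map (oracle for extract_quant)
brute_extract <- function(map, rt_lo, rt_hi, mz_lo, mz_hi) {
  ions <- map$ions
  hit <- ions$rt >= rt_lo & ions$rt <= rt_hi &
    ions$mz >= mz_lo & ions$mz <= mz_hi
  list(n = sum(hit), total = sum(ions$intensity[hit]))
}

# brute-force bivariate normal KDE evaluated at a point (oracle for kde2d:
# kernel sd = h/4 per dimension)
brute_kde <- function(x, y, hx, hy, px, py) {
  sx <- hx / 4; sy <- hy / 4
  mean(stats::dnorm(px, x, sx) * stats::dnorm(py, y, sy))
}

# tiny synthetic world for fast pipeline tests
tiny_synth_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 4L, n_species = 60L, peptides_per_protein = 3L,
         rt_range = c(10, 20), mz_range = c(400, 412),
         noise_ion_density = 500, n_extra_features = 300L),
    list(...))
  do.call(synthetic_config, args)
}

tiny_pipeline_config <- function(...) {
  pipeline_config(
    fdr = list(n_mask = 25L),
    mz_model = list(min_rows = 40L, min_node = 20L),
    ...)
}
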