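## Detected-feature tables (MaxQuant-like dialects) and result writers -------

# canonical column -> header per dialect; NA marks an optional column
dialect_maps <- list(
  allpeptides = c(sample_id      = "Raw file",
                  sequence       = "Sequence",
                  modifications  = "Modifications",
                  charge         = "Charge",
                  mz_calibrated  = "m/z",
                  mz_uncalibrated = "Uncalibrated m/z",
                  rt             = "Retention time",
                  rt_peak_width  = "Retention length",
                  intensity      = "Intensity",
                  resolution     = "Resolution",
                  protein        = "Proteins",
                  is_contaminant = "Potential contaminant",
                  is_reverse     = "Reverse"),
  evidence    = c(sample_id      = "Raw file",
                  sequence       = "Sequence",
                  modifications  = "Modifications",
                  charge         = "Charge",
                  mz_calibrated  = "m/z",
                  mz_uncalibrated = "Uncalibrated m/z",
                  rt             = "Retention time",
                  rt_peak_width  = "Retention length",
                  intensity      = "Intensity",
                  resolution     = "Resolution",
                  protein        = "Leading razor protein",
                  is_contaminant = "Potential contaminant",
                  is_reverse     = "Reverse"),
  generic     = c(sample_id      = "sample_id",
                  sequence       = "sequence",
                  modifications  = "modifications",
                  charge         = "charge",
                  mz_calibrated  = "mz_calibrated",
                  mz_uncalibrated = "mz_uncalibrated",
                  rt             = "rt",
                  rt_peak_width  = "rt_peak_width",
                  intensity      = "intensity",
                  resolution     = "resolution",
                  protein        = "protein",
                  is_contaminant = "is_contaminant",
                  is_reverse     = "is_reverse")
)

# columns that must be present and numeric-parseable for a row to survive
.required_cols <- c("charge", "mz_calibrated", "rt")
.optional_cols <- c("sample_id", "sequence", "modifications",
                    "mz_uncalibrated", "rt_peak_width", "intensity",
                    "resolution", "protein", "is_contaminant", "is_reverse")

#' Read a detected-feature table
#'
#' Parses a tab-delimited per-sample feature table in a MaxQuant-like
#' dialect into the canonical `DetectedFeature` layout used throughout the
#' package: `sample_id`, `sequence` (NA for unidentified features),
#' `modifications`, `charge`, `mz_calibrated`, `mz_uncalibrated`, `rt`
#' (minutes), `rt_peak_width` (minutes), `intensity`, `resolution`,
#' `protein`, `is_contaminant`, `is_reverse`. Unknown extra columns are
#' ignored; rows whose required numeric fields (`charge`, `mz_calibrated`,
#' `rt`) fail to parse are dropped and counted in the `"n_dropped"`
#' attribute of the result.
#'
#' @param path tab-delimited file with one header row.
#' @param dialect one of `"allpeptides"`, `"evidence"`, `"generic"`.
#' @param sample_id fallback sample label when the table carries none.
#' @return data.table of detected features, attribute `n_dropped`.
#' @export
read_feature_table <- function(path, dialect = c("generic", "allpeptides",
                                                 "evidence"),
                               sample_id = NULL) {
  dialect <- match.arg(dialect)
  map <- dialect_maps[[dialect]]
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = c("", "NA", "NaN"))
  need <- map[.required_cols]
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("feature table '", path, "' (dialect ", dialect,
         ") misses required column(s): ", paste(miss, collapse = ", "))
  out <- data.table(row = seq_len(nrow(raw)))
  for (cn in c(.required_cols, .optional_cols)) {
    src <- map[[cn]]
    out[[cn]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]]
                 else NA_character_
  }
  out$row <- NULL
  num_cols <- c("charge", "mz_calibrated", "mz_uncalibrated", "rt",
                "rt_peak_width", "intensity", "resolution")
  for (cn in num_cols)
    out[[cn]] <- suppressWarnings(as.numeric(out[[cn]]))
  ok <- stats::complete.cases(out[, .required_cols, with = FALSE])
  n_dropped <- sum(!ok)
  out <- out[ok]
  out[, charge := as.integer(charge)]
  # MaxQuant marks contaminants/reverse hits with "+"
  out[, is_contaminant := !is.na(is_contaminant) &
        is_contaminant %in% c("+", "TRUE", "true", "1")]
  out[, is_reverse := !is.na(is_reverse) &
        is_reverse %in% c("+", "TRUE", "true", "1")]
  if (!is.null(sample_id)) {
    fallback_id <- sample_id
    out[is.na(sample_id), sample_id := fallback_id]
  }
  out[is.na(modifications) & !is.na(sequence), modifications := "Unmodified"]
  setattr(out, "n_dropped", n_dropped)
  out[]
}

#' Write peptide- and protein-level quantification tables
#'
#' Both tables are written as tab-delimited UTF-8 text with `.` decimals
#' and one header row; numeric values keep 15 significant digits so a
#' read-back reproduces them to well beyond 6 significant digits.
#'
#' @param peptide_table,protein_table data.frames (wide: one quantification
#'   column per sample plus annotation columns).
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix, default `"requant"`.
#' @return named character vector of the two file paths.
#' @export
write_quant_tables <- function(peptide_table, protein_table, out_dir,
                               prefix = "requant") {
  stopifnot(!is.null(peptide_table), !is.null(protein_table))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(
    peptide = file.path(out_dir, paste0(prefix, "_peptides.tsv")),
    protein = file.path(out_dir, paste0(prefix, "_proteins.tsv")))
  fwrite(as.data.table(peptide_table), paths[["peptide"]], sep = "\t",
         quote = FALSE, na = "NA")
  fwrite(as.data.table(protein_table), paths[["protein"]], sep = "\t",
         quote = FALSE, na = "NA")
  paths
}

#' Read back a table written by [write_quant_tables()]
#' @param path tab-delimited file.
#' @return data.table.
#' @export
read_quant_table <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}
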