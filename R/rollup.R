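## Peptide filtering, normalization and protein rollup -----------------------

#' Filter a peptide quantification matrix for protein rollup
#'
#' Removes contaminant and reverse rows, then proteins identified by fewer
#' than `min_peptides` distinct peptides. Per-sample protein cells backed
#' by fewer than `min_peptides` quantified peptides are reported missing
#' during rollup (see [aggregate_protein()]).
#'
#' @param peptide_table data.table: one row per peptide feature with
#'   `protein`, `is_contaminant`, `is_reverse` and one numeric column per
#'   sample.
#' @param sample_cols names of the per-sample quantification columns.
#' @param min_peptides default 2.
#' @return filtered peptide table.
#' @export
filter_tables <- function(peptide_table, sample_cols, min_peptides = 2L) {
  pt <- as.data.table(peptide_table)
  if ("is_contaminant" %in% names(pt))
    pt <- pt[is.na(is_contaminant) | !is_contaminant]
  if ("is_reverse" %in% names(pt))
    pt <- pt[is.na(is_reverse) | !is_reverse]
  pt <- pt[!is.na(protein)]
  pt[, n_pep := .N, by = protein]
  pt <- pt[n_pep >= min_peptides]
  pt[, n_pep := NULL]
  pt[]
}

#' Median-normalize a quantification matrix across samples
#'
#' Per-sample scale factors equalize the median (over `reference_rows`,
#' default all rows) across samples; the anchor is the median of the
#' per-sample medians, so a typical sample keeps a factor near 1.
#' Intensities are multiplied by their sample's factor.
#'
#' @param table data.table with numeric sample columns.
#' @param sample_cols names of the per-sample columns.
#' @param reference_rows optional logical/integer row subset used to
#'   compute the factors (e.g. constant background proteins in spike-in
#'   designs).
#' @return list: `table` (normalized copy), `factors` (named numeric).
#' @export
normalize_median <- function(table, sample_cols, reference_rows = NULL) {
  tab <- copy(as.data.table(table))
  ref <- if (is.null(reference_rows)) tab else tab[reference_rows]
  meds <- vapply(sample_cols, function(cn)
    median(ref[[cn]], na.rm = TRUE), numeric(1))
  if (any(!is.finite(meds)))
    stop("sample(s) without reference values: ",
         paste(sample_cols[!is.finite(meds)], collapse = ", "))
  target <- median(meds)
  factors <- target / meds
  for (cn in sample_cols)
    tab[[cn]] <- tab[[cn]] * factors[[cn]]
  list(table = tab, factors = factors)
}

#' Aggregate peptide quantifications to protein level
#'
#' Methods: `top3` = mean of the (up to) 3 most intense peptide values per
#' protein and sample; `sum` = total over quantified peptides; `maxlfq` =
#' per-protein least-squares reconstruction of sample abundances from
#' median pairwise peptide log-ratios (minimum 2 shared peptides per
#' sample pair), anchored so the mean log abundance equals the mean log of
#' the per-sample peptide sums. Missing peptide cells never contribute;
#' protein cells backed by fewer than `min_peptides` quantified peptides
#' are set missing.
#'
#' @param peptide_table filtered peptide table (see [filter_tables()]).
#' @param sample_cols names of the per-sample quantification columns.
#' @param method `"top3"`, `"sum"` or `"maxlfq"`.
#' @param min_peptides minimum contributing quantifications per cell
#'   (default 2).
#' @return data.table: `protein`, one intensity column per sample, and
#'   `n_<sample>` contributing-peptide counts.
#' @export
aggregate_protein <- function(peptide_table, sample_cols,
                              method = c("top3", "sum", "maxlfq"),
                              min_peptides = 2L) {
  if (!is.character(method) ||
      !all(method %in% c("top3", "sum", "maxlfq")))
    stop("unknown rollup method: ", paste(method, collapse = ","))
  method <- match.arg(method)
  pt <- as.data.table(peptide_table)
  prots <- unique(pt$protein)
  rows <- lapply(prots, function(pr) {
    m <- as.matrix(pt[protein == pr, ..sample_cols])
    counts <- colSums(!is.na(m) & m > 0)
    vals <- switch(method,
      top3 = apply(m, 2, function(x) {
        x <- sort(x[!is.na(x) & x > 0], decreasing = TRUE)
        if (!length(x)) NA_real_ else mean(head(x, 3L))
      }),
      sum = apply(m, 2, function(x) {
        x <- x[!is.na(x) & x > 0]
        if (!length(x)) NA_real_ else sum(x)
      }),
      maxlfq = maxlfq_protein(m))
    vals[counts < min_peptides] <- NA_real_
    c(list(protein = pr), as.list(vals),
      setNames(as.list(as.integer(counts)), paste0("n_", sample_cols)))
  })
  out <- rbindlist(rows)
  setnames(out, c("protein", sample_cols, paste0("n_", sample_cols)))
  out[]
}

# MaxLFQ-style abundance reconstruction for one protein: peptides x samples
# intensity matrix -> per-sample abundances on the natural scale.
maxlfq_protein <- function(m, min_ratio_peptides = 2L) {
  S <- ncol(m)
  lm_ <- log(ifelse(!is.na(m) & m > 0, m, NA))
  r <- matrix(NA_real_, S, S)
  for (s in seq_len(S - 1L)) for (t in (s + 1L):S) {
    d <- lm_[, s] - lm_[, t]
    d <- d[is.finite(d)]
    if (length(d) >= min_ratio_peptides) {
      r[s, t] <- median(d)
      r[t, s] <- -r[s, t]
    }
  }
  has <- which(colSums(is.finite(r)) > 0 | colSums(is.finite(lm_)) > 0)
  # least squares: minimize sum over known pairs of (a_s - a_t - r_st)^2
  A <- matrix(0, S, S); b <- numeric(S)
  for (s in seq_len(S)) for (t in seq_len(S)) {
    if (s == t || !is.finite(r[s, t])) next
    A[s, s] <- A[s, s] + 1
    A[s, t] <- A[s, t] - 1
    b[s] <- b[s] + r[s, t]
  }
  conn <- which(rowSums(A != 0) > 0)
  a <- rep(NA_real_, S)
  if (length(conn) >= 2L) {
    Ac <- A[conn, conn, drop = FALSE] + diag(1e-10, length(conn))
    sol <- tryCatch(solve(Ac, b[conn]), error = function(e) NULL)
    if (!is.null(sol)) a[conn] <- sol
  }
  quantified <- colSums(is.finite(lm_)) > 0
  if (all(is.na(a))) {
    # no usable pair: fall back to per-sample log sums
    a[quantified] <- log(colSums(m[, quantified, drop = FALSE],
                                 na.rm = TRUE))
    return(ifelse(quantified, exp(a), NA_real_))
  }
  # anchor: mean log abundance = mean log of per-sample peptide sums
  sums <- log(colSums(ifelse(is.na(m), 0, m))[!is.na(a) & quantified])
  sums <- sums[is.finite(sums)]
  if (length(sums))
    a <- a - mean(a[!is.na(a) & quantified], na.rm = TRUE) + mean(sums)
  a[!quantified] <- NA_real_
  exp(a)
}
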