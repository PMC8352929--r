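## small shared helpers ------------------------------------------------------

# identity key of a sequenced feature: sequence | normalized PTM string |
# charge. Modifications are normalized by sorting their comma-separated
# terms so "2 Oxidation (M),Acetyl" == "Acetyl,2 Oxidation (M)".
feature_key <- function(sequence, modifications, charge) {
  mods <- normalize_modifications(modifications)
  paste(sequence, mods, charge, sep = "|")
}

normalize_modifications <- function(modifications) {
  mods <- ifelse(is.na(modifications) | modifications == "",
                 "Unmodified", modifications)
  multi <- grepl(",", mods, fixed = TRUE)
  if (any(multi)) {
    mods[multi] <- vapply(strsplit(mods[multi], ",", fixed = TRUE),
                          function(p) paste(sort(trimws(p)), collapse = ","),
                          character(1))
  }
  mods
}

# robust z-scores: (x - median) / (1.4826 * MAD); returns 0s when MAD is 0
robust_z <- function(x) {
  med <- median(x, na.rm = TRUE)
  s <- mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - med) / s
}

# type-7 interquartile range of a numeric vector
iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  q[2] - q[1]
}

# deterministic derived seed kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
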