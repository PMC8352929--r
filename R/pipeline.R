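## End-to-end pipeline orchestration -----------------------------------------

#' Build a pipeline configuration
#'
#' All defaults are the workflow's standard constants: data-driven
#' alignment windows (floors 0.2 min / 0.001 Th), feature merge below
#' 0.002 Th, decoys offset by 5 alignment windows, +1-isotope companions
#' at 1.002 Th per charge, KDE resolution 50, transfer limit of 3 m/z
#' windows, signal ions above background + 2 sd, significance alpha 0.05,
#' 500 masked features per sample for the FDR estimate, imputation
#' enabled, Top3 rollup with at least 2 peptides per protein.
#'
#' @param ... overrides of the nested defaults, e.g.
#'   `windows = list(fixed_rt = 0.5)`, `rollup = list(method = "sum")`.
#' @return nested list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    paths = list(ion_maps = NULL, feature_tables = NULL, out_dir = NULL,
                 dialect = "generic"),
    windows = list(fixed_rt = NULL, fixed_mz = NULL, min_rt = 0.2,
                   min_mz = 0.001),
    kde = list(resolution = 50L),
    merge = list(delta_mass = 0.002),
    decoy = list(offset_multiplier = 5),
    isotope = list(enabled = TRUE, delta = 1.002),
    transfer = list(max_mz_multiple = 3),
    signal = list(sd_multiple = 2),
    significance = list(alpha = 0.05),
    fdr = list(n_mask = 500L, tolerance = 0.2),
    impute = list(enabled = TRUE),
    noise = list(sd_estimator = "mad"),
    mz_model = list(ntree = 100L, mtry = 4L, min_node = 100L,
                    min_rows = 200L),
    rollup = list(method = "top3", min_peptides = 2L),
    assembly = list(aggregate_unknown = FALSE),
    filters = list(z_cut = 3),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], ov[[nm]])
    else cfg[[nm]] <- ov[[nm]]
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration file (YAML)
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## stage implementations; each takes and returns the state ------------------

stage_load <- function(state) {
  cfg <- state$config
  if (is.null(state$features)) {
    ft <- lapply(seq_along(cfg$paths$feature_tables), function(i) {
      p <- cfg$paths$feature_tables[[i]]
      sid <- names(cfg$paths$feature_tables)[i] %||% NULL
      read_feature_table(p, dialect = cfg$paths$dialect, sample_id = sid)
    })
    state$features <- rbindlist(ft)
  }
  if (is.null(state$ion_maps)) {
    ims <- lapply(seq_along(cfg$paths$ion_maps), function(i)
      read_ms1_map(cfg$paths$ion_maps[[i]],
                   names(cfg$paths$ion_maps)[i] %||% NULL))
    names(ims) <- vapply(ims, `[[`, character(1), "sample_id")
    state$ion_maps <- ims
  }
  state$samples <- sort(unique(state$features$sample_id))
  stopifnot(all(state$samples %in% names(state$ion_maps)))
  state$counts$n_features_in <- nrow(state$features)
  state
}

stage_windows <- function(state) {
  cfg <- state$config
  w <- alignment_windows(user_fixed_rt = cfg$windows$fixed_rt,
                         user_fixed_mz = cfg$windows$fixed_mz,
                         user_min_rt = cfg$windows$min_rt,
                         user_min_mz = cfg$windows$min_mz)
  state$windows <- estimate_alignment_windows(state$features, w)
  state
}

stage_assembly <- function(state) {
  cfg <- state$config
  cons <- aggregate_features(state$features, state$windows,
                             aggregate_unknown =
                               cfg$assembly$aggregate_unknown)
  cons <- merge_overlapping(cons, delta_mass = cfg$merge$delta_mass)
  state$consensus <- cons
  state$counts$n_consensus <- nrow(cons)
  state
}

stage_companions <- function(state) {
  cfg <- state$config
  dec <- generate_decoys(state$consensus, state$windows,
                         offset_multiplier = cfg$decoy$offset_multiplier)
  iso <- if (isTRUE(cfg$isotope$enabled))
    generate_isotope_features(state$consensus, delta = cfg$isotope$delta)
  else state$consensus[0L]
  state$decoys <- dec
  state$isotopes <- iso
  state$counts$n_decoys <- nrow(dec)
  state$counts$n_isotopes <- nrow(iso)
  state
}

stage_models <- function(state) {
  cfg <- state$config
  state$models <- fit_correction_models(
    state$features, state$consensus, seed = derive_seed(cfg$seed, 5L),
    ntree = cfg$mz_model$ntree, mtry = cfg$mz_model$mtry,
    min_node = cfg$mz_model$min_node, min_rows = cfg$mz_model$min_rows)
  state
}

stage_identities <- function(state) {
  state$identities <- propagate_identities(state$consensus, state$samples)
  state
}

stage_noise <- function(state) {
  cfg <- state$config
  noise_models <- list(); decoy_events <- list()
  for (s in state$samples) {
    expd <- predict_feature_windows(state$decoys, state$models[[s]],
                                    state$windows)
    m <- vapply(seq_len(nrow(expd)), function(i)
      .extract_vec(state$ion_maps[[s]],
                   expd$rt_center[i] - expd$rt_half[i],
                   expd$rt_center[i] + expd$rt_half[i],
                   expd$mz_center[i] - expd$mz_half[i],
                   expd$mz_center[i] + expd$mz_half[i]),
      numeric(3))
    ev <- data.table(id = expd$id, sample_id = s,
                     rt_center = expd$rt_center,
                     ion_count = as.integer(m[1, ]),
                     total_intensity = m[2, ])
    decoy_events[[s]] <- ev
    noise_models[[s]] <- fit_noise_model(
      ev[, .(rt_center, ion_count, total_intensity)],
      sd_estimator = cfg$noise$sd_estimator)
  }
  state$decoy_events <- rbindlist(decoy_events)
  state$noise_models <- noise_models
  state
}

stage_candidates <- function(state) {
  cfg <- state$config
  feats <- rbind(state$consensus, state$isotopes, fill = TRUE)
  contrib <- attr(state$consensus, "contributions")
  # per (feature, sample) individual correction: the sample's own observed
  # feature position (median contributor RT / uncalibrated m/z); model
  # predictions are the fallback for samples without an observed feature
  obs <- contrib[, .(rt_obs = median(rt),
                     mz_obs = median(mz_uncal, na.rm = TRUE)),
                 by = .(consensus_id, sample_id)]
  iso_delta <- cfg$isotope$delta
  expected <- list(); cands <- list()
  for (s in state$samples) {
    expd <- predict_feature_windows(feats, state$models[[s]],
                                    state$windows)
    expd[, sample_id := s]
    setnames(expd, c("rt_center", "mz_center"),
             c("rt_center_model", "mz_center_model"))
    expd[, `:=`(rt_center = rt_center_model, mz_center = mz_center_model,
                known_center = FALSE)]
    ob <- obs[sample_id == s]
    expd[ob, on = .(id = consensus_id),
         `:=`(rt_center = fifelse(is.finite(i.rt_obs), i.rt_obs,
                                  rt_center),
              mz_center = fifelse(is.finite(i.mz_obs), i.mz_obs,
                                  mz_center),
              known_center = TRUE)]
    # isotope features inherit the parent's observed center + spacing
    iso_idx <- which(feats$kind == "isotope_plus1")
    if (length(iso_idx)) {
      iso_map <- data.table(id = feats$id[iso_idx],
                            consensus_id = feats$parent_id[iso_idx],
                            charge = feats$charge[iso_idx])
      iso_obs <- ob[iso_map, on = "consensus_id", nomatch = NULL]
      if (nrow(iso_obs)) {
        expd[iso_obs, on = "id",
             `:=`(rt_center = fifelse(is.finite(i.rt_obs), i.rt_obs,
                                      rt_center),
                  mz_center = fifelse(is.finite(i.mz_obs),
                                      i.mz_obs + iso_delta / i.charge,
                                      mz_center),
                  known_center = TRUE)]
      }
    }
    min_ions <- state$noise_models[[s]]$median_decoy_count
    cl <- vector("list", nrow(expd))
    for (i in seq_len(nrow(expd))) {
      km <- compute_kde_map(state$ion_maps[[s]],
                            c(expd$rt_center[i], expd$mz_center[i]),
                            state$windows, expd$rt_half[i],
                            resolution = cfg$kde$resolution)
      pk <- detect_peaks(km, min_ions = min_ions)
      if (nrow(pk)) {
        pk[, `:=`(id = expd$id[i], sample_id = s)]
        cl[[i]] <- pk
      }
    }
    cands[[s]] <- rbindlist(cl)
    expected[[s]] <- expd
  }
  state$expected <- rbindlist(expected)
  state$candidates <- rbindlist(cands)
  state$counts$n_candidates <- nrow(state$candidates)
  state
}

stage_selection <- function(state) {
  cfg <- state$config
  feats <- rbind(state$consensus, state$isotopes, fill = TRUE)
  min_ions <- vapply(state$noise_models, `[[`, numeric(1),
                     "median_decoy_count")
  known_tab <- state$identities[status %in%
                                  c("sequenced_here", "feature_propagated")]
  contrib <- attr(state$consensus, "contributions")
  known_by_cons <- c(
    split(known_tab$sample_id, known_tab$consensus_id),
    split(contrib$sample_id, contrib$consensus_id))
  sels <- vector("list", nrow(feats))
  cand_split <- split(state$candidates,
                      by = "id", keep.by = FALSE, sorted = FALSE)
  exp_split <- split(state$expected, by = "id", sorted = FALSE)
  for (i in seq_len(nrow(feats))) {
    fid <- feats$id[i]
    parent <- if (feats$kind[i] == "target") fid else feats$parent_id[i]
    known <- unique(unlist(known_by_cons[names(known_by_cons) == parent],
                           use.names = FALSE))
    cf <- cand_split[[fid]]
    if (is.null(cf))
      cf <- data.table(sample_id = character(), u = numeric(),
                       v = numeric(), count = integer(),
                       in_window = logical(), dist = numeric())
    e1 <- exp_split[[fid]]
    offs <- data.table(
      sample_id = e1$sample_id,
      du = (e1$rt_center - e1$rt_center_model) / state$windows$rt_window,
      dv = (e1$mz_center - e1$mz_center_model) / state$windows$mz_window)
    sel <- select_window(cf, known_samples = known, min_ions = min_ions,
                         rt_half_std = e1$rt_half[1] /
                           state$windows$rt_window,
                         max_mz_multiple = cfg$transfer$max_mz_multiple,
                         frame_offsets = offs)
    sel[, `:=`(consensus_id = fid, kind = feats$kind[i],
               parent_id = feats$parent_id[i], charge = feats$charge[i])]
    sels[[i]] <- sel
  }
  sel <- rbindlist(sels)
  setnames(sel, c("u", "v"), c("sel_u", "sel_v"))
  sel <- state$expected[, .(consensus_id = id, sample_id, rt_center,
                            mz_center, rt_half, mz_half)][
    sel, on = .(consensus_id, sample_id)]
  sel[, `:=`(peak_rt = rt_center + sel_u * state$windows$rt_window,
             peak_mz = mz_center + sel_v * state$windows$mz_window)]
  state$selections <- sel
  state
}

stage_extraction <- function(state) {
  cfg <- state$config
  sel <- state$selections
  # per-sample vectorized signal thresholds (noise mean at the window RT)
  thr <- numeric(nrow(sel))
  for (s in state$samples) {
    idx <- which(sel$sample_id == s)
    nm <- state$noise_models[[s]]
    thr[idx] <- nm$mean_intensity(sel$peak_rt[idx]) +
      cfg$signal$sd_multiple * nm$sd_intensity
  }
  m <- vapply(seq_len(nrow(sel)), function(i)
    .extract_vec(state$ion_maps[[sel$sample_id[i]]],
                 sel$peak_rt[i] - sel$rt_half[i],
                 sel$peak_rt[i] + sel$rt_half[i],
                 sel$peak_mz[i] - sel$mz_half[i],
                 sel$peak_mz[i] + sel$mz_half[i], thr = thr[i]),
    numeric(3))
  ev <- data.table(
    ion_count = as.integer(m[1, ]), total_intensity = m[2, ],
    signal_intensity = m[3, ], background_intensity = m[2, ] - m[3, ],
    missing = m[1, ] == 0,
    consensus_id = sel$consensus_id, sample_id = sel$sample_id,
    kind = sel$kind, origin = sel$origin,
    rt_center = sel$peak_rt, mz_center = sel$peak_mz)
  ev[, p_value := NA_real_]
  for (s in state$samples) {
    idx <- which(ev$sample_id == s)
    ev$p_value[idx] <- score_significance(ev$ion_count[idx],
                                          state$noise_models[[s]])
  }
  ev[, signal_to_background :=
       ifelse(background_intensity > 0,
              signal_intensity / background_intensity, Inf)]
  ev[, `:=`(imputed = FALSE, removed_reason = NA_character_)]
  state$selections[, total_intensity := ev$total_intensity]
  state$events <- ev
  state$counts$n_events <- nrow(ev)
  state
}

stage_filters <- function(state) {
  cfg <- state$config
  selx <- state$expected[, .(consensus_id = id, sample_id,
                             rt_center_model, mz_center_model)][
    state$selections, on = .(consensus_id, sample_id)]
  selx[, `:=`(dev_rt = peak_rt - rt_center_model,
              dev_mz = peak_mz - mz_center_model)]
  flt <- filter_outlier_peaks(
    selx[, .(consensus_id, sample_id, kind, parent_id, charge,
             peak_rt, peak_mz, dev_rt, dev_mz, origin, rt_half)],
    state$windows, z_cut = cfg$filters$z_cut,
    isotope_delta = cfg$isotope$delta)
  ev <- state$events
  ev[consensus_id %in% flt$removed_features,
     removed_reason := "dispersed_feature"]
  ev[flt$excluded_cells, on = .(consensus_id, sample_id),
     removed_reason := i.reason]
  state$filter_log <- flt$log
  state$counts$n_removed_cells <- sum(!is.na(ev$removed_reason))
  state
}

stage_fdr <- function(state) {
  cfg <- state$config
  state$fdr <- estimate_fdr(state, n_mask = cfg$fdr$n_mask,
                            seed = derive_seed(cfg$seed, 11L),
                            tolerance = cfg$fdr$tolerance)
  state
}

stage_impute <- function(state) {
  cfg <- state$config
  state$events_raw <- copy(state$events)
  state$events <- impute_missing(state$events, state$noise_models,
                                 enabled = cfg$impute$enabled,
                                 seed = derive_seed(cfg$seed, 12L))
  state$counts$n_imputed <- sum(state$events$imputed)
  state
}

# wide peptide table from the event table (targets with a sequence)
build_peptide_table <- function(state, events) {
  cons <- state$consensus[!is.na(sequence)]
  ev <- events[kind == "target" & consensus_id %in% cons$id &
                 is.na(removed_reason)]
  ident <- dcast(state$identities, consensus_id ~ sample_id,
                 value.var = "status")
  quant <- dcast(ev, consensus_id ~ sample_id,
                 value.var = c("total_intensity", "p_value", "imputed",
                               "signal_to_background"))
  out <- cons[, .(consensus_id = id, sequence, modifications, charge,
                  mz_ref, rt_ref, protein, is_contaminant, is_reverse)]
  out <- quant[out, on = "consensus_id"]
  out <- ident[out, on = "consensus_id"]
  # missing / removed cells -> NA intensity
  for (s in state$samples) {
    cn <- paste0("total_intensity_", s)
    mis <- ev[sample_id == s & missing & !imputed, consensus_id]
    if (length(mis)) out[consensus_id %in% mis, (cn) := NA_real_]
    gone <- setdiff(out$consensus_id, ev[sample_id == s, consensus_id])
    if (length(gone)) out[consensus_id %in% gone, (cn) := NA_real_]
  }
  out[]
}

stage_tables <- function(state) {
  cfg <- state$config
  sample_cols <- paste0("total_intensity_", state$samples)
  pep <- build_peptide_table(state, state$events)
  pep_raw <- build_peptide_table(state, state$events_raw)
  roll <- function(pt) {
    ft <- filter_tables(pt, sample_cols,
                        min_peptides = cfg$rollup$min_peptides)
    if (!nrow(ft)) return(list(protein = data.table(), factors = NULL,
                               peptides = ft))
    nrm <- normalize_median(ft, sample_cols)
    prot <- aggregate_protein(nrm$table, sample_cols,
                              method = cfg$rollup$method,
                              min_peptides = cfg$rollup$min_peptides)
    list(protein = prot, factors = nrm$factors, peptides = nrm$table)
  }
  r1 <- roll(pep); r2 <- roll(pep_raw)
  state$peptide_table <- pep
  state$peptide_table_raw <- pep_raw
  state$protein_table <- r1$protein
  state$protein_table_raw <- r2$protein
  state$norm_factors <- r1$factors
  state$counts$n_peptides <- nrow(pep)
  state$counts$n_proteins <- nrow(r1$protein)
  state
}

stage_write <- function(state) {
  cfg <- state$config
  out_dir <- cfg$paths$out_dir
  if (is.null(out_dir)) return(state)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_quant_tables(state$peptide_table, state$protein_table,
                              out_dir, prefix = "requant")
  write_quant_tables(state$peptide_table_raw, state$protein_table_raw,
                     out_dir, prefix = "requant_nonimputed")
  cons_out <- state$consensus[, .(id, kind, sequence, charge, mz_ref,
                                  rt_ref, rt_peak_width, n_samples)]
  fwrite(cons_out, file.path(out_dir, "consensus_features.tsv"),
         sep = "\t", quote = FALSE, na = "NA")
  fwrite(state$fdr$per_sample, file.path(out_dir, "fdr_report.tsv"),
         sep = "\t", quote = FALSE, na = "NA")
  fwrite(state$events, file.path(out_dir, "quant_events.tsv"),
         sep = "\t", quote = FALSE, na = "NA")
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  tf <- tempfile(); writeLines(cfg_yaml, tf)
  manifest <- list(
    package_version = as.character(packageVersion("requant")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tf)),
    windows = list(rt = state$windows$rt_window,
                   mz = state$windows$mz_window),
    counts = state$counts,
    fdr = state$fdr$fdr)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$paths <- paths
  state
}

pipeline_stages <- list(
  load = stage_load, windows = stage_windows, assembly = stage_assembly,
  companions = stage_companions, models = stage_models,
  identities = stage_identities, noise = stage_noise,
  candidates = stage_candidates, selection = stage_selection,
  extraction = stage_extraction, filters = stage_filters,
  fdr = stage_fdr, impute = stage_impute, tables = stage_tables,
  write = stage_write)

#' Run the full re-quantification pipeline
#'
#' Executes the stages in order: alignment windows, consensus assembly,
#' decoy/isotope companions, correction models, identity propagation,
#' decoy noise models, KDE candidate peaks, window selection, DICE
#' extraction and significance, outlier filters, masking FDR, imputation,
#' and rollup. Identical config + seed gives identical outputs. The
#' returned state can be resumed from any stage.
#'
#' @param config a [pipeline_config()].
#' @param data optional in-memory input (list with `ion_maps`,
#'   `features` or `feature_tables`), bypassing file paths.
#' @param stop_after optional stage name; the partial state is returned.
#' @param resume a previously returned state to continue from.
#' @param verbose log stage progress to stderr.
#' @return the pipeline state: list with `consensus`, `selections`,
#'   `events`, `peptide_table`, `protein_table` (+ `_raw` non-imputed
#'   variants), `fdr`, `noise_models`, `windows`, `counts`, ...
#' @export
run_pipeline <- function(config, data = NULL, stop_after = NULL,
                         resume = NULL, verbose = FALSE) {
  stage_names <- names(pipeline_stages)
  if (!is.null(resume)) {
    state <- resume
    start <- match(state$stage, stage_names) + 1L
  } else {
    state <- list(config = config, counts = list(), stage = NA_character_)
    if (!is.null(data)) {
      state$ion_maps <- data$ion_maps
      state$features <- if (!is.null(data$features)) data$features
        else rbindlist(data$feature_tables)
    }
    start <- 1L
  }
  if (is.na(start)) stop("unknown resume stage: ", state$stage)
  for (k in seq(start, length(stage_names))) {
    nm <- stage_names[k]
    if (verbose) message("[requant] stage: ", nm)
    state <- tryCatch(
      pipeline_stages[[nm]](state),
      error = function(e) stop("pipeline stage '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    state$stage <- nm
    if (!is.null(stop_after) && nm == stop_after) break
  }
  class(state) <- "RequantRun"
  state
}

#' @export
print.RequantRun <- function(x, ...) {
  cat("<RequantRun> stage:", x$stage, "\n")
  if (!is.null(x$counts) && length(x$counts))
    cat(paste0("  ", names(x$counts), ": ",
               unlist(x$counts), collapse = "\n"), "\n")
  invisible(x)
}
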