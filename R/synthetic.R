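## Synthetic DDA experiment generator with ground truth ----------------------

#' Configuration for the synthetic DDA experiment generator
#'
#' Defaults describe a small label-free cohort as the pipeline expects it:
#' 6 samples in two groups of 3, 500 peptide species (5 peptides per
#' protein), a 30-min gradient, smooth per-sample RT drift (linear +
#' sinusoid, amplitude 0.5 min), smooth ppm-scale m/z error (constant +
#' slow RT-dependent term, amplitude 3 ppm), Gaussian elution peaks
#' (sd 0.08 min) sampled on a regular 0.01-min MS1 scan grid, centroid m/z
#' jitter (sd 5e-4 Th), 30% MS2-identification dropout, optional +1
#' isotope envelopes, and uniform background ions.
#'
#' @param n_samples,n_species cohort size and number of true peptide
#'   species.
#' @param groups integer group label per sample (default two halves).
#' @param peptides_per_protein species per synthetic protein (default 5).
#' @param spike_fraction fraction of proteins spiked between groups
#'   (default 0 = constant design).
#' @param spike_ratios group-2/group-1 abundance ratios cycled over spiked
#'   proteins.
#' @param contaminant_fraction fraction of proteins flagged as
#'   contaminants.
#' @param rt_range,mz_range gradient and precursor ranges (min / Th).
#' @param rt_drift_amplitude,mz_error_ppm drift and mass-error amplitudes.
#' @param id_dropout_rate probability a species lacks MS2 identification
#'   in a sample.
#' @param unknown_feature_rate fraction of unidentified cells that still
#'   yield a sequence-less detected feature.
#' @param n_extra_features unsequenced molecular species (real ion
#'   clusters reported as sequence-less feature rows, as in MaxQuant's
#'   allPeptides tables, which are dominated by unidentified features);
#'   they provide realistic training mass for the m/z-correction models.
#' @param extra_detect_rate probability an extra species is reported in a
#'   sample's feature table.
#' @param extra_intensity_meanlog base abundance of extra species (log).
#' @param noise_ion_density background ions per minute per Th.
#' @param noise_intensity_meanlog,noise_intensity_sdlog background ion
#'   intensity (log-normal).
#' @param elution_sigma_rt Gaussian elution sd (minutes).
#' @param mz_sigma centroid m/z jitter sd (Th).
#' @param intensity_meanlog,intensity_sdlog species base abundance
#'   (log-normal).
#' @param sample_intensity_sdlog between-sample measurement noise (log
#'   scale).
#' @param scan_noise_sdlog per-scan intensity jitter (log scale).
#' @param isotope_enabled,isotope_ratio +1-isotope envelope and its
#'   relative intensity.
#' @param scan_interval MS1 cycle time (minutes).
#' @param cal_residual_ppm residual error of the calibrated m/z.
#' @param rt_obs_sigma RT noise of detected-feature apexes (minutes).
#' @param interference_rate fraction of species with an injected
#'   interfering peak (in every sample).
#' @param interference_rt_offset,interference_mz_offset absolute offset
#'   ranges of the interference (min / Th; sign randomized).
#' @param interference_intensity_ratio interference vs species abundance.
#' @param seed RNG seed fixing the full output bit-exactly.
#' @return object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_samples = 6L, n_species = 500L,
                             groups = NULL, peptides_per_protein = 5L,
                             spike_fraction = 0, spike_ratios = c(1.5, 2, 3),
                             contaminant_fraction = 0,
                             rt_range = c(10, 40), mz_range = c(400, 424),
                             rt_drift_amplitude = 0.5, mz_error_ppm = 3,
                             id_dropout_rate = 0.3,
                             unknown_feature_rate = 0.3,
                             n_extra_features = 2000L,
                             extra_detect_rate = 0.8,
                             extra_intensity_meanlog = log(2e5),
                             noise_ion_density = 2000,
                             noise_intensity_meanlog = log(5e3),
                             noise_intensity_sdlog = 0.5,
                             elution_sigma_rt = 0.08, mz_sigma = 5e-4,
                             intensity_meanlog = log(1e6),
                             intensity_sdlog = 1,
                             sample_intensity_sdlog = 0.05,
                             scan_noise_sdlog = 0.1,
                             isotope_enabled = TRUE, isotope_ratio = 0.5,
                             scan_interval = 0.01,
                             cal_residual_ppm = 0.2, rt_obs_sigma = 0.01,
                             interference_rate = 0,
                             interference_rt_offset = c(0.1, 0.3),
                             interference_mz_offset = c(0.001, 0.0025),
                             interference_intensity_ratio = 1,
                             seed = 1L) {
  if (n_samples < 1L || n_species < 1L)
    stop("n_samples and n_species must be >= 1")
  if (is.null(groups))
    groups <- sort(rep(1:2, length.out = n_samples))
  stopifnot(length(groups) == n_samples)
  rates <- c(id_dropout_rate, unknown_feature_rate, spike_fraction,
             contaminant_fraction, interference_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            rt_drift_amplitude >= 0, mz_error_ppm >= 0,
            noise_ion_density >= 0, elution_sigma_rt > 0)
  cfg <- as.list(environment())
  class(cfg) <- "SyntheticConfig"
  cfg
}

random_peptide <- function(n, len_range = c(8L, 15L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1L),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# smooth per-sample functions: drift(rt) in minutes, ppm(rt) in ppm
make_drift_fn <- function(amp, rt_range) {
  w1 <- runif(1, -1, 1); w2 <- runif(1, -1, 1)
  ph <- runif(1, 0, 2 * pi)
  period <- diff(rt_range) / 1.5
  mid <- mean(rt_range); half <- diff(rt_range) / 2
  nrm <- abs(w1) + abs(w2)
  if (nrm == 0) nrm <- 1
  force(amp)
  function(rt) amp * (w1 * (rt - mid) / half +
                        w2 * sin(2 * pi * rt / period + ph)) / nrm
}

#' Generate a complete synthetic DDA experiment
#'
#' Produces per-sample centroided MS1 ion maps, MaxQuant-like detected
#' feature tables, and a ground-truth record. Each species contributes a
#' cluster of ions Gaussian in RT around its drifted true RT, at m/z
#' perturbed by the sample's smooth ppm error plus centroid jitter, with
#' intensities following the elution profile scaled by the sample's true
#' abundance; a +1-isotope cluster at `+1.002/charge` Th when enabled;
#' uniform background ions at the configured density. A detected-feature
#' row exists for a species in a sample iff the identification mask is
#' true; a fraction of unidentified cells still yield a sequence-less
#' feature row. Equal seeds give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @param out_dir when given, mzXML ion maps, feature tables (generic
#'   dialect) and the ground truth are also written there.
#' @return list: `ion_maps` (named list of [sample_ion_map()]),
#'   `feature_tables` (named list), `features` (combined table), `truth`
#'   (see below), `paths` (when `out_dir` given). `truth` carries
#'   `species` (static species table), `cells` (species x sample: drifted
#'   `true_rt`, observed-scale `true_mz`, `abundance`, `identified`,
#'   `unknown_feature`, `interference` and its offsets), `drift_fns`,
#'   `ppm_fns`, and exact per-sample ion bookkeeping (`ion_counts`).
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  ns <- config$n_samples; np <- config$n_species
  samples <- sprintf("S%02d", seq_len(ns))

  n_prot <- ceiling(np / config$peptides_per_protein)
  n_con <- floor(config$contaminant_fraction * n_prot)
  n_spike <- floor(config$spike_fraction * (n_prot - n_con))
  prot_ids <- c(sprintf("CON_P%04d", seq_len(n_con)),
                sprintf("P%04d", seq_len(n_prot - n_con)))
  spiked <- rep(FALSE, n_prot)
  if (n_spike > 0)  # spike only non-contaminant proteins
    spiked[n_con + sample.int(n_prot - n_con, n_spike)] <- TRUE
  prot_ratio <- rep(1, n_prot)
  prot_ratio[spiked] <- rep(config$spike_ratios,
                            length.out = sum(spiked))

  species <- data.table(
    species = sprintf("SP%05d", seq_len(np)),
    sequence = random_peptide(np),
    modifications = "Unmodified",
    charge = sample(2:3, np, replace = TRUE),
    protein_idx = rep(seq_len(n_prot),
                      each = config$peptides_per_protein)[seq_len(np)],
    true_mz = runif(np, config$mz_range[1], config$mz_range[2]),
    base_rt = runif(np, config$rt_range[1] + 1, config$rt_range[2] - 1),
    base_abundance = rlnorm(np, config$intensity_meanlog,
                            config$intensity_sdlog))
  species[, protein := prot_ids[protein_idx]]
  species[, ratio := prot_ratio[protein_idx]]
  species[, is_contaminant := protein_idx <= n_con]
  species[, resolution := 7e4 * sqrt(400 / true_mz)]
  n_intf <- floor(config$interference_rate * np)
  species[, interference := seq_len(np) %in% sample.int(np, n_intf)]
  species[, `:=`(intf_drt = 0, intf_dmz = 0)]
  if (n_intf > 0) {
    species[interference == TRUE, `:=`(
      intf_drt = sample(c(-1, 1), sum(interference), TRUE) *
        runif(sum(interference), config$interference_rt_offset[1],
              config$interference_rt_offset[2]),
      intf_dmz = sample(c(-1, 1), sum(interference), TRUE) *
        runif(sum(interference), config$interference_mz_offset[1],
              config$interference_mz_offset[2]))]
  }

  n_extra <- config$n_extra_features
  extras <- if (n_extra > 0) data.table(
    extra_id = sprintf("X%05d", seq_len(n_extra)),
    charge = sample(1:3, n_extra, replace = TRUE),
    true_mz = runif(n_extra, config$mz_range[1], config$mz_range[2]),
    base_rt = runif(n_extra, config$rt_range[1] + 1,
                    config$rt_range[2] - 1),
    base_abundance = rlnorm(n_extra, config$extra_intensity_meanlog,
                            config$intensity_sdlog))
  else NULL

  drift_fns <- lapply(seq_len(ns), function(i)
    make_drift_fn(config$rt_drift_amplitude, config$rt_range))
  ppm_fns <- lapply(seq_len(ns), function(i)
    make_drift_fn(config$mz_error_ppm, config$rt_range))
  names(drift_fns) <- names(ppm_fns) <- samples

  identified <- matrix(runif(np * ns) >= config$id_dropout_rate, np, ns)
  unknown_feat <- matrix(runif(np * ns) < config$unknown_feature_rate,
                         np, ns) & !identified
  abund <- outer(species$base_abundance, rep(1, ns)) *
    vapply(seq_len(ns), function(s)
      ifelse(rep(config$groups[s] == 2L, np), species$ratio, 1),
      numeric(np)) *
    matrix(rlnorm(np * ns, 0, config$sample_intensity_sdlog), np, ns)

  scan_rts <- seq(config$rt_range[1], config$rt_range[2],
                  by = config$scan_interval)
  sig <- config$elution_sigma_rt
  area <- diff(config$rt_range) * diff(config$mz_range)

  ion_maps <- list(); feature_rows <- list(); cell_rows <- list()
  counts_rows <- list()
  for (s in seq_len(ns)) {
    sid <- samples[s]
    apex <- species$base_rt + drift_fns[[s]](species$base_rt)
    ppm_apex <- ppm_fns[[s]](apex)
    obs_mz_center <- species$true_mz * (1 + ppm_apex * 1e-6)

    # species ion clusters on the shared scan grid
    lo_i <- findInterval(apex - 3 * sig, scan_rts) + 1L
    hi_i <- findInterval(apex + 3 * sig, scan_rts)
    nsc <- pmax(0L, hi_i - lo_i + 1L)
    sp_idx <- rep(seq_len(np), nsc)
    t_idx <- unlist(lapply(seq_len(np), function(i)
      if (nsc[i] > 0L) lo_i[i]:hi_i[i] else integer()))
    t_rt <- scan_rts[t_idx]
    prof <- exp(-(t_rt - apex[sp_idx])^2 / (2 * sig^2))
    inten <- abund[cbind(sp_idx, s)] * prof *
      rlnorm(length(prof), 0, config$scan_noise_sdlog)
    ppm_t <- ppm_fns[[s]](t_rt)
    mz_sp <- species$true_mz[sp_idx] * (1 + ppm_t * 1e-6) +
      rnorm(length(t_rt), 0, config$mz_sigma)
    sp_ions <- data.table(rt = t_rt, mz = mz_sp, intensity = inten)

    iso_ions <- data.table()
    if (config$isotope_enabled) {
      mz_iso <- (species$true_mz[sp_idx] + 1.002 / species$charge[sp_idx]) *
        (1 + ppm_t * 1e-6) + rnorm(length(t_rt), 0, config$mz_sigma)
      iso_ions <- data.table(rt = t_rt, mz = mz_iso,
                             intensity = inten * config$isotope_ratio)
    }

    intf_ions <- data.table()
    if (n_intf > 0) {
      ii <- which(species$interference)
      apex_i <- apex[ii] + species$intf_drt[ii]
      lo2 <- findInterval(apex_i - 3 * sig, scan_rts) + 1L
      hi2 <- findInterval(apex_i + 3 * sig, scan_rts)
      nsc2 <- pmax(0L, hi2 - lo2 + 1L)
      k_idx <- rep(seq_along(ii), nsc2)
      t2 <- scan_rts[unlist(lapply(seq_along(ii), function(k)
        if (nsc2[k] > 0L) lo2[k]:hi2[k] else integer()))]
      prof2 <- exp(-(t2 - apex_i[k_idx])^2 / (2 * sig^2))
      int2 <- abund[cbind(ii[k_idx], s)] *
        config$interference_intensity_ratio * prof2 *
        rlnorm(length(prof2), 0, config$scan_noise_sdlog)
      mz2 <- (species$true_mz[ii[k_idx]] + species$intf_dmz[ii[k_idx]]) *
        (1 + ppm_fns[[s]](t2) * 1e-6) +
        rnorm(length(t2), 0, config$mz_sigma)
      intf_ions <- data.table(rt = t2, mz = mz2, intensity = int2)
    }

    # unsequenced extra species: real clusters + sequence-less feature rows
    ex_ions <- data.table(); ex_feat <- NULL
    if (n_extra > 0) {
      apex_x <- extras$base_rt + drift_fns[[s]](extras$base_rt)
      lo_x <- findInterval(apex_x - 3 * sig, scan_rts) + 1L
      hi_x <- findInterval(apex_x + 3 * sig, scan_rts)
      nscx <- pmax(0L, hi_x - lo_x + 1L)
      xi <- rep(seq_len(n_extra), nscx)
      tx <- scan_rts[unlist(lapply(seq_len(n_extra), function(i)
        if (nscx[i] > 0L) lo_x[i]:hi_x[i] else integer()))]
      profx <- exp(-(tx - apex_x[xi])^2 / (2 * sig^2))
      abx <- extras$base_abundance *
        rlnorm(n_extra, 0, config$sample_intensity_sdlog)
      intx <- abx[xi] * profx *
        rlnorm(length(profx), 0, config$scan_noise_sdlog)
      ppm_tx <- ppm_fns[[s]](tx)
      mzx <- extras$true_mz[xi] * (1 + ppm_tx * 1e-6) +
        rnorm(length(tx), 0, config$mz_sigma)
      ex_ions <- data.table(rt = tx, mz = mzx, intensity = intx)
      if (config$isotope_enabled) {
        mzxi <- (extras$true_mz[xi] + 1.002 / extras$charge[xi]) *
          (1 + ppm_tx * 1e-6) + rnorm(length(tx), 0, config$mz_sigma)
        ex_ions <- rbind(ex_ions,
                         data.table(rt = tx, mz = mzxi,
                                    intensity = intx *
                                      config$isotope_ratio))
      }
      detx <- which(runif(n_extra) < config$extra_detect_rate)
      if (length(detx)) {
        ppm_ax <- ppm_fns[[s]](apex_x)
        ex_feat <- data.table(
          sample_id = sid, sequence = NA_character_,
          modifications = NA_character_,
          charge = extras$charge[detx],
          mz_calibrated = extras$true_mz[detx] *
            (1 + rnorm(length(detx), 0, config$cal_residual_ppm) * 1e-6),
          mz_uncalibrated = extras$true_mz[detx] *
            (1 + ppm_ax[detx] * 1e-6) *
            (1 + rnorm(length(detx), 0, config$cal_residual_ppm) * 1e-6),
          rt = apex_x[detx] + rnorm(length(detx), 0, config$rt_obs_sigma),
          rt_peak_width = 6 * sig,
          intensity = abx[detx],
          resolution = 7e4 * sqrt(400 / extras$true_mz[detx]) +
            rnorm(length(detx), 0, 500),
          protein = NA_character_, is_contaminant = FALSE,
          is_reverse = FALSE)
      }
    }

    n_bg <- rpois(1, config$noise_ion_density * area)
    # background centroids live on the MS1 scan grid like every other ion
    bg_ions <- data.table(
      rt = scan_rts[sample.int(length(scan_rts), n_bg, replace = TRUE)],
      mz = runif(n_bg, config$mz_range[1], config$mz_range[2]),
      intensity = rlnorm(n_bg, config$noise_intensity_meanlog,
                         config$noise_intensity_sdlog))

    all_ions <- rbindlist(list(sp_ions, iso_ions, intf_ions, ex_ions,
                               bg_ions))
    ion_maps[[sid]] <- sample_ion_map(all_ions, sid)
    counts_rows[[sid]] <- data.table(
      sample_id = sid, species_ions = nrow(sp_ions),
      isotope_ions = nrow(iso_ions), interference_ions = nrow(intf_ions),
      extra_ions = nrow(ex_ions), background_ions = n_bg,
      total_ions = nrow(all_ions))

    if (!is.null(ex_feat)) feature_rows[[paste0(sid, "_x")]] <- ex_feat
    # detected-feature rows (identified, or unidentified-but-detected)
    det <- which(identified[, s] | unknown_feat[, s])
    if (length(det)) {
      isid <- identified[det, s]
      feature_rows[[sid]] <- data.table(
        sample_id = sid,
        sequence = ifelse(isid, species$sequence[det], NA_character_),
        modifications = ifelse(isid, species$modifications[det],
                               NA_character_),
        charge = species$charge[det],
        mz_calibrated = species$true_mz[det] *
          (1 + rnorm(length(det), 0, config$cal_residual_ppm) * 1e-6),
        mz_uncalibrated = obs_mz_center[det] *
          (1 + rnorm(length(det), 0, config$cal_residual_ppm) * 1e-6),
        rt = apex[det] + rnorm(length(det), 0, config$rt_obs_sigma),
        rt_peak_width = 6 * sig,
        intensity = abund[cbind(det, s)],
        resolution = species$resolution[det] +
          rnorm(length(det), 0, 500),
        protein = ifelse(isid, species$protein[det], NA_character_),
        is_contaminant = isid & species$is_contaminant[det],
        is_reverse = FALSE)
    }
    cell_rows[[sid]] <- data.table(
      species = species$species, sample_id = sid, true_rt = apex,
      true_mz = obs_mz_center, abundance = abund[, s],
      identified = identified[, s], unknown_feature = unknown_feat[, s],
      interference = species$interference,
      intf_rt = apex + species$intf_drt,
      intf_mz = obs_mz_center + species$intf_dmz)
  }

  features <- rbindlist(feature_rows)
  truth <- list(species = species[, .(species, sequence, modifications,
                                      charge, protein, true_mz, base_rt,
                                      base_abundance, ratio,
                                      is_contaminant, interference,
                                      intf_drt, intf_dmz)],
                cells = rbindlist(cell_rows),
                drift_fns = drift_fns, ppm_fns = ppm_fns,
                groups = setNames(config$groups, samples),
                ion_counts = rbindlist(counts_rows))
  out <- list(ion_maps = ion_maps,
              feature_tables = split(features, features$sample_id),
              features = features, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(ion_maps = character(), feature_tables = character())
    for (sid in samples) {
      p1 <- file.path(out_dir, paste0(sid, ".mzXML"))
      write_mzxml(ion_maps[[sid]]$ions, p1)
      p2 <- file.path(out_dir, paste0(sid, "_features.tsv"))
      fwrite(out$feature_tables[[sid]], p2, sep = "\t", na = "NA",
             quote = FALSE)
      paths$ion_maps[sid] <- p1
      paths$feature_tables[sid] <- p2
    }
    fwrite(truth$cells, file.path(out_dir, "ground_truth_cells.tsv"),
           sep = "\t", na = "NA", quote = FALSE)
    paths$truth <- file.path(out_dir, "ground_truth_cells.tsv")
    out$paths <- paths
  }
  out
}

#' Compare pipeline output against synthetic ground truth
#'
#' Links species to consensus features by identity key and reports:
#' `missing_value_rate` (fraction of species x sample cells without a
#' non-imputed quantification), `median_log2_ratio_error` (spiked species
#' only; estimated vs true group-2/group-1 log2 ratio), and
#' `wrong_window_rate` (fraction of non-fallback selected windows whose
#' center deviates from the drifted truth by more than the tolerances).
#'
#' @param result a [run_pipeline()] result (needs `selections`, `events`,
#'   `consensus`).
#' @param truth the `truth` element of [generate_dataset()].
#' @param tol_rt,tol_mz wrong-window tolerances (minutes / Th). By
#'   default each selection's own window half-sizes are used, i.e. a
#'   selection is wrong when its window no longer covers the true
#'   (drifted) peak location.
#' @return list of metrics plus per-cell detail tables.
#' @export
evaluate_against_truth <- function(result, truth, tol_rt = NULL,
                                   tol_mz = NULL) {
  cons <- as.data.table(result$consensus)[kind == "target" &
                                            !is.na(sequence)]
  sp <- copy(truth$species)
  sp[, key_id := feature_key(sequence, modifications, charge)]
  cons[, key_id := feature_key(sequence, modifications, charge)]
  link <- sp[cons, on = "key_id", nomatch = NULL,
             .(species, consensus_id = id, ratio)]
  if (!nrow(link)) stop("no species linkable to consensus features")

  ev <- as.data.table(result$events)[kind == "target"]
  ev <- link[ev, on = "consensus_id", nomatch = NULL]
  cells <- truth$cells[ev, on = .(species, sample_id), nomatch = NULL]
  cells[, ok_quant := !missing & !imputed]
  mvr <- 1 - mean(cells$ok_quant)

  selq <- as.data.table(result$selections)[kind == "target"]
  selq <- link[selq, on = "consensus_id", nomatch = NULL]
  selc <- truth$cells[selq, on = .(species, sample_id), nomatch = NULL]
  selc <- selc[origin != "expected_fallback"]
  t_rt <- if (is.null(tol_rt)) selc$rt_half else tol_rt
  t_mz <- if (is.null(tol_mz)) selc$mz_half else tol_mz
  selc[, wrong := abs(peak_rt - true_rt) > t_rt |
         abs(peak_mz - true_mz) > t_mz]
  wwr <- if (nrow(selc)) mean(selc$wrong) else NA_real_

  groups <- truth$groups
  g1 <- names(groups)[groups == 1L]; g2 <- names(groups)[groups == 2L]
  ratio_err <- NA_real_; ratio_tab <- NULL
  if (length(g1) && length(g2)) {
    est <- cells[ok_quant == TRUE,
                 .(m1 = mean(log2(total_intensity[sample_id %in% g1])),
                   m2 = mean(log2(total_intensity[sample_id %in% g2])),
                   ratio = ratio[1L]), by = species]
    est <- est[is.finite(m1) & is.finite(m2)]
    est[, err := abs((m2 - m1) - log2(ratio))]
    ratio_tab <- est
    spk <- est[ratio != 1]
    ratio_err <- if (nrow(spk)) median(spk$err) else median(est$err)
  }
  list(missing_value_rate = mvr,
       wrong_window_rate = wwr,
       median_log2_ratio_error = ratio_err,
       cells = cells, selections = selc, ratios = ratio_tab)
}
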