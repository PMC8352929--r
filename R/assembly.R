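## Consensus feature assembly -------------------------------------------------

#' Aggregate detected features into cross-sample consensus features
#'
#' Detected features sharing the identity key (sequence, normalized
#' modifications, charge) are aggregated into one consensus feature with
#' reference RT and m/z equal to the medians over contributing features.
#' Contributors deviating from those medians by more than the alignment
#' windows are excluded and the medians recomputed once. Detected features
#' without sequence information falling inside a consensus window (same
#' charge, |rt - rt_ref| <= rt window, |mz - mz_ref| <= mz window) are then
#' attached to the nearest consensus (window-standardized distance). The
#' consensus RT peak width is the maximum width over its contributors.
#'
#' @param features combined detected-feature table (all samples).
#' @param windows resolved [alignment_windows()].
#' @param aggregate_unknown also cluster leftover sequence-less features
#'   into their own consensus features (default `FALSE`).
#' @return data.table of consensus features (`id`, `kind = "target"`,
#'   `sequence`, `modifications`, `charge`, `mz_ref`, `rt_ref`,
#'   `rt_peak_width`, `protein`, `n_samples`), with attribute
#'   `"contributions"`: one row per attached detected feature
#'   (`consensus_id`, `feature_id`, `sample_id`, `rt`, `mz`, `intensity`,
#'   `sequenced`).
#' @export
aggregate_features <- function(features, windows,
                               aggregate_unknown = FALSE) {
  stopifnot(isTRUE(windows$resolved))
  ft <- copy(as.data.table(features))
  ft[, feature_id := .I]
  seqd <- ft[!is.na(sequence)]
  seqd[, key_id := feature_key(sequence, modifications, charge)]

  # first pass medians, single exclusion pass, second (final) medians
  seqd[, `:=`(med_rt = median(rt), med_mz = median(mz_calibrated)),
       by = key_id]
  seqd[, keep := abs(rt - med_rt) <= windows$rt_window &
         abs(mz_calibrated - med_mz) <= windows$mz_window]
  # degenerate keys (e.g. two far-apart contributors straddling their
  # median) must keep at least the contributor nearest the median
  seqd[, keep := {
    if (any(keep)) keep else {
      d <- pmax(abs(rt - med_rt) / windows$rt_window,
                abs(mz_calibrated - med_mz) / windows$mz_window)
      # ties (two contributors equidistant from their median) break by
      # intensity then position so the result is order-independent
      pick <- order(d, -intensity, rt, mz_calibrated, sample_id)[1L]
      replace(keep, pick, TRUE)
    }
  }, by = key_id]
  kept <- seqd[keep == TRUE]
  cons <- kept[, .(
    sequence = sequence[1L],
    modifications = normalize_modifications(modifications[1L]),
    charge = charge[1L],
    mz_ref = median(mz_calibrated),
    rt_ref = median(rt),
    rt_peak_width = {
      w <- rt_peak_width[is.finite(rt_peak_width)]
      if (length(w)) max(w) else NA_real_
    },
    protein = {
      p <- protein[!is.na(protein)]
      if (length(p)) p[1L] else NA_character_
    },
    is_contaminant = any(is_contaminant, na.rm = TRUE),
    is_reverse = any(is_reverse, na.rm = TRUE)
  ), by = key_id]
  cons[, id := sprintf("CF%05d", .I)]
  cons[, kind := "target"]
  cons[, parent_id := NA_character_]

  contrib <- kept[cons, on = "key_id",
                  .(consensus_id = i.id, feature_id, sample_id, rt,
                    mz = mz_calibrated, mz_uncal = mz_uncalibrated,
                    intensity, sequenced = TRUE)]

  # attach in-window unknown features to the nearest consensus
  unk <- ft[is.na(sequence)]
  if (nrow(unk) && nrow(cons)) {
    cand <- cons[, .(id, charge, mz_ref, rt_ref)][
      unk, on = .(charge), allow.cartesian = TRUE, nomatch = NULL]
    cand <- cand[abs(rt - rt_ref) <= windows$rt_window &
                   abs(mz_calibrated - mz_ref) <= windows$mz_window]
    if (nrow(cand)) {
      cand[, dist := sqrt(((rt - rt_ref) / windows$rt_window)^2 +
                            ((mz_calibrated - mz_ref) /
                               windows$mz_window)^2)]
      setorder(cand, feature_id, dist)
      cand <- cand[, .SD[1L], by = feature_id]
      contrib <- rbind(contrib, cand[, .(
        consensus_id = id, feature_id, sample_id, rt,
        mz = mz_calibrated, mz_uncal = mz_uncalibrated,
        intensity, sequenced = FALSE)])
      # widths may grow through attached unknown contributors
      wmax <- cand[is.finite(rt_peak_width),
                   .(w = max(rt_peak_width)), by = id]
      cons[wmax, on = "id",
           rt_peak_width := pmax(rt_peak_width, w, na.rm = TRUE)]
    }
  }

  # optional: cluster leftover unknown features into unsequenced consensus
  if (aggregate_unknown) {
    left <- unk[!feature_id %in% contrib$feature_id]
    if (nrow(left)) {
      extra <- cluster_unknown_features(left, windows)
      if (nrow(extra$consensus)) {
        extra$consensus[, id := sprintf("UF%05d", .I)]
        extra$contrib[, consensus_id := extra$consensus$id[consensus_row]]
        extra$contrib[, consensus_row := NULL]
        cons <- rbind(cons, extra$consensus, fill = TRUE)
        contrib <- rbind(contrib, extra$contrib, use.names = TRUE)
      }
    }
  }

  fallback_w <- 2 * windows$rt_window
  cons[!is.finite(rt_peak_width), rt_peak_width := fallback_w]
  cons[, key_id := NULL]
  setcolorder(cons, c("id", "kind", "sequence", "modifications", "charge",
                      "mz_ref", "rt_ref", "rt_peak_width", "protein",
                      "parent_id"))
  ns <- contrib[, .(n_samples = uniqueN(sample_id)), by = consensus_id]
  cons[, n_samples := 0L]
  cons[ns, on = .(id = consensus_id), n_samples := i.n_samples]
  setattr(cons, "contributions", contrib)
  cons[]
}

# transitive clustering of sequence-less features by charge + windows
cluster_unknown_features <- function(left, windows) {
  left <- copy(left)
  setorder(left, charge, mz_calibrated)
  left[, cluster := {
    cl <- integer(.N); cur <- 0L
    for (i in seq_len(.N)) {
      if (i == 1L || mz_calibrated[i] - mz_calibrated[i - 1L] >
            windows$mz_window)
        cur <- cur + 1L
      cl[i] <- cur
    }
    cl
  }, by = charge]
  # split m/z clusters further by RT gaps > rt_window
  left[, cluster2 := {
    o <- order(rt)
    cl <- integer(.N); cur <- 0L
    prev_rt <- -Inf
    tmp <- integer(.N)
    for (j in seq_len(.N)) {
      i <- o[j]
      if (rt[i] - prev_rt > windows$rt_window) cur <- cur + 1L
      tmp[i] <- cur
      prev_rt <- rt[i]
    }
    tmp
  }, by = .(charge, cluster)]
  grp <- left[, .(
    sequence = NA_character_, modifications = NA_character_,
    charge = charge[1L], mz_ref = median(mz_calibrated),
    rt_ref = median(rt),
    rt_peak_width = {
      w <- rt_peak_width[is.finite(rt_peak_width)]
      if (length(w)) max(w) else NA_real_
    },
    protein = NA_character_, is_contaminant = FALSE, is_reverse = FALSE,
    kind = "target", parent_id = NA_character_,
    .ids = list(feature_id)
  ), by = .(charge_grp = charge, cluster, cluster2)]
  contrib <- grp[, {
    idx <- unlist(.ids)
    left[match(idx, feature_id),
         .(feature_id, sample_id, rt, mz = mz_calibrated,
           mz_uncal = mz_uncalibrated, intensity)]
  }, by = .(charge_grp, cluster, cluster2)]
  grp[, consensus_row := .I]
  contrib <- contrib[grp, on = .(charge_grp, cluster, cluster2)][
    , .(feature_id, sample_id, rt, mz, mz_uncal, intensity,
        sequenced = FALSE, consensus_row)]
  list(consensus = grp[, .(sequence, modifications, charge, mz_ref, rt_ref,
                           rt_peak_width, protein, is_contaminant,
                           is_reverse, kind, parent_id)],
       contrib = contrib)
}

#' Merge overlapping consensus features
#'
#' Two consensus features of equal charge overlap when their reference m/z
#' differ by less than `delta_mass` and their RT extents
#' (`rt_ref +- rt_peak_width / 2`) overlap. Overlap is closed transitively
#' (union-find). A merged feature keeps the sequence of its sequenced
#' member; pairs of sequenced features with conflicting identity keys are
#' never merged (the conflict is logged in the `"merge_conflicts"`
#' attribute).
#'
#' @param consensus consensus table from [aggregate_features()].
#' @param delta_mass m/z closeness threshold in Th (default 0.002).
#' @return merged consensus table (contributions updated accordingly).
#' @export
merge_overlapping <- function(consensus, delta_mass = 0.002) {
  cons <- copy(as.data.table(consensus))
  contrib <- attr(consensus, "contributions")
  n <- nrow(cons)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  conflicts <- list()

  setorder(cons, charge, mz_ref)
  ord <- seq_len(n)
  # pair scan: within charge, sorted by mz_ref, look ahead while < delta
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && cons$charge[j] == cons$charge[i] &&
             cons$mz_ref[j] - cons$mz_ref[i] < delta_mass) {
      rt_lo_i <- cons$rt_ref[i] - cons$rt_peak_width[i] / 2
      rt_hi_i <- cons$rt_ref[i] + cons$rt_peak_width[i] / 2
      rt_lo_j <- cons$rt_ref[j] - cons$rt_peak_width[j] / 2
      rt_hi_j <- cons$rt_ref[j] + cons$rt_peak_width[j] / 2
      if (rt_lo_i <= rt_hi_j && rt_lo_j <= rt_hi_i) {
        si <- cons$sequence[i]; sj <- cons$sequence[j]
        if (!is.na(si) && !is.na(sj) &&
              (si != sj || cons$modifications[i] != cons$modifications[j])) {
          conflicts[[length(conflicts) + 1L]] <-
            c(cons$id[i], cons$id[j])
        } else {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
      j <- j + 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cons[, cluster := root]
  merged <- cons[, {
    sel <- which(!is.na(sequence))
    lead <- if (length(sel)) sel[1L] else 1L
    .(id = id[lead], sequence = sequence[lead],
      modifications = modifications[lead], charge = charge[1L],
      mz_ref = NA_real_, rt_ref = NA_real_,
      rt_peak_width = max(rt_peak_width),
      protein = protein[lead], is_contaminant = any(is_contaminant),
      is_reverse = any(is_reverse), kind = "target",
      parent_id = NA_character_, members = list(id))
  }, by = cluster]
  # remap contributions, recompute medians over the union
  remap <- merged[, .(old = unlist(members), new = id), by = cluster]
  contrib2 <- copy(contrib)
  contrib2[remap, on = .(consensus_id = old), consensus_id := i.new]
  med <- contrib2[, .(mz_ref = median(mz), rt_ref = median(rt),
                      n_samples = uniqueN(sample_id)),
                  by = consensus_id]
  merged[med, on = .(id = consensus_id),
         `:=`(mz_ref = i.mz_ref, rt_ref = i.rt_ref,
              n_samples = i.n_samples)]
  merged[, c("cluster", "members") := NULL]
  setattr(merged, "contributions", contrib2)
  setattr(merged, "merge_conflicts", conflicts)
  merged[]
}

#' Generate decoy companion features
#'
#' One decoy per target, offset by `offset_multiplier` alignment windows in
#' both RT and m/z. A decoy whose window (RT extent x m/z window) would
#' collide with any target window is shifted by further +1 m/z window steps
#' (up to `max_shifts`) until collision-free, else dropped with a warning.
#' Decoys inherit the parent's RT peak width, charge and sample set.
#'
#' @param consensus merged target consensus table.
#' @param windows resolved [alignment_windows()].
#' @param offset_multiplier default 5.
#' @param max_shifts maximum collision-resolution shifts (default 10).
#' @return decoy consensus table (`kind = "decoy"`, `parent_id` set).
#' @export
generate_decoys <- function(consensus, windows, offset_multiplier = 5,
                            max_shifts = 10L) {
  cons <- as.data.table(consensus)[kind == "target"]
  if (!nrow(cons)) return(cons[0L])
  dec <- copy(cons)
  dec[, `:=`(parent_id = id, id = paste0("D_", id), kind = "decoy",
             sequence = NA_character_, protein = NA_character_,
             rt_ref = rt_ref + offset_multiplier * windows$rt_window,
             mz_ref = mz_ref + offset_multiplier * windows$mz_window)]
  tgt <- cons[, .(rt_lo = rt_ref - rt_peak_width / 2,
                  rt_hi = rt_ref + rt_peak_width / 2,
                  mz_lo = mz_ref - windows$mz_window,
                  mz_hi = mz_ref + windows$mz_window)]
  setkey(tgt, mz_lo, mz_hi)
  collides <- function(d) {
    q <- d[, .(mz_lo = mz_ref - windows$mz_window,
               mz_hi = mz_ref + windows$mz_window,
               rt_lo = rt_ref - rt_peak_width / 2,
               rt_hi = rt_ref + rt_peak_width / 2,
               row = .I)]
    ov <- foverlaps(q, tgt, by.x = c("mz_lo", "mz_hi"), nomatch = NULL)
    hit <- ov[i.rt_lo <= rt_hi & rt_lo <= i.rt_hi, unique(row)]
    seq_len(nrow(d)) %in% hit
  }
  bad <- collides(dec)
  shifts <- 0L
  while (any(bad) && shifts < max_shifts) {
    dec[bad, mz_ref := mz_ref + windows$mz_window]
    bad <- collides(dec)
    shifts <- shifts + 1L
  }
  if (any(bad)) {
    warning(sum(bad), " decoy feature(s) could not be placed ",
            "collision-free and were dropped")
    dec <- dec[!bad]
  }
  dec[, n_samples := NA_integer_]
  dec[]
}

#' Generate +1-isotope companion features
#'
#' One isotope feature per target at `mz_ref + 1.002 / charge` (Th), same
#' reference RT and peak width. Targets without a known charge are skipped
#' and counted in the `"n_skipped"` attribute.
#'
#' @param consensus merged target consensus table.
#' @param delta isotope spacing in Th (default 1.002).
#' @return isotope consensus table (`kind = "isotope_plus1"`).
#' @export
generate_isotope_features <- function(consensus, delta = 1.002) {
  cons <- as.data.table(consensus)[kind == "target"]
  ok <- is.finite(cons$charge) & cons$charge >= 1
  iso <- copy(cons[ok])
  iso[, `:=`(parent_id = id, id = paste0("I_", id), kind = "isotope_plus1",
             mz_ref = mz_ref + delta / charge)]
  setattr(iso, "n_skipped", sum(!ok))
  iso[]
}

#' Label per-sample identification provenance of consensus features
#'
#' For every sequenced consensus feature and every sample, the sample is
#' labeled `sequenced_here` when it contributed a sequenced detected
#' feature, `feature_propagated` when it contributed only a sequence-less
#' feature (feature-based identity propagation), and
#' `to_recover_by_ion_PIP` otherwise (to be recovered by ion-based
#' propagation during DICE).
#'
#' @param consensus consensus table with `"contributions"` attribute.
#' @param samples character vector of all sample ids in the experiment.
#' @return data.table `consensus_id`, `sample_id`, `status`.
#' @export
propagate_identities <- function(consensus, samples) {
  cons <- as.data.table(consensus)
  contrib <- attr(consensus, "contributions")
  seq_ids <- cons[kind == "target" & !is.na(sequence), id]
  grid <- CJ(consensus_id = seq_ids, sample_id = samples, unique = TRUE)
  st <- contrib[, .(any_seq = any(sequenced), any_unk = any(!sequenced)),
                by = .(consensus_id, sample_id)]
  grid[, status := "to_recover_by_ion_PIP"]
  grid[st[any_unk == TRUE], on = .(consensus_id, sample_id),
       status := "feature_propagated"]
  grid[st[any_seq == TRUE], on = .(consensus_id, sample_id),
       status := "sequenced_here"]
  grid[]
}
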