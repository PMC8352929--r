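## Direct ion current extraction: KDE maps, peak detection, window selection -

# normal-reference bandwidth per dimension on standardized (window-unit)
# coordinates, floored at kernel sd 0.5 window units: structure finer than
# half the alignment window is centroid jitter by construction, peaks
# closer than a window are not separable targets for selection, and a
# larger floor keeps the maximum of a flat elution ridge from wandering.
# On kde2d's h scale (kernel sd = h/4).
kde_bandwidth <- function(x, floor_h = 2) {
  h <- if (length(x) > 1L) MASS::bandwidth.nrd(x) else 0
  if (!is.finite(h) || h < floor_h) h <- floor_h
  h
}

#' Compute the local KDE ion-accumulation map of one feature in one sample
#'
#' Ions are gathered from an extended search region around the expected
#' window center: `+- max(3 x rt_window, rt_half)` in RT and
#' `+- 3 x mz_window` in m/z. Coordinates are standardized by dividing each
#' dimension by its alignment window (the two raw scales differ by ~1e5),
#' then an intensity-unweighted bivariate normal-kernel density is
#' evaluated on a `resolution x resolution` grid spanning the region.
#'
#' @param ion_map a [sample_ion_map()].
#' @param center expected window center, numeric `c(rt, mz)`.
#' @param windows resolved [alignment_windows()].
#' @param rt_half RT half-width of the feature's DICE window
#'   (`rt_peak_width / 2`, minutes).
#' @param resolution grid points per dimension (default 50).
#' @return object of class `KdeMap`: `z` (resolution x resolution density,
#'   all-zero when the region holds no ions), `u`, `v` (grid coordinates in
#'   window units, RT and m/z), `ions` (list of standardized coordinate
#'   vectors `u`, `v` and `intensity`), `center`, `rt_half_std`, plus the
#'   window sizes used.
#' @export
compute_kde_map <- function(ion_map, center, windows, rt_half,
                            resolution = 50L) {
  stopifnot(is.finite(center[1]), is.finite(center[2]))
  rt_ext <- max(3 * windows$rt_window, rt_half)
  mz_ext <- 3 * windows$mz_window
  idx <- .win_idx(ion_map, center[1] - rt_ext, center[1] + rt_ext,
                  center[2] - mz_ext, center[2] + mz_ext)
  u_lim <- c(-rt_ext, rt_ext) / windows$rt_window
  v_lim <- c(-mz_ext, mz_ext) / windows$mz_window
  std <- list(u = (ion_map$rt_s[idx] - center[1]) / windows$rt_window,
              v = (ion_map$mz_s[idx] - center[2]) / windows$mz_window,
              intensity = ion_map$int_s[idx])
  if (length(idx)) {
    k <- MASS::kde2d(std$u, std$v,
                     h = c(kde_bandwidth(std$u), kde_bandwidth(std$v)),
                     n = resolution, lims = c(u_lim, v_lim))
    z <- k$z; u <- k$x; v <- k$y
  } else {
    u <- seq(u_lim[1], u_lim[2], length.out = resolution)
    v <- seq(v_lim[1], v_lim[2], length.out = resolution)
    z <- matrix(0, resolution, resolution)
  }
  out <- list(z = z, u = u, v = v, ions = std, center = center,
              rt_half_std = rt_half / windows$rt_window,
              rt_window = windows$rt_window, mz_window = windows$mz_window)
  class(out) <- "KdeMap"
  out
}

# strict 8-neighborhood local maxima of a matrix; returns integer matrix of
# (row, col). Plateaus (exact ties) yield no strict maximum; the caller's
# tie-break keeps the weak maximum nearest the expected center instead.
local_maxima <- function(z) {
  n <- nrow(z); m <- ncol(z)
  if (n < 1L || m < 1L) return(cbind(integer(), integer()))
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- z
  ctr <- pad[2:(n + 1L), 2:(m + 1L)]
  strict <- matrix(TRUE, n, m)
  weak <- matrix(TRUE, n, m)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(n + 1L)) + di, (2:(m + 1L)) + dj, drop = FALSE]
    strict <- strict & (ctr > nb)
    weak <- weak & (ctr >= nb)
  }
  idx <- which(strict & ctr > 0, arr.ind = TRUE)
  if (!nrow(idx)) {
    # plateau fallback: weak maxima (deduplicated later by the caller)
    idx <- which(weak & ctr > 0, arr.ind = TRUE)
  }
  idx
}

#' Detect candidate peaks on a KDE map
#'
#' Local maxima of the density grid (strictly greater than all 8
#' neighbours; exact-tie plateaus are broken toward the cell nearest the
#' expected center) become candidates. Each candidate's supporting ion
#' count is the number of ions inside a window of the feature's half-widths
#' centered at the candidate. Candidates are kept when the count reaches
#' `min_ions` (the median decoy ion count) *or* the candidate lies inside
#' the expected DICE window, then ranked by standardized distance from the
#' expected center; at most 5 are returned.
#'
#' @param kde_map a [compute_kde_map()] result.
#' @param min_ions minimum supporting ion count (median decoy ion count).
#' @param max_peaks maximum number of candidates (default 5).
#' @return data.table: `u`, `v` (window units relative to expected
#'   center), `rt`, `mz` (absolute), `count`, `in_window`, `dist`, `rank`.
#' @export
detect_peaks <- function(kde_map, min_ions, max_peaks = 5L) {
  empty <- data.table(u = numeric(), v = numeric(), rt = numeric(),
                      mz = numeric(), count = integer(),
                      in_window = logical(), dist = numeric(),
                      rank = integer())
  if (!length(kde_map$ions$u) || all(kde_map$z == 0)) return(empty)
  idx <- local_maxima(kde_map$z)
  if (!nrow(idx)) return(empty)
  cu <- kde_map$u[idx[, 1L]]; cv <- kde_map$v[idx[, 2L]]
  cz <- kde_map$z[idx]
  cdist <- sqrt(cu^2 + cv^2)
  o <- order(cdist)
  cu <- cu[o]; cv <- cv[o]; cz <- cz[o]; cdist <- cdist[o]
  # plateau tie-break: among equal-density candidates closer than ~one
  # grid cell apart, keep the one nearest the expected center
  if (length(cu) > 1L) {
    du <- kde_map$u[2L] - kde_map$u[1L]
    dv <- kde_map$v[2L] - kde_map$v[1L]
    keep <- rep(TRUE, length(cu))
    for (i in 2:length(cu)) {
      prior <- which(keep[seq_len(i - 1L)])
      drop_i <- any(cz[prior] == cz[i] &
                      abs(cu[prior] - cu[i]) <= 1.5 * du &
                      abs(cv[prior] - cv[i]) <= 1.5 * dv)
      if (drop_i) keep[i] <- FALSE
    }
    cu <- cu[keep]; cv <- cv[keep]; cdist <- cdist[keep]
  }
  iu <- kde_map$ions$u; iv <- kde_map$ions$v
  rhs <- kde_map$rt_half_std
  count <- vapply(seq_along(cu), function(i)
    sum(abs(iu - cu[i]) <= rhs & abs(iv - cv[i]) <= 1), integer(1))
  in_window <- abs(cu) <= rhs & abs(cv) <= 1
  sel <- count >= min_ions | in_window
  if (!any(sel)) return(empty)
  sel <- which(sel)[seq_len(min(max_peaks, sum(sel)))]
  data.table(u = cu[sel], v = cv[sel],
             rt = kde_map$center[1] + cu[sel] * kde_map$rt_window,
             mz = kde_map$center[2] + cv[sel] * kde_map$mz_window,
             count = count[sel], in_window = in_window[sel],
             dist = cdist[sel], rank = seq_along(sel))
}

#' Select one extraction window per sample for a consensus feature
#'
#' Samples with a contributing detected feature ("known" samples) take the
#' candidate nearest the expected center, provided it has at least
#' `min_ions` supporting ions *and* lies inside the expected DICE window.
#' All other samples take the candidate closest to the known peaks'
#' consensus location that does not overlap a distinct rejected peak seen
#' in known samples, subject to the transfer limits of one RT alignment
#' window and `max_mz_multiple` m/z alignment windows around that
#' consensus location ("transferred").
#' When nothing qualifies the expected window itself is used
#' ("expected_fallback").
#'
#' Candidate deviations are measured from each sample's expected center
#' (the sample's own observed feature for known samples, the model
#' prediction otherwise). For the cross-sample transfer matching all
#' positions are re-expressed relative to the *model* centers via
#' `frame_offsets`, which cancels the shared feature-level alignment error
#' so the known peaks' consensus location is meaningful in the recovery
#' sample's frame.
#'
#' @param candidates data.table of per-sample candidates (columns of
#'   [detect_peaks()] plus `sample_id`).
#' @param known_samples character vector of samples with a contributing
#'   detected feature.
#' @param min_ions named numeric: per-sample median decoy ion count.
#' @param rt_half_std expected-window RT half-width in window units.
#' @param max_mz_multiple transfer limit in m/z windows (default 3).
#' @param frame_offsets optional data.table (`sample_id`, `du`, `dv`):
#'   offset of each sample's candidate frame from its model frame, in
#'   window units (0 when the frames coincide).
#' @return data.table: `sample_id`, `u`, `v` (selected deviation in window
#'   units; 0 for fallback), `origin`.
#' @export
select_window <- function(candidates, known_samples, min_ions,
                          rt_half_std, max_mz_multiple = 3,
                          frame_offsets = NULL) {
  samples <- names(min_ions)
  res <- data.table(sample_id = samples, u = 0, v = 0,
                    origin = "expected_fallback")
  cand <- as.data.table(candidates)
  off <- function(s) {
    if (is.null(frame_offsets)) return(c(0, 0))
    i <- match(s, frame_offsets$sample_id)
    if (is.na(i)) c(0, 0) else c(frame_offsets$du[i], frame_offsets$dv[i])
  }
  sel_known <- list()
  rejected <- list()
  for (s in intersect(known_samples, samples)) {
    cs <- cand[sample_id == s]
    if (!nrow(cs)) next
    valid <- cs[count >= min_ions[[s]] & in_window == TRUE]
    o <- off(s)
    if (nrow(valid)) {
      pick <- valid[which.min(dist)]
      res[sample_id == s, `:=`(u = pick$u, v = pick$v, origin = "known")]
      sel_known[[s]] <- c(pick$u + o[1], pick$v + o[2])
      # other, non-selected peaks of samples with a known peak may block
      # transfers onto a neighbouring distinct peak
      rej <- cs[!(u == pick$u & v == pick$v)]
      if (nrow(rej))
        rejected[[s]] <- data.table(u = rej$u + o[1], v = rej$v + o[2])
    }
  }
  ref <- if (length(sel_known)) {
    m <- do.call(rbind, sel_known)
    c(median(m[, 1]), median(m[, 2]))
  } else c(0, 0)
  rej_all <- if (length(rejected)) rbindlist(rejected) else NULL
  if (!is.null(rej_all)) {
    # only peaks distinct from the consensus location block a transfer
    rej_all <- rej_all[abs(u - ref[1]) > rt_half_std / 2 |
                         abs(v - ref[2]) > 0.5]
  }
  todo <- setdiff(samples, res[origin == "known", sample_id])
  for (s in todo) {
    cs <- cand[sample_id == s]
    if (!nrow(cs)) next
    o <- off(s)
    um <- cs$u + o[1]; vm <- cs$v + o[2]
    # transfer limits bound the deviation from the known peaks' location
    # (model frame); without known peaks, from the expected center
    ok <- abs(um - ref[1]) <= 1 & abs(vm - ref[2]) <= max_mz_multiple
    cs <- cs[ok]; um <- um[ok]; vm <- vm[ok]
    if (!nrow(cs)) next
    d2 <- (um - ref[1])^2 + (vm - ref[2])^2
    if (!is.null(rej_all) && nrow(rej_all)) {
      # blocked: overlapping a distinct rejected peak and matching it
      # better than the known consensus location
      blocked <- vapply(seq_len(nrow(cs)), function(i) {
        d_rej <- (rej_all$u - um[i])^2 + (rej_all$v - vm[i])^2
        any(abs(rej_all$u - um[i]) <= rt_half_std &
              abs(rej_all$v - vm[i]) <= 1 & d_rej < d2[i])
      }, logical(1))
      cs <- cs[!blocked]; d2 <- d2[!blocked]
    }
    if (!nrow(cs)) next
    pick <- cs[which.min(d2)]
    res[sample_id == s,
        `:=`(u = pick$u, v = pick$v, origin = "transferred")]
  }
  res[]
}

#' Extract a DICE quantification from one window
#'
#' Counts all ions inside the selected window and sums their intensities.
#' Ions brighter than the background noise at the window's RT plus twice
#' the noise standard deviation are signal; signal and background
#' intensities partition the total. A window without ions yields a
#' missing quantification.
#'
#' @param ion_map a [sample_ion_map()].
#' @param dice_window list/row with `rt_center`, `rt_half`, `mz_center`,
#'   `mz_half`.
#' @param noise_model a [fit_noise_model()] result (or `NULL`: all ions
#'   counted as signal).
#' @param sd_multiple noise standard deviations above the background mean
#'   defining a signal ion (default 2).
#' @return one-row data.table: `ion_count`, `total_intensity`,
#'   `signal_intensity`, `background_intensity`, `missing`.
#' @export
extract_quant <- function(ion_map, dice_window, noise_model = NULL,
                          sd_multiple = 2) {
  thr <- if (is.null(noise_model)) -Inf else
    noise_model$mean_intensity(dice_window$rt_center) +
      sd_multiple * noise_model$sd_intensity
  v <- .extract_vec(ion_map,
                    dice_window$rt_center - dice_window$rt_half,
                    dice_window$rt_center + dice_window$rt_half,
                    dice_window$mz_center - dice_window$mz_half,
                    dice_window$mz_center + dice_window$mz_half,
                    thr = thr)
  data.table(ion_count = as.integer(v[1]), total_intensity = v[2],
             signal_intensity = v[3], background_intensity = v[2] - v[3],
             missing = v[1] == 0)
}

#' Remove unreliable peak selections
#'
#' Three filters on the selected peak positions:
#' \enumerate{
#'   \item whole-feature removal when the feature's cross-sample IQR of
#'     selected-peak RT or m/z is an upper outlier against the population
#'     of features (robust z of log-IQR > `z_cut`);
#'   \item per-sample exclusion when a sample's selected peak deviates from
#'     the feature's cross-sample median position by robust z > `z_cut`
#'     (scale pooled over all features per dimension);
#'   \item per-sample exclusion when the monoisotopic and +1-isotope
#'     selected peaks disagree (`|dRT| > rt_window` or
#'     `|dm/z - 1.002/charge| > mz_window`).
#' }
#'
#' @param selections data.table of selected windows: `consensus_id`,
#'   `sample_id`, `kind`, `parent_id`, `charge`, `peak_rt`, `peak_mz`,
#'   `origin`, optionally `rt_half` and alignment residuals `dev_rt`,
#'   `dev_mz` (peak minus the sample's model-predicted center; used for
#'   the cross-sample filters when present so injected drift does not
#'   count as dispersion).
#' @param windows resolved [alignment_windows()].
#' @param z_cut robust-z threshold (default 3).
#' @param isotope_delta isotope spacing in Th (default 1.002).
#' @return list: `removed_features` (ids), `excluded_cells`
#'   (`consensus_id`, `sample_id`, `reason`), `log` (combined reason
#'   table).
#' @export
filter_outlier_peaks <- function(selections, windows, z_cut = 3,
                                 isotope_delta = 1.002) {
  sel <- as.data.table(selections)
  tgt <- sel[kind == "target"]
  # cross-sample comparisons happen on alignment residuals (peak minus
  # the sample's model-predicted center) when available: raw peak
  # positions legitimately differ between samples by the injected drift
  if (!"dev_rt" %in% names(tgt)) tgt[, dev_rt := peak_rt]
  if (!"dev_mz" %in% names(tgt)) tgt[, dev_mz := peak_mz]
  # (1) dispersion outliers over the feature population
  disp <- tgt[, .(iqr_rt = iqr7(dev_rt), iqr_mz = iqr7(dev_mz),
                  n = .N), by = consensus_id][n >= 3L]
  removed <- character()
  if (nrow(disp) >= 5L) {
    z_rt <- robust_z(log(disp$iqr_rt + 1e-3 * windows$rt_window))
    z_mz <- robust_z(log(disp$iqr_mz + 1e-3 * windows$mz_window))
    # physical floor: dispersion below half an alignment window is
    # localization jitter, not a wandering feature
    removed <- disp[(z_rt > z_cut & disp$iqr_rt > windows$rt_window / 2) |
                      (z_mz > z_cut &
                         disp$iqr_mz > windows$mz_window / 2),
                    consensus_id]
  }
  # (2) per-sample deviation outliers, pooled scale per dimension; a
  # physical floor (the window half-sizes) keeps peak-localization jitter
  # from being flagged when the pooled scale is very tight
  tgt[, `:=`(d_rt = dev_rt - median(dev_rt),
             d_mz = dev_mz - median(dev_mz)), by = consensus_id]
  s_rt <- mad(tgt$d_rt, center = 0)
  s_mz <- mad(tgt$d_mz, center = 0)
  if (!"rt_half" %in% names(tgt)) tgt[, rt_half := windows$rt_window]
  excl2 <- tgt[((s_rt > 0 & abs(d_rt) / s_rt > z_cut) &
                  abs(d_rt) > rt_half) |
                 ((s_mz > 0 & abs(d_mz) / s_mz > z_cut) &
                    abs(d_mz) > windows$mz_window),
               .(consensus_id, sample_id, reason = "deviating_peak")]
  # (3) monoisotopic vs +1-isotope consistency
  iso <- sel[kind == "isotope_plus1",
             .(parent_id, sample_id, iso_rt = peak_rt, iso_mz = peak_mz,
               iso_origin = origin)]
  pair <- iso[tgt, on = .(parent_id = consensus_id, sample_id),
              nomatch = NULL]
  excl3 <- pair[iso_origin != "expected_fallback" &
                  (abs(iso_rt - peak_rt) > windows$rt_window |
                     abs((iso_mz - peak_mz) - isotope_delta / charge) >
                       windows$mz_window),
                .(consensus_id = parent_id, sample_id,
                  reason = "isotope_mismatch")]
  excluded <- unique(rbind(excl2, excl3))
  log <- rbind(
    data.table(consensus_id = removed, sample_id = NA_character_,
               reason = "dispersed_feature"),
    excluded)
  list(removed_features = removed, excluded_cells = excluded, log = log)
}
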