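## Decoy-derived noise models, significance, masking FDR, imputation ---------

#' Fit the per-sample background-noise model from decoy quantifications
#'
#' An RT-dependent smoother (GAM) of decoy total intensity against the
#' decoy window RT gives the expected background intensity at any RT; its
#' residual dispersion gives the noise standard deviation (robust
#' 1.4826 x MAD by default). The empirical distribution of decoy ion
#' counts drives both the KDE minimum-ion threshold (its median) and the
#' significance score.
#'
#' @param decoy_events data.table of decoy quantifications of one sample:
#'   `rt_center`, `ion_count`, `total_intensity`.
#' @param sd_estimator `"mad"` (robust, default) or `"sd"`.
#' @param min_events below this, a constant-median model is used with a
#'   warning (default 20).
#' @return object of class `NoiseModel`: `mean_intensity(rt)`,
#'   `sd_intensity`, `count_distribution`, `median_decoy_count`,
#'   `residuals`, `rt_range`.
#' @export
fit_noise_model <- function(decoy_events, sd_estimator = c("mad", "sd"),
                            min_events = 20L) {
  sd_estimator <- match.arg(sd_estimator)
  ev <- as.data.table(decoy_events)
  stopifnot(all(c("rt_center", "ion_count", "total_intensity") %in%
                  names(ev)))
  counts <- as.integer(ev$ion_count)
  disp <- function(r) {
    if (!length(r)) return(0)
    if (sd_estimator == "mad") mad(r) else sd(r)
  }
  if (nrow(ev) < min_events || length(unique(ev$rt_center)) < 4L) {
    if (nrow(ev) < min_events)
      warning(sprintf("only %d decoy events (< %d); using constant noise",
                      nrow(ev), min_events))
    med <- if (nrow(ev)) median(ev$total_intensity) else 0
    r <- ev$total_intensity - med
    model <- list(mean_intensity = function(rt) rep(med, length(rt)),
                  sd_intensity = disp(r), residuals = r,
                  count_distribution = counts,
                  median_decoy_count = if (length(counts))
                    median(counts) else 0,
                  rt_range = if (nrow(ev)) range(ev$rt_center) else c(NA, NA))
    class(model) <- "NoiseModel"
    return(model)
  }
  k <- max(5L, min(15L, length(unique(ev$rt_center)) - 1L))
  fit <- mgcv::gam(y ~ s(x, k = k),
                   data = data.frame(x = ev$rt_center,
                                     y = ev$total_intensity))
  lo <- min(ev$rt_center); hi <- max(ev$rt_center)
  r <- as.numeric(stats::residuals(fit))
  model <- list(
    mean_intensity = function(rt) {
      pmax(0, as.numeric(predict(fit, newdata = data.frame(
        x = pmin(pmax(rt, lo), hi)))))
    },
    sd_intensity = if (sd_estimator == "mad") mad(r) else sd(r),
    residuals = r,
    count_distribution = counts,
    median_decoy_count = median(counts),
    rt_range = c(lo, hi))
  class(model) <- "NoiseModel"
  model
}

#' @export
print.NoiseModel <- function(x, ...) {
  cat(sprintf(paste0("<NoiseModel> %d decoy events, median count %s, ",
                     "sd %.3g\n"), length(x$count_distribution),
              format(x$median_decoy_count), x$sd_intensity))
  invisible(x)
}

#' Score significance of ion accumulation
#'
#' One-sided empirical p-value with an add-one pseudocount comparing each
#' observed ion count against the sample's decoy ion-count distribution:
#' `p = (1 + #\{decoy counts >= observed\}) / (1 + #decoys)`. An observed
#' count of 0 scores p = 1; a count above every decoy scores the floor
#' `1 / (#decoys + 1)`.
#'
#' @param ion_count integer vector of observed counts.
#' @param noise a [fit_noise_model()] result.
#' @return numeric vector of p-values in (0, 1].
#' @export
score_significance <- function(ion_count, noise) {
  counts <- sort(noise$count_distribution)
  n <- length(counts)
  if (!n) return(rep(1, length(ion_count)))
  n_ge <- n - findInterval(ion_count - 0.5, counts)
  p <- (1 + n_ge) / (1 + n)
  p[ion_count == 0L] <- 1
  p
}

#' Estimate the peak-selection FDR by masking
#'
#' Per sample, up to `n_mask` sequenced consensus features whose window in
#' that sample came from its own detected feature are randomly chosen and
#' masked: the selection is re-run as if the sample had contributed no
#' feature, so the window must be recovered by transfer (or falls back to
#' the expected window). A masked re-selection is wrong when its window
#' center leaves the originally selected window, or its extracted total
#' intensity deviates from the original by more than `tolerance`
#' (relative). FDR = wrong / masked, per sample and pooled.
#'
#' @param state a pipeline state (see [run_pipeline()]), needing
#'   `candidates`, `selections`, `expected`, `identities`, `ion_maps`,
#'   `noise_models`, `windows`.
#' @param n_mask features to mask per sample (clamped to availability;
#'   default 500).
#' @param seed RNG seed for the random choice of masked features.
#' @param tolerance relative intensity deviation counted as wrong
#'   (default 0.2).
#' @return list: `fdr` (pooled), `per_sample` (data.table `sample_id`,
#'   `n_masked`, `n_wrong`, `fdr`), `details`.
#' @export
estimate_fdr <- function(state, n_mask = 500L, seed = 1L,
                         tolerance = 0.2) {
  sel <- state$selections[kind == "target"]
  cand <- state$candidates
  expd <- state$expected
  min_ions <- vapply(state$noise_models, `[[`, numeric(1),
                     "median_decoy_count")
  samples <- names(state$noise_models)
  known_tab <- state$identities[status %in%
                                  c("sequenced_here", "feature_propagated")]
  per_sample <- list()
  details <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    eligible <- intersect(
      known_tab[sample_id == s & status == "sequenced_here", consensus_id],
      sel[sample_id == s & origin == "known", consensus_id])
    if (!length(eligible)) {
      per_sample[[s]] <- data.table(sample_id = s, n_masked = 0L,
                                    n_wrong = 0L, fdr = NA_real_)
      next
    }
    set.seed(derive_seed(seed, si))
    masked <- sample(eligible, min(n_mask, length(eligible)))
    wrong <- logical(length(masked))
    new_origin <- character(length(masked))
    outside_v <- logical(length(masked))
    dev_v <- numeric(length(masked))
    new_rt_v <- numeric(length(masked))
    new_mz_v <- numeric(length(masked))
    for (mi in seq_along(masked)) {
      f <- masked[mi]
      known_f <- setdiff(
        known_tab[consensus_id == f, unique(sample_id)], s)
      e <- expd[id == f & sample_id == s]
      # re-express the masked sample's cached candidates relative to the
      # model-predicted center (the frame an unknown sample would use)
      cf <- cand[id == f][, .(sample_id, u, v, count, in_window, dist)]
      rhs <- e$rt_half / state$windows$rt_window
      du <- (e$rt_center - e$rt_center_model) / state$windows$rt_window
      dv <- (e$mz_center - e$mz_center_model) / state$windows$mz_window
      cf[sample_id == s, `:=`(u = u + du, v = v + dv)]
      cf[sample_id == s, `:=`(dist = sqrt(u^2 + v^2),
                              in_window = abs(u) <= rhs & abs(v) <= 1)]
      ef <- expd[id == f]
      offs <- data.table(
        sample_id = ef$sample_id,
        du = (ef$rt_center - ef$rt_center_model) /
          state$windows$rt_window,
        dv = (ef$mz_center - ef$mz_center_model) /
          state$windows$mz_window)
      offs[sample_id == s, c("du", "dv") := 0]  # already re-framed
      resel <- select_window(
        cf, known_samples = known_f, min_ions = min_ions,
        rt_half_std = rhs,
        max_mz_multiple = state$config$transfer$max_mz_multiple %||% 3,
        frame_offsets = offs)
      new <- resel[sample_id == s]
      orig <- sel[consensus_id == f & sample_id == s]
      new_rt <- e$rt_center_model + new$u * state$windows$rt_window
      new_mz <- e$mz_center_model + new$v * state$windows$mz_window
      outside <- abs(new_rt - orig$peak_rt) > e$rt_half |
        abs(new_mz - orig$peak_mz) > e$mz_half
      same_pos <- abs(new_rt - orig$peak_rt) < 1e-9 &
        abs(new_mz - orig$peak_mz) < 1e-12
      new_origin[mi] <- new$origin
      outside_v[mi] <- isTRUE(outside)
      new_rt_v[mi] <- new_rt
      new_mz_v[mi] <- new_mz
      if (!outside && same_pos) {
        wrong[mi] <- FALSE
        next
      }
      q <- extract_quant(state$ion_maps[[s]],
                         list(rt_center = new_rt, rt_half = e$rt_half,
                              mz_center = new_mz, mz_half = e$mz_half),
                         state$noise_models[[s]])
      orig_int <- orig$total_intensity
      dev_int <- if (is.finite(orig_int) && orig_int > 0)
        abs(q$total_intensity - orig_int) / orig_int else
          as.numeric(q$total_intensity > 0)
      dev_v[mi] <- dev_int
      wrong[mi] <- isTRUE(outside) || dev_int > tolerance
    }
    per_sample[[s]] <- data.table(sample_id = s,
                                  n_masked = length(masked),
                                  n_wrong = sum(wrong),
                                  fdr = mean(wrong))
    details[[s]] <- data.table(sample_id = s, consensus_id = masked,
                               wrong = wrong, new_origin = new_origin,
                               outside = outside_v, dev_int = dev_v,
                               new_rt = new_rt_v, new_mz = new_mz_v)
  }
  per_sample <- rbindlist(per_sample)
  pooled <- with(per_sample, sum(n_wrong) / max(1L, sum(n_masked)))
  list(fdr = pooled, per_sample = per_sample,
       details = if (length(details)) rbindlist(details) else NULL)
}

#' Impute missing quantifications from the background-noise model
#'
#' Events with zero extracted ions receive a total intensity drawn from
#' the sample's noise model at their window RT: the model mean plus a
#' resampled model residual (clamped at 0), flagged `imputed`. Imputed
#' cells never claim significance (p = 1). When disabled, events are
#' returned unchanged.
#'
#' @param events quantification-event table (needs `sample_id`,
#'   `rt_center`, `missing`, `total_intensity`, `p_value`, `imputed`).
#' @param noise_models named list of per-sample [fit_noise_model()]
#'   results.
#' @param enabled default `TRUE`.
#' @param seed base seed; each sample imputes with a derived seed.
#' @return the event table with imputed values filled in.
#' @export
impute_missing <- function(events, noise_models, enabled = TRUE,
                           seed = 1L) {
  ev <- copy(as.data.table(events))
  if (!"imputed" %in% names(ev)) ev[, imputed := FALSE]
  if (!enabled || !nrow(ev)) return(ev)
  samples <- names(noise_models)
  for (si in seq_along(samples)) {
    s <- samples[si]
    idx <- which(ev$sample_id == s & ev$missing)
    if (!length(idx)) next
    nm <- noise_models[[s]]
    set.seed(derive_seed(seed, 1000L + si))
    res <- if (length(nm$residuals)) {
      sample(nm$residuals, length(idx), replace = TRUE)
    } else rep(0, length(idx))
    val <- pmax(0, nm$mean_intensity(ev$rt_center[idx]) + res)
    ev[idx, `:=`(total_intensity = val, signal_intensity = 0,
                 background_intensity = val, imputed = TRUE,
                 p_value = 1)]
  }
  ev[]
}
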