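## Alignment windows and per-sample correction models ------------------------

#' Specify alignment-window options
#'
#' Holds the user's window options before resolution: optional hard
#' overrides (`user_fixed_*`, used verbatim) and minimal floors
#' (`user_min_*`, applied when the data-derived window is smaller).
#'
#' @param user_fixed_rt,user_fixed_mz fixed windows (minutes / Th) that
#'   short-circuit estimation, or `NULL`.
#' @param user_min_rt,user_min_mz window floors; defaults 0.2 min and
#'   0.001 Th.
#' @return object of class `AlignmentWindows` (unresolved).
#' @export
alignment_windows <- function(user_fixed_rt = NULL, user_fixed_mz = NULL,
                              user_min_rt = 0.2, user_min_mz = 0.001) {
  w <- list(rt_window = NA_real_, mz_window = NA_real_,
            user_fixed_rt = user_fixed_rt, user_fixed_mz = user_fixed_mz,
            user_min_rt = user_min_rt, user_min_mz = user_min_mz,
            resolved = FALSE)
  class(w) <- "AlignmentWindows"
  w
}

#' @export
print.AlignmentWindows <- function(x, ...) {
  cat(sprintf("<AlignmentWindows> rt = %s min, mz = %s Th%s\n",
              format(x$rt_window), format(x$mz_window),
              if (isTRUE(x$resolved)) "" else " (unresolved)"))
  invisible(x)
}

#' Estimate global RT and m/z alignment windows
#'
#' For every peptide identity key (sequence, modifications, charge)
#' observed in at least two samples, per-sample deviations of RT and
#' calibrated m/z from the key's cross-sample median are pooled as absolute
#' deviations. The RT window is 1.5 x the interquartile range (type-7
#' quantiles) of the pooled absolute RT deviations; the m/z window is 1.0 x
#' the IQR of the pooled absolute m/z deviations. User floors are applied
#' when the data-derived window is smaller; user fixed values short-circuit
#' estimation entirely.
#'
#' @param features combined detected-feature table across samples (see
#'   [read_feature_table()]).
#' @param windows an [alignment_windows()] specification.
#' @return the resolved `AlignmentWindows` (fields `rt_window`,
#'   `mz_window` set, `resolved = TRUE`).
#' @export
estimate_alignment_windows <- function(features,
                                       windows = alignment_windows()) {
  if (!is.null(windows$user_fixed_rt) && !is.null(windows$user_fixed_mz)) {
    windows$rt_window <- windows$user_fixed_rt
    windows$mz_window <- windows$user_fixed_mz
    windows$resolved <- TRUE
    return(windows)
  }
  features <- as.data.table(features)
  seqd <- features[!is.na(sequence)]
  if (nrow(seqd)) {
    seqd <- copy(seqd)
    seqd[, key_id := feature_key(sequence, modifications, charge)]
    shared <- seqd[, .N, by = key_id][N >= 2L, key_id]
    seqd <- seqd[key_id %in% shared]
  }
  if (!nrow(seqd))
    stop("no peptide identity key observed in >= 2 samples; ",
         "set fixed alignment windows (user_fixed_rt / user_fixed_mz)")
  devs <- seqd[, .(rt_dev = abs(rt - median(rt)),
                   mz_dev = abs(mz_calibrated - median(mz_calibrated))),
               by = key_id]
  rt_win <- 1.5 * iqr7(devs$rt_dev)
  mz_win <- 1.0 * iqr7(devs$mz_dev)
  if (!is.null(windows$user_fixed_rt)) rt_win <- windows$user_fixed_rt
  else if (!is.null(windows$user_min_rt))
    rt_win <- max(rt_win, windows$user_min_rt)
  if (!is.null(windows$user_fixed_mz)) mz_win <- windows$user_fixed_mz
  else if (!is.null(windows$user_min_mz))
    mz_win <- max(mz_win, windows$user_min_mz)
  stopifnot(rt_win > 0, mz_win > 0)
  windows$rt_window <- rt_win
  windows$mz_window <- mz_win
  windows$resolved <- TRUE
  windows
}

## -- m/z correction model ----------------------------------------------------

#' Fit the per-sample m/z-error model
#'
#' Random-forest regression (bagged variance-reduction trees; 100 trees, 4
#' candidate predictors per split, minimum terminal node size 100) of the
#' mass-error `dev = mz_uncalibrated - mz_calibrated` on predictors
#' (`rt`, `mz_calibrated`, `charge`, `resolution`), trained on 80% of the
#' sample's features and validated on the remaining 20% (holdout RMSE).
#' With fewer than `min_rows` usable rows the model falls back to the
#' global median deviation.
#'
#' The prediction is the expected deviation of this sample's *observed*
#' (uncalibrated) m/z from the calibrated/reference m/z, i.e. it is added
#' to a consensus reference m/z to locate the sample's ion cloud.
#'
#' @param features detected features of one sample.
#' @param ntree,mtry,min_node forest hyper-parameters.
#' @param min_rows minimum usable rows before falling back (default 200).
#' @param seed RNG seed for the 80/20 split and the forest.
#' @return object of class `MzCorrectionModel` with fields `predict_dev`
#'   (function of a data.frame with `rt`, `mz`, `charge`, `resolution`),
#'   `holdout_rmse`, `fallback` flag and `n_train`.
#' @export
fit_mz_correction <- function(features, ntree = 100L, mtry = 4L,
                              min_node = 100L, min_rows = 200L, seed = 1L) {
  features <- as.data.table(features)
  d <- features[is.finite(mz_uncalibrated) & is.finite(mz_calibrated) &
                  is.finite(rt)]
  d[, dev := mz_uncalibrated - mz_calibrated]
  med_res <- median(d$resolution, na.rm = TRUE)
  if (!is.finite(med_res)) med_res <- 0
  fill_res <- function(r) ifelse(is.finite(r), r, med_res)
  if (nrow(d) < min_rows) {
    if (nrow(d) == 0L)
      warning("no usable features; m/z correction fixed at 0")
    else
      warning(sprintf(paste0("only %d usable features (< %d); falling back",
                             " to global median m/z correction"),
                      nrow(d), min_rows))
    med <- if (nrow(d)) median(d$dev) else 0
    model <- list(predict_dev = function(newdata) rep(med, nrow(newdata)),
                  holdout_rmse = NA_real_, fallback = TRUE,
                  n_train = nrow(d), median_resolution = med_res)
    class(model) <- "MzCorrectionModel"
    return(model)
  }
  set.seed(seed)
  X <- cbind(rt = d$rt, mz = d$mz_calibrated, charge = as.numeric(d$charge),
             resolution = fill_res(d$resolution))
  y <- d$dev
  n <- nrow(X)
  train <- sort(sample.int(n, size = floor(0.8 * n)))
  test <- setdiff(seq_len(n), train)
  forest <- .bagged_forest_train(X[train, , drop = FALSE], y[train],
                                 as.integer(ntree), as.integer(mtry),
                                 as.integer(min_node))
  pred_test <- .bagged_forest_predict(forest, X[test, , drop = FALSE])
  rmse <- sqrt(mean((pred_test - y[test])^2))
  model <- list(
    predict_dev = function(newdata) {
      nd <- as.data.table(newdata)
      Xn <- cbind(rt = nd$rt, mz = nd$mz, charge = as.numeric(nd$charge),
                  resolution = fill_res(nd$resolution %||%
                                          rep(NA_real_, nrow(nd))))
      .bagged_forest_predict(forest, Xn)
    },
    holdout_rmse = rmse, fallback = FALSE, n_train = length(train),
    median_resolution = med_res)
  class(model) <- "MzCorrectionModel"
  model
}

## -- RT deviation model ------------------------------------------------------

#' Fit the per-sample RT-deviation smoother
#'
#' Generalized additive model (thin-plate spline, automatic smoothness
#' selection via `mgcv`) of the deviation `observed RT - reference RT`
#' against the consensus reference RT. Predictions outside the training
#' range are clamped to the boundary value. With fewer than `min_pairs`
#' pairs a constant-median fallback is used.
#'
#' @param rt_ref consensus reference RTs (minutes).
#' @param rt_obs observed feature RTs of this sample at those references.
#' @param min_pairs minimum pairs before falling back (default 10).
#' @return object of class `RtDeviationModel` with `predict_dev(rt)`,
#'   `range`, `fallback`, `residual_sd`.
#' @export
fit_rt_deviation <- function(rt_ref, rt_obs, min_pairs = 10L) {
  ok <- is.finite(rt_ref) & is.finite(rt_obs)
  rt_ref <- rt_ref[ok]; rt_obs <- rt_obs[ok]
  dev <- rt_obs - rt_ref
  if (length(dev) < min_pairs) {
    med <- if (length(dev)) median(dev) else 0
    model <- list(predict_dev = function(rt) rep(med, length(rt)),
                  range = if (length(dev)) range(rt_ref) else c(NA, NA),
                  fallback = TRUE,
                  residual_sd = if (length(dev) > 1) sd(dev) else 0)
    class(model) <- "RtDeviationModel"
    return(model)
  }
  k <- max(5L, min(20L, length(unique(rt_ref)) - 1L))
  fit <- mgcv::gam(dev ~ s(rt_ref, k = k),
                   data = data.frame(rt_ref = rt_ref, dev = dev))
  lo <- min(rt_ref); hi <- max(rt_ref)
  model <- list(
    predict_dev = function(rt) {
      as.numeric(predict(fit, newdata = data.frame(
        rt_ref = pmin(pmax(rt, lo), hi))))
    },
    range = c(lo, hi), fallback = FALSE,
    residual_sd = sd(stats::residuals(fit)))
  class(model) <- "RtDeviationModel"
  model
}

#' Fit all per-sample correction models
#'
#' Convenience wrapper running [fit_mz_correction()] on each sample's raw
#' features and [fit_rt_deviation()] on the (reference RT, observed RT)
#' pairs obtained from the consensus contributions.
#'
#' @param features combined detected-feature table.
#' @param consensus consensus features from [aggregate_features()] (the
#'   `contributions` attribute supplies the RT pairs).
#' @param seed base seed; each sample uses a derived seed.
#' @param ... passed to [fit_mz_correction()].
#' @return named list (by sample) of lists `list(mz, rt)`.
#' @export
fit_correction_models <- function(features, consensus, seed = 1L, ...) {
  features <- as.data.table(features)
  cons <- as.data.table(consensus)[kind == "target" & !is.na(sequence)]
  cons <- cons[, .(key_id = feature_key(sequence, modifications, charge),
                   rt_ref)]
  samples <- sort(unique(features$sample_id))
  models <- lapply(seq_along(samples), function(i) {
    s <- samples[i]
    feats <- features[sample_id == s]
    mzm <- fit_mz_correction(feats, seed = derive_seed(seed, i), ...)
    # RT pairs come from the sample's sequenced features matched by
    # identity key (not only retained contributors), so large smooth
    # drifts are not truncated at the alignment window
    sf <- feats[!is.na(sequence)]
    pairs <- if (nrow(sf)) {
      sf[, key_id := feature_key(sequence, modifications, charge)]
      cons[sf, on = "key_id", nomatch = NULL]
    } else data.table(rt_ref = numeric(), rt = numeric())
    rtm <- fit_rt_deviation(pairs$rt_ref, pairs$rt)
    list(mz = mzm, rt = rtm)
  })
  names(models) <- samples
  models
}

#' Predict the expected DICE window center of a feature in a sample
#'
#' Expected center = (`rt_ref` + RT-model deviation at `rt_ref`,
#' `mz_ref` + m/z-model deviation at (`rt_ref`, `mz_ref`, charge)).
#' Window half-sizes are `rt_peak_width / 2` (RT) and the m/z alignment
#' window (m/z) — identical for every sample of a feature.
#'
#' @param consensus consensus-feature table (any subset of rows).
#' @param sample_models `list(mz, rt)` for one sample
#'   (see [fit_correction_models()]).
#' @param windows resolved [alignment_windows()].
#' @return data.table: `id`, `rt_center`, `mz_center`, `rt_half`,
#'   `mz_half`.
#' @export
predict_feature_windows <- function(consensus, sample_models, windows) {
  cons <- as.data.table(consensus)
  stopifnot(isTRUE(windows$resolved))
  rt_dev <- sample_models$rt$predict_dev(cons$rt_ref)
  mz_dev <- sample_models$mz$predict_dev(data.frame(
    rt = cons$rt_ref, mz = cons$mz_ref, charge = cons$charge,
    resolution = rep(NA_real_, nrow(cons))))
  data.table(id = cons$id,
             rt_center = cons$rt_ref + rt_dev,
             mz_center = cons$mz_ref + mz_dev,
             rt_half = cons$rt_peak_width / 2,
             mz_half = windows$mz_window)
}
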