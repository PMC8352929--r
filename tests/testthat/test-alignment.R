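test_that("alignment windows follow the 1.5x/1.0x IQR rule with floors and overrides", {
  # two samples sharing keys whose absolute RT deviations are exactly
  # {0.0, 0.1, ..., 0.8}: per key the two samples sit at median +- d, so
  # absolute deviations from the key median are d each; construct keys
  # with d = {0.0, 0.1, ..., 0.8} -> pooled abs deviations contain each d
  # twice, and IQR is unchanged by the duplication. Oracle: type-7
  # quantiles of {0..0.8} give IQR 0.4 -> rt_window 1.5 * 0.4 = 0.6.
  d <- seq(0, 0.8, by = 0.1)
  seqs <- sprintf("PEPT%02dK", seq_along(d))
  fA <- make_features("A", seqs, 2L, mz = 500 + seq_along(d),
                      rt = 30 - d)
  fB <- make_features("B", seqs, 2L, mz = 500 + seq_along(d),
                      rt = 30 + d)
  w <- estimate_alignment_windows(rbind(fA, fB),
                                  alignment_windows(user_min_rt = 0.01,
                                                    user_min_mz = 1e-5))
  expect_equal(w$rt_window, 0.6, tolerance = 1e-9)
  expect_true(w$resolved)

  # all deviations identical -> IQR 0 -> floor forced
  f2 <- rbind(make_features("A", seqs, 2L, 500 + seq_along(d), rt = 30),
              make_features("B", seqs, 2L, 500 + seq_along(d), rt = 30))
  w2 <- estimate_alignment_windows(f2, alignment_windows())
  expect_equal(w2$rt_window, 0.2)   # default floor
  expect_equal(w2$mz_window, 0.001)

  # fixed user windows short-circuit the data entirely
  w3 <- estimate_alignment_windows(rbind(fA, fB),
                                   alignment_windows(user_fixed_rt = 0.7,
                                                     user_fixed_mz = 0.02))
  expect_equal(w3$rt_window, 0.7)
  expect_equal(w3$mz_window, 0.02)

  # no shared keys -> instructive error
  expect_error(
    estimate_alignment_windows(make_features("A", "ONLYONCE", 2L, 500, 10),
                               alignment_windows()),
    "fixed")
})

test_that("alignment windows are invariant under relabeling and row permutation", {
  set.seed(5)
  seqs <- sprintf("SEQ%03dR", 1:40)
  f <- rbind(
    make_features("A", seqs, 2L, 500 + 1:40, rt = 30 + rnorm(40, 0, 0.2)),
    make_features("B", seqs, 2L, 500 + 1:40 + rnorm(40, 0, 0.001),
                  rt = 30 + rnorm(40, 0, 0.2)),
    make_features("C", seqs, 2L, 500 + 1:40 + rnorm(40, 0, 0.001),
                  rt = 30 + rnorm(40, 0, 0.2)))
  w1 <- estimate_alignment_windows(f, alignment_windows())
  f2 <- copy(f)[sample(.N)]
  f2[, sample_id := chartr("ABC", "XYZ", sample_id)]
  w2 <- estimate_alignment_windows(f2, alignment_windows())
  expect_equal(w1$rt_window, w2$rt_window)
  expect_equal(w1$mz_window, w2$mz_window)
})

test_that("m/z correction forest recovers constant and smooth ppm errors", {
  set.seed(11)
  n <- 1000
  mz <- runif(n, 400, 900)
  ft <- make_features("A", sprintf("Q%04dK", 1:n), 2L, mz = mz,
                      rt = runif(n, 10, 60),
                      mz_uncal = mz * (1 + 3e-6))  # constant +3 ppm
  m <- fit_mz_correction(ft, seed = 1)
  expect_false(m$fallback)
  pred <- m$predict_dev(data.frame(rt = ft$rt, mz = ft$mz_calibrated,
                                   charge = ft$charge,
                                   resolution = ft$resolution))
  ppm_err <- abs(pred - (ft$mz_uncalibrated - ft$mz_calibrated)) /
    ft$mz_calibrated * 1e6
  expect_lt(median(ppm_err), 0.5)
  expect_lt(m$holdout_rmse, 0.5 * 650e-6)  # < 0.5 ppm at mid-range m/z

  # error = 2 ppm + 1 ppm * sin(rt / 20): holdout RMSE < amplitude / 3
  set.seed(12)
  n <- 5000
  mz <- runif(n, 400, 900); rt <- runif(n, 10, 60)
  ppm <- 2 + sin(rt / 20)
  ft2 <- make_features("A", sprintf("W%05dK", 1:n), 2L, mz = mz, rt = rt,
                       mz_uncal = mz * (1 + ppm * 1e-6))
  m2 <- fit_mz_correction(ft2, seed = 1)
  amplitude <- 3e-6 * 650  # 3 ppm at mid-range m/z, in Th
  expect_lt(m2$holdout_rmse, amplitude / 3)
})

test_that("m/z correction falls back to the median below the row minimum", {
  ft <- make_features("A", sprintf("F%02dK", 1:50), 2L,
                      mz = 500 + 1:50, rt = 1:50,
                      mz_uncal = 500 + 1:50 + 0.002)
  expect_warning(m <- fit_mz_correction(ft, seed = 1), "median")
  expect_true(m$fallback)
  expect_equal(m$predict_dev(data.frame(rt = 5, mz = 505, charge = 2,
                                        resolution = 6e4)),
               0.002, tolerance = 1e-9)
})

test_that("RT deviation smoother recovers zero, linear and sinusoidal drift", {
  rt <- seq(10, 60, length.out = 300)
  m0 <- fit_rt_deviation(rt, rt)       # zero deviation everywhere
  expect_lt(max(abs(m0$predict_dev(seq(10, 60, 1)))), 1e-6)

  m1 <- fit_rt_deviation(rt, rt + 0.01 * rt)   # linear drift 0.01 * rt
  grid <- seq(15, 55, 1)
  slope <- coef(lm(m1$predict_dev(grid) ~ grid))[[2]]
  expect_lt(abs(slope - 0.01) / 0.01, 0.1)

  set.seed(3)
  rt2 <- runif(2000, 10, 60)
  drift <- 0.4 * sin(rt2 / 5)
  m2 <- fit_rt_deviation(rt2, rt2 + drift + rnorm(2000, 0, 0.01))
  resid <- m2$predict_dev(rt2) - drift
  expect_lt(max(abs(resid)), 0.1)

  # extrapolation clamps to the boundary value
  expect_equal(m2$predict_dev(5), m2$predict_dev(min(rt2)))
  expect_equal(m2$predict_dev(99), m2$predict_dev(max(rt2)))

  # too few pairs -> constant median fallback
  m3 <- fit_rt_deviation(1:5, 1:5 + 0.3)
  expect_true(m3$fallback)
  expect_equal(m3$predict_dev(c(1, 99)), c(0.3, 0.3))
})

test_that("predict_feature_windows applies the additive corrections", {
  cons <- data.table(id = c("a", "b"), rt_ref = c(20, 40),
                     mz_ref = c(500, 700), charge = c(2L, 3L),
                     rt_peak_width = c(0.5, 0.3))
  ident <- list(mz = list(predict_dev = function(nd) rep(0, nrow(nd))),
                rt = list(predict_dev = function(rt) rep(0, length(rt))))
  w <- fixed_windows(rt = 0.5, mz = 0.004)
  p0 <- predict_feature_windows(cons, ident, w)
  expect_equal(p0$rt_center, cons$rt_ref)
  expect_equal(p0$mz_center, cons$mz_ref)
  expect_equal(p0$rt_half, cons$rt_peak_width / 2)
  expect_equal(p0$mz_half, rep(0.004, 2))

  shift <- list(mz = list(predict_dev = function(nd) rep(0.001, nrow(nd))),
                rt = list(predict_dev = function(rt) rep(0.2, length(rt))))
  p1 <- predict_feature_windows(cons, shift, w)
  expect_equal(p1$rt_center, cons$rt_ref + 0.2)
  expect_equal(p1$mz_center, cons$mz_ref + 0.001)
})

test_that("correction models shrink deviation dispersion on drifted data", {
  # drift amplitude >> jitter: post-correction IQR <= 0.5 * pre-correction
  ds <- generate_dataset(synthetic_config(
    n_samples = 4L, n_species = 250L, rt_range = c(10, 25),
    mz_range = c(400, 412), noise_ion_density = 0,
    rt_drift_amplitude = 0.6, rt_obs_sigma = 0.02,
    id_dropout_rate = 0.1, seed = 21))
  w <- estimate_alignment_windows(ds$features, alignment_windows())
  cons <- aggregate_features(ds$features, w)
  models <- fit_correction_models(ds$features, cons, seed = 1,
                                  min_rows = 50, min_node = 25)
  pre <- post <- list()
  for (s in names(models)) {
    exp_s <- predict_feature_windows(cons, models[[s]], w)
    tr <- merge(
      merge(exp_s, cons[, .(id, sequence, rt_ref)], by = "id"),
      merge(ds$truth$cells[sample_id == s],
            ds$truth$species[, .(species, sequence)], by = "species"),
      by = "sequence")
    pre[[s]] <- abs(tr$rt_ref - tr$true_rt)
    post[[s]] <- abs(tr$rt_center - tr$true_rt)
  }
  pre <- unlist(pre); post <- unlist(post)
  expect_lt(quantile(post, 0.75), 0.5 * quantile(pre, 0.75))
})
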