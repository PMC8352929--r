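wdd <- fixed_windows(rt = 0.4, mz = 0.002)

test_that("KDE map localizes a tight cluster; empty region gives a zero map", {
  set.seed(2)
  map <- make_map(rt = rnorm(100, 50.0, 0.01),
                  mz = rnorm(100, 500.000, 0.0002))
  km <- compute_kde_map(map, c(50.0, 500.000), wdd, rt_half = 0.25)
  expect_s3_class(km, "KdeMap")
  expect_true(all(km$z >= 0))
  ij <- which(km$z == max(km$z), arr.ind = TRUE)[1, ]
  # global maximum within one grid cell of the cluster center
  cell_u <- km$u[2] - km$u[1]; cell_v <- km$v[2] - km$v[1]
  expect_lte(abs(km$u[ij[1]] - 0), cell_u * 1.5)
  expect_lte(abs(km$v[ij[2]] - 0), cell_v * 1.5)

  empty <- compute_kde_map(map, c(10, 400), wdd, rt_half = 0.25)
  expect_true(all(empty$z == 0))
  expect_identical(nrow(detect_peaks(empty, min_ions = 0)), 0L)
})

test_that("KDE grid values match a brute-force kernel evaluation", {
  set.seed(3)
  map <- make_map(rt = rnorm(60, 50, 0.05), mz = rnorm(60, 500, 5e-4))
  km <- compute_kde_map(map, c(50, 500), wdd, rt_half = 0.2,
                        resolution = 25)
  hx <- requant:::kde_bandwidth(km$ions$u)
  hy <- requant:::kde_bandwidth(km$ions$v)
  for (pt in list(c(3, 4), c(13, 13), c(20, 7))) {
    ref <- brute_kde(km$ions$u, km$ions$v, hx, hy,
                     km$u[pt[1]], km$v[pt[2]])
    expect_equal(km$z[pt[1], pt[2]], ref, tolerance = 1e-8)
  }
})

test_that("doubling KDE resolution moves the argmax by at most one coarse cell", {
  set.seed(4)
  for (k in 1:5) {
    map <- make_map(rt = rnorm(80, 50 + runif(1, -0.1, 0.1), 0.04),
                    mz = rnorm(80, 500 + runif(1, -5e-4, 5e-4), 3e-4))
    k1 <- compute_kde_map(map, c(50, 500), wdd, 0.2, resolution = 50)
    k2 <- compute_kde_map(map, c(50, 500), wdd, 0.2, resolution = 100)
    a1 <- which(k1$z == max(k1$z), arr.ind = TRUE)[1, ]
    a2 <- which(k2$z == max(k2$z), arr.ind = TRUE)[1, ]
    cell_u <- k1$u[2] - k1$u[1]; cell_v <- k1$v[2] - k1$v[1]
    expect_lte(abs(k1$u[a1[1]] - k2$u[a2[1]]), cell_u)
    expect_lte(abs(k1$v[a1[2]] - k2$v[a2[2]]), cell_v)
  }
})

test_that("detect_peaks finds clusters, applies the count/in-window rule, ranks by distance", {
  set.seed(5)
  # one cluster at the expected center -> exactly one candidate
  map1 <- make_map(rt = rnorm(50, 50, 0.03), mz = rnorm(50, 500, 3e-4))
  km1 <- compute_kde_map(map1, c(50, 500), wdd, 0.2)
  p1 <- detect_peaks(km1, min_ions = 5)
  expect_identical(nrow(p1), 1L)
  expect_gte(p1$count, 45L)
  expect_true(p1$in_window)

  # two separated clusters, the nearer ranked first
  map2 <- make_map(rt = c(rnorm(50, 50.05, 0.02), rnorm(50, 50.6, 0.02)),
                   mz = c(rnorm(50, 500.0005, 2e-4),
                          rnorm(50, 500.0030, 2e-4)))
  km2 <- compute_kde_map(map2, c(50, 500), wdd, 0.2)
  p2 <- detect_peaks(km2, min_ions = 5)
  expect_identical(nrow(p2), 2L)
  expect_lt(p2$dist[1], p2$dist[2])
  expect_lt(abs(p2$rt[1] - 50.05), 0.1)
  expect_lt(abs(p2$rt[2] - 50.6), 0.1)

  # a sparse far cluster below min_ions and outside the window: dropped
  map3 <- make_map(rt = c(rnorm(50, 50, 0.02), rnorm(3, 50.7, 0.01)),
                   mz = c(rnorm(50, 500, 2e-4), rnorm(3, 500.004, 1e-4)))
  km3 <- compute_kde_map(map3, c(50, 500), wdd, 0.2)
  p3 <- detect_peaks(km3, min_ions = 5)
  expect_identical(nrow(p3), 1L)
  expect_true(all(abs(p3$rt - 50) < 0.1))
})

test_that("select_window picks nearest valid candidate for known samples", {
  mi <- c(A = 3, B = 3)
  cand <- data.table(
    sample_id = c("A", "A", "B"),
    u = c(0.15, 1.2, 0.1), v = c(0.1, 1.5, 0),
    count = c(50L, 60L, 40L), in_window = c(TRUE, FALSE, TRUE),
    dist = c(0.2, 1.8, 0.1))
  sel <- select_window(cand, known_samples = c("A", "B"), min_ions = mi,
                       rt_half_std = 0.6)
  expect_identical(sel[sample_id == "A", origin], "known")
  expect_equal(sel[sample_id == "A", u], 0.15)   # nearer valid one
  expect_identical(sel[sample_id == "B", origin], "known")
})

test_that("select_window transfers within limits and falls back otherwise", {
  mi <- c(A = 2, B = 2)
  known_cand <- data.table(sample_id = "A", u = 0.1, v = 0.2, count = 50L,
                           in_window = TRUE, dist = 0.22)
  # unknown sample with candidate at dmz = 2.5 windows -> transferred
  c1 <- rbind(known_cand,
              data.table(sample_id = "B", u = 0.2, v = 2.5, count = 30L,
                         in_window = FALSE, dist = 2.51))
  s1 <- select_window(c1, "A", mi, rt_half_std = 0.6)
  expect_identical(s1[sample_id == "B", origin], "transferred")
  expect_equal(s1[sample_id == "B", v], 2.5)
  # at 3.5 windows -> fallback to the expected window
  c2 <- rbind(known_cand,
              data.table(sample_id = "B", u = 0.2, v = 3.5, count = 30L,
                         in_window = FALSE, dist = 3.51))
  s2 <- select_window(c2, "A", mi, rt_half_std = 0.6)
  expect_identical(s2[sample_id == "B", origin], "expected_fallback")
  expect_equal(s2[sample_id == "B", .(u, v)], data.table(u = 0, v = 0))
  # RT beyond one alignment window -> fallback
  c3 <- rbind(known_cand,
              data.table(sample_id = "B", u = 1.4, v = 0.2, count = 30L,
                         in_window = FALSE, dist = 1.41))
  s3 <- select_window(c3, "A", mi, rt_half_std = 0.6)
  expect_identical(s3[sample_id == "B", origin], "expected_fallback")
  # no candidates anywhere -> fallback everywhere
  s4 <- select_window(known_cand[0L], "A", mi, rt_half_std = 0.6)
  expect_identical(unique(s4$origin), "expected_fallback")
})

test_that("select_window blocks transfers onto distinct rejected peaks", {
  mi <- c(A = 3, B = 3)
  cand <- rbind(
    data.table(sample_id = "A", u = 0.05, v = 0.1, count = 60L,
               in_window = TRUE, dist = 0.11),
    data.table(sample_id = "A", u = 0.4, v = 2.2, count = 25L,
               in_window = FALSE, dist = 2.24),   # distinct rejected peak
    data.table(sample_id = "B", u = 0.45, v = 2.3, count = 20L,
               in_window = FALSE, dist = 2.34),   # matches the rejected one
    data.table(sample_id = "B", u = 0.1, v = 0.3, count = 18L,
               in_window = TRUE, dist = 0.32))
  sel <- select_window(cand, "A", mi, rt_half_std = 0.6)
  expect_identical(sel[sample_id == "B", origin], "transferred")
  expect_equal(sel[sample_id == "B", v], 0.3)  # blocked off the 2.3 one
})

test_that("frame offsets re-express known peaks for the transfer matching", {
  mi <- c(A = 2, B = 2)
  # A's candidate sits at +0.1 in its own frame, but its frame is offset
  # by +0.5 from the model frame -> consensus location at 0.6
  cand <- rbind(
    data.table(sample_id = "A", u = 0.1, v = 0, count = 50L,
               in_window = TRUE, dist = 0.1),
    data.table(sample_id = "B", u = 0.62, v = 0, count = 30L,
               in_window = FALSE, dist = 0.62),
    data.table(sample_id = "B", u = 0.05, v = 0, count = 3L,
               in_window = TRUE, dist = 0.05))
  offs <- data.table(sample_id = c("A", "B"), du = c(0.5, 0), dv = c(0, 0))
  sel <- select_window(cand, "A", mi, rt_half_std = 0.7,
                       frame_offsets = offs)
  # with offsets the 0.62 candidate matches the consensus (0.6); without
  # them the noise candidate at 0.05 would win
  expect_equal(sel[sample_id == "B", u], 0.62)
  sel0 <- select_window(cand, "A", mi, rt_half_std = 0.7)
  expect_equal(sel0[sample_id == "B", u], 0.05)
})

test_that("extract_quant counts, sums and splits signal against the noise threshold", {
  map <- make_map(rt = rep(50, 5), mz = rep(500.0005, 5),
                  intensity = c(10, 20, 30, 40, 50))
  noise <- list(mean_intensity = function(rt) rep(25, length(rt)),
                sd_intensity = 5)
  q <- extract_quant(map, list(rt_center = 50, rt_half = 0.2,
                               mz_center = 500, mz_half = 0.001), noise)
  # threshold 25 + 2*5 = 35 -> signal {40, 50} = 90, background 60
  expect_identical(q$ion_count, 5L)
  expect_equal(q$total_intensity, 150)
  expect_equal(q$signal_intensity, 90)
  expect_equal(q$background_intensity, 60)
  expect_false(q$missing)

  # empty window -> flagged missing
  q0 <- extract_quant(map, list(rt_center = 10, rt_half = 0.1,
                                mz_center = 400, mz_half = 0.001), noise)
  expect_identical(q0$ion_count, 0L)
  expect_true(q0$missing)

  # all ions below threshold -> signal 0, total > 0
  hi <- list(mean_intensity = function(rt) rep(1e3, length(rt)),
             sd_intensity = 1)
  q1 <- extract_quant(map, list(rt_center = 50, rt_half = 0.2,
                                mz_center = 500, mz_half = 0.001), hi)
  expect_equal(q1$signal_intensity, 0)
  expect_equal(q1$total_intensity, 150)
  expect_equal(q1$signal_intensity + q1$background_intensity,
               q1$total_intensity)
})

test_that("extract_quant equals a brute-force scan on random windows", {
  set.seed(9)
  n <- 2000
  map <- make_map(runif(n, 0, 30), runif(n, 400, 420),
                  rlnorm(n, log(1e4), 1))
  for (k in 1:100) {
    rt_c <- runif(1, 0, 30); mz_c <- runif(1, 400, 420)
    rt_h <- runif(1, 0.05, 1); mz_h <- runif(1, 1e-3, 0.5)
    q <- extract_quant(map, list(rt_center = rt_c, rt_half = rt_h,
                                 mz_center = mz_c, mz_half = mz_h))
    ref <- brute_extract(map, rt_c - rt_h, rt_c + rt_h,
                         mz_c - mz_h, mz_c + mz_h)
    expect_identical(q$ion_count, as.integer(ref$n))
    expect_equal(q$total_intensity, ref$total)
  }
})

test_that("filter_outlier_peaks removes dispersed features and deviating samples", {
  set.seed(10)
  w <- fixed_windows(rt = 0.3, mz = 0.002)
  n_feat <- 40; samples <- sprintf("S%d", 1:6)
  sel <- CJ(consensus_id = sprintf("CF%03d", 1:n_feat),
            sample_id = samples)
  sel[, `:=`(kind = "target", parent_id = NA_character_, charge = 2L,
             origin = "known",
             peak_rt = 30 + rnorm(.N, 0, 0.01),
             peak_mz = 500 + rnorm(.N, 0, 1e-4))]
  base <- filter_outlier_peaks(copy(sel), w)
  expect_identical(length(base$removed_features), 0L)
  expect_identical(nrow(base$excluded_cells), 0L)

  # one sample of one feature shifted by 10 windows -> that cell excluded
  sel2 <- copy(sel)
  sel2[consensus_id == "CF001" & sample_id == "S1",
       peak_rt := peak_rt + 10 * w$rt_window]
  f2 <- filter_outlier_peaks(sel2, w)
  expect_identical(f2$excluded_cells$consensus_id, "CF001")
  expect_identical(f2$excluded_cells$sample_id, "S1")
  expect_false("CF001" %in% f2$removed_features)

  # a feature with hugely dispersed peaks across samples -> removed
  sel3 <- copy(sel)
  sel3[consensus_id == "CF002",
       peak_rt := 30 + seq(-1.5, 1.5, length.out = 6)]
  f3 <- filter_outlier_peaks(sel3, w)
  expect_true("CF002" %in% f3$removed_features)

  # isotope disagreement excludes the sample
  sel4 <- copy(sel)
  iso <- copy(sel)[, `:=`(parent_id = consensus_id,
                          consensus_id = paste0("I_", consensus_id),
                          kind = "isotope_plus1",
                          peak_mz = peak_mz + 1.002 / 2)]
  iso[parent_id == "CF003" & sample_id == "S2",
      peak_mz := peak_mz + 5 * w$mz_window]
  f4 <- filter_outlier_peaks(rbind(sel4, iso), w)
  expect_true(nrow(f4$excluded_cells[
    consensus_id == "CF003" & sample_id == "S2" &
      reason == "isotope_mismatch"]) == 1L)
})
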