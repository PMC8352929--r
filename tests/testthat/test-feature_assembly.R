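w55 <- fixed_windows(rt = 0.6, mz = 0.005)

test_that("aggregate_features takes medians and excludes out-of-window contributors", {
  f <- rbind(
    make_features(c("A", "B", "C"), "AAAAK", 2L,
                  mz = c(500.000, 500.001, 500.002),
                  rt = c(50.0, 50.1, 50.2)),
    make_features("D", "AAAAK", 2L, mz = 500.001, rt = 52.0))  # outlier
  cons <- aggregate_features(f, w55)
  expect_identical(nrow(cons), 1L)
  expect_equal(cons$rt_ref, 50.1)
  expect_equal(cons$mz_ref, 500.001)
  contrib <- attr(cons, "contributions")
  expect_identical(nrow(contrib), 3L)             # rt 52.0 excluded
  expect_false("D" %in% contrib$sample_id)
  expect_identical(cons$n_samples, 3L)
})

test_that("aggregate_features attaches in-window unknown features to the nearest consensus", {
  f <- rbind(
    make_features(c("A", "B", "C"), "CCCCK", 2L, mz = 500.000, rt = 50.0),
    make_features("D", NA_character_, 2L, mz = 500.0003, rt = 50.05),
    make_features("D", NA_character_, 2L, mz = 500.2, rt = 50.05),  # far
    make_features("D", NA_character_, 3L, mz = 500.0003, rt = 50.05)) # charge
  w <- fixed_windows(rt = 0.6, mz = 0.001)
  cons <- aggregate_features(f, w)
  contrib <- attr(cons, "contributions")
  expect_identical(nrow(cons), 1L)
  expect_identical(nrow(contrib), 4L)
  expect_identical(contrib[sequenced == FALSE, sample_id], "D")
  # identity propagation labels follow the contribution structure
  lab <- propagate_identities(cons, samples = c("A", "B", "C", "D", "E"))
  expect_identical(lab[sample_id == "A", status], "sequenced_here")
  expect_identical(lab[sample_id == "D", status], "feature_propagated")
  expect_identical(lab[sample_id == "E", status], "to_recover_by_ion_PIP")
})

test_that("every detected feature contributes to at most one consensus", {
  set.seed(8)
  ds <- generate_dataset(tiny_synth_config(seed = 31))
  w <- estimate_alignment_windows(ds$features, alignment_windows())
  cons <- aggregate_features(ds$features, w)
  contrib <- attr(cons, "contributions")
  expect_lte(max(table(contrib$feature_id)), 1L)
  # aggregation is invariant to input row order
  perm <- copy(ds$features)[sample(.N)]
  cons2 <- aggregate_features(perm, w)
  o1 <- cons[order(sequence, charge)]
  o2 <- cons2[order(sequence, charge)]
  expect_equal(o1$rt_ref, o2$rt_ref)
  expect_equal(o1$mz_ref, o2$mz_ref)
  expect_equal(o1$rt_peak_width, o2$rt_peak_width)
})

test_that("merge_overlapping merges within delta mass and RT overlap, transitively", {
  f <- rbind(
    make_features("A", "MMMMK", 2L, mz = 500.0000, rt = 30, rt_peak_width = 0.4),
    make_features("B", "MMMMK", 2L, mz = 500.0000, rt = 30, rt_peak_width = 0.4),
    make_features("A", NA, 2L, mz = 500.0015, rt = 30.1, rt_peak_width = 0.4),
    make_features("B", NA, 2L, mz = 500.0015, rt = 30.1, rt_peak_width = 0.4),
    make_features("A", NA, 2L, mz = 500.0029, rt = 30.2, rt_peak_width = 0.4),
    make_features("B", NA, 2L, mz = 500.0029, rt = 30.2, rt_peak_width = 0.4),
    make_features("A", "GGGGR", 2L, mz = 500.0100, rt = 30, rt_peak_width = 0.4),
    make_features("B", "GGGGR", 2L, mz = 500.0100, rt = 30, rt_peak_width = 0.4))
  w <- fixed_windows(rt = 0.2, mz = 0.0001)  # tight: no unknown attachment
  cons <- aggregate_features(f, w, aggregate_unknown = TRUE)
  expect_identical(nrow(cons), 4L)
  merged <- merge_overlapping(cons, delta_mass = 0.002)
  # chain A~B, B~C merges {500.0000, 500.0015, 500.0029} although the
  # extremes are 0.0029 apart (union-find closure); GGGGR at +0.010 stays
  expect_identical(nrow(merged), 2L)
  m1 <- merged[sequence == "MMMMK"]
  expect_identical(attr(merged, "contributions")[consensus_id == m1$id, .N],
                   6L)
  expect_identical(nrow(merged[sequence == "GGGGR"]), 1L)
})

test_that("merge_overlapping never merges conflicting sequences", {
  f <- rbind(
    make_features(c("A", "B"), "AATTK", 2L, mz = 500.0000, rt = 30),
    make_features(c("A", "B"), "TTAAK", 2L, mz = 500.0010, rt = 30))
  w <- fixed_windows(rt = 0.3, mz = 0.0005)
  cons <- aggregate_features(f, w)
  merged <- merge_overlapping(cons, delta_mass = 0.002)
  expect_identical(nrow(merged), 2L)
  expect_identical(length(attr(merged, "merge_conflicts")), 1L)
})

test_that("decoys sit at +5 windows and inherit the parent's width and samples", {
  f <- make_features(c("A", "B"), "DDDDK", 2L, mz = 500, rt = 50,
                     rt_peak_width = 0.44)
  w <- fixed_windows(rt = 0.5, mz = 0.005)
  cons <- aggregate_features(f, w)
  dec <- generate_decoys(cons, w, offset_multiplier = 5)
  expect_identical(nrow(dec), 1L)
  expect_equal(dec$rt_ref, 52.5)
  expect_equal(dec$mz_ref, 500.025)
  expect_equal(dec$rt_peak_width, cons$rt_peak_width)
  expect_identical(dec$parent_id, cons$id)
  expect_identical(dec$kind, "decoy")
})

test_that("decoys colliding with a target window are shifted until free", {
  # second target placed exactly where the first decoy would land
  f <- rbind(make_features(c("A", "B"), "EEEEK", 2L, mz = 500.000, rt = 50,
                           rt_peak_width = 0.5),
             make_features(c("A", "B"), "FFFFK", 2L, mz = 500.025, rt = 52.5,
                           rt_peak_width = 0.5))
  w <- fixed_windows(rt = 0.5, mz = 0.005)
  cons <- aggregate_features(f, w)
  dec <- generate_decoys(cons, w)
  d1 <- dec[parent_id == cons[sequence == "EEEEK", id]]
  # oracle: scan +1-window steps until no target window overlaps
  tgt <- cons[, .(rt_lo = rt_ref - rt_peak_width / 2,
                  rt_hi = rt_ref + rt_peak_width / 2,
                  mz_lo = mz_ref - w$mz_window, mz_hi = mz_ref + w$mz_window)]
  mz_try <- 500.025
  repeat {
    hit <- tgt[rt_lo <= 52.75 & 52.25 <= rt_hi &
                 mz_lo <= mz_try + w$mz_window & mz_try - w$mz_window <= mz_hi]
    if (!nrow(hit)) break
    mz_try <- mz_try + w$mz_window
  }
  expect_gt(d1$mz_ref, 500.025)
  expect_equal(d1$mz_ref, mz_try)
  # bookkeeping: every target got exactly one decoy
  expect_identical(nrow(dec), nrow(cons))
})

test_that("isotope companions sit at +1.002/charge with unchanged RT", {
  f <- rbind(make_features("A", "HHHHK", 2L, mz = 500.000, rt = 50),
             make_features("A", "IIIIK", 1L, mz = 600.000, rt = 20))
  cons <- aggregate_features(f, w55)
  iso <- generate_isotope_features(cons)
  expect_identical(nrow(iso), 2L)
  i2 <- iso[parent_id == cons[sequence == "HHHHK", id]]
  i1 <- iso[parent_id == cons[sequence == "IIIIK", id]]
  expect_equal(i2$mz_ref, 500.501)
  expect_equal(i1$mz_ref, 601.002)
  expect_equal(iso$rt_ref, cons[match(iso$parent_id, id), rt_ref])
  expect_identical(attr(iso, "n_skipped"), 0L)
})

test_that("decoy/isotope bookkeeping is exact on synthetic data", {
  ds <- generate_dataset(tiny_synth_config(seed = 32))
  w <- estimate_alignment_windows(ds$features, alignment_windows())
  cons <- merge_overlapping(aggregate_features(ds$features, w))
  dec <- suppressWarnings(generate_decoys(cons, w))
  iso <- generate_isotope_features(cons)
  n_dropped <- nrow(cons) - nrow(dec)
  expect_gte(n_dropped, 0L)
  expect_identical(nrow(iso) + attr(iso, "n_skipped"), nrow(cons))
})
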