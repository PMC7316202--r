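mk_ecg <- function(r) {
  data.frame(beat_id = seq_along(r), p = r - 204, q = r - 30, r = r,
             s = r + 31, t = r + 288, qrs_on = r - 52, qrs_off = r + 53)
}
mk_ppg <- function(dp, dn_na = FALSE) {
  data.frame(beat_id = seq_along(dp), sp = dp - 300,
             dn = if (dn_na) NA_integer_ else dp - 120,
             dp = dp, eb = dp + 260)
}

test_that("the canonical feature set is exactly the 5/7/20 partition", {
  expect_length(feature_names(), 32)
  expect_length(feature_names("ecg"), 5)
  expect_length(feature_names("ppg"), 7)
  expect_length(feature_names("cross"), 20)
  expect_setequal(feature_names(),
                  c(feature_names("ecg"), feature_names("ppg"),
                    feature_names("cross")))
  expect_false(anyDuplicated(feature_names()) > 0)
})

test_that("beats pair by back-tracing the latest R before each DP", {
  pairs <- pair_beats(mk_ecg(c(100, 1300)), mk_ppg(c(350, 1560)))
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$r, c(100, 1300))
  expect_equal(pairs$dp, c(350, 1560))

  # a DP with no preceding R is dropped
  dropped <- pair_beats(mk_ecg(100), mk_ppg(50))
  expect_equal(nrow(dropped), 0)
  expect_equal(attr(dropped, "n_dropped_ppg"), 1)

  # two Rs, one later DP: the later R wins and the earlier stays unpaired
  late <- pair_beats(mk_ecg(c(100, 1300)), mk_ppg(1560))
  expect_equal(nrow(late), 1)
  expect_equal(late$r, 1300)
  expect_equal(attr(late, "n_unpaired_ecg"), 1)

  # an R already claimed cannot pair twice
  greedy <- pair_beats(mk_ecg(100), mk_ppg(c(350, 500)))
  expect_equal(nrow(greedy), 1)
})

test_that("per-beat features are index differences in seconds", {
  # sp = dp - 300, so dp 720 puts SP at 420: PAT = (420 - 120)/1200
  pairs <- pair_beats(mk_ecg(c(120, 1320)), mk_ppg(c(720, 1920)))
  fm <- feature_matrix(pairs, fs = 1200)
  expect_identical(names(fm), feature_names())
  expect_equal(fm$Tqrs[1], (53 + 52) / 1200)
  expect_equal(fm$T_RN2[1], 0.25)        # R 120 -> SP 420 at 1200 Hz
  expect_equal(fm$Trr[1], 1)
  expect_true(is.na(fm$Trr[2]))          # inter-beat features end at last beat
  expect_true(is.na(fm$Tbb[2]) && is.na(fm$Taa[2]))
  expect_true(all(fm[1, !is.na(fm[1, ])] >= 0))
})

test_that("a missing dicrotic notch nulls exactly the DN features", {
  pairs <- pair_beats(mk_ecg(120), mk_ppg(720, dn_na = TRUE))
  fm <- feature_matrix(pairs, fs = 1200)
  dn_feats <- c("Tn1b", "Tn2n1", paste0("T_", c("P", "Q", "R", "S", "T"), "N1"))
  expect_true(all(is.na(fm[1, dn_feats])))
  other <- setdiff(feature_names(), c(dn_feats, "Trr", "Tbb", "Taa"))
  expect_false(anyNA(fm[1, other]))
})

test_that("the mean +/- SD filter removes detection outliers once", {
  expect_equal(robust_mean(c(1, 2, 3, 100)), 2)
  expect_equal(robust_mean(c(5, 5, 5)), 5)
  expect_equal(robust_mean(c(2, 4)), 3)
  expect_warning(out <- robust_mean(c(NA, NA)), "missing")
  expect_true(is.na(out))
  # idempotence: a single surviving mean passes through unchanged
  set.seed(51)
  for (rep in 1:20) {
    v <- rnorm(30)
    expect_equal(robust_mean(robust_mean(v)), robust_mean(v))
  }
})

test_that("segment aggregation reproduces programmed intervals", {
  prof <- subject_profile(hr_mean = 75, hr_jitter = 0.02, pat = 0.25,
                          noise_snr = Inf, seed = 5)
  rec <- synth_paired(prof, 80)
  fv <- aggregate_segment(rec$ecg, rec$ppg)
  expect_s3_class(fv, "feature_vector")
  expect_identical(names(fv), feature_names())
  expect_gte(attr(fv, "n_pairs"), 60)

  expect_lt(abs(fv[["T_RN2"]] - 0.25), 0.010)   # programmed PAT
  truth <- colMeans(rec$truth$features, na.rm = TRUE)
  # every interval within the coarsest native sampling period (1/75 s);
  # QRS width excepted: its onset/offset are threshold conventions whose
  # placement shifts when the narrow Q/S flanks pass through the 200 Hz
  # native grid
  for (f in setdiff(feature_names(), "Tqrs")) {
    expect_lt(abs(fv[[f]] - truth[[f]]), 1 / 75)
  }
  expect_lt(abs(fv[["Tqrs"]] - truth[["Tqrs"]]), 0.030)
})

test_that("segments shorter than settling plus analysis are rejected", {
  prof <- quiet_profile(seed = 6)
  rec <- synth_paired(prof, 40)
  expect_error(aggregate_segment(rec$ecg, rec$ppg), "at least 90000")
})

test_that("sparse corrupted beats barely move the aggregated features", {
  prof <- subject_profile(hr_mean = 75, hr_jitter = 0.02, noise_snr = 30,
                          seed = 8)
  rec <- synth_paired(prof, 80)
  clean <- aggregate_segment(rec$ecg, rec$ppg)

  # corrupt ~5% of beats with large spikes on both channels
  ecg2 <- rec$ecg; ppg2 <- rec$ppg
  spikes <- rec$truth$ecg$r[c(12, 30, 48, 66)] + 350L
  for (s in spikes) {
    idx <- s:(s + 6)
    ecg2$samples[idx] <- ecg2$samples[idx] + 1.2
    ppg2$samples[idx + 100L] <- ppg2$samples[idx + 100L] - 1.5
  }
  dirty <- aggregate_segment(ecg2, ppg2)
  rel <- abs(dirty - clean) / pmax(abs(clean), 1e-9)
  expect_lt(max(rel), 0.02)
})
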