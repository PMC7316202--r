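test_that("a clean single pulse is delineated to within sampling tolerance", {
  g <- synth_ppg(quiet_profile(hr = 60, seed = 3), 10, fs = 1200)
  tr <- g$truth
  st <- tr$eb[5] - 750L
  det <- detect_ppg_beat(signal_window(g$stream, st, 1500L))
  expect_true(det$ok)
  got <- det$fiducials + st - 1L
  truth <- unlist(tr[5, c("sp", "dn", "dp", "eb")])
  expect_lte(abs(got[["eb"]] - truth[["eb"]]), 24)  # 20 ms
  expect_lte(abs(got[["sp"]] - truth[["sp"]]), 36)  # 30 ms
  expect_lte(abs(got[["dp"]] - truth[["dp"]]), 36)
  expect_lte(abs(got[["dn"]] - truth[["dn"]]), 36)
  expect_true(got[["sp"]] < got[["dn"]] && got[["dn"]] < got[["dp"]] &&
              got[["dp"]] < got[["eb"]])
})

test_that("degenerate and notchless pulses are handled as specified", {
  const <- detect_ppg_beat(rep(1.5, 256))
  expect_false(const$ok)

  # dicrotic amplitude zero: the beat is kept but DN is missing
  pm <- default_ppg_morphology()
  pm$dn_amp <- 0
  prof <- quiet_profile(hr = 60, seed = 4, ppg_morph = pm)
  g <- synth_ppg(prof, 10, fs = 1200)
  expect_true(all(is.na(g$truth$dn)))
  st <- g$truth$eb[4] - 750L
  det <- detect_ppg_beat(signal_window(g$stream, st, 1500L))
  expect_true(det$ok)
  expect_true(is.na(det$fiducials[["dn"]]))
})

test_that("PPG window validity needs more flanking maxima before the anchor", {
  pol <- window_policy()
  before4 <- c(100, 200, 300, 400); after3 <- c(700, 800, 900)
  expect_true(check_ppg_window(1000, 500, c(before4, after3), pol)$valid)

  only3 <- check_ppg_window(1000, 500, c(100, 200, 300, 700, 800, 900), pol)
  expect_false(only3$valid); expect_equal(only3$reason, "MMT before")

  off <- check_ppg_window(1000, 200, c(before4, after3), pol)
  expect_false(off$valid); expect_equal(off$reason, "vicinity")
})

test_that("adaptive window size follows the pulse period", {
  pol <- window_policy()
  g <- synth_ppg(subject_profile(hr_mean = 72, hr_jitter = 0,
                                 noise_snr = Inf, seed = 5), 10, fs = 1200)
  expect_equal(estimate_ppg_window_size(g$stream, 1, pol), 1250,
               tolerance = 0.02)
  gj <- synth_ppg(subject_profile(hr_mean = 72, hr_jitter = 0.1,
                                  noise_snr = Inf, seed = 6), 10, fs = 1200)
  est <- estimate_ppg_window_size(gj$stream, 1, pol)
  expect_gt(est, 0.85 * 1250)
  expect_lt(est, 1.15 * 1250)
  flat <- signal_stream(rep(0, 4000), 1200, "ppg")
  expect_equal(estimate_ppg_window_size(flat, 1, pol), pol$fwwt_size)
})

test_that("continuous pulse delineation tracks the programmed beats", {
  g <- synth_ppg(quiet_profile(hr = 72, snr = 30, seed = 11), 60, fs = 1200)
  det <- detect_ppg(g$stream)
  expect_gte(nrow(det), nrow(g$truth) - 3)
  expect_lte(nrow(det), nrow(g$truth) + 2)
  errs <- match_beats(det, g$truth, "eb", 24, "eb")
  expect_gte(mean(!is.na(errs$eb)), 0.95)
  # ordering invariant for every emitted beat (dn may be missing)
  ok <- det$sp < det$dp & det$dp < det$eb &
    (is.na(det$dn) | (det$sp < det$dn & det$dn < det$dp))
  expect_true(all(ok))
  expect_true(all(diff(det$eb) > 0))
})

test_that("flat-line and mid-beat starts behave gracefully", {
  flat <- signal_stream(rep(1, 30000), 1200, "ppg")
  expect_equal(nrow(detect_ppg(flat)), 0)

  # stream beginning mid-beat: first emitted beat is a complete cycle
  g <- synth_ppg(quiet_profile(hr = 72, snr = 30, seed = 12), 30, fs = 1200)
  cut <- signal_stream(g$stream$samples[-(1:500)], 1200, "ppg")
  det <- detect_ppg(cut)
  expect_gt(nrow(det), 0)
  expect_true(all(det$sp < det$dp & det$dp < det$eb))
  expect_gte(det$sp[1], 1)
})

test_that("detection indices ignore amplitude scale and DC offset", {
  g <- synth_ppg(quiet_profile(hr = 80, snr = 30, seed = 13), 30, fs = 1200)
  det1 <- detect_ppg(g$stream)
  scaled <- signal_stream(0.31 * g$stream$samples + 4, 1200, "ppg")
  det2 <- detect_ppg(scaled)
  expect_equal(det1$eb, det2$eb)
  expect_equal(det1$sp, det2$sp)
})
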