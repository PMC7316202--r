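test_that("a clean single beat is delineated to within sampling tolerance", {
  g <- synth_ecg(quiet_profile(hr = 60, seed = 3), 10, fs = 1200)
  tr <- g$truth
  st <- tr$r[5] - 750L
  det <- detect_ecg_beat(signal_window(g$stream, st, 1500L))
  expect_true(det$ok)
  got <- det$fiducials + st - 1L
  truth <- unlist(tr[5, c("p", "q", "r", "s", "t", "qrs_on", "qrs_off")])
  expect_lte(abs(got[["r"]] - truth[["r"]]), 2)
  expect_lte(abs(got[["q"]] - truth[["q"]]), 12)   # 10 ms
  expect_lte(abs(got[["s"]] - truth[["s"]]), 12)
  expect_lte(abs(got[["p"]] - truth[["p"]]), 36)   # 30 ms
  expect_lte(abs(got[["t"]] - truth[["t"]]), 36)
  expect_lte(abs(got[["qrs_on"]] - truth[["qrs_on"]]), 12)
  expect_lte(abs(got[["qrs_off"]] - truth[["qrs_off"]]), 12)
  f <- got
  expect_true(f[["p"]] < f[["qrs_on"]] && f[["qrs_on"]] < f[["q"]] &&
              f[["q"]] < f[["r"]] && f[["r"]] < f[["s"]] &&
              f[["s"]] < f[["qrs_off"]] && f[["qrs_off"]] < f[["t"]])
})

test_that("degenerate windows are rejected, not mis-delineated", {
  expect_equal(detect_ecg_beat(rep(0.7, 256))$ok, FALSE)
  set.seed(41)
  noise <- rnorm(1024, sd = 0.02)
  det <- detect_ecg_beat(noise)
  valid <- if (det$ok) {
    check_ecg_window(1024, det$fiducials[["r"]], det$maxima)$valid
  } else FALSE
  expect_false(valid)
  expect_error(detect_ecg_beat(rnorm(100)), "128")
})

test_that("window validity enforces centering and flanking maxima counts", {
  pol <- window_policy()
  mm <- c(100, 200, 300, 700, 800, 900)
  expect_true(check_ecg_window(1000, 500, mm, pol)$valid)

  off <- check_ecg_window(1000, 350, mm, pol)
  expect_false(off$valid); expect_equal(off$reason, "vicinity")

  few <- check_ecg_window(1000, 500, c(100, 200, 700, 800, 900), pol)
  expect_false(few$valid); expect_equal(few$reason, "MMT before")

  after <- check_ecg_window(1000, 500, c(100, 200, 300, 700, 800), pol)
  expect_false(after$valid); expect_equal(after$reason, "MMT after")

  expect_false(check_ecg_window(1000, NA, mm, pol)$valid)
})

test_that("adaptive window size follows the programmed R-R interval", {
  pol <- window_policy()
  g60 <- synth_ecg(subject_profile(hr_mean = 60, hr_jitter = 0,
                                   noise_snr = Inf, seed = 5), 10, fs = 1200)
  expect_equal(estimate_ecg_window_size(g60$stream, 1, pol), 1500,
               tolerance = 0.02)
  g100 <- synth_ecg(subject_profile(hr_mean = 100, hr_jitter = 0,
                                    noise_snr = Inf, seed = 5), 10, fs = 1200)
  expect_equal(estimate_ecg_window_size(g100$stream, 1, pol), 900,
               tolerance = 0.02)
  flat <- signal_stream(rep(0, 4000), 1200, "ecg")
  expect_equal(estimate_ecg_window_size(flat, 1, pol), pol$fwwt_size)
  expect_error(estimate_ecg_window_size(flat, 3000, pol), "exceeds")
})

test_that("continuous delineation recovers nearly every programmed beat", {
  g <- synth_ecg(quiet_profile(hr = 60, snr = 30, seed = 7), 60, fs = 1200)
  det <- detect_ecg(g$stream)
  expect_gte(nrow(det), 58)
  expect_lte(nrow(det), 61)
  errs <- match_beats(det, g$truth, "r", 12, c("r", "p", "t"))
  expect_gte(mean(!is.na(errs$r)), 0.95)
  expect_lte(max(errs$r, na.rm = TRUE), 12)
  # ordering invariant on every emitted beat
  expect_true(all(det$p < det$qrs_on & det$qrs_on < det$q & det$q < det$r &
                  det$r < det$s & det$s < det$qrs_off & det$qrs_off < det$t))
  expect_true(all(diff(det$r) > 0))
})

test_that("a flat-line stream yields an empty result, not an error", {
  flat <- signal_stream(rep(0.3, 30000), 1200, "ecg")
  det <- detect_ecg(flat)
  expect_s3_class(det, "ecg_fiducials")
  expect_equal(nrow(det), 0)
})

test_that("detection indices ignore amplitude scale and DC offset", {
  g <- synth_ecg(quiet_profile(hr = 80, snr = 30, seed = 9), 30, fs = 1200)
  det1 <- detect_ecg(g$stream)
  scaled <- signal_stream(5.7 * g$stream$samples - 11, 1200, "ecg")
  det2 <- detect_ecg(scaled)
  expect_equal(det1$r, det2$r)
  expect_equal(det1$p, det2$p)
  expect_equal(det1$t, det2$t)
})

test_that("annotation table reports one row per fiducial with times", {
  g <- synth_ecg(quiet_profile(seed = 10), 20, fs = 1200)
  det <- detect_ecg(g$stream)
  ann <- fiducial_annotation(det, g$stream)
  expect_setequal(unique(ann$point),
                  c("p", "q", "r", "s", "t", "qrs_on", "qrs_off"))
  expect_equal(nrow(ann), 7 * nrow(det))
  expect_equal(ann$time_s, (ann$index - 1) / 1200)
})
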