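#' Delineate a single PPG beat inside an analysis window
#'
#' Operates on transmission-intensity PPG, where detected light
#' intensity is low during systole (high blood volume absorbs more) and
#' high in diastole, so the dicrotic notch appears *before* the
#' prominent end-of-beat maximum.  Steps: level-3 detail extremes
#' `t1`/`t2` bracket the steepest slopes of the pulse and the
#' end-of-beat (EB) is the raw-amplitude maximum between them; the
#' level-5 detail is differentiated and, scanning left from the
#' maximum of that differentiated wave, the first zero-crossing of the
#' detail in the peak direction (negative to positive, i.e. a local
#' amplitude maximum) marks the diastolic peak (DP), refined against
#' the raw amplitude within the crossing's support; the systolic peak
#' (SP) is the amplitude minimum before DP (systole = least detected
#' intensity); the dicrotic notch (DN) is the modulus-maxima point
#' between SP and DP that, climbed to its local summit, has the
#' largest topographic prominence -- a beat whose rise carries no such
#' summit (no notch) gets `dn = NA`, and features involving DN are
#' skipped downstream for that beat.
#'
#' @param x Numeric window of at least 128 samples.
#' @param policy A [window_policy()].
#' @param fs Sampling rate in Hz; accepted for interface symmetry with
#'   [detect_ecg_beat()] and unused.
#' @return On success, `ok = TRUE`, integer `fiducials` (named
#'   `sp, dn, dp, eb`; `dn` may be `NA`) and `maxima`.  Otherwise
#'   `ok = FALSE` and `step`.
#' @export
detect_ppg_beat <- function(x, policy = window_policy(), fs = 1200) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 128L) stop("detect_ppg_beat: window must have at least 128 samples")
  reject <- function(step) list(ok = FALSE, step = step)

  dec <- haar_dwt(x, 5L)
  cd3 <- dec$cD[[3L]]
  br <- bracket_peak_cd3(cd3)
  if (is.null(br)) return(reject("cD_l3 flat"))
  t1 <- br[1L]; t2 <- br[2L]
  if (t1 == t2) return(reject("t1/t2 coincide"))

  eb <- t1 - 1L + which.max(x[t1:t2])
  # the bracket can clip the summit by a few coefficient supports when
  # one of its ends lies on the peak itself; let the maximum settle
  # locally, on a lightly smoothed summit so measurement noise cannot
  # drag the argmax across the flat top
  lo <- max(1L, eb - 64L); hi <- min(n, eb + 64L)
  eb <- lo - 1L + smoothed_argmax(x[lo:hi])

  # The level-5 detail tracks the negated slope at the 32-sample scale,
  # so a zero-crossing of cD_l5 from negative to positive (in increasing
  # index) marks an amplitude *maximum* of the waveform.  The maximum of
  # the differentiated detail sits at the sharpest concave-down point --
  # the end-of-beat top -- and the first peak-direction zero-crossing
  # encountered scanning left from it is the diastolic peak.
  cd5 <- dec$cD[[5L]]
  dd <- diff(cd5)
  if (length(dd) < 2L) return(reject("cD_l5 too short"))
  kmax <- which.max(dd)
  # Candidate diastolic peaks are the peak-direction crossings left of
  # the end-of-beat's own support, no further back than ~half a beat
  # (0.4 of the window), so neither EB itself, the systolic trough nor
  # the previous beat can be taken.  The 32-sample coefficient grid
  # quantizes each crossing, so every candidate is refined against the
  # raw amplitude in its support and the highest-amplitude one wins --
  # the diastolic summit dominates both the notch and valley wiggles.
  k_eb <- signal_to_coeff_index(5L, eb)
  k_start <- min(kmax, k_eb - 2L)
  k_lo <- max(1L, signal_to_coeff_index(5L, max(1L, eb - as.integer(0.4 * n))))
  dp <- NA_integer_
  dp_val <- -Inf
  if (k_start > k_lo) {
    for (j in (k_start - 1L):k_lo) {
      if (cd5[j] < 0 && cd5[j + 1L] >= 0) {
        cc <- coeff_to_signal_index(5L, j + 1L)
        lo <- max(1L, cc - 32L)
        hi <- min(cc + 32L, eb - 16L, n)
        if (lo > hi) next
        cand <- lo - 1L + which.max(x[lo:hi])
        if (x[cand] > dp_val) { dp_val <- x[cand]; dp <- cand }
      }
    }
  }
  if (is.na(dp)) return(reject("DP zero-crossing"))
  if (dp >= eb) dp <- eb - 1L
  if (dp < 2L) return(reject("SP search range"))

  sp <- which.min(x[1:(dp - 1L)])

  maxima <- modulus_maxima(x, policy$threshold_frac)
  # The notch is a small bump riding the systolic-to-diastolic rise:
  # each modulus maximum between SP and DP marks one of its slopes, so
  # candidates are climbed to the nearest local summit and the one that
  # actually stands above both its flanks (positive bump prominence)
  # is the notch.  Notchless beats leave no such summit and yield NA.
  marg <- max(8L, as.integer(round(0.02 * n)))   # n ~ 1.25 beat periods
  w_climb <- max(16L, as.integer(round(0.06 * n)))
  lo_dn <- sp + marg
  hi_dn <- dp - marg
  cand <- maxima[maxima > lo_dn & maxima < hi_dn]
  dn <- NA_integer_
  if (hi_dn > lo_dn && length(cand) > 0L) {
    # topographic prominence over [sp, dp]: a genuine notch summit
    # stands above the higher of its two surrounding minima; points on
    # the monotone systolic-to-diastolic rise score ~0 and are skipped
    seg <- x[sp:dp]
    cmin_f <- cummin(seg)
    cmin_b <- rev(cummin(rev(seg)))
    floor_score <- 0.008 * diff(range(x))
    best <- floor_score
    for (cc in cand) {
      a <- max(lo_dn, cc - w_climb)
      b <- min(hi_dn, cc + w_climb)
      rc <- a - 1L + which.max(x[a:b])
      i <- rc - sp + 1L
      score <- seg[i] - max(cmin_f[i], cmin_b[i])
      if (score > best) { best <- score; dn <- rc }
    }
  }

  if (!(sp < dp && dp < eb) || (!is.na(dn) && !(sp < dn && dn < dp))) {
    return(reject("ordering"))
  }
  list(ok = TRUE,
       fiducials = c(sp = sp, dn = dn, dp = dp, eb = eb),
       maxima = maxima)
}

# Argmax of a lightly smoothed segment (25-sample moving average via
# cumulative sums), so measurement noise cannot drag the maximum across
# a flat summit.  Edges are left unsmoothed.
smoothed_argmax <- function(seg) {
  nseg <- length(seg)
  k <- min(25L, 2L * ((nseg - 1L) %/% 2L) + 1L)
  if (k < 3L) return(which.max(seg))
  h <- k %/% 2L
  cs <- cumsum(seg)
  sm <- seg
  idx <- (h + 1L):(nseg - h)
  sm[idx] <- (cs[idx + h] - c(0, cs)[idx - h]) / k
  which.max(sm)
}

#' Validity conditions for a PPG analysis window
#'
#' The end-of-beat maximum must be detected and near the window center,
#' with more than 3 modulus-maxima points before it (ensuring SP, DN
#' and DP are inside the window) and more than 2 after it.
#'
#' @param size Window size in samples.
#' @param eb Window-local end-of-beat index (or `NA`).
#' @param maxima Modulus-maxima indices of the window.
#' @param policy A [window_policy()]; the "before" count is raised to
#'   at least 3 for PPG.
#' @return A list with `valid` and `reason`.
#' @export
check_ppg_window <- function(size, eb, maxima, policy = window_policy()) {
  check_anchor_window(size, eb, maxima, policy,
                      max(policy$min_mmt_before, 3L), policy$min_mmt_after)
}

#' Adaptive window size from the running pulse interval
#'
#' Peak-to-peak distance of prominent PPG maxima (the end-of-beat
#' peaks in intensity orientation) within a 2400-sample block, inflated
#' by `buffer_frac`; falls back to `fwwt_size` when fewer than two
#' peaks are found.
#'
#' @inheritParams estimate_ecg_window_size
#' @return Window size in samples.
#' @export
estimate_ppg_window_size <- function(stream, at = 1L, policy = window_policy()) {
  n <- length(stream$samples)
  at <- as.integer(at)
  if (at < 1L || at + 2399L > n) {
    stop("estimate_ppg_window_size: block [", at, ", ", at + 2399L,
         "] exceeds the stream")
  }
  block <- stream$samples[at:(at + 2399L)]
  peaks <- find_prominent_peaks(block, rel_thr = 0.6, refractory = 240L)
  if (length(peaks) < 2L && at + 4799L <= n) {
    block <- stream$samples[at:(at + 4799L)]
    peaks <- find_prominent_peaks(block, rel_thr = 0.6, refractory = 240L)
  }
  if (length(peaks) < 2L) return(policy$fwwt_size)
  pp <- stats::median(diff(peaks))
  as.integer(round(pp * (1 + policy$buffer_frac)))
}

#' Beat-by-beat PPG delineation of a continuous stream
#'
#' As [detect_ecg()], with two differences: each new analysis window
#' starts one tenth of the window size *before* the detected beginning
#' of the next pulse, and that beginning is seeded from the current
#' beat's end-of-beat point (the end of one pulse is the beginning of
#' the next).
#'
#' @param stream A PPG `signal_stream` at the 1200 Hz working rate, in
#'   transmission-intensity orientation.  Conventional volume-PPG input
#'   should be inverted first (see `ppg_orientation` in
#'   [pipeline_config()]).
#' @param policy A [window_policy()].
#' @return A data.frame of class `ppg_fiducials` with columns
#'   `beat_id, sp, dn, dp, eb` (stream coordinates; `dn` may be `NA`).
#' @export
detect_ppg <- function(stream, policy = window_policy()) {
  stopifnot(inherits(stream, "signal_stream"))
  detect_stream_loop(stream, policy,
                     detector = detect_ppg_beat,
                     checker = check_ppg_window,
                     anchor_name = "eb",
                     next_start_field = "eb",
                     preroll_frac = 0.10,
                     size_estimator = estimate_ppg_window_size,
                     out_class = "ppg_fiducials")
}
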