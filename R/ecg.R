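#' Delineate a single ECG beat inside an analysis window
#'
#' Wavelet delineation of one cardiac cycle.  The steps, in order:
#' the window is decomposed to level 5 with [haar_dwt()]; the minimum
#' and maximum of the level-3 detail `cD_l3` mark the steepest up- and
#' down-slope of the QRS complex (`t1`, `t2`, swapped if needed so
#' `t1 < t2`); R is the raw-amplitude maximum between them.  Modulus
#' maxima of the window give `t3` (last maximum before `t1`) and `t4`
#' (first after `t2`); Q is the amplitude minimum in `[t3, R)` and S
#' the minimum in `(R, t4]`.  QRS onset/offset are found by walking
#' outward from Q and S until the absolute first difference falls to
#' `qrs_slope_frac` of the window's largest slope.  P and T are the
#' raw-amplitude maxima bracketed by the extreme level-5 detail
#' coefficients restricted to the pre-onset and post-offset segments,
#' where the slower atrial and repolarization waves dominate.
#'
#' All returned indices are window-local (1-based).  Detection uses
#' only the ranks of coefficients and amplitudes, so the result is
#' invariant under amplitude scaling and DC offset.
#'
#' Because a well-centered window also contains the tail of the
#' previous beat, the P search is additionally bounded to the
#' `p_window_s` seconds (default 0.22 s, above the clinical bound on
#' the P-to-QRS-onset interval) preceding the QRS onset, so the
#' previous T wave cannot capture it.
#'
#' @param x Numeric window of at least 128 samples.
#' @param policy A [window_policy()]; supplies the modulus-maxima and
#'   QRS slope thresholds.
#' @param fs Sampling rate of the window in Hz (default the 1200 Hz
#'   working rate); used only to convert `p_window_s` to samples.
#' @return On success, a list with `ok = TRUE`, integer `fiducials`
#'   (named `p, q, r, s, t, qrs_on, qrs_off`) and the window's
#'   `maxima`.  On failure, `ok = FALSE` plus `step`, the name of the
#'   sub-step whose search range was empty.
#' @export
detect_ecg_beat <- function(x, policy = window_policy(), fs = 1200) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 128L) stop("detect_ecg_beat: window must have at least 128 samples")
  reject <- function(step) list(ok = FALSE, step = step)

  dec <- haar_dwt(x, 5L)
  cd3 <- dec$cD[[3L]]
  br <- bracket_peak_cd3(cd3)
  if (is.null(br)) return(reject("cD_l3 flat"))
  t1 <- br[1L]; t2 <- br[2L]
  if (t1 == t2) return(reject("t1/t2 coincide"))

  r <- t1 - 1L + which.max(x[t1:t2])

  maxima <- modulus_maxima(x, policy$threshold_frac)
  before <- maxima[maxima < t1]
  # with the left-edge support convention the level-1 maximum of the edge
  # that produced t2 falls inside t2's level-3 support: skip those 8 samples
  after <- maxima[maxima > t2 + 8L]
  if (length(before) == 0L) return(reject("MMT before t1"))
  if (length(after) == 0L) return(reject("MMT after t2"))
  t3 <- max(before)
  t4 <- min(after)

  if (t3 >= r) return(reject("Q search range"))
  q <- t3 - 1L + which.min(x[t3:(r - 1L)])
  if (t4 <= r) return(reject("S search range"))
  s <- r + which.min(x[(r + 1L):t4])

  d <- scaled_slope(x)
  theta <- policy$qrs_slope_frac * max(abs(d), na.rm = TRUE)
  # walk outward from the Q/S troughs: first cross the steep QRS flank,
  # then stop at the first sample whose slope has flattened below theta
  qrs_on <- walk_to_flat(d, from = q - 1L, step = -1L, theta = theta)
  if (is.na(qrs_on)) return(reject("QRS onset"))
  qrs_off <- walk_to_flat(d, from = s + 1L, step = 1L, theta = theta)
  if (is.na(qrs_off)) return(reject("QRS offset"))

  cd5 <- dec$cD[[5L]]
  left_edge <- coeff_to_signal_index(5L, seq_along(cd5))

  # cap the P look-back both at p_window_s and at 35% of the beat period
  # implied by the window size, so at high heart rates the previous T
  # tail stays out of reach
  p_back <- min(round(policy$p_window_s * fs),
                round(0.35 * n / (1 + policy$buffer_frac)))
  p_from <- max(1L, qrs_on - as.integer(p_back))
  # whole 32-sample support must precede the QRS onset, or the QRS edge
  # itself dominates the level-5 extremes
  pre <- which(left_edge >= p_from & left_edge + 31L < qrs_on)
  if (length(pre) < 2L) return(reject("P segment"))
  p_lo <- coeff_to_signal_index(5L, pre[which.min(cd5[pre])])
  p_hi <- coeff_to_signal_index(5L, pre[which.max(cd5[pre])])
  lo <- max(min(p_lo, p_hi), p_from)
  hi <- min(max(p_lo, p_hi), qrs_on - 1L)
  if (lo > hi) return(reject("P search range"))
  p <- lo - 1L + which.max(x[lo:hi])

  post <- which(left_edge > qrs_off)
  if (length(post) < 2L) return(reject("T segment"))
  t_lo <- coeff_to_signal_index(5L, post[which.min(cd5[post])])
  t_hi <- coeff_to_signal_index(5L, post[which.max(cd5[post])])
  lo <- max(min(t_lo, t_hi), qrs_off + 1L); hi <- min(max(t_lo, t_hi), n)
  if (lo > hi) return(reject("T search range"))
  tw <- lo - 1L + which.max(x[lo:hi])

  fid <- c(p = p, q = q, r = r, s = s, t = tw,
           qrs_on = qrs_on, qrs_off = qrs_off)
  if (!(p < qrs_on && qrs_on < q && q < r && r < s && s < qrs_off &&
        qrs_off < tw)) {
    return(reject("ordering"))
  }
  list(ok = TRUE, fiducials = fid, maxima = maxima)
}

# Slope of the window at the QRS scale: 9-sample moving average followed
# by a central difference over +/- 4 samples.  Smoothing keeps additive
# wideband noise out of the derivative thresholds; NA at the edges.
scaled_slope <- function(x) {
  n <- length(x)
  sm <- stats::filter(x, rep(1 / 9, 9), sides = 2)
  d <- rep(NA_real_, n)
  if (n >= 13L) {
    idx <- 9:(n - 8L)
    d[idx] <- (sm[idx + 4L] - sm[idx - 4L]) / 8
  }
  d
}

# Two-phase outward walk used for QRS onset/offset: from `from`, move by
# `step` while inside the steep flank (|slope| > theta, or the flat trough
# bottom before reaching the flank); return the first index past the flank
# whose slope has flattened, or NA if the window edge is hit first.
walk_to_flat <- function(d, from, step, theta) {
  n <- length(d)
  in_flank <- FALSE
  j <- from
  while (j >= 1L && j <= n) {
    v <- d[j]
    if (!is.na(v) && abs(v) > theta) {
      in_flank <- TRUE
    } else if (in_flank && !is.na(v)) {
      return(j)
    }
    j <- j + step
  }
  NA_integer_
}

#' Validity conditions for an ECG analysis window
#'
#' A window holds one complete, well-placed cardiac cycle when the R
#' peak was detected, lies within `vicinity_frac` of the window size
#' about the center, and more than `min_mmt_before` (default 2)
#' modulus-maxima points precede it and more than `min_mmt_after`
#' (default 2) follow it -- the flanking maxima guarantee the P and T
#' waves are inside the window.
#'
#' @param size Window size in samples.
#' @param r Window-local R index (or `NA` if not detected).
#' @param maxima Modulus-maxima indices of the window.
#' @param policy A [window_policy()].
#' @return A list with `valid` (logical) and `reason`.
#' @export
check_ecg_window <- function(size, r, maxima, policy = window_policy()) {
  check_anchor_window(size, r, maxima, policy,
                      policy$min_mmt_before, policy$min_mmt_after)
}

#' Adaptive window size from the running R-R interval
#'
#' Scans a 2400-sample block (two seconds at the 1200 Hz working rate,
#' enough for 2-4 R peaks) starting at `at` for R peaks by amplitude
#' thresholding on the mean-removed block (peaks above 0.6 of the block
#' maximum, 240-sample refractory), and returns the median adjacent
#' R-R distance inflated by `buffer_frac`.  With fewer than two peaks
#' the fixed fallback `fwwt_size` is returned.
#'
#' @param stream An ECG `signal_stream` at the 1200 Hz working rate.
#' @param at Block start index (1-based); `at + 2399` must not exceed
#'   the stream length.
#' @param policy A [window_policy()].
#' @return Window size in samples.
#' @export
estimate_ecg_window_size <- function(stream, at = 1L, policy = window_policy()) {
  n <- length(stream$samples)
  at <- as.integer(at)
  if (at < 1L || at + 2399L > n) {
    stop("estimate_ecg_window_size: block [", at, ", ", at + 2399L,
         "] exceeds the stream")
  }
  block <- stream$samples[at:(at + 2399L)]
  peaks <- find_prominent_peaks(block, rel_thr = 0.6, refractory = 240L)
  if (length(peaks) < 2L && at + 4799L <= n) {
    # at low heart rates a 2400-sample block can hold a single R peak;
    # double the block once before giving up on an adaptive estimate
    block <- stream$samples[at:(at + 4799L)]
    peaks <- find_prominent_peaks(block, rel_thr = 0.6, refractory = 240L)
  }
  if (length(peaks) < 2L) return(policy$fwwt_size)
  rr <- stats::median(diff(peaks))
  as.integer(round(rr * (1 + policy$buffer_frac)))
}

#' Beat-by-beat ECG delineation of a continuous stream
#'
#' Slides analysis windows over the stream, delineating one beat per
#' valid window.  In `"awwt"` mode the window size is re-estimated
#' from the local R-R interval before each beat search; an invalid
#' window (see [check_ecg_window()]) is slid forward by
#' `slide_step` samples and retried, with a retry budget of
#' `2 * size / slide_step` before skipping one whole window.  After a
#' successful beat the next search starts from the current beat's T
#' wave.  In `"fwwt"` mode the stream is tiled with consecutive
#' fixed-size windows with no sliding, so beats that happen to fall off
#' center are lost -- the fixed baseline is only adequate over a narrow
#' heart-rate band.
#'
#' @param stream An ECG `signal_stream` at the 1200 Hz working rate.
#' @param policy A [window_policy()].
#' @return A data.frame of class `ecg_fiducials` with columns
#'   `beat_id, p, q, r, s, t, qrs_on, qrs_off` (stream-coordinate
#'   1-based indices, strictly increasing in `r`) and attributes
#'   `n_windows_tried`, `n_skips`.
#' @export
detect_ecg <- function(stream, policy = window_policy()) {
  stopifnot(inherits(stream, "signal_stream"))
  detect_stream_loop(stream, policy,
                     detector = detect_ecg_beat,
                     checker = check_ecg_window,
                     anchor_name = "r",
                     next_start_field = "t",
                     preroll_frac = 0,
                     size_estimator = estimate_ecg_window_size,
                     out_class = "ecg_fiducials")
}

# Shared stream-scanning loop for both channels.  `detector` maps a
# window to a beat result; `checker` validates anchor placement;
# `anchor_name` names the anchor fiducial; `next_start_field` names the
# fiducial the next beat search is seeded from; `preroll_frac` shifts
# the next window back by that fraction of the window size.
detect_stream_loop <- function(stream, policy, detector, checker,
                               anchor_name, next_start_field,
                               preroll_frac, size_estimator, out_class) {
  n <- length(stream$samples)
  rows <- list()
  last_anchor <- -Inf
  tried <- 0L
  skips <- 0L

  if (policy$mode == "fwwt") {
    # fixed baseline: consecutive tiles, no sliding and no placement
    # validity -- the fixed window cannot verify that it holds one
    # complete, centered cycle, which is exactly its limitation
    size <- policy$fwwt_size
    start <- 1L
    while (start + size - 1L <= n) {
      tried <- tried + 1L
      w <- stream$samples[start:(start + size - 1L)]
      det <- detector(w, policy, stream$fs)
      if (isTRUE(det$ok)) {
        a_stream <- start - 1L + det$fiducials[[anchor_name]]
        if (a_stream > last_anchor) {
          rows[[length(rows) + 1L]] <- start - 1L + det$fiducials
          last_anchor <- a_stream
        }
      }
      start <- start + size
    }
  } else {
    size <- NULL
    start <- 1L
    repeat {
      if (start + 2400L - 1L <= n) {
        size <- size_estimator(stream, start, policy)
      } else if (is.null(size)) {
        size <- policy$fwwt_size
      }
      size <- min(size, n)
      if (start + size - 1L > n) break
      budget <- as.integer(ceiling(2 * size / policy$slide_step))
      found <- FALSE
      s0 <- start
      for (try in seq_len(budget)) {
        if (start + size - 1L > n) break
        tried <- tried + 1L
        w <- stream$samples[start:(start + size - 1L)]
        det <- detector(w, policy, stream$fs)
        if (isTRUE(det$ok)) {
          anchor <- det$fiducials[[anchor_name]]
          chk <- checker(size, anchor, det$maxima, policy)
          if (chk$valid && start - 1L + anchor > last_anchor) {
            fid <- start - 1L + det$fiducials
            rows[[length(rows) + 1L]] <- fid
            last_anchor <- start - 1L + anchor
            nxt <- fid[[next_start_field]] - as.integer(round(preroll_frac * size))
            start <- max(nxt, start + 1L)
            found <- TRUE
            break
          }
        }
        start <- start + policy$slide_step
      }
      if (!found) {
        skips <- skips + 1L
        start <- max(s0 + size, start)
      }
      if (start + 128L > n) break
    }
  }

  out <- if (length(rows) == 0L) {
    as.data.frame(setNames(
      rep(list(integer(0)), length(c("beat_id", names_of_detector(out_class)))),
      c("beat_id", names_of_detector(out_class))))
  } else {
    df <- as.data.frame(do.call(rbind, rows))
    df <- cbind(beat_id = seq_len(nrow(df)), df)
    df
  }
  attr(out, "n_windows_tried") <- tried
  attr(out, "n_skips") <- skips
  attr(out, "fs") <- stream$fs
  class(out) <- c(out_class, "data.frame")
  out
}

names_of_detector <- function(out_class) {
  if (out_class == "ecg_fiducials") {
    c("p", "q", "r", "s", "t", "qrs_on", "qrs_off")
  } else {
    c("sp", "dn", "dp", "eb")
  }
}

#' Convert per-beat fiducial indices to an annotation table with times
#'
#' @param fiducials An `ecg_fiducials` or `ppg_fiducials` data.frame.
#' @param stream The `signal_stream` the indices refer to.
#' @return A long-format data.frame with columns `beat_id`, `point`,
#'   `index`, `time_s`, suitable for writing as CSV.
#' @export
fiducial_annotation <- function(fiducials, stream) {
  cols <- setdiff(names(fiducials), "beat_id")
  out <- do.call(rbind, lapply(cols, function(cn) {
    data.frame(beat_id = fiducials$beat_id, point = cn,
               index = fiducials[[cn]],
               time_s = stream_time(stream, fiducials[[cn]]))
  }))
  out[order(out$beat_id, out$index), , drop = FALSE]
}
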