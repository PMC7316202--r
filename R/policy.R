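#' Windowing policy for beat-by-beat detection
#'
#' Controls how analysis windows are sized and validated while sliding
#' over a continuous stream.
#'
#' Two modes are supported.  `"awwt"` (adaptive window) re-estimates the
#' window size for every beat from the running R-R (ECG) or
#' peak-to-peak (PPG) interval, plus a safety buffer, so a window always
#' holds one complete cycle regardless of heart rate.  `"fwwt"` (fixed
#' window) tiles the stream with consecutive `fwwt_size`-sample windows
#' and keeps whatever valid beats fall inside them; it is only adequate
#' over a limited heart-rate band and is provided as the baseline the
#' adaptive mode is compared against.
#'
#' A window is accepted only if the anchor peak (R for ECG, end-of-beat
#' for PPG) sits within `vicinity_frac` of the window size about the
#' window center, and enough modulus-maxima points flank it:
#' more than `min_mmt_before` before and more than `min_mmt_after`
#' after, which guarantees the surrounding low-amplitude waves are
#' inside the window.
#'
#' @param mode `"awwt"` (adaptive, default) or `"fwwt"` (fixed 1100).
#' @param slide_step Samples to slide a rejected window by (default 10).
#' @param vicinity_frac Allowed offset of the anchor peak from the
#'   window center, as a fraction of the window size (default 0.10).
#' @param min_mmt_before,min_mmt_after Modulus-maxima counts that must
#'   be *exceeded* before/after the anchor.  Defaults 2 and 2 for ECG;
#'   the PPG detector raises the "before" count to 3.
#' @param fwwt_size Fixed window size in samples (default 1100); also
#'   the fallback window when no peaks can be found for the adaptive
#'   estimate.
#' @param buffer_frac Fraction added to the adaptive beat-interval
#'   estimate (default 0.25).
#' @param threshold_frac Relative modulus-maxima floor passed through
#'   to [modulus_maxima()].
#' @param qrs_slope_frac QRS onset/offset derivative threshold as a
#'   fraction of the window's largest absolute first difference
#'   (default 0.05).
#' @param p_window_s Upper bound on the P-to-QRS-onset interval in
#'   seconds (default 0.22, above the clinical upper bound of the PR
#'   interval); the P search never reaches further back,
#'   so the previous beat's T wave cannot capture it.
#' @return A list of class `window_policy`.
#' @export
window_policy <- function(mode = c("awwt", "fwwt"),
                          slide_step = 10L,
                          vicinity_frac = 0.10,
                          min_mmt_before = 2L,
                          min_mmt_after = 2L,
                          fwwt_size = 1100L,
                          buffer_frac = 0.25,
                          threshold_frac = 0.05,
                          qrs_slope_frac = 0.05,
                          p_window_s = 0.22) {
  mode <- match.arg(mode)
  stopifnot(slide_step >= 1L, vicinity_frac > 0, vicinity_frac < 0.5,
            fwwt_size >= 128L, buffer_frac >= 0)
  structure(
    list(mode = mode, slide_step = as.integer(slide_step),
         vicinity_frac = vicinity_frac,
         min_mmt_before = as.integer(min_mmt_before),
         min_mmt_after = as.integer(min_mmt_after),
         fwwt_size = as.integer(fwwt_size),
         buffer_frac = buffer_frac,
         threshold_frac = threshold_frac,
         qrs_slope_frac = qrs_slope_frac,
         p_window_s = p_window_s),
    class = "window_policy"
  )
}

# Shared anchor-validity predicate: `anchor` is the window-local index of
# the R peak (ECG) or end-of-beat (PPG); `maxima` the window's modulus
# maxima.  Returns list(valid, reason).
check_anchor_window <- function(size, anchor, maxima, policy,
                                min_before, min_after) {
  if (is.null(anchor) || is.na(anchor)) {
    return(list(valid = FALSE, reason = "anchor not detected"))
  }
  center <- (size + 1) / 2
  if (abs(anchor - center) > policy$vicinity_frac * size) {
    return(list(valid = FALSE, reason = "vicinity"))
  }
  if (sum(maxima < anchor) <= min_before) {
    return(list(valid = FALSE, reason = "MMT before"))
  }
  if (sum(maxima > anchor) <= min_after) {
    return(list(valid = FALSE, reason = "MMT after"))
  }
  list(valid = TRUE, reason = "ok")
}

# Bracket the window's dominant peak with the level-3 detail extremes:
# the steepest rise (detail minimum) followed by the steepest fall
# (detail maximum *after* it).  The reversed pairing covers inverted
# polarity; the pair with the larger combined modulus wins.  Returns
# signal-coordinate c(t1, t2) with t1 < t2, or NULL.
bracket_peak_cd3 <- function(cd3) {
  n <- length(cd3)
  best <- NULL
  k1 <- which.min(cd3)
  if (k1 < n) {
    k2 <- k1 + which.max(cd3[(k1 + 1L):n])
    best <- list(score = abs(cd3[k1]) + abs(cd3[k2]), k = c(k1, k2))
  }
  k1r <- which.max(cd3)
  if (k1r < n) {
    k2r <- k1r + which.min(cd3[(k1r + 1L):n])
    score <- abs(cd3[k1r]) + abs(cd3[k2r])
    if (is.null(best) || score > best$score) {
      best <- list(score = score, k = c(k1r, k2r))
    }
  }
  if (is.null(best) || best$score == 0) return(NULL)
  coeff_to_signal_index(3L, best$k)
}

# Threshold-based prominent-peak scan used by the adaptive window-size
# estimators: mean-removed block, peaks above `rel_thr` of the block
# maximum, separated by at least `refractory` samples (larger peak kept).
find_prominent_peaks <- function(block, rel_thr = 0.6, refractory = 240L) {
  b <- block - mean(block)
  mx <- max(b)
  if (mx <= 0) return(integer(0))
  thr <- rel_thr * mx
  n <- length(b)
  cand <- which(b[-c(1L, n)] >= b[-c(n - 1L, n)] &
                b[-c(1L, n)] >= b[-(1:2)] &
                b[-c(1L, n)] >= thr) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || i - keep[length(keep)] >= refractory) {
      keep <- c(keep, i)
    } else if (b[i] > b[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}
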