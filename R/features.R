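#' Canonical names of the 32 interval features
#'
#' Every feature is a duration in seconds.  Five are ECG-only (QRS
#' width, P-R, S-T, R-R, P-T), seven are PPG-only (intervals among
#' systolic peak SP, dicrotic notch DN, diastolic peak DP and
#' end-of-beat EB), and twenty are cross-channel transit times between
#' each ECG wave (P, Q, R, S, T) and each PPG landmark: `T_iA`
#' (i to DP), `T_iB` (i to EB), `T_iN1` (i to DN), `T_iN2` (i to SP).
#' `T_RN2`, the R-to-systolic-peak delay, is the classical pulse
#' arrival time.
#'
#' @param which `"all"`, `"ecg"`, `"ppg"` or `"cross"`.
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_names())          # 32
#' length(feature_names("cross"))   # 20
feature_names <- function(which = c("all", "ecg", "ppg", "cross")) {
  which <- match.arg(which)
  ecg <- c("Tqrs", "Tpr", "Tst", "Trr", "Tpt")
  ppg <- c("Tab", "Tbb", "Taa", "Tn1b", "Tn2b", "Tn2n1", "Tn2a")
  cross <- as.vector(t(outer(c("P", "Q", "R", "S", "T"),
                             c("A", "B", "N1", "N2"),
                             function(i, j) paste0("T_", i, j))))
  switch(which,
         all = c(ecg, ppg, cross),
         ecg = ecg, ppg = ppg, cross = cross)
}

#' Pair simultaneous ECG and PPG beats
#'
#' For each detected PPG beat, the R peak is back-traced from its
#' diastolic peak: the beat is paired with the latest ECG beat whose R
#' precedes the DP.  PPG beats with no preceding R, or whose candidate
#' R is already claimed by an earlier PPG beat, are dropped; each R
#' pairs at most once.
#'
#' @param ecg_beats An `ecg_fiducials` data.frame (sorted by `r`).
#' @param ppg_beats A `ppg_fiducials` data.frame (sorted by `dp`).
#' @return A data.frame of class `beat_pairs` with columns `pair_id`,
#'   the seven ECG indices, the four PPG indices, and attributes
#'   `n_dropped_ppg` / `n_unpaired_ecg`.
#' @export
pair_beats <- function(ecg_beats, ppg_beats) {
  er <- ecg_beats$r
  used <- rep(FALSE, length(er))
  rows <- list()
  dropped <- 0L
  for (j in seq_len(nrow(ppg_beats))) {
    dp <- ppg_beats$dp[j]
    cand <- which(er < dp & !used)
    if (length(cand) == 0L) { dropped <- dropped + 1L; next }
    i <- cand[length(cand)]
    # latest preceding R overall must itself be unclaimed
    latest <- max(which(er < dp))
    if (latest != i) { dropped <- dropped + 1L; next }
    used[i] <- TRUE
    e <- ecg_beats[i, setdiff(names(ecg_beats), "beat_id"), drop = FALSE]
    p <- ppg_beats[j, setdiff(names(ppg_beats), "beat_id"), drop = FALSE]
    rows[[length(rows) + 1L]] <- cbind(e, p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(rep(list(integer(0)), 11L)),
                    c(names_of_detector("ecg_fiducials"),
                      names_of_detector("ppg_fiducials")))
  rownames(out) <- NULL
  out <- cbind(pair_id = seq_len(nrow(out)), out)
  attr(out, "n_dropped_ppg") <- dropped
  attr(out, "n_unpaired_ecg") <- sum(!used)
  class(out) <- c("beat_pairs", "data.frame")
  out
}

#' Per-beat interval features from paired fiducials
#'
#' Each feature is an index difference divided by the sampling rate,
#' taken as the nonnegative (later minus earlier) duration.  The
#' inter-beat intervals `Trr`, `Tbb`, `Taa` use the *next* beat's R,
#' EB and DP and are `NA` for the last pair; any feature touching a
#' missing fiducial (e.g. an undetected dicrotic notch) is `NA`.
#'
#' @param pairs A `beat_pairs` data.frame.
#' @param fs Sampling rate of the underlying streams in Hz.
#' @return A data.frame of class `feature_matrix`: one row per pair,
#'   exactly the 32 columns of [feature_names()], values in seconds.
#' @export
feature_matrix <- function(pairs, fs) {
  stopifnot(fs > 0)
  n <- nrow(pairs)
  lead1 <- function(v) if (n > 0) c(v[-1L], NA) else v
  dur <- function(a, b) abs(b - a) / fs
  out <- data.frame(
    Tqrs = dur(pairs$qrs_on, pairs$qrs_off),
    Tpr  = dur(pairs$p, pairs$r),
    Tst  = dur(pairs$s, pairs$t),
    Trr  = (lead1(pairs$r) - pairs$r) / fs,
    Tpt  = dur(pairs$p, pairs$t),
    Tab  = dur(pairs$dp, pairs$eb),
    Tbb  = (lead1(pairs$eb) - pairs$eb) / fs,
    Taa  = (lead1(pairs$dp) - pairs$dp) / fs,
    Tn1b = dur(pairs$dn, pairs$eb),
    Tn2b = dur(pairs$sp, pairs$eb),
    Tn2n1 = dur(pairs$sp, pairs$dn),
    Tn2a = dur(pairs$sp, pairs$dp)
  )
  for (i in c("p", "q", "r", "s", "t")) {
    ei <- pairs[[i]]
    out[[paste0("T_", toupper(i), "A")]] <- dur(ei, pairs$dp)
    out[[paste0("T_", toupper(i), "B")]] <- dur(ei, pairs$eb)
    out[[paste0("T_", toupper(i), "N1")]] <- dur(ei, pairs$dn)
    out[[paste0("T_", toupper(i), "N2")]] <- dur(ei, pairs$sp)
  }
  out <- out[feature_names()]
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Robust mean with one-pass mean +/- SD outlier rejection
#'
#' Detection slips produce occasional wild interval values; these are
#' removed by keeping only values inside `[mean - SD, mean + SD]`
#' (sample SD, n-1 denominator) and averaging the survivors.  The
#' filter is applied once, not iterated.  With a single value or zero
#' variance the plain mean is returned, so the operation is idempotent
#' on its own output.
#'
#' @param values Numeric vector (NAs are ignored).
#' @return The filtered mean, or `NA` (with a warning) if no non-NA
#'   values remain.
#' @export
#' @examples
#' robust_mean(c(1, 2, 3, 100)) # 2
robust_mean <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) {
    warning("robust_mean: all values missing")
    return(NA_real_)
  }
  m <- mean(v)
  if (length(v) == 1L) return(m)
  s <- stats::sd(v)
  if (s == 0) return(m)
  keep <- v >= m - s & v <= m + s
  mean(v[keep])
}

#' Aggregate one analysis segment to a single feature vector
#'
#' Reproduces the full per-segment pipeline: the first
#' `settle_samples` samples are discarded (the PPG front end needs
#' time to settle), detection runs on the next `segment_samples`
#' samples (about 67 s at 1200 Hz, roughly 60-100 beats), beats are
#' paired, the 32-column feature matrix is built and each column is
#' reduced with [robust_mean()].
#'
#' @param ecg,ppg `signal_stream`s at the working rate, time-aligned.
#' @param policy A [window_policy()].
#' @param settle_samples Samples to discard at the start (default
#'   10000).
#' @param segment_samples Segment length in samples (default 80000).
#' @param min_pairs Minimum paired beats required (default 20); below
#'   this the segment is rejected.
#' @return A named numeric vector of class `feature_vector` (32
#'   entries, seconds) with attributes `n_pairs` and `n_contributing`
#'   (per-feature beat counts after NA removal).
#' @export
aggregate_segment <- function(ecg, ppg, policy = window_policy(),
                              settle_samples = 10000L,
                              segment_samples = 80000L,
                              min_pairs = 20L) {
  need <- settle_samples + segment_samples
  if (length(ecg$samples) < need || length(ppg$samples) < need) {
    stop("aggregate_segment: streams must have at least ", need,
         " samples (settling + segment); got ",
         min(length(ecg$samples), length(ppg$samples)))
  }
  if (ecg$fs != ppg$fs) stop("aggregate_segment: sampling rates differ")
  sl <- function(s) signal_stream(
    s$samples[(settle_samples + 1L):need], s$fs, s$kind,
    t0 = s$t0 + settle_samples / s$fs
  )
  ecg_b <- detect_ecg(sl(ecg), policy)
  ppg_b <- detect_ppg(sl(ppg), policy)
  pairs <- pair_beats(ecg_b, ppg_b)
  if (nrow(pairs) < min_pairs) {
    stop("aggregate_segment: only ", nrow(pairs),
         " paired beats (need >= ", min_pairs, ")")
  }
  fm <- feature_matrix(pairs, ecg$fs)
  vec <- vapply(fm, function(col) suppressWarnings(robust_mean(col)),
                numeric(1))
  structure(vec,
            n_pairs = nrow(pairs),
            n_contributing = vapply(fm, function(col) sum(!is.na(col)),
                                    integer(1)),
            class = "feature_vector")
}
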