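#' Pipeline configuration
#'
#' Collects every tunable constant of the detection pipeline.  The
#' defaults reproduce the standard operating point: 1200 Hz working
#' rate, 10000-sample settling skip, 80000-sample analysis segment,
#' adaptive windows with a 10-sample slide and 10% vicinity bound, and
#' intensity-orientation PPG.
#'
#' @param working_fs Working sampling rate in Hz (default 1200).
#' @param policy A [window_policy()].
#' @param settle_samples Samples discarded before analysis (default
#'   10000).
#' @param segment_samples Segment length in samples (default 80000).
#' @param min_pairs Minimum paired beats per segment (default 20).
#' @param ppg_orientation `"intensity"` (native) or `"volume"`;
#'   volume-mode PPG is inverted on load so the core always sees the
#'   notch-before-peak orientation.
#' @param seed Seed forwarded to any randomized step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(working_fs = 1200,
                            policy = window_policy(),
                            settle_samples = 10000L,
                            segment_samples = 80000L,
                            min_pairs = 20L,
                            ppg_orientation = c("intensity", "volume"),
                            seed = 1L) {
  ppg_orientation <- match.arg(ppg_orientation)
  structure(
    list(working_fs = working_fs, policy = policy,
         settle_samples = as.integer(settle_samples),
         segment_samples = as.integer(segment_samples),
         min_pairs = as.integer(min_pairs),
         ppg_orientation = ppg_orientation, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a two-column time/value CSV as a signal stream
#'
#' The file must have a header and two columns (time in seconds, value);
#' timestamps must be uniform within a relative tolerance of 1e-6 of
#' the sampling period and contain no missing values.
#'
#' @param path CSV file path.
#' @param kind `"ecg"` or `"ppg"`.
#' @param fs Expected sampling rate; inferred from the timestamps when
#'   `NULL`.
#' @return A `signal_stream`.
#' @export
read_signal_csv <- function(path, kind = c("ecg", "ppg"), fs = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("read_signal_csv: expected two columns in ", path)
  tt <- df[[1L]]
  v <- df[[2L]]
  bad <- which(!is.finite(tt) | !is.finite(v))
  if (length(bad)) {
    stop("read_signal_csv: non-finite value at data row ", bad[1L],
         " of ", path)
  }
  dt <- diff(tt)
  period <- stats::median(dt)
  if (period <= 0 || any(abs(dt - period) > 1e-6 * period + 1e-12)) {
    stop("read_signal_csv: non-uniform timestamps in ", path,
         " (first offending row ",
         which(abs(dt - period) > 1e-6 * period + 1e-12)[1L] + 1L, ")")
  }
  fs_obs <- 1 / period
  if (!is.null(fs) && abs(fs_obs - fs) > 1e-6 * fs) {
    stop("read_signal_csv: observed rate ", signif(fs_obs, 8),
         " Hz differs from declared ", fs, " Hz")
  }
  signal_stream(v, fs = if (is.null(fs)) fs_obs else fs, kind = kind,
                t0 = tt[1L])
}

#' @rdname read_signal_csv
#' @param stream A `signal_stream` to write.
#' @export
write_signal_csv <- function(stream, path) {
  n <- length(stream$samples)
  utils::write.csv(
    data.frame(time_s = stream$t0 + (seq_len(n) - 1) / stream$fs,
               value = stream$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Load a concurrent ECG/PPG recording and bring it to the working rate
#'
#' Reads both channels (two-column time/value CSV), validates uniform
#' sampling, optionally inverts volume-orientation PPG, and resamples
#' both channels to `working_fs` (native 200 Hz ECG is upsampled by 6,
#' 75 Hz PPG by 16).
#'
#' @param ecg_path,ppg_path CSV paths.
#' @param fs_ecg,fs_ppg Declared native rates (validated against the
#'   timestamps; `NULL` to infer).
#' @param config A [pipeline_config()].
#' @param subject_id Identifier carried through reports.
#' @param reference_sbp,reference_dbp Optional reference pressures.
#' @return A list of class `recording_bundle` with `ecg`, `ppg`
#'   (streams at the working rate), `subject_id`, `reference_sbp`,
#'   `reference_dbp`.
#' @export
read_recording <- function(ecg_path, ppg_path, fs_ecg = NULL, fs_ppg = NULL,
                           config = pipeline_config(),
                           subject_id = "subject",
                           reference_sbp = NA_real_,
                           reference_dbp = NA_real_) {
  ecg <- read_signal_csv(ecg_path, "ecg", fs_ecg)
  ppg <- read_signal_csv(ppg_path, "ppg", fs_ppg)
  if (config$ppg_orientation == "volume") {
    ppg <- signal_stream(-ppg$samples, ppg$fs, "ppg", ppg$t0)
  }
  structure(
    list(ecg = resample_to(ecg, config$working_fs),
         ppg = resample_to(ppg, config$working_fs),
         subject_id = subject_id,
         reference_sbp = reference_sbp, reference_dbp = reference_dbp),
    class = "recording_bundle"
  )
}

#' Run the full detection / feature / prediction pipeline on one bundle
#'
#' Settling skip, beat-by-beat delineation of both channels, beat
#' pairing, 32-feature extraction with robust aggregation, and -- when
#' fitted models are supplied -- log-linear BP prediction.
#'
#' @param bundle A `recording_bundle` (or a list with `ecg`, `ppg`
#'   streams at the working rate).
#' @param config A [pipeline_config()].
#' @param sbp_model,dbp_model Optional `log_linear_model`s.
#' @return A list of class `pipeline_result`: `features` (a
#'   `feature_vector`), `n_pairs`, and `sbp`/`dbp` predictions (mmHg,
#'   `NULL` when no model was given).
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         sbp_model = NULL, dbp_model = NULL) {
  fv <- aggregate_segment(bundle$ecg, bundle$ppg, config$policy,
                          settle_samples = config$settle_samples,
                          segment_samples = config$segment_samples,
                          min_pairs = config$min_pairs)
  res <- list(features = fv, n_pairs = attr(fv, "n_pairs"),
              subject_id = bundle$subject_id,
              sbp = NULL, dbp = NULL)
  if (!is.null(sbp_model)) res$sbp <- predict(sbp_model, unclass(fv))
  if (!is.null(dbp_model)) res$dbp <- predict(dbp_model, unclass(fv))
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d paired beats\n",
              x$subject_id, x$n_pairs))
  if (!is.null(x$sbp)) cat(sprintf("  predicted SBP: %.1f mmHg\n", x$sbp))
  if (!is.null(x$dbp)) cat(sprintf("  predicted DBP: %.1f mmHg\n", x$dbp))
  invisible(x)
}
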