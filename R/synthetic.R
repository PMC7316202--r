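# Synthetic paired ECG/PPG generator with exact ground-truth landmarks.
# ECG beats are sums of five Gaussian bumps (P, Q, R, S, T); PPG beats are
# built in transmission-intensity orientation from an end-of-beat peak, a
# systolic trough and dicrotic-notch / diastolic-peak bumps.  Truth indices
# are the programmed bump centers, so they are exact by construction.

# Evaluate code with a temporary RNG state so generators are
# deterministic per seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_ecg_morphology <- function() {
  data.frame(
    wave   = c("p", "q", "r", "s", "t"),
    offset = c(-0.170, -0.025, 0.000, 0.026, 0.240),  # s relative to R
    amp    = c(0.12, -0.12, 1.00, -0.16, 0.32),
    width  = c(0.022, 0.009, 0.011, 0.009, 0.040)     # Gaussian SD, s
  )
}

default_ppg_morphology <- function() {
  list(
    # fractions of the beat period, measured from the systolic trough;
    # the notch sits mid-way between trough and diastolic peak, clear
    # of both flanks
    dn_frac = 0.20, dp_frac = 0.35, eb_frac = 0.62,
    # component amplitudes (intensity orientation: EB is the prominent max)
    sp_amp = -0.85, dn_amp = 0.18, dp_amp = 0.40, eb_amp = 1.00,
    # component widths as fractions of the beat period; the notch must
    # stay resolvable at the 75 Hz native acquisition rate
    sp_width = 0.050, dn_width = 0.032, dp_width = 0.040, eb_width = 0.045
  )
}

#' Synthetic subject profile
#'
#' Bundles the programmable physiology of one simulated subject: mean
#' heart rate and beat-to-beat variability, the R-to-systolic-peak
#' delay (pulse arrival time), per-wave morphology, waveform noise
#' level and reference blood pressure.
#'
#' @param hr_mean Mean heart rate in beats per minute (40-180).
#' @param hr_jitter Fractional beat-to-beat standard deviation of the
#'   R-R interval (lognormal multiplier; 0 = metronomic).
#' @param pat Pulse arrival time in seconds: programmed delay from each
#'   R peak to the same beat's systolic trough on the PPG.  Must be
#'   positive and shorter than the beat period.
#' @param noise_snr Additive white-noise level as a signal-to-noise
#'   ratio in dB relative to the mean-removed clean waveform power;
#'   `Inf` disables noise.
#' @param sbp,dbp Reference systolic/diastolic pressure in mmHg.
#' @param seed Integer seed; generation is deterministic given the
#'   profile.
#' @param ecg_morph Data frame with columns `wave, offset, amp, width`
#'   (Gaussian bumps for P, Q, R, S, T; offsets in seconds relative to
#'   R).  Waves must be time-ordered with non-overlapping 1-SD
#'   supports, otherwise the profile is rejected as infeasible.
#' @param ppg_morph List of PPG component placements/amplitudes (see
#'   source); fractions are of the beat period, measured from the
#'   systolic trough.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(hr_mean = 75, hr_jitter = 0.02, pat = 0.25,
                            noise_snr = 30, sbp = 120, dbp = 80, seed = 1L,
                            ecg_morph = default_ecg_morphology(),
                            ppg_morph = default_ppg_morphology()) {
  if (hr_mean < 40 || hr_mean > 180) {
    stop("subject_profile: hr_mean must be within 40..180 bpm")
  }
  if (pat <= 0) stop("subject_profile: pat must be positive")
  if (pat >= 60 / hr_mean) {
    stop("subject_profile: pat (", pat, " s) must be shorter than the mean ",
         "beat period (", round(60 / hr_mean, 3), " s)")
  }
  if (!(sbp > dbp && dbp > 0)) stop("subject_profile: need sbp > dbp > 0")
  m <- ecg_morph[order(ecg_morph$offset), , drop = FALSE]
  lo <- m$offset - m$width
  hi <- m$offset + m$width
  if (any(hi[-nrow(m)] >= lo[-1L])) {
    stop("subject_profile: infeasible ECG morphology (overlapping wave supports)")
  }
  structure(
    list(hr_mean = hr_mean, hr_jitter = hr_jitter, pat = pat,
         noise_snr = noise_snr, sbp = sbp, dbp = dbp, seed = as.integer(seed),
         ecg_morph = ecg_morph, ppg_morph = ppg_morph),
    class = "subject_profile"
  )
}

# Where the dicrotic notch actually crests.  The notch bump rides the
# flanks of the systolic trough and diastolic peak, which drag its
# summit away from the bump center; the true landmark of the waveform
# is the summit.  All component positions and widths scale with the
# beat period, so the apex offset is a fixed fraction of it, found
# once on a fine grid in period units (distances measured from the
# systolic trough).
dn_apex_frac <- function(pm) {
  g <- function(u, c, w) exp(-(u - c)^2 / (2 * w^2))
  u <- seq(pm$dn_frac - 2 * pm$dn_width, pm$dn_frac + 2 * pm$dn_width,
           by = 1e-4)
  f <- pm$sp_amp * g(u, 0, pm$sp_width) +
    pm$dn_amp * g(u, pm$dn_frac, pm$dn_width) +
    pm$dp_amp * g(u, pm$dp_frac, pm$dp_width) +
    pm$eb_amp * g(u, pm$eb_frac, pm$eb_width)
  n <- length(f)
  loc <- which(f[-c(1L, n)] > f[-c(n - 1L, n)] & f[-c(1L, n)] >= f[-(1:2)]) + 1L
  if (length(loc) == 0L) return(pm$dn_frac)  # no distinct summit
  u[loc[which.min(abs(u[loc] - pm$dn_frac))]]
}

# Beat schedule: R-peak times and per-beat periods covering `duration_s`
# with a lead-in so the first beat's P wave is inside the record.
# Lognormal multiplicative jitter with unit mean.
beat_schedule <- function(profile, duration_s) {
  base <- 60 / profile$hr_mean
  lead_in <- 0.40
  n_max <- ceiling(duration_s / base * (1 + 6 * profile$hr_jitter)) + 4L
  mult <- if (profile$hr_jitter > 0) {
    exp(stats::rnorm(n_max, 0, profile$hr_jitter) - profile$hr_jitter^2 / 2)
  } else {
    rep(1, n_max)
  }
  rr <- base * mult
  r_times <- lead_in + c(0, cumsum(rr[-n_max]))
  keep <- r_times < duration_s
  list(r_times = r_times[keep], rr = rr[seq_len(sum(keep))], base = base)
}

# Add amp * exp(-(t - center)^2 / (2 sd^2)) to `sig` in place (windowed
# to +/- 5 sd for speed); returns the updated signal.
add_bump <- function(sig, fs, center, amp, sd) {
  i0 <- max(1L, floor((center - 5 * sd) * fs) + 1L)
  i1 <- min(length(sig), ceiling((center + 5 * sd) * fs) + 1L)
  if (i0 > i1) return(sig)
  idx <- i0:i1
  tt <- (idx - 1) / fs
  sig[idx] <- sig[idx] + amp * exp(-(tt - center)^2 / (2 * sd^2))
  sig
}

# Additive measurement noise.  Noise enters at the channel's native
# acquisition rate (200 Hz ECG, 75 Hz PPG) and is carried through the
# same linear interpolation as the signal, so at the working rate it is
# band-limited -- white noise injected directly at 1200 Hz would have
# no physical source.  `snr_db` is measured against the mean-removed
# clean power at the output rate.
add_noise <- function(clean, snr_db, fs, native_fs = fs) {
  if (!is.finite(snr_db)) return(clean)
  p_sig <- stats::var(clean)
  sd_target <- sqrt(p_sig / 10^(snr_db / 10))
  n <- length(clean)
  if (native_fs >= fs) {
    return(clean + stats::rnorm(n, 0, sd_target))
  }
  n_nat <- ceiling((n - 1) * native_fs / fs) + 1L
  e_nat <- stats::rnorm(n_nat)
  t_nat <- (seq_len(n_nat) - 1) / native_fs
  e <- stats::approx(t_nat, e_nat, xout = (seq_len(n) - 1) / fs,
                     rule = 2)$y
  clean + e * (sd_target / stats::sd(e))
}

ecg_from_schedule <- function(profile, sched, duration_s, fs) {
  n <- round(duration_s * fs)
  sig <- numeric(n)
  m <- profile$ecg_morph
  rownames(m) <- m$wave
  truth <- vector("list", length(sched$r_times))
  for (k in seq_along(sched$r_times)) {
    r_t <- sched$r_times[k]
    centers <- r_t + m$offset
    for (w in seq_len(nrow(m))) {
      sig <- add_bump(sig, fs, centers[w], m$amp[w], m$width[w])
    }
    truth[[k]] <- c(
      p = r_t + m["p", "offset"], q = r_t + m["q", "offset"], r = r_t,
      s = r_t + m["s", "offset"], t = r_t + m["t", "offset"],
      qrs_on = r_t + m["q", "offset"] - 2 * m["q", "width"],
      qrs_off = r_t + m["s", "offset"] + 2 * m["s", "width"]
    )
  }
  list(signal = sig, truth_times = do.call(rbind, truth))
}

ppg_from_schedule <- function(profile, sched, duration_s, fs) {
  n <- round(duration_s * fs)
  sig <- numeric(n)
  pm <- profile$ppg_morph
  apex <- if (pm$dn_amp != 0) dn_apex_frac(pm) else NA_real_
  truth <- vector("list", length(sched$r_times))
  for (k in seq_along(sched$r_times)) {
    T_k <- sched$rr[k]
    sp_t <- sched$r_times[k] + profile$pat
    dn_t <- sp_t + pm$dn_frac * T_k
    dp_t <- sp_t + pm$dp_frac * T_k
    eb_t <- sp_t + pm$eb_frac * T_k
    sig <- add_bump(sig, fs, sp_t, pm$sp_amp, pm$sp_width * T_k)
    if (pm$dn_amp != 0) {
      sig <- add_bump(sig, fs, dn_t, pm$dn_amp, pm$dn_width * T_k)
    }
    sig <- add_bump(sig, fs, dp_t, pm$dp_amp, pm$dp_width * T_k)
    sig <- add_bump(sig, fs, eb_t, pm$eb_amp, pm$eb_width * T_k)
    truth[[k]] <- c(sp = sp_t,
                    dn = if (pm$dn_amp != 0) sp_t + apex * T_k else NA_real_,
                    dp = dp_t, eb = eb_t)
  }
  list(signal = sig, truth_times = do.call(rbind, truth))
}

truth_to_indices <- function(truth_times, fs, n) {
  idx <- round(truth_times * fs) + 1
  idx[idx < 1 | idx > n] <- NA
  df <- as.data.frame(idx)
  # keep only beats fully inside the record
  complete <- stats::complete.cases(df[, setdiff(names(df), "dn"), drop = FALSE])
  df <- df[complete, , drop = FALSE]
  tt <- as.data.frame(truth_times)[complete, , drop = FALSE]
  cbind(beat_id = seq_len(nrow(df)), df, setNames(tt, paste0(names(tt), "_time")))
}

#' Generate a synthetic ECG stream with ground truth
#'
#' @param profile A [subject_profile()].
#' @param duration_s Record duration in seconds (at least 2 beats).
#' @param fs Sampling rate in Hz.
#' @return A list with `stream` (a `signal_stream`) and `truth`, a
#'   data.frame of per-beat true indices (`p, q, r, s, t, qrs_on,
#'   qrs_off`, 1-based at `fs`) and times (`*_time`, seconds).
#' @export
synth_ecg <- function(profile, duration_s, fs = 1200) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration_s < 2 * 60 / profile$hr_mean) {
    stop("synth_ecg: duration must cover at least 2 beats")
  }
  with_seed(profile$seed, {
    sched <- beat_schedule(profile, duration_s)
    gen <- ecg_from_schedule(profile, sched, duration_s, fs)
    sig <- add_noise(gen$signal, profile$noise_snr, fs, native_fs = 200)
    list(stream = signal_stream(sig, fs, "ecg"),
         truth = truth_to_indices(gen$truth_times, fs, length(sig)))
  })
}

#' Generate a synthetic PPG stream with ground truth
#'
#' @inheritParams synth_ecg
#' @return A list with `stream` and `truth` (`sp, dn, dp, eb`; `dn` is
#'   `NA` when the dicrotic amplitude is 0).
#' @export
synth_ppg <- function(profile, duration_s, fs = 1200) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration_s < 2 * 60 / profile$hr_mean) {
    stop("synth_ppg: duration must cover at least 2 beats")
  }
  with_seed(profile$seed + 1L, {
    sched <- beat_schedule(profile, duration_s)
    gen <- ppg_from_schedule(profile, sched, duration_s, fs)
    sig <- add_noise(gen$signal, profile$noise_snr, fs, native_fs = 75)
    list(stream = signal_stream(sig, fs, "ppg"),
         truth = truth_to_indices(gen$truth_times, fs, length(sig)))
  })
}

#' Generate a concurrent ECG/PPG pair at native acquisition rates
#'
#' Both channels share one beat clock: beat `k`'s systolic trough on
#' the PPG is placed `pat` seconds after its R peak.  The ECG is
#' synthesized at 200 samples/s and the PPG at 75 samples/s (typical
#' bedside-monitor rates), then both are upsampled to the 1200 Hz
#' working rate with [resample_to()] -- exercising the same
#' acquisition-to-analysis path the detectors expect.  Truth indices
#' are reported at 1200 Hz.
#'
#' @inheritParams synth_ecg
#' @param fs_ecg,fs_ppg Native acquisition rates (defaults 200 and 75).
#' @param fs_work Working rate after interpolation (default 1200).
#' @return A list with `ecg` and `ppg` (both `signal_stream`s at
#'   `fs_work`) and `truth`: `$ecg`, `$ppg` per-beat index tables, the
#'   per-beat `$features` implied by the programmed offsets (seconds)
#'   and the profile's `$sbp`, `$dbp`.
#' @export
synth_paired <- function(profile, duration_s, fs_ecg = 200, fs_ppg = 75,
                         fs_work = 1200) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(profile$seed, {
    sched <- beat_schedule(profile, duration_s)
    gen_e <- ecg_from_schedule(profile, sched, duration_s, fs_ecg)
    gen_p <- ppg_from_schedule(profile, sched, duration_s, fs_ppg)
    ecg <- signal_stream(add_noise(gen_e$signal, profile$noise_snr, fs_ecg),
                         fs_ecg, "ecg")
    ppg <- signal_stream(add_noise(gen_p$signal, profile$noise_snr, fs_ppg),
                         fs_ppg, "ppg")
    ecg_w <- resample_to(ecg, fs_work)
    ppg_w <- resample_to(ppg, fs_work)
    n_w <- min(length(ecg_w$samples), length(ppg_w$samples))
    truth <- list(
      ecg = truth_to_indices(gen_e$truth_times, fs_work, n_w),
      ppg = truth_to_indices(gen_p$truth_times, fs_work, n_w),
      features = true_beat_features(profile, sched),
      sbp = profile$sbp, dbp = profile$dbp
    )
    list(ecg = ecg_w, ppg = ppg_w, truth = truth)
  })
}

# Analytic per-beat feature values (seconds) implied by the programmed
# morphology -- no waveform involved.
true_beat_features <- function(profile, sched) {
  m <- profile$ecg_morph
  rownames(m) <- m$wave
  pm <- profile$ppg_morph
  apex <- if (pm$dn_amp != 0) dn_apex_frac(pm) else NA_real_
  nb <- length(sched$r_times)
  rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    T_k <- sched$rr[k]
    nxt <- if (k < nb) sched$rr[k] else NA_real_  # interval to next beat
    e <- c(p = m["p", "offset"], q = m["q", "offset"], r = 0,
           s = m["s", "offset"], t = m["t", "offset"])
    qrs_on <- m["q", "offset"] - 2 * m["q", "width"]
    qrs_off <- m["s", "offset"] + 2 * m["s", "width"]
    sp <- profile$pat
    dn <- if (pm$dn_amp != 0) sp + apex * T_k else NA_real_
    dp <- sp + pm$dp_frac * T_k
    eb <- sp + pm$eb_frac * T_k
    v <- c(
      Tqrs = qrs_off - qrs_on,
      Tpr = e[["r"]] - e[["p"]],
      Tst = e[["t"]] - e[["s"]],
      Trr = if (k < nb) sched$r_times[k + 1] - sched$r_times[k] else NA_real_,
      Tpt = e[["t"]] - e[["p"]],
      Tab = eb - dp,
      Tbb = if (k < nb) {
        (sched$r_times[k + 1] + profile$pat + pm$eb_frac * sched$rr[k + 1]) -
          (sched$r_times[k] + eb)
      } else NA_real_,
      Taa = if (k < nb) {
        (sched$r_times[k + 1] + profile$pat + pm$dp_frac * sched$rr[k + 1]) -
          (sched$r_times[k] + dp)
      } else NA_real_,
      Tn1b = eb - dn, Tn2b = eb - sp, Tn2n1 = dn - sp, Tn2a = dp - sp
    )
    cross <- unlist(lapply(c("p", "q", "r", "s", "t"), function(i) {
      ei <- e[[i]]
      setNames(abs(c(dp - ei, eb - ei, dn - ei, sp - ei)),
               paste0("T_", toupper(i), c("A", "B", "N1", "N2")))
    }))
    rows[[k]] <- c(v, cross)
  }
  out <- as.data.frame(do.call(rbind, rows))
  out[feature_names()]
}

#' Ground-truth blood-pressure map of the synthetic cohort
#'
#' The generator couples blood pressure to timing features through a
#' log-linear map: `ln(BP) = b0 + b' x` over the features `T_RN2`
#' (pulse arrival time), `Trr` (beat period) and `Tn2b` (systolic
#' trough to end of beat, the pulse's active portion).  Slopes carry
#' the physiologically expected signs (shorter PAT, higher pressure);
#' the intercepts are set so that, over the default parameter ranges,
#' cohort SBP and DBP center on 128.45 and 77.73 mmHg, matching the
#' reference population the cohort emulates.  This map is the recovery
#' target for the model stage, not a claim about physiology.
#'
#' @return A list with numeric vectors `sbp` and `dbp`, each
#'   `c(intercept, T_RN2, Trr, Tn2b)`.
#' @export
default_bp_map <- function() {
  sbp_slopes <- c(T_RN2 = -1.8, Trr = 0.25, Tn2b = -1.0)
  dbp_slopes <- c(T_RN2 = -1.5, Trr = 0.18, Tn2b = -0.8)
  # exponentiation makes the arithmetic cohort mean exceed
  # exp(E[b'x]); anchor the intercept with the exact expectation of
  # exp(b'x) over the cohort parameter ranges (midpoint quadrature;
  # the three underlying draws are independent uniforms, with the
  # default 0.03 lognormal label noise)
  e_exp <- function(s) {
    mid <- function(a, b, n = 200) seq(a + (b - a) / (2 * n),
                                       b - (b - a) / (2 * n),
                                       length.out = n)
    f_pat <- mean(exp(s[["T_RN2"]] * mid(0.15, 0.33)))
    trr_g <- 60 / mid(55, 100)
    eb_g <- mid(0.54, 0.70)
    f_te <- mean(exp(outer(trr_g, eb_g,
                           function(t, e) (s[["Trr"]] + s[["Tn2b"]] * e) * t)))
    f_pat * f_te * exp(0.03^2 / 2)
  }
  list(
    sbp = c(intercept = log(128.45) - log(e_exp(sbp_slopes)), sbp_slopes),
    dbp = c(intercept = log(77.73) - log(e_exp(dbp_slopes)), dbp_slopes)
  )
}

#' Simulate a cohort of subjects with feature-coupled blood pressure
#'
#' Draws per-subject physiology (heart rate uniform on 55-100 bpm,
#' pulse arrival time uniform on 0.15-0.33 s, dicrotic-notch placement
#' uniform on 0.16-0.24 and end-of-beat placement uniform on 0.54-0.70
#' of the beat period) and computes reference SBP/DBP from the
#' ground-truth log-linear map plus lognormal noise.
#' Under the defaults the resulting pressures are approximately
#' normal with SBP near 128 +/- 15 mmHg and DBP near 78 +/- 9 mmHg;
#' draws outside plausible clinical ranges are rejected and redrawn.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @param bp_map Ground-truth map, as [default_bp_map()].
#' @param bp_noise_sd SD of the log-scale BP noise (default 0.03).
#' @param noise_snr Waveform noise level passed to each profile (dB).
#' @param hr_jitter Beat-to-beat R-R variability for each profile.
#' @return A list of class `synth_cohort`; each element has `profile`,
#'   `true_features` (named vector `T_RN2, Trr, Tn2b`), `sbp`, `dbp`.
#' @export
synth_cohort <- function(n_subjects, seed = 1L, bp_map = default_bp_map(),
                         bp_noise_sd = 0.03, noise_snr = 30,
                         hr_jitter = 0.02) {
  stopifnot(n_subjects >= 2L)
  with_seed(seed, {
    subjects <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      for (attempt in 1:100) {
        hr <- stats::runif(1, 55, 100)
        pat <- stats::runif(1, 0.15, 0.33)
        pm_i <- default_ppg_morphology()
        pm_i$dn_frac <- stats::runif(1, 0.16, 0.24)
        pm_i$eb_frac <- stats::runif(1, 0.54, 0.70)
        trr <- 60 / hr
        x <- c(T_RN2 = pat, Trr = trr, Tn2b = pm_i$eb_frac * trr)
        sbp <- exp(bp_map$sbp[["intercept"]] + sum(bp_map$sbp[-1L] * x) +
                     stats::rnorm(1, 0, bp_noise_sd))
        dbp <- exp(bp_map$dbp[["intercept"]] + sum(bp_map$dbp[-1L] * x) +
                     stats::rnorm(1, 0, bp_noise_sd))
        ok <- sbp >= 90 && sbp <= 185 && dbp >= 50 && dbp <= 115 &&
          sbp > dbp + 15
        if (ok) break
      }
      prof <- subject_profile(
        hr_mean = hr, hr_jitter = hr_jitter, pat = pat,
        noise_snr = noise_snr, sbp = sbp, dbp = dbp,
        seed = sample.int(2^20, 1L), ppg_morph = pm_i
      )
      subjects[[i]] <- list(profile = prof, true_features = x,
                            sbp = sbp, dbp = dbp)
    }
    structure(subjects, class = "synth_cohort")
  })
}
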