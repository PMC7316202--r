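# Independent brute-force oracles, written as plain per-level loops so
# they share no code path with the package implementation.

# Orthonormal Haar analysis: explicit 2-tap filter + downsample per
# level, scalar loop, last-sample padding for odd lengths.
oracle_haar <- function(x, max_level) {
  cA <- list(); cD <- list()
  cur <- x
  for (l in seq_len(max_level)) {
    if (length(cur) %% 2 == 1) cur <- c(cur, cur[length(cur)])
    m <- length(cur) / 2
    a <- numeric(m); d <- numeric(m)
    for (k in seq_len(m)) {
      a[k] <- (cur[2 * k - 1] + cur[2 * k]) / sqrt(2)
      d[k] <- (cur[2 * k - 1] - cur[2 * k]) / sqrt(2)
    }
    cA[[l]] <- a; cD[[l]] <- d
    cur <- a
  }
  list(cA = cA, cD = cD)
}

# Brute-force modulus maxima of the level-1 detail: scalar scan for
# strict-left / weak-right local maxima above the relative floor.
oracle_modulus_maxima <- function(x, threshold_frac = 0.05) {
  d <- oracle_haar(x, 1)$cD[[1]]
  m <- abs(d)
  thr <- threshold_frac * max(m)
  if (max(m) == 0) return(integer(0))
  out <- integer(0)
  for (k in 2:(length(m) - 1)) {
    if (m[k] > m[k - 1] && m[k] >= m[k + 1] && m[k] >= thr) {
      out <- c(out, (k - 1) * 2 + 1)
    }
  }
  out
}

# Scalar-loop agreement statistics (mean error, mean absolute error,
# n-1 standard deviation of errors).
oracle_eval <- function(p, y) {
  n <- length(p)
  me <- 0
  for (i in seq_len(n)) me <- me + (p[i] - y[i])
  me <- me / n
  mae <- 0
  for (i in seq_len(n)) mae <- mae + abs(p[i] - y[i])
  mae <- mae / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + ((p[i] - y[i]) - me)^2
  list(me = me, mae = mae, sd = sqrt(ss / (n - 1)))
}

# Shared fixtures: a standard quiet subject and its matched-beat table.
quiet_profile <- function(hr = 75, snr = Inf, seed = 7, ...) {
  subject_profile(hr_mean = hr, hr_jitter = 0.02, noise_snr = snr,
                  seed = seed, ...)
}

# Match detected beats to truth on an anchor column; returns a
# data.frame of per-beat absolute index errors for the given points,
# NA where the beat was not matched within `tol` samples.
match_beats <- function(det, truth, anchor, tol, points) {
  out <- lapply(points, function(pt) {
    vapply(seq_len(nrow(truth)), function(i) {
      if (nrow(det) == 0) return(NA_real_)
      j <- which.min(abs(det[[anchor]] - truth[[anchor]][i]))
      if (abs(det[[anchor]][j] - truth[[anchor]][i]) <= tol) {
        abs(det[[pt]][j] - truth[[pt]][i])
      } else NA_real_
    }, numeric(1))
  })
  names(out) <- points
  as.data.frame(out)
}
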