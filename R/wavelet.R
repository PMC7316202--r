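#' Multilevel Haar discrete wavelet transform
#'
#' Orthonormal Haar analysis cascade: at each level the current
#' approximation `x` is split into pairs and
#' `cA[k] = (x[2k-1] + x[2k]) / sqrt(2)`,
#' `cD[k] = (x[2k-1] - x[2k]) / sqrt(2)`.
#' Detail coefficients are proportional to the local (negated, for an
#' upslope) derivative at scale `2^level`, which is what the
#' delineators exploit: steep deflections show up as extreme detail
#' coefficients.  Odd-length inputs are extended by repeating the last
#' sample, which adds no artificial edge singularity.
#'
#' @param x Numeric vector (an analysis window).
#' @param max_level Decomposition depth, 1..5.
#' @return A list of class `haar_dwt` with elements `level` and lists
#'   `cA`, `cD` (`cA[[l]]`, `cD[[l]]` for l = 1..`max_level`).
#' @export
#' @examples
#' d <- haar_dwt(c(1, 3), 1)
#' d$cA[[1]] # 2*sqrt(2)
#' d$cD[[1]] # -sqrt(2)
haar_dwt <- function(x, max_level = 5L) {
  x <- as.numeric(x)
  max_level <- as.integer(max_level)
  if (max_level < 1L || max_level > 5L) {
    stop("haar_dwt: 'max_level' must be between 1 and 5")
  }
  if (length(x) < 2^max_level) {
    stop("haar_dwt: window of ", length(x),
         " samples is too short for level ", max_level,
         " (needs >= ", 2^max_level, ")")
  }
  cA <- vector("list", max_level)
  cD <- vector("list", max_level)
  cur <- x
  for (l in seq_len(max_level)) {
    if (length(cur) %% 2L == 1L) cur <- c(cur, cur[length(cur)])
    ev <- cur[seq(1L, length(cur), by = 2L)]
    od <- cur[seq(2L, length(cur), by = 2L)]
    cA[[l]] <- (ev + od) / sqrt(2)
    cD[[l]] <- (ev - od) / sqrt(2)
    cur <- cA[[l]]
  }
  structure(list(level = max_level, cA = cA, cD = cD), class = "haar_dwt")
}

#' Map between coefficient and signal indices
#'
#' A level-`l` coefficient `k` (1-based) summarizes samples
#' `(k-1)*2^l + 1 .. k*2^l` of the analysis window.  The forward map
#' returns the left edge of that support; the inverse map returns the
#' coefficient whose support contains a sample.  The two compose to
#' the identity on coefficient indices.
#'
#' @param level Decomposition level, 1..5.
#' @param k Coefficient index (1-based).
#' @param i Sample index (1-based).
#' @return A 1-based sample or coefficient index.
#' @export
#' @examples
#' coeff_to_signal_index(3, 3) # 17: left edge of the third level-3 support
coeff_to_signal_index <- function(level, k) {
  stopifnot(level >= 1L, level <= 5L, all(k >= 1L))
  as.integer((k - 1L) * 2^level + 1L)
}

#' @rdname coeff_to_signal_index
#' @export
signal_to_coeff_index <- function(level, i) {
  stopifnot(level >= 1L, level <= 5L, all(i >= 1L))
  as.integer((i - 1L) %/% 2^level + 1L)
}

#' Wavelet-transform modulus maxima
#'
#' Locations of singularities in an analysis window: strict local
#' maxima of the level-1 Haar detail modulus `|cD_l1|`, kept when they
#' reach at least `threshold_frac` of the window's largest modulus, and
#' mapped back to signal coordinates (left edge of the coefficient
#' support).  Level 1 is the finest scale and therefore the sharpest
#' localizer of sudden amplitude changes.  Plateaus keep their leftmost
#' sample.  The threshold is relative, so the result is invariant under
#' amplitude scaling of the window.
#'
#' @param x Numeric analysis window, at least 128 samples (the working
#'   minimum for modulus-maxima analysis after five halvings).
#' @param threshold_frac Fraction of the global maximum modulus used as
#'   floor (default 0.05).
#' @return Integer vector of strictly increasing 1-based sample
#'   indices; attribute `threshold` records the absolute floor used.
#' @export
modulus_maxima <- function(x, threshold_frac = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 128L) {
    stop("modulus_maxima: window has ", length(x),
         " samples; at least 128 are required")
  }
  stopifnot(threshold_frac >= 0, threshold_frac <= 1)
  d <- haar_dwt(x, 1L)$cD[[1L]]
  m <- abs(d)
  mx <- max(m)
  thr <- threshold_frac * mx
  if (mx == 0) {
    out <- integer(0)
    attr(out, "threshold") <- 0
    return(out)
  }
  n <- length(m)
  k <- which(m[-c(1L, n)] > m[-c(n - 1L, n)] &      # strictly above left
             m[-c(1L, n)] >= m[-(1:2)] &            # at least right (plateau: leftmost)
             m[-c(1L, n)] >= thr) + 1L
  out <- coeff_to_signal_index(1L, k)
  attr(out, "threshold") <- thr
  out
}
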