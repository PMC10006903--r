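# Time- and frequency-domain descriptors of a signal window.
#
# Conventions used throughout: population (1/N) moments; quantiles with
# linear interpolation between order statistics (stats::quantile type 7);
# spectra from the unnormalised DFT (stats::fft); one-sided spectrum =
# bins DC..Nyquist.

#' Signal mean
#' @param x Numeric series (length >= 1).
#' @return `(1/N) * sum(x)`.
#' @export
signal_mean <- function(x) {
  if (length(x) < 1) stop("empty series")
  sum(x) / length(x)
}

#' Population variance
#'
#' The `1/N` (population) form, i.e. the mean squared deviation from the
#' series mean.
#'
#' @param x Numeric series (length >= 1).
#' @return Non-negative number.
#' @export
signal_variance <- function(x) {
  if (length(x) < 1) stop("empty series")
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

#' Pearson correlation coefficient between two series
#'
#' `cov(x, y) / (sd(x) * sd(y))`. If either input is constant the
#' coefficient is undefined; it is returned as 0 with a warning.
#'
#' @param x,y Numeric series of equal length (>= 2).
#' @return Number in `[-1, 1]`.
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2) stop("need at least 2 samples")
  sx <- sqrt(signal_variance(x))
  sy <- sqrt(signal_variance(y))
  if (sx == 0 || sy == 0) {
    warning("constant input; correlation coefficient defined as 0")
    return(0)
  }
  mx <- signal_mean(x)
  my <- signal_mean(y)
  cv <- sum((x - mx) * (y - my)) / length(x)
  max(-1, min(1, cv / (sx * sy)))
}

#' Spectral signal energy
#'
#' `(1/N) * sum(|F_k|^2)` over the full unnormalised DFT of `x`; by
#' Parseval's theorem this equals `sum(x^2)`.
#'
#' @param x Numeric series (length >= 1).
#' @return Non-negative number.
#' @export
signal_energy <- function(x) {
  if (length(x) < 1) stop("empty series")
  sum(Mod(stats::fft(x))^2) / length(x)
}

# One-sided magnitude-squared spectrum: bins DC .. Nyquist.
.one_sided_power <- function(x) {
  p <- Mod(stats::fft(x))^2
  p[seq_len(floor(length(x) / 2) + 1L)]
}

#' Spectral entropy over K subframes
#'
#' The one-sided magnitude-squared spectrum is partitioned into `K`
#' contiguous subframes of `floor(M / K)` bins each (any remainder bins at
#' the top of the band are dropped); the subframe energies are normalised to
#' a distribution and its Shannon entropy (base 2) returned, with
#' `0 * log2(0) := 0`. A zero-energy signal has no spectral distribution;
#' its entropy is defined as 0 with a warning.
#'
#' @param x Numeric series with `length(x) >= K`.
#' @param K Number of subframes (>= 2).
#' @return Number in `[0, log2(K)]`.
#' @export
spectral_entropy <- function(x, K = 8L) {
  if (K < 2) stop("K must be >= 2")
  if (length(x) < K) stop("series shorter than K")
  p <- .one_sided_power(x)
  m <- length(p) %/% K
  if (m < 1) stop("too few spectral bins for K subframes")
  e_k <- vapply(seq_len(K), function(k) {
    sum(p[((k - 1L) * m + 1L):(k * m)])
  }, numeric(1))
  tot <- sum(e_k)
  if (tot <= 0) {
    warning("zero-energy signal; spectral entropy defined as 0")
    return(0)
  }
  n_k <- e_k / tot
  nz <- n_k > 0
  -sum(n_k[nz] * log2(n_k[nz]))
}

#' Dominant frequency within a band
#'
#' Returns the frequency of the largest one-sided spectral magnitude whose
#' bin frequency lies in `[band[1], band[2]]`. Ties are broken toward the
#' lower frequency.
#'
#' @param x Numeric series.
#' @param rate Sampling rate in Hz.
#' @param band Length-2 numeric `(f_lo, f_hi)` inside `(0, rate/2]`.
#' @return Frequency in Hz.
#' @export
#' @examples
#' t <- (0:799) / 20
#' dominant_frequency(sin(2 * pi * 0.25 * t), 20, c(0.1, 1))  # 0.25
dominant_frequency <- function(x, rate, band) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < 0 || band[2] > rate / 2) stop("band must lie within (0, rate/2]")
  p <- .one_sided_power(x)
  freqs <- (seq_along(p) - 1) * rate / length(x)
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0) stop("band contains no spectral bins at this resolution")
  freqs[sel[which.max(p[sel])]]
}
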