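#' Welch power spectral density estimate
#'
#' Hann-windowed, overlapping-segment averaged one-sided periodogram.  The
#' normalization is density-style: summing \code{psd * df} over all
#' frequencies recovers the windowed signal variance (Parseval).
#'
#' @param x Numeric series (demeaned internally).
#' @param fs Sampling frequency (Hz).
#' @param nperseg Segment length in samples; shortened to \code{length(x)}
#'   when the series is shorter.
#' @param overlap Fractional overlap between segments in [0, 1).
#' @param demean_segments Remove each segment's mean before windowing.
#' @return A list with \code{freq} (Hz, excluding 0) and \code{psd}
#'   (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 2048, overlap = 0.5,
                      demean_segments = TRUE) {
  n <- length(x)
  nseg <- min(as.integer(nperseg), n)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  nfreq <- nseg %/% 2L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean_segments) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- Mod(X[2:(nfreq + 1L)])^2
    acc <- acc + p
  }
  psd <- acc / (length(starts) * u * fs) * 2
  # the bin at the Nyquist frequency (even nseg) is not doubled
  if (nseg %% 2L == 0L) psd[nfreq] <- psd[nfreq] / 2
  freq <- (1:nfreq) * fs / nseg
  list(freq = freq, psd = psd)
}

band_mask <- function(freq, band) freq >= band[1] & freq <= band[2]
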