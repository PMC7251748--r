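## Whole-token magnitude spectrum, Hamming-segmented variance envelope and
## the regression slope matrix feeding the matching filter.

hamming_window <- function(L) {
  if (L == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

# magnitude spectrum of a bare sample vector: signals longer than fft_size
# are cut into fft_size chunks (last chunk zero-padded) and the chunk
# magnitude spectra averaged; shorter signals are zero-padded.
spectrum_of_samples <- function(x, fs, fft_size) {
  half <- fft_size %/% 2L
  n_chunks <- max(1L, ceiling(length(x) / fft_size))
  padded <- c(x, numeric(n_chunks * fft_size - length(x)))
  acc <- numeric(half)
  for (k in seq_len(n_chunks)) {
    chunk <- padded[((k - 1L) * fft_size + 1L):(k * fft_size)]
    acc <- acc + Mod(stats::fft(chunk))[seq_len(half)]
  }
  list(amplitudes = acc / n_chunks,
       freqs = (seq_len(half) - 1) * fs / fft_size,
       fft_size = as.integer(fft_size), fs = fs)
}

#' Whole-token magnitude spectrum
#'
#' One stable magnitude spectrum per token (FFT size 1024 by default):
#' tokens longer than the FFT size are split into FFT-size chunks whose
#' magnitude spectra are averaged; shorter tokens are zero-padded. Bins run
#' from 0 to just under the Nyquist frequency.
#'
#' @param token a [speech_token].
#' @param fft_size FFT length, a power of two.
#' @return object of class `pf_spectrum` with fields `amplitudes`, `freqs`,
#'   `fft_size`, `fs`.
#' @export
magnitude_spectrum <- function(token, fft_size = 1024L) {
  stopifnot(inherits(token, "speech_token"))
  fft_size <- as.integer(fft_size)
  if (fft_size < 2L || bitwAnd(fft_size, fft_size - 1L) != 0L)
    stop("config error: fft_size must be a power of two", call. = FALSE)
  structure(spectrum_of_samples(token$samples, token$fs, fft_size),
            class = "pf_spectrum")
}

#' Segment a spectrum into overlapping Hamming-weighted windows
#'
#' The magnitude spectrum is cut into sliding segments of `win_hz` Hz,
#' shifted by `hop_hz` Hz (689 / 344 Hz equal exactly 16 / 8 bins at
#' 44.1 kHz, FFT 1024). Each segment is multiplied elementwise by a Hamming
#' window (disable with `window = "rect"`). `seg_freqs` holds the mean bin
#' frequency of each segment, the frequency coordinate used for the cut-off.
#'
#' @param spec a `pf_spectrum`.
#' @param win_hz,hop_hz window size and shift in Hz; converted to bins by
#'   rounding.
#' @param window `"hamming"` or `"rect"`.
#' @return object of class `pf_segments`: `segments` (win_bins x N matrix),
#'   `seg_freqs`, `win_bins`, `hop_bins`.
#' @export
segment_spectrum <- function(spec, win_hz = 689, hop_hz = 344,
                             window = c("hamming", "rect")) {
  stopifnot(inherits(spec, "pf_spectrum"), win_hz > hop_hz, hop_hz > 0)
  window <- match.arg(window)
  bin_hz <- spec$fs / spec$fft_size
  win_bins <- max(2L, as.integer(round(win_hz / bin_hz)))
  hop_bins <- max(1L, as.integer(round(hop_hz / bin_hz)))
  nb <- length(spec$amplitudes)
  if (win_bins > nb)
    stop("invalid-config error: window wider than the spectrum",
         call. = FALSE)
  starts <- seq(1L, nb - win_bins + 1L, by = hop_bins)
  w <- if (window == "hamming") hamming_window(win_bins) else rep(1, win_bins)
  segments <- vapply(starts, function(s)
    spec$amplitudes[s:(s + win_bins - 1L)] * w, numeric(win_bins))
  seg_freqs <- vapply(starts, function(s)
    mean(spec$freqs[s:(s + win_bins - 1L)]), numeric(1))
  structure(list(segments = segments, seg_freqs = seg_freqs,
                 win_bins = win_bins, hop_bins = hop_bins,
                 window = window, bin_hz = bin_hz),
            class = "pf_segments")
}

#' Variance envelope of a segmented spectrum
#'
#' Per-segment population variance (divisor L, not L-1) of the
#' window-weighted amplitude values. Low-energy spectral regions have small,
#' slowly varying amplitudes and hence a small variance, which is what the
#' cut-off search exploits.
#'
#' @param segs a `pf_segments`.
#' @return object of class `pf_envelope`: `M` (variances), `N`.
#' @export
variance_envelope <- function(segs) {
  stopifnot(inherits(segs, "pf_segments"))
  if (ncol(segs$segments) == 0L)
    stop("segments non-empty required", call. = FALSE)
  L <- nrow(segs$segments)
  M <- apply(segs$segments, 2L, function(s) sum((s - mean(s))^2) / L)
  structure(list(M = M, N = length(M)), class = "pf_envelope")
}

#' Regression slope matrix of a variance envelope
#'
#' `R[c]` is the ordinary least-squares slope of the points
#' `(v, M[v]), v = c..N`, for `c = 1..N-1`: the tail fit starting at each
#' segment. Small `|R[c]|` marks the flat low-energy tail; the magnitude
#' grows once the fit window reaches the high-energy region.
#'
#' @param env a `pf_envelope`.
#' @return object of class `pf_slopes` with field `R` (length N-1).
#' @export
slope_matrix <- function(env) {
  stopifnot(inherits(env, "pf_envelope"))
  N <- env$N
  if (N < 2L)
    stop("insufficient-data error: need at least 2 segments", call. = FALSE)
  R <- vapply(seq_len(N - 1L), function(c) {
    v <- c:N
    x <- v - mean(v)
    sum(x * (env$M[v] - mean(env$M[v]))) / sum(x^2)
  }, numeric(1))
  structure(list(R = R, N = N), class = "pf_slopes")
}
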