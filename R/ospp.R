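## OSPP: per-frame excess of the most prominent one-third-octave spectral
## line over a least-squares regression baseline across band indices.

#' One-third-octave band set
#'
#' Divides 0..fs/2 into `n_bands` one-third-octave bands, anchored at the
#' top: the last band's upper edge `f2` equals fs/2 and each band satisfies
#' `f2/f1 = 2^(1/3)` and `fc = sqrt(f1*f2)` exactly. The first band's
#' *collection* range is extended down to 0 Hz (column `lo`) so the bands
#' cover \[0, fs/2\] with no gap, while its tabulated `f1` stays geometric
#' so the band-ratio identities hold for every band.
#'
#' @param fs sampling rate in Hz.
#' @param n_bands number of bands (default 43, the published count for
#'   44.1 kHz).
#' @return a `data.frame` of class `pf_octave_bands` with columns
#'   `index`, `f1`, `fc`, `f2`, `lo` and attribute `fs`.
#' @export
octave_bands <- function(fs = 44100, n_bands = 43L) {
  stopifnot(fs > 0, n_bands >= 1L)
  r <- 2^(1 / 3)
  i <- seq_len(n_bands)
  f2 <- (fs / 2) * r^(i - n_bands)
  f1 <- f2 / r
  fc <- f1 * 2^(1 / 6)
  lo <- f1
  lo[1] <- 0
  out <- data.frame(index = i, f1 = f1, fc = fc, f2 = f2, lo = lo)
  attr(out, "fs") <- fs
  class(out) <- c("pf_octave_bands", "data.frame")
  out
}

#' One-third-octave spectrum of a frame
#'
#' Magnitude spectrum of the frame (FFT size 1024, chunk-averaged when the
#' frame is longer), then per band the mean of the linear magnitudes of the
#' bins whose center frequency falls in the band's collection range,
#' converted to dB (`20*log10`). Bands containing no bin, or only zero
#' magnitudes, are clamped to `db_floor` so the values stay finite.
#'
#' @param frame numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param bands a [octave_bands()] table.
#' @param fft_size FFT length (default 1024).
#' @param db_floor floor value in dB for empty/silent bands (default -120).
#' @param scale `"db"` (default) or `"linear"` spectral lines.
#' @return object of class `pf_octave_spectrum`: `E` (one value per band),
#'   `floor`, `scale`.
#' @export
octave_spectrum <- function(frame, fs, bands = octave_bands(fs),
                            fft_size = 1024L, db_floor = -120,
                            scale = c("db", "linear")) {
  scale <- match.arg(scale)
  if (length(frame) == 0L)
    stop("empty-input error: frame has no samples", call. = FALSE)
  sp <- spectrum_of_samples(frame, fs, fft_size)
  idx <- findInterval(sp$freqs, c(bands$lo, bands$f2[nrow(bands)]),
                      rightmost.closed = TRUE)
  E <- vapply(bands$index, function(i) {
    m <- sp$amplitudes[idx == i]
    if (length(m) == 0L) return(NA_real_)
    mean(m)
  }, numeric(1))
  if (scale == "db") {
    E <- ifelse(is.na(E) | E <= 0, db_floor, pmax(db_floor, 20 * log10(E)))
    flo <- db_floor
  } else {
    E <- ifelse(is.na(E), 0, E)
    flo <- 0
  }
  structure(list(E = E, floor = flo, scale = scale,
                 n_bands = nrow(bands)), class = "pf_octave_spectrum")
}

#' Least-squares baseline of a one-third-octave spectrum
#'
#' Ordinary least squares of the spectral line `E_i` on the band index `i`,
#' excluding floor-clamped bands. The line normalizes overall level and any
#' broad spectral tilt, so the peak excess measured against it is invariant
#' to global gain and to linear-in-index trends.
#'
#' @param os a `pf_octave_spectrum`.
#' @return list with `slope`, `intercept`, `used` (logical per band).
#' @export
octave_regression <- function(os) {
  stopifnot(inherits(os, "pf_octave_spectrum"))
  used <- os$E > os$floor
  if (sum(used) < 2L)
    stop("degenerate-spectrum error: fewer than 2 usable bands",
         call. = FALSE)
  i <- which(used)
  y <- os$E[used]
  xi <- i - mean(i)
  slope <- sum(xi * (y - mean(y))) / sum(xi^2)
  intercept <- mean(y) - slope * mean(i)
  list(slope = slope, intercept = intercept, used = used)
}

#' Prominent-peak excess of one frame
#'
#' `DF = peak - RL`: the most prominent spectral line (global maximum of
#' `E` by default) minus the regression-line value at the same band index.
#' `peak = "max_prominence"` instead selects the local maximum with the
#' greatest topographic prominence before measuring its excess.
#'
#' @param os a `pf_octave_spectrum`.
#' @param line a fitted baseline from [octave_regression()].
#' @param peak `"global_max"` or `"max_prominence"`.
#' @return the differential value `DF` (dB).
#' @export
ospp_frame <- function(os, line = octave_regression(os),
                       peak = c("global_max", "max_prominence")) {
  peak <- match.arg(peak)
  E <- os$E
  if (peak == "global_max") {
    k <- which.max(E)
  } else {
    k <- which.max(peak_prominences(E))
  }
  E[k] - (line$intercept + line$slope * k)
}

# topographic prominence of each position treated as a candidate peak
peak_prominences <- function(E) {
  n <- length(E)
  vapply(seq_len(n), function(k) {
    right <- if (k < n) (k + 1L):n else integer(0)
    higher_l <- which(E[seq_len(k - 1L)] > E[k])
    higher_r <- right[E[right] > E[k]]
    left_min <- if (length(higher_l)) min(E[max(higher_l):k]) else min(E[1:k])
    right_min <- if (length(higher_r)) min(E[k:min(higher_r)]) else min(E[k:n])
    E[k] - max(left_min, right_min)
  }, numeric(1))
}

#' OSPP feature of a token
#'
#' The token is cut into `n_frames` non-overlapping frames; each frame
#' yields one differential value `DF_n` = prominent one-third-octave peak
#' minus the least-squares regression line at the peak's band index.
#' Invariant to global gain (a dB shift is absorbed by the intercept).
#'
#' @param token a [speech_token].
#' @param n_frames number of frames N (default 10, shared with CSIFs).
#' @param config a [pf_config].
#' @return object of class `pf_ospp`: `DF` (length N), `n_frames`.
#' @export
ospp_feature <- function(token, n_frames = 10L, config = pf_config()) {
  stopifnot(inherits(token, "speech_token"))
  frames <- frame_signal(token$samples, n_frames)
  bands <- octave_bands(token$fs, config$n_bands)
  DF <- vapply(seq_len(ncol(frames)), function(n) {
    os <- octave_spectrum(frames[, n], token$fs, bands,
                          fft_size = config$fft_size,
                          db_floor = config$db_floor,
                          scale = config$octave_scale)
    ospp_frame(os, peak = config$peak)
  }, numeric(1))
  structure(list(DF = DF, n_frames = as.integer(n_frames)),
            class = "pf_ospp")
}
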