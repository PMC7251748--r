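# Fixtures built in code: constructed spectra, tones and noise tokens.

# step spectrum: high-amplitude noisy plateau up to (0-based) bin
# `step_bin`, low-amplitude tail after it -- the canonical input for the
# cut-off search
make_step_spectrum <- function(step_bin, seed, n_bins = 512L, fs = 44100,
                               hi = 10, hi_sd = 0.5, lo = 0.1,
                               lo_sd = 0.01) {
  set.seed(seed)
  amps <- c(pmax(0, stats::rnorm(step_bin, hi, hi_sd)),
            pmax(0, stats::rnorm(n_bins - step_bin, lo, lo_sd)))
  structure(list(amplitudes = amps,
                 freqs = (seq_len(n_bins) - 1) * fs / (2 * n_bins),
                 fft_size = 2L * n_bins, fs = fs),
            class = "pf_spectrum")
}

run_cutoff <- function(spec, ...) {
  segs <- segment_spectrum(spec)
  env <- variance_envelope(segs)
  detect_cutoff(segs, env, slope_matrix(env), ...)
}

sine_token <- function(freq, fs = 44100, dur = 0.25, amp = 0.5) {
  t <- seq(0, dur, by = 1 / fs)[-1]
  speech_token(amp * sin(2 * pi * freq * t), fs)
}

noise_token <- function(seed, n = 11025, fs = 44100) {
  set.seed(seed)
  speech_token(stats::rnorm(n, sd = 0.1), fs)
}

# a band split constructed directly (bypassing the filters) to exercise the
# framing + correlation stage in isolation
fake_split <- function(X_H, X_L, c_f = 5000, fs = 44100) {
  structure(list(X_H = X_H, X_L = X_L, c_f = c_f, fs = fs),
            class = "pf_bandsplit")
}

# write a 16-bit PCM WAV with an arbitrary channel count (the package
# writer is mono-only); channels are interleaved columns of `x`
write_wav_multichannel <- function(x, path, fs = 44100) {
  x <- as.matrix(x)
  ch <- ncol(x)
  pcm <- as.integer(round(t(x) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(ch, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L * ch), con, size = 4L, endian = "little")
  writeBin(2L * ch, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
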