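CONSONANT_TYPES <- c("c", "ch", "q", "s", "sh", "x")
CLASS_LABELS <- c("PF", "NS")
TARGET_FS <- 44100L

#' Construct a speech token
#'
#' A `speech_token` holds one pre-segmented initial consonant: the waveform,
#' its sampling rate and the clinical metadata carried through feature
#' extraction. Amplitudes are dimensionless, nominally in \[-1, 1\].
#'
#' @param samples numeric vector of finite amplitudes.
#' @param fs sampling rate in Hz (> 0).
#' @param consonant one of `"c","ch","q","s","sh","x"` or `NA`.
#' @param label class label, `"PF"` (pharyngeal fricative), `"NS"` (normal
#'   speech) or `"unknown"`.
#' @param source_id opaque identifier (defaults to `""`).
#' @return an object of class `speech_token`.
#' @export
speech_token <- function(samples, fs, consonant = NA_character_,
                         label = "unknown", source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("empty-input error: token has no samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("token samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  if (!is.na(consonant) && !consonant %in% CONSONANT_TYPES)
    stop("unknown consonant type: ", consonant, call. = FALSE)
  if (!label %in% c(CLASS_LABELS, "unknown"))
    stop("value error: label must be PF, NS or unknown", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs),
                 consonant = consonant, label = label,
                 source_id = as.character(source_id)),
            class = "speech_token")
}

#' @export
print.speech_token <- function(x, ...) {
  cat(sprintf("<speech_token> %s: %d samples @ %g Hz (%.3f s), consonant=%s label=%s\n",
              x$source_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              ifelse(is.na(x$consonant), "?", x$consonant), x$label))
  invisible(x)
}

## ---- RIFF/PCM WAV I/O -----------------------------------------------------
## Minimal 16-bit PCM (format 1) and 32-bit IEEE float (format 3) reader.
## No audio package ships with this R stack, and the format is trivial.

read_le_int <- function(con, n, size, signed = TRUE) {
  # size-4 reads must be signed in R; WAV chunk sizes stay below 2^31 here
  readBin(con, "integer", n = n, size = size, endian = "little",
          signed = signed || size == 4L)
}

#' Read a PCM WAV file as a speech token
#'
#' Multichannel audio is averaged to mono; integer samples are scaled to
#' \[-1, 1\]. Files not sampled at 44.1 kHz are linearly resampled to
#' 44.1 kHz with a warning, because the band geometry downstream (one-third
#' octave bands up to 22,050 Hz, the 689/344 Hz segmentation) assumes that
#' rate.
#'
#' @param path WAV file path.
#' @param consonant,label,source_id metadata attached to the token;
#'   `source_id` defaults to the file name.
#' @return a [speech_token].
#' @export
read_wav <- function(path, consonant = NA_character_, label = "unknown",
                     source_id = basename(path)) {
  if (!file.exists(path))
    stop("format error: no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  invisible(read_le_int(con, 1L, 4L, signed = FALSE))  # chunk size
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("format error: not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    sz <- read_le_int(con, 1L, 4L, signed = FALSE)
    if (is.na(sz)) break
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format   = sum(as.integer(body[1:2]) * c(1, 256)),
        channels = sum(as.integer(body[3:4]) * c(1, 256)),
        fs       = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt))
        stop("format error: data chunk before fmt chunk", call. = FALSE)
      if (fmt$format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
                           endian = "little", signed = TRUE) / 32768
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = sz %/% 4L, size = 4L,
                           endian = "little")
      } else {
        stop("format error: unsupported WAV encoding (format ", fmt$format,
             ", ", fmt$bits, " bits)", call. = FALSE)
      }
      break
    } else {
      # skip unknown chunk (word-aligned)
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
  }
  if (is.null(samples) || length(samples) == 0L)
    stop("empty-input error: WAV file has no audio data: ", path,
         call. = FALSE)
  if (fmt$channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  if (fmt$fs != TARGET_FS) {
    warning(sprintf("resampling %s from %d Hz to %d Hz", basename(path),
                    fmt$fs, TARGET_FS), call. = FALSE)
    samples <- resample_linear(samples, fmt$fs, TARGET_FS)
  }
  speech_token(samples, TARGET_FS, consonant = consonant, label = label,
               source_id = source_id)
}

#' Write a speech token (or numeric vector) as 16-bit PCM mono WAV
#'
#' @param x a [speech_token] or numeric vector in \[-1, 1\].
#' @param path output file; parent directory must exist.
#' @param fs sampling rate, taken from the token when `x` is one.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = TARGET_FS) {
  if (inherits(x, "speech_token")) {
    fs <- x$fs
    x <- x$samples
  }
  x <- pmin(pmax(as.numeric(x), -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")            # block align
  writeBin(16L, con, size = 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

# linear-interpolation resampler; adequate for rate normalization of
# clinic WAVs (documented limitation: no anti-alias filter for downsampling)
resample_linear <- function(x, fs_in, fs_out) {
  n_out <- max(1L, round(length(x) * fs_out / fs_in))
  t_out <- (seq_len(n_out) - 1) / fs_out
  t_in <- (seq_along(x) - 1) / fs_in
  stats::approx(t_in, x, xout = pmin(t_out, t_in[length(t_in)]))$y
}

#' Split a signal into N contiguous non-overlapping frames
#'
#' Frames partition the first `floor(length(x)/n_frames) * n_frames` samples;
#' trailing remainder samples are discarded so all frames have equal length.
#'
#' @param x numeric vector.
#' @param n_frames number of frames N.
#' @return a `floor(length(x)/N) x N` matrix, one frame per column.
#' @export
frame_signal <- function(x, n_frames) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L || n_frames > length(x))
    stop("invalid-framing error: need 1 <= n_frames <= length(x)",
         call. = FALSE)
  flen <- length(x) %/% n_frames
  matrix(x[seq_len(flen * n_frames)], nrow = flen, ncol = n_frames)
}

## ---- manifests ------------------------------------------------------------

#' Load a dataset manifest
#'
#' The manifest is a CSV with header `path,consonant,label`; consonants must
#' be one of the six affected initial-consonant types and labels one of
#' `PF`/`NS`. Paths must be unique.
#'
#' @param path CSV file.
#' @return a `data.frame` with columns `path`, `consonant`, `label` and a
#'   `provenance` attribute.
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("path", "consonant", "label")
  if (!all(required %in% names(df)))
    stop("schema error: manifest must have columns path,consonant,label",
         call. = FALSE)
  df <- df[required]
  if (nrow(df) > 0L) {
    bad_c <- setdiff(unique(df$consonant), CONSONANT_TYPES)
    if (length(bad_c))
      stop("schema error: unknown consonant type(s): ",
           paste(bad_c, collapse = ", "), call. = FALSE)
    bad_l <- setdiff(unique(df$label), CLASS_LABELS)
    if (length(bad_l))
      stop("value error: unknown label(s): ", paste(bad_l, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(df$path))
      stop("schema error: duplicate paths in manifest", call. = FALSE)
  }
  attr(df, "provenance") <- path
  df
}

#' Save a dataset manifest
#'
#' @param manifest data.frame with columns `path`, `consonant`, `label`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  utils::write.csv(manifest[c("path", "consonant", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
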