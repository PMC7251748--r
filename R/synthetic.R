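## Synthetic two-class fricative-like tokens: band-shaped Gaussian noise
## with controllable high-energy-region placement, high/low contrast,
## cross-band coupling and prominent-peak gain. No phonetic realism is
## attempted; the generator realizes exactly the spectral/temporal
## contrasts the two features measure.

#' Synthesis parameters
#'
#' @param fs sampling rate (Hz).
#' @param duration_s token duration in seconds (default 0.25 s, a typical
#'   initial-consonant length).
#' @param her_low,her_high edges (Hz) of the high-energy region.
#' @param contrast_db how far (dB) the low-energy region sits below the
#'   high-energy region.
#' @param coupling rho in \[0, 1\]: weight of a shared narrowband component
#'   straddling the HER/LER boundary that is mixed into *both* band
#'   signals (with weight rho in the LER and rho/2 in the HER). The
#'   correlation between the generating band components is rho/sqrt(2) by
#'   construction; the shared content straddles the adaptive cut-off, so
#'   the measured per-frame band correlation rises with rho.
#' @param peak_fc,peak_gain_db center (Hz) and spectral-density boost (dB)
#'   of a narrow (1/6-octave) prominent resonance.
#' @param seed integer RNG seed; tokens are bit-reproducible.
#' @return a validated list of class `pf_synth_params`.
#' @export
synth_params <- function(fs = 44100, duration_s = 0.25,
                         her_low = 2500, her_high = 9000,
                         contrast_db = 25, coupling = 0,
                         peak_fc = 5500, peak_gain_db = 12, seed = 1L) {
  p <- list(fs = fs, duration_s = duration_s, her_low = her_low,
            her_high = her_high, contrast_db = contrast_db,
            coupling = coupling, peak_fc = peak_fc,
            peak_gain_db = peak_gain_db, seed = as.integer(seed))
  if (!(0 < p$her_low && p$her_low < p$her_high && p$her_high < fs / 2))
    stop("config error: need 0 < her_low < her_high < fs/2", call. = FALSE)
  if (p$coupling < 0 || p$coupling > 1)
    stop("config error: coupling must be in [0, 1]", call. = FALSE)
  if (round(fs * duration_s) < 20L)
    stop("config error: token too short for 10 frames", call. = FALSE)
  structure(p, class = "pf_synth_params")
}

#' Class presets for the generator
#'
#' Encodes the qualitative clinical contrasts: normal speech (NS) has a
#' wider, higher-reaching high-energy region, a much weaker low-energy
#' region, no cross-band coupling and a prominent spectral peak; the
#' pharyngeal fricative (PF) preset shifts the energy down, narrows it,
#' weakens the contrast, couples the two regions and flattens the peak.
#'
#' @param name `"NS"` or `"PF"`.
#' @param ... overrides forwarded to [synth_params()].
#' @return a `pf_synth_params`.
#' @export
class_preset <- function(name = c("NS", "PF"), ...) {
  name <- match.arg(name)
  base <- if (name == "NS") {
    list(her_low = 2500, her_high = 9000, contrast_db = 25, coupling = 0,
         peak_fc = 5500, peak_gain_db = 12)
  } else {
    list(her_low = 400, her_high = 3200, contrast_db = 8, coupling = 0.7,
         peak_fc = 1200, peak_gain_db = 3)
  }
  args <- utils::modifyList(base, list(...))
  p <- do.call(synth_params, args)
  attr(p, "preset") <- name
  p
}

band_noise <- function(n, fs, lo, hi, order = 10L) {
  x <- stats::rnorm(n)
  y <- apply_fft_gain(x, fs, function(f)
    butter_lowpass_gain(f, hi, order) *
      (1 - butter_lowpass_gain(f, lo, order)))
  y / stats::sd(y)
}

#' Generate one synthetic fricative-like token
#'
#' Token = unit-RMS band noise in \[her_low, her_high\]
#' + out-of-band noise above her_high at `-contrast_db`
#' + a shared boundary-straddling component weighted by `sqrt(coupling)`
#'   in both band signals
#' + a narrow resonance at `peak_fc` boosted by `peak_gain_db`.
#' The waveform is normalized to peak 0.9 so 16-bit WAV round-trips do not
#' clip (all downstream features are gain-invariant). The generating band
#' components are attached as attributes `band_h` / `band_l` so tests can
#' measure the "true-band" correlation independently of the filters.
#'
#' @param params a [synth_params()].
#' @param consonant,label,source_id token metadata.
#' @return a [speech_token].
#' @export
synth_token <- function(params, consonant = NA_character_,
                        label = "unknown", source_id = "synth") {
  stopifnot(inherits(params, "pf_synth_params"))
  set.seed(params$seed)
  n <- round(params$fs * params$duration_s)
  fs <- params$fs
  rho <- params$coupling
  h0 <- band_noise(n, fs, params$her_low, params$her_high)
  l0 <- band_noise(n, fs, params$her_high, 0.98 * fs / 2)
  s0 <- band_noise(n, fs, params$her_high / 1.12, params$her_high * 1.12)
  # the HER keeps at least half its broadband content so full coupling does
  # not collapse the token to the straddling narrowband; the correlation of
  # the generating band components is sqrt(rho/2 * rho) = rho/sqrt(2)
  a <- rho / 2
  h <- sqrt(1 - a) * h0 + sqrt(a) * s0
  l <- sqrt(1 - rho) * l0 + sqrt(rho) * s0
  g_l <- 10^(-params$contrast_db / 20)
  # peak boosted by peak_gain_db in spectral density relative to the HER
  bw_peak <- params$peak_fc * (2^(1 / 12) - 2^(-1 / 12))
  bw_her <- params$her_high - params$her_low
  g_p <- 10^(params$peak_gain_db / 20) * sqrt(bw_peak / bw_her)
  pk <- band_noise(n, fs, params$peak_fc * 2^(-1 / 12),
                   params$peak_fc * 2^(1 / 12)) * g_p
  x <- h + g_l * l + pk
  scale <- 0.9 / max(abs(x))
  tok <- speech_token(x * scale, fs, consonant = consonant, label = label,
                      source_id = source_id)
  attr(tok, "band_h") <- h * scale
  attr(tok, "band_l") <- g_l * l * scale
  attr(tok, "params") <- params
  tok
}

#' Generate a balanced synthetic dataset on disk
#'
#' Writes `n_per_class` WAV tokens per class with consonant types cycled
#' over the six affected initials, plus a manifest CSV and a provenance
#' JSON of the presets. Per-token seeds are drawn from the master seed, so
#' regeneration with the same seed is byte-identical.
#'
#' @param n_per_class tokens per class.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param presets named list with elements `NS` and `PF` (defaults:
#'   [class_preset()]).
#' @return the manifest `data.frame`, invisibly; manifest written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
synth_dataset <- function(n_per_class, out_dir, seed = 1L,
                          presets = list(NS = class_preset("NS"),
                                         PF = class_preset("PF"))) {
  stopifnot(n_per_class >= 1L, all(c("NS", "PF") %in% names(presets)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", out_dir, call. = FALSE)
  set.seed(as.integer(seed))
  token_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
  rows <- list()
  i <- 0L
  for (cls in c("PF", "NS")) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      cons <- CONSONANT_TYPES[(j - 1L) %% 6L + 1L]
      p <- presets[[cls]]
      p$seed <- token_seeds[i]
      tok <- synth_token(p, consonant = cons, label = cls,
                         source_id = sprintf("%s_%s_%03d", cls, cons, j))
      path <- file.path(out_dir, paste0(tok$source_id, ".wav"))
      write_wav(tok, path)
      rows[[i]] <- data.frame(path = path, consonant = cons, label = cls,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  prov <- list(seed = seed, n_per_class = n_per_class,
               NS = unclass(presets$NS), PF = unclass(presets$PF))
  jsonlite::write_json(prov, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a balanced set of in-memory tokens
#'
#' Same sampling scheme as [synth_dataset()] but returns the tokens as a
#' list without touching the filesystem — the workhorse for tests.
#'
#' @inheritParams synth_dataset
#' @return list of [speech_token]s with metadata set.
#' @export
synth_tokens <- function(n_per_class, seed = 1L,
                         presets = list(NS = class_preset("NS"),
                                        PF = class_preset("PF"))) {
  set.seed(as.integer(seed))
  token_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
  toks <- vector("list", 2L * n_per_class)
  i <- 0L
  for (cls in c("PF", "NS")) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      cons <- CONSONANT_TYPES[(j - 1L) %% 6L + 1L]
      p <- presets[[cls]]
      p$seed <- token_seeds[i]
      toks[[i]] <- synth_token(p, consonant = cons, label = cls,
                               source_id = sprintf("%s_%s_%03d", cls, cons,
                                                   j))
    }
  }
  toks
}
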