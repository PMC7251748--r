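#' Default analysis configuration
#'
#' Central place for every tunable of the feature pipeline. Values are the
#' published operating point: FFT size 1024, spectrum segmentation window
#' 689 Hz with 344 Hz shift (16 / 8 bins at 43.07 Hz per bin), order-10
#' Butterworth split, 10 frames per token, 43 one-third-octave bands and a
#' 1 % significance level.
#'
#' @param ... named overrides of the defaults, e.g. `pf_config(n_frames = 8)`.
#' @return a named list of class `pf_config`.
#' @export
#' @examples
#' cfg <- pf_config(segment_window = "rect")
#' cfg$win_hz
pf_config <- function(...) {
  cfg <- list(
    fft_size       = 1024L,
    win_hz         = 689,
    hop_hz         = 344,
    segment_window = "hamming",   # hamming | rect
    alpha          = 0.01,
    sig_test       = "welch",     # welch | wilcox
    populations    = "amplitudes", # amplitudes | slopes (cut-off scan groups)
    butter_order   = 10L,
    her_side       = "low",       # low | high
    n_frames       = 10L,
    n_bands        = 43L,
    db_floor       = -120,
    octave_scale   = "db",        # db | linear
    peak           = "global_max" # global_max | max_prominence
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("config error: unknown option(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$win_hz > cfg$hop_hz, cfg$hop_hz > 0)
  structure(cfg, class = "pf_config")
}
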