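## CSIFs: per-frame Pearson correlation between the DSCS-aligned HER and
## LER band signals.

#' Pearson correlation coefficient of a frame pair
#'
#' Population-moment form (expectation = arithmetic mean). When either
#' input has zero variance the correlation is undefined; silent or clipped
#' frames do occur in clinical tokens, so the value is defined as 0
#' (uncorrelated) and a warning is raised rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return a value in \[-1, 1\].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y))
    stop("invalid-pair error: frames must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("invalid-pair error: frames must have length >= 2", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean(x^2) - mx^2
  vy <- mean(y^2) - my^2
  if (vx <= 0 || vy <= 0) {
    warning("degenerate frame: zero variance, PCC set to 0", call. = FALSE)
    return(0)
  }
  r <- (mean(x * y) - mx * my) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' CSIFs values from an existing band split
#'
#' Frames the (DSCS-translated, if present) HER and LER signals into
#' `n_frames` aligned non-overlapping frames and computes the per-frame
#' Pearson correlation. Useful for testing the correlation stage in
#' isolation; [csifs_feature()] runs the whole pipeline.
#'
#' @param split a `pf_bandsplit` (with or without the DSCS fields).
#' @param n_frames number of frames N (default 10).
#' @return object of class `pf_csifs`: `p` (length N), `n_frames`, `c_f`.
#' @export
csifs_from_split <- function(split, n_frames = 10L) {
  stopifnot(inherits(split, "pf_bandsplit"))
  h <- if (!is.null(split$NX_H)) split$NX_H else split$X_H
  l <- if (!is.null(split$NX_L)) split$NX_L else split$X_L
  # apply the DSCS translation here, idempotently: an already-translated
  # signal has max(h) == 0 / min(l) == 0 exactly, so subtracting again is a
  # no-op and the with/without-DSCS routes run bit-identical arithmetic
  h <- h - max(h)
  l <- l - min(l)
  fh <- frame_signal(h, n_frames)
  fl <- frame_signal(l, n_frames)
  p <- vapply(seq_len(n_frames), function(n) pcc(fh[, n], fl[, n]),
              numeric(1))
  structure(list(p = p, n_frames = as.integer(n_frames), c_f = split$c_f),
            class = "pf_csifs")
}

#' CSIFs feature of a token
#'
#' Full pipeline: matching filter to find the HER/LER cut-off, zero-phase
#' order-10 Butterworth split, DSCS translation, framing of both band
#' signals into `n_frames` aligned non-overlapping frames, per-frame
#' Pearson correlation. The result is scale-invariant: the cut-off search
#' works on relative spectral structure and correlation is unit-free.
#'
#' @param token a [speech_token].
#' @param n_frames number of frames N (default 10).
#' @param config a [pf_config].
#' @return object of class `pf_csifs`: `p`, `n_frames`, `c_f`,
#'   `fallback_used`.
#' @export
csifs_feature <- function(token, n_frames = 10L, config = pf_config()) {
  cut <- matching_filter(token, config)
  split <- butterworth_split(token, cut$c_f, order = config$butter_order,
                             her_side = config$her_side)
  split <- dscs_transform(split)
  out <- csifs_from_split(split, n_frames)
  out$fallback_used <- cut$fallback_used
  out
}
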