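## The matching filter: significance-gated back-to-front cut-off search,
## order-10 zero-phase Butterworth band split, and the DSCS translation.

#' Two-sample significance flag
#'
#' Returns `H = 1` iff a two-sample test rejects equality of the two groups
#' at level `alpha`. Default is Welch's t-test, computed in closed form so
#' degenerate inputs are handled deterministically: when both groups have
#' zero variance, `H = 0` if the means agree and `H = 1` otherwise.
#' `method = "wilcox"` switches to a Mann-Whitney test (normal
#' approximation).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param alpha significance level (default 0.01, i.e. the 1 % level).
#' @param method `"welch"` or `"wilcox"`.
#' @return a list with `H` (0/1 integer) and `p` (the p-value).
#' @export
significance_flag <- function(a, b, alpha = 0.01,
                              method = c("welch", "wilcox")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    stop("significance_flag needs at least 2 values per group",
         call. = FALSE)
  if (method == "welch") {
    na <- length(a); nb <- length(b)
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tstat <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      p <- 2 * stats::pt(-abs(tstat), df)
    }
  } else {
    p <- tryCatch(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
      error = function(e) 1)
    if (is.na(p)) p <- 1
  }
  list(H = as.integer(p < alpha), p = p)
}

#' Locate the HER/LER cut-off frequency
#'
#' Back-to-front scan over the slope matrix: candidate boundaries
#' `c = N-2, N-3, ..., 4` are tested in order and the first (largest) `c`
#' satisfying both gates is declared the boundary between the low-energy
#' tail (`c..N`) and the high-energy region:
#' \itemize{
#'   \item a two-sample significance test between a *front* group just
#'     before `c` and the *back* group from `c` onwards rejects equality at
#'     `alpha`, and
#'   \item `|R[c-1]| > |R[c+1]|` — the tail fit steepens when it starts to
#'     include the boundary.
#' }
#' With `populations = "amplitudes"` (default) the groups are the
#' window-weighted amplitude values of segment `c-1` (front) and of the
#' tail segments `c..N` (back), and the per-candidate significance level is
#' Bonferroni-corrected (`alpha / (N-5)`) so the family-wise false-boundary
#' rate over the whole scan stays at `alpha`; without the correction the
#' scan declares spurious boundaries in the noise tail. With
#' `populations = "slopes"` the groups are slope values (`R[c-3..c-1]` vs
#' `R[c..N-1]`) at level `alpha` (three-value groups have no power left
#' after correction).
#' The cut-off frequency is the mean bin frequency of segment `c`. If no
#' candidate qualifies the fall-back picks the segment with the largest
#' slope change `|R[c-1] - R[c+1]|` and flags `fallback_used` (a degenerate
#' token must not abort a batch run).
#'
#' @param segs a `pf_segments`.
#' @param env a `pf_envelope` for the same segmentation.
#' @param slopes a `pf_slopes` for `env`.
#' @param alpha significance level.
#' @param method significance test family, see [significance_flag()].
#' @param populations `"slopes"` or `"amplitudes"`.
#' @return object of class `pf_cutoff`: `c_f` (Hz), `segment_index`,
#'   `fallback_used`.
#' @export
detect_cutoff <- function(segs, env, slopes, alpha = 0.01,
                          method = c("welch", "wilcox"),
                          populations = c("amplitudes", "slopes")) {
  stopifnot(inherits(segs, "pf_segments"), inherits(env, "pf_envelope"),
            inherits(slopes, "pf_slopes"))
  method <- match.arg(method)
  populations <- match.arg(populations)
  N <- env$N
  if (N < 8L)
    stop("insufficient-segments error: need at least 8 segments",
         call. = FALSE)
  R <- slopes$R
  level <- if (populations == "amplitudes") alpha / (N - 5L) else alpha
  for (c in seq(N - 2L, 4L)) {
    if (populations == "slopes") {
      front <- R[max(1L, c - 3L):(c - 1L)]
      back <- R[c:(N - 1L)]
    } else {
      front <- segs$segments[, c - 1L]
      back <- as.vector(segs$segments[, c:N])
    }
    H <- significance_flag(front, back, alpha = level, method = method)$H
    if (H == 1L && abs(R[c - 1L]) > abs(R[c + 1L])) {
      return(structure(list(c_f = segs$seg_freqs[c],
                            segment_index = c, fallback_used = FALSE),
                       class = "pf_cutoff"))
    }
  }
  cs <- 4L:(N - 2L)
  c <- cs[which.max(abs(R[cs - 1L] - R[cs + 1L]))]
  warning("no significant HER/LER boundary found; using maximal slope change",
          call. = FALSE)
  structure(list(c_f = segs$seg_freqs[c], segment_index = c,
                 fallback_used = TRUE), class = "pf_cutoff")
}

#' Run the full matching filter on a token
#'
#' Convenience wrapper: magnitude spectrum, segmentation, variance envelope,
#' slope matrix and cut-off detection with the settings in `config`.
#'
#' @param token a [speech_token].
#' @param config a [pf_config].
#' @return a `pf_cutoff`.
#' @export
matching_filter <- function(token, config = pf_config()) {
  spec <- magnitude_spectrum(token, config$fft_size)
  segs <- segment_spectrum(spec, config$win_hz, config$hop_hz,
                           window = config$segment_window)
  env <- variance_envelope(segs)
  slopes <- slope_matrix(env)
  detect_cutoff(segs, env, slopes, alpha = config$alpha,
                method = config$sig_test, populations = config$populations)
}

# order-n Butterworth low-pass power response, applied in the frequency
# domain; equals the magnitude response of forward-backward (zero-phase)
# filtering with the analog prototype, and is power-complementary with the
# matching high-pass so X_H + X_L reconstructs the input exactly.
butter_lowpass_gain <- function(f, c_f, order) {
  1 / (1 + (f / c_f)^(2 * order))
}

apply_fft_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n       # folded (absolute) frequency per bin
  Re(stats::fft(stats::fft(x) * gain_fun(f), inverse = TRUE)) / n
}

#' Split a token into HER and LER signals at a cut-off frequency
#'
#' Zero-phase order-10 Butterworth low-pass/high-pass pair applied in the
#' frequency domain. By default the high-energy region (HER, `X_H`) is the
#' band *below* `c_f` and the low-energy region (LER, `X_L`) the band above
#' (`her_side = "high"` swaps them). The two responses are
#' power-complementary, so `X_H + X_L` equals the input to machine
#' precision, and zero phase keeps the two signals sample-aligned for
#' paired per-frame correlation.
#'
#' @param token a [speech_token].
#' @param c_f cut-off frequency in Hz, `0 < c_f < fs/2`.
#' @param order Butterworth order (default 10).
#' @param her_side `"low"` (default) or `"high"`.
#' @return object of class `pf_bandsplit`: `X_H`, `X_L`, `c_f`, `fs`.
#' @export
butterworth_split <- function(token, c_f, order = 10L,
                              her_side = c("low", "high")) {
  stopifnot(inherits(token, "speech_token"))
  her_side <- match.arg(her_side)
  if (!is.numeric(c_f) || length(c_f) != 1L || c_f <= 0 ||
      c_f >= token$fs / 2)
    stop("invalid-cutoff error: need 0 < c_f < fs/2", call. = FALSE)
  low <- apply_fft_gain(token$samples, token$fs,
                        function(f) butter_lowpass_gain(f, c_f, order))
  high <- token$samples - low
  if (her_side == "low") {
    split <- list(X_H = low, X_L = high)
  } else {
    split <- list(X_H = high, X_L = low)
  }
  split$c_f <- c_f
  split$fs <- token$fs
  structure(split, class = "pf_bandsplit")
}

#' DSCS amplitude translation of a band split
#'
#' Translates the HER signal down by its maximum and the LER signal up by
#' its minimum (`NX_H = X_H - max(X_H)`, `NX_L = X_L - min(X_L)`) so the two
#' signals can be displayed in one coordinate system without overlap. Pure
#' translation: the per-frame correlation downstream is unchanged.
#'
#' @param split a `pf_bandsplit`.
#' @return the split with `NX_H`, `NX_L`, `Trans_H`, `Trans_L` added.
#' @export
dscs_transform <- function(split) {
  stopifnot(inherits(split, "pf_bandsplit"))
  split$Trans_H <- max(split$X_H)
  split$Trans_L <- min(split$X_L)
  split$NX_H <- split$X_H - split$Trans_H
  split$NX_L <- split$X_L - split$Trans_L
  split
}
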