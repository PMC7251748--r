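test_that("magnitude spectrum localizes a pure tone to one bin width", {
  tok <- sine_token(4000)
  sp <- magnitude_spectrum(tok)
  bin_hz <- 44100 / 1024
  expect_lt(abs(sp$freqs[which.max(sp$amplitudes)] - 4000), bin_hz)
  expect_length(sp$amplitudes, 512L)
  expect_error(magnitude_spectrum(tok, fft_size = 1000), "config error")
})

test_that("all-zero signal gives an all-zero spectrum", {
  sp <- magnitude_spectrum(speech_token(numeric(2048) + 0, 44100))
  expect_true(all(sp$amplitudes == 0))
})

test_that("half-spectrum energy obeys Parseval within 1%", {
  set.seed(3)
  x <- stats::rnorm(1024)                 # exactly one FFT chunk
  sp <- magnitude_spectrum(speech_token(x, 44100))
  expect_equal(sum(sp$amplitudes^2), 1024 * sum(x^2) / 2, tolerance = 0.01)
})

test_that("segmentation arithmetic matches the sliding-window formula", {
  sp <- make_step_spectrum(256, seed = 1)
  segs <- segment_spectrum(sp)
  expect_equal(segs$win_bins, 16L)         # 689 Hz at 43.066 Hz/bin
  expect_equal(segs$hop_bins, 8L)          # 344 Hz
  expect_equal(ncol(segs$segments), (512L - 16L) %/% 8L + 1L)  # 63
  # seg_freqs spacing = hop_bins * bin width
  expect_equal(diff(segs$seg_freqs),
               rep(8 * 44100 / 1024, 62), tolerance = 1e-12)
})

test_that("constant spectrum yields identical segments", {
  sp <- make_step_spectrum(512, seed = 1, hi = 3, hi_sd = 0)
  segs <- segment_spectrum(sp)
  expect_true(all(apply(segs$segments, 1, function(r) diff(range(r)) == 0)))
})

test_that("variance envelope matches the population-variance oracle", {
  sp <- make_step_spectrum(256, seed = 7)
  segs <- segment_spectrum(sp)
  env <- variance_envelope(segs)
  # independent two-pass oracle on the same weighted values
  oracle <- apply(segs$segments, 2, function(s) {
    mu <- sum(s) / length(s)
    sum((s - mu)^2) / length(s)
  })
  expect_equal(env$M, oracle, tolerance = 1e-12)
  expect_true(all(env$M >= 0))
})

test_that("variance of known values is exact", {
  seg <- structure(list(segments = cbind(c(1, 2, 3), c(5, 5, 5))),
                   class = "pf_segments")
  env <- variance_envelope(seg)
  expect_equal(env$M, c(2 / 3, 0))
})

test_that("variance envelope shift/scale behaviour", {
  sp <- make_step_spectrum(256, seed = 9)
  # rectangular window: adding a constant to the spectrum leaves M unchanged
  sp_shift <- sp; sp_shift$amplitudes <- sp$amplitudes + 5
  M0 <- variance_envelope(segment_spectrum(sp, window = "rect"))$M
  M1 <- variance_envelope(segment_spectrum(sp_shift, window = "rect"))$M
  expect_equal(M0, M1, tolerance = 1e-9)
  # Hamming window: scaling the spectrum by k scales M by k^2
  sp_k <- sp; sp_k$amplitudes <- sp$amplitudes * 3
  Mh0 <- variance_envelope(segment_spectrum(sp))$M
  Mhk <- variance_envelope(segment_spectrum(sp_k))$M
  expect_equal(Mhk, 9 * Mh0, tolerance = 1e-9)
})

test_that("slope matrix matches closed-form and lm() oracles", {
  env <- structure(list(M = c(3, 2, 1), N = 3L), class = "pf_envelope")
  expect_equal(slope_matrix(env)$R[1], -1)
  env <- structure(list(M = rep(4, 6), N = 6L), class = "pf_envelope")
  expect_true(all(slope_matrix(env)$R == 0))
  env <- structure(list(M = c(4, 1, 0, 1), N = 4L), class = "pf_envelope")
  expect_equal(slope_matrix(env)$R[2], 0)   # fit of (2,1),(3,0),(4,1)
  expect_error(
    slope_matrix(structure(list(M = 1, N = 1L), class = "pf_envelope")),
    "insufficient-data")

  set.seed(11)
  for (rep in 1:20) {
    N <- sample(5:40, 1)
    M <- stats::rexp(N)
    env <- structure(list(M = M, N = N), class = "pf_envelope")
    R <- slope_matrix(env)$R
    oracle <- vapply(seq_len(N - 1), function(c)
      unname(stats::coef(stats::lm(M[c:N] ~ seq(c, N)))[2]), numeric(1))
    expect_equal(R, oracle, tolerance = 1e-9)
    # last slope is the two-point difference, exactly
    expect_equal(R[N - 1], M[N] - M[N - 1], tolerance = 1e-12)
  }
})
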