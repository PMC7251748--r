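test_that("one-third-octave geometry is exact", {
  b <- octave_bands(44100)
  expect_equal(nrow(b), 43L)
  r <- 2^(1 / 3)
  expect_equal(b$f2 / b$f1, rep(r, 43), tolerance = 1e-12)
  expect_equal(b$fc^2, b$f1 * b$f2, tolerance = 1e-9)
  expect_equal(b$fc / b$f1, rep(2^(1 / 6), 43), tolerance = 1e-12)
  expect_equal(b$f2[43], 22050)
  expect_equal(b$f1[-1], b$f2[-43], tolerance = 1e-12)   # contiguous
  expect_equal(b$lo[1], 0)                               # coverage from 0
  # top band printed values
  expect_equal(b$f1[43], 22050 / r, tolerance = 1e-9)
  expect_equal(b$f1[43], 17501.1, tolerance = 1e-4)
  expect_equal(b$fc[43], sqrt(b$f1[43] * 22050), tolerance = 1e-9)
  # total span is 43/3 octaves
  expect_equal(prod(b$f2 / b$f1), 2^(43 / 3), tolerance = 1e-9)
})

test_that("octave spectrum is flat for white noise and peaked for tones", {
  bands <- octave_bands(44100)
  # white noise: E approximately flat in dB, averaged over 20 seeds
  Es <- sapply(1:20, function(s) {
    set.seed(400 + s)
    octave_spectrum(stats::rnorm(4096), 44100, bands)$E
  })
  Ebar <- rowMeans(Es)
  usable <- Ebar > -120
  expect_lt(diff(range(Ebar[usable])), 6)
  # pure tone at the center of band 30 dominates band 30
  fc30 <- bands$fc[30]
  t <- seq_len(4096) / 44100
  os <- octave_spectrum(sin(2 * pi * fc30 * t), 44100, bands)
  expect_equal(which.max(os$E), 30L)
  # silence: everything at the floor
  os0 <- octave_spectrum(numeric(1024), 44100, bands)
  expect_true(all(os0$E == -120))
})

test_that("octave regression matches exact lines and the lm() oracle", {
  mk <- function(E) structure(list(E = E, floor = -120, scale = "db",
                                   n_bands = length(E)),
                              class = "pf_octave_spectrum")
  fit <- octave_regression(mk(2 * (1:43) + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(octave_regression(mk(rep(7, 43)))$slope, 0)
  expect_error(octave_regression(mk(c(5, rep(-120, 42)))),
               "degenerate-spectrum")
  set.seed(17)
  for (i in 1:20) {
    E <- stats::rnorm(43, -20, 10)
    E[sample(43, 5)] <- -120            # floor bands must be excluded
    fit <- octave_regression(mk(E))
    keep <- E > -120
    ol <- stats::lm(E[keep] ~ which(keep))
    expect_equal(fit$slope, unname(stats::coef(ol)[2]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(stats::coef(ol)[1]),
                 tolerance = 1e-9)
  }
})

test_that("frame-level peak excess follows the refit-and-subtract oracle", {
  mk <- function(E) structure(list(E = E, floor = -120, scale = "db",
                                   n_bands = length(E)),
                              class = "pf_octave_spectrum")
  line <- list(slope = 1, intercept = 0)
  expect_equal(ospp_frame(mk(1:43), line), 0)   # E exactly on the line
  E <- as.numeric(1:43); E[20] <- 25
  os <- mk(E)
  df <- ospp_frame(os)
  k <- which.max(E)
  ofit <- stats::lm(E ~ seq_along(E))
  expect_equal(df, E[k] - unname(predict(ofit))[k], tolerance = 1e-9)
  # adding a constant is absorbed by the intercept
  expect_equal(ospp_frame(mk(E + 11)), df, tolerance = 1e-9)
})

test_that("DF is invariant to linear-in-band-index trends", {
  set.seed(18)
  mk <- function(E) structure(list(E = E, floor = -120, scale = "db",
                                   n_bands = 43L),
                              class = "pf_octave_spectrum")
  # a clear peak keeps the argmax fixed; any linear-in-index trend (and any
  # offset) is then absorbed by the regression line
  E <- stats::rnorm(43, -10, 6)
  E[25] <- max(E) + 60
  base <- ospp_frame(mk(E))
  for (sl in c(-2, 0.5, 3))
    expect_equal(ospp_frame(mk(E + sl * (1:43) - 4)), base,
                 tolerance = 1e-9)
})

test_that("OSPP separates peaked from flat spectra and ignores gain", {
  # strong narrow resonance far above the floor -> every frame's DF large
  peaked <- synth_token(synth_params(her_low = 500, her_high = 10000,
                                     contrast_db = 30, peak_fc = 3000,
                                     peak_gain_db = 25, seed = 501))
  df1 <- ospp_feature(peaked)$DF
  expect_length(df1, 10L)
  expect_true(all(df1 > 10))
  # unshaped white noise -> small mean DF
  df0 <- ospp_feature(noise_token(502, n = 22050))$DF
  expect_lt(mean(df0), 6)
  # global gain changes nothing (dB shift absorbed by the intercept)
  tok <- synth_token(class_preset("NS", seed = 503))
  big <- speech_token(tok$samples * 10, tok$fs)
  expect_equal(ospp_feature(big)$DF, ospp_feature(tok)$DF,
               tolerance = 1e-9)
})
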