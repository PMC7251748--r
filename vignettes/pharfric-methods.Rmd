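---
title: "pharfric: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pharfric: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Pharyngeal fricatives (PF) are compensatory misarticulations in cleft
palate speech: the fricative constriction moves from the oral cavity to
the pharynx. Acoustically this (a) shifts and narrows the high-energy
region (HER) of the consonant spectrum, (b) reduces the amplitude
contrast between the HER and the low-energy region (LER), (c) couples
the temporal behaviour of the two regions, and (d) flattens the dominant
spectral peak. `pharfric` quantifies (a)–(c) with the CSIFs feature and
(d) with the OSPP feature, then classifies tokens with a bagged
decision-tree ensemble.

## The matching filter

The whole-token magnitude spectrum (FFT 1024; longer tokens are cut into
FFT-size chunks whose magnitude spectra are averaged, shorter ones
zero-padded — one deterministic spectrum per token) is segmented with a
689 Hz window shifted by 344 Hz. At 44.1 kHz and FFT 1024 these are
exactly 16 and 8 bins (43.066 Hz per bin); other rates round to the
nearest bin. Each segment is Hamming-weighted (`segment_window = "rect"`
preserves the unweighted reading) and reduced to its population variance
`M_v` (divisor L). The slope matrix holds the least-squares slope `R_c`
of `(v, M_v), v = c..N` for every tail fit.

**Cut-off scan.** Candidates `c = N-2 .. 4` are visited back to front.
The boundary is the first (largest) `c` where

1. the window-weighted amplitudes of segment `c-1` differ significantly
   from those of the tail segments `c..N` (Welch two-sample t-test), and
2. `|R_(c-1)| > |R_(c+1)|` — the tail fit steepens once it reaches the
   boundary.

The per-candidate significance level is Bonferroni-corrected
(`alpha / (N-5)`, family-wise level `alpha = 0.01`): the scan performs
~58 tests on a 63-segment envelope, and without the correction it
declares spurious boundaries inside the flat noise tail at the nominal
1 % rate per candidate. This exact design was selected against
constructed step spectra with known boundaries: a three-segment front
group leaves a Welch test with ~2 degrees of freedom (critical t ≈ 9.9
at the 1 % level, so the scan runs past the boundary), while an
uncorrected multi-segment amplitude front fires one to two segments
above the true step. The single-segment front with correction recovers
10/10 constructed boundaries within one hop width (≈ 345 Hz). A
slope-population variant is retained behind `populations = "slopes"`.
`c_f` is the mean bin frequency of segment `c`. When no candidate
qualifies (e.g. a flat spectrum) the fall-back picks the largest slope
change `|R_(c-1) − R_(c+1)|` and flags the token rather than aborting a
clinical batch.

**Band split.** The waveform is split at `c_f` by an order-10
Butterworth low-pass/high-pass pair applied as *power* responses in the
frequency domain. This equals the magnitude behaviour of
forward–backward (`filtfilt`) filtering with the analog prototype, is
exactly zero-phase (the HER/LER frames stay sample-aligned for paired
correlation), avoids the numerical instability of a direct-form
order-10 IIR, and makes the pair power-complementary so `X_H + X_L`
reconstructs the input to machine precision. HER defaults to the band
*below* `c_f` (`her_side = "high"` swaps), because clinical PF energy
concentrates low and the scan approaches from the high-frequency tail.

## CSIFs

Both band signals are translated (DSCS): `NX_H = X_H − max(X_H)`,
`NX_L = X_L − min(X_L)`. Translation cannot change correlation; to make
the with/without-DSCS routes *bit-identical* (not merely equal to
rounding), `csifs_from_split()` applies the translation itself,
idempotently — an already-translated signal has `max = 0` exactly, so
the second subtraction is a no-op. Each band signal is cut into N = 10
non-overlapping frames (trailing remainder samples discarded, keeping
frame lengths equal for the paired correlation) and
`p_n = corr(NX_H(n), NX_L(n))` uses the population-moment form of the
Pearson coefficient. A zero-variance frame (silence, hard clipping)
returns 0 with a warning instead of an error. The feature is invariant
to global gain end-to-end: the cut-off search uses relative spectral
structure and correlation is unit-free. No amplitude normalization is
applied anywhere for the same reason.

## OSPP

43 one-third-octave bands are anchored at the top: `f2(43) = fs/2`,
`f1 = f2/2^(1/3)`, `fc = f1·2^(1/6)`. Top-anchoring makes "0–22,050 Hz
in 43 bands" hold exactly; standard nominal ANSI centers do not yield 43
bands over this range. The first band's collection range is extended to
0 Hz so coverage is gapless while the tabulated edges keep the exact
band-ratio identities. Per frame, `E_i` is the mean *linear* magnitude
in the band converted to dB (mean-then-log, not log-then-mean); bands
with no FFT bin — unavoidable in the lowest bands at 43 Hz resolution —
are clamped to a −120 dB floor and excluded from the regression, which
keeps every value finite. The regression of `E_i` on band index absorbs
global gain and any linear-in-index tilt, so `DF = E(peak) − line(peak)`
responds only to peak prominence. The "most prominent peak" is the
global maximum of `E` (a topographic-prominence alternative sits behind
`peak = "max_prominence"`). N defaults to 10, shared with CSIFs, because
the detector consumes "N or 2N" values per token.

## Detector

A bagging ensemble of 30 CART trees (Gini impurity, unlimited depth,
bootstrap samples of training-set size). Tree hyper-parameters are
deliberately plain and exposed in the API; depth limits are unnecessary
at these data sizes. Majority voting with an even-vote tie resolved
toward NS — with an even ensemble size this case occurs, and at
equivocal evidence the detector prefers "no disorder". The PF vote
fraction is the AUC score (midrank/trapezoidal, ties averaged).
Cross-validation is stratified (the clinical design is balanced
per class), repeated with fresh shuffles; accuracy, sensitivity
(PF positive: a miss is a missed diagnosis), specificity and AUC are
averaged over repeats and the spread reported is the **standard
deviation** over repeats. Repeat-level seeds are derived from the master
seed so repeat 1 is identical regardless of the repeat count.

## The synthetic world

`synth_token()` builds fricative-like tokens from Gaussian noise shaped
by zero-phase band filters (duration 0.25 s — a typical initial
consonant; peak-normalized to 0.9 so 16-bit WAV round-trips do not
clip):

* HER: unit-RMS noise in `[her_low, her_high]`;
* LER: noise above `her_high` at `−contrast_db`;
* a narrow (1/6-octave) resonance at `peak_fc` boosted `peak_gain_db`
  above the HER spectral density;
* coupling `rho`: a shared narrowband component straddling the HER/LER
  boundary (±12 %), mixed with weight `rho` into the LER and `rho/2`
  into the HER.

The coupling construction deserves a note: the lag-0 sample correlation
of two signals confined to disjoint bands equals the overlap integral of
their spectra (Parseval), so *no* amplitude-envelope co-modulation of
disjoint bands can produce a positive mean per-frame correlation. The
shared straddling component is the honest mechanism — it is also why
real PF speech shows high CSIFs: energy smeared across the adaptive
cut-off is passed by both split filters. The generating band components
correlate at `rho/√2` by construction and are exposed as token
attributes for oracle tests. The HER keeps at least half its broadband
content at `rho = 1` so full coupling does not collapse the token to a
narrowband bump (which would move the detected cut-off and break knob
monotonicity).

Class presets encode only the stated qualitative contrasts: NS =
`her 2500–9000 Hz, contrast 25 dB, rho 0, peak +12 dB at 5500 Hz`;
PF = `her 400–3200 Hz, contrast 8 dB, rho 0.7, peak +3 dB at 1200 Hz`.
Values were fixed once from the clinical description (PF energy low and
narrow, weak HER/LER contrast, coupled bands, flattened peak) before the
acceptance measurements were frozen.

**What a green test establishes — and what it does not.** The generator
realizes the spectral geometry the features measure; it contains no
voicing, formant transitions, coarticulation, room noise or speaker
variability. Passing tests demonstrate that the pipeline measures what
it claims on signals with known structure, not that clinical accuracy
matches the published figures (those were measured on a private
database and are out of reach by design).

## Numerical choices and degenerate inputs

* Linear (not dB, not power) magnitudes feed the variance envelope; the
  published plots are linear spectra. A dB variant is a config away.
* Hz→bin conversions round to the nearest bin; 689/344 Hz are exact at
  the reference resolution.
* Non-44.1 kHz WAVs are linearly resampled (with a warning) rather than
  rejected; the band geometry assumes 22,050 Hz on top. Linear
  interpolation has no anti-alias filter — acceptable for rate
  normalization of clinic recordings, documented as a limitation.
* Tokens shorter than 10 usable frames are rejected, not padded.
* Zero-variance frames → correlation 0 + warning; flat spectra → cut-off
  fall-back + warning; empty octave bands → floor value; all are
  warnings, never aborts, because batch clinical runs must survive
  degenerate tokens.
* `c_f` is estimated once per token (the whole-token spectrum), not per
  frame.

## Known limitations

* The Algorithm-2 step-5 gate is a reconstruction (the original is shown
  only graphically); it is isolated in `detect_cutoff()` for easy
  replacement and both population variants are configurable.
* Whether clinical CSIFs ranges refer to per-frame values or per-token
  aggregates is ambiguous; the package reports per-frame values and
  leaves aggregation to the classifier.
* The ± spreads in the published result tables are unspecified; this
  package reports SD over CV repeats and labels it as such.
* Segmentation of consonants from running speech, denoising and
  formant-based synthesis are out of scope.
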