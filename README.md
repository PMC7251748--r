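# pharfric

Automatic detection of **pharyngeal fricatives** in cleft palate speech
from two bespoke acoustic features and a bagged decision-tree detector.

## The problem

Speakers with cleft palate and velopharyngeal insufficiency often replace
oral fricative constrictions with a compensatory constriction in the
pharynx — a *pharyngeal fricative* (PF). The misarticulation affects the
six Mandarin initial consonants /c/, /ch/, /q/, /s/, /sh/, /x/ and is
normally rated perceptually by speech-language pathologists. `pharfric`
implements an objective, signal-based detector that discriminates PF from
normal speech (NS) on pre-segmented initial-consonant tokens (mono PCM
WAV, nominally 44.1 kHz).

## The method

Two per-token feature vectors, each with one value per frame
(N = 10 non-overlapping frames):

* **CSIFs** — *correlation of signals in independent frequency bands.*
  A matching filter splits the token's magnitude spectrum (FFT 1024) into
  a high-energy region (HER) and a low-energy region (LER) at an
  adaptively detected cut-off frequency `c_f`: the spectrum is segmented
  with a 689 Hz Hamming window shifted by 344 Hz, each segment's
  population variance forms the variance envelope `M_v`, the tail
  regression slopes `R_c` (least-squares fit of `M_c..M_N`) magnify the
  HER/LER contrast, and a significance-gated back-to-front scan declares
  the boundary where the tail stops being statistically flat and the
  slope magnitude starts growing (`|R_(c-1)| > |R_(c+1)|`). Order-10
  zero-phase Butterworth filters split the waveform at `c_f`; after the
  DSCS amplitude translation (`NX_H = X_H − max X_H`,
  `NX_L = X_L − min X_L`) the per-frame Pearson correlation
  `p_n = corr(NX_H(n), NX_L(n))` is the feature. PF tokens couple the two
  regions (energy smeared across the cut-off) and score high; clean NS
  splits score near zero.

* **OSPP** — *octave spectrum prominent peak.* Each frame's magnitude
  spectrum is reduced to 43 one-third-octave spectral lines
  `E_i = 20·log10(mean magnitude in band i)` (bands satisfy
  `f2/f1 = 2^(1/3)`, `fc = √(f1·f2)`, top-anchored at 22,050 Hz), a
  least-squares line of `E_i` on the band index normalizes level and
  tilt, and the feature is `DF_n = peak_n − RL_n`: the excess of the most
  prominent line over the regression line at the peak's band. NS keeps a
  concentrated anterior energy peak (large DF); PF flattens it.

The detector is a bootstrap-aggregated ensemble of 30 CART decision
trees with majority voting (ties resolved toward NS), evaluated by
10 repeats of stratified 10-fold cross-validation reporting accuracy,
sensitivity (PF = positive class), specificity and trapezoidal AUC, with
per-consonant breakdowns and Welch-test feature significance at the 1 %
level.

Because clinical recordings are not distributable, the package ships a
synthetic token generator (`synth_token()`, `synth_dataset()`) producing
band-shaped Gaussian-noise tokens whose class presets encode exactly the
qualitative PF/NS contrasts above; every pipeline stage is testable
end-to-end without patient data.

## Worked example

```r
library(pharfric)

toks  <- synth_tokens(50, seed = 11)                 # 50 PF + 50 NS tokens
feats <- extract_features(toks)                      # p_1..p_10, df_1..df_10
fm    <- feature_matrix(feats, "both")

feature_significance(fm$x[, 1:10], fm$labels)        # CSIFs class contrast
#>   consonant             p H
#> 1       all 3.088199e-184 1

cv <- cross_validate(fm$x, fm$labels, fm$consonants,
                     k = 10, repeats = 10, n_trees = 30, seed = 5)
cv
#> <pf_cv> 10x10-fold CV, 30 trees
#>   accuracy      97.5 +/- 1.1 %
#>   sensitivity   95.8 +/- 2.0 %
#>   specificity   99.2 +/- 1.0 %
#>   auc           99.3 +/- 1.1 %
```

The mean CSIFs of the PF class exceeds the NS class and the Welch test
flags the contrast far below the 1 % level (`H = 1`); the detector
separates the two synthetic presets almost perfectly. On clinical data
the published protocol reports accuracies near 88 % — the synthetic
world is deliberately easier (see the methods vignette).

The same pipeline is available from the command line:

```sh
inst/exec/pharfric simulate --n 50 --out data/ --seed 7
inst/exec/pharfric extract  --manifest data/manifest.csv \
    --features csifs,ospp --out feats.csv
inst/exec/pharfric evaluate --features feats.csv --set both \
    --k 10 --repeats 10 --trees 30 --seed 7 --report report.json
```

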