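Package: pharfric
Title: Detection of Pharyngeal Fricatives in Cleft Palate Speech from
    Band-Coupling and Octave-Peak Acoustic Features
Version: 0.1.0
Authors@R:
    person("pharfric", "maintainers", email = "pharfric@example.org",
           role = c("aut", "cre"))
Description: Tools for automatic detection of pharyngeal fricative
    misarticulation in pre-segmented Mandarin initial consonants.
    Implements an adaptive matching filter that splits each token's
    spectrum into high- and low-energy regions at a data-driven cut-off
    frequency, the CSIFs feature (per-frame Pearson correlation between
    the two band signals), the OSPP feature (per-frame excess of the most
    prominent one-third-octave spectral line over a least-squares
    regression baseline), a bootstrap-aggregated decision-tree detector
    with repeated stratified k-fold evaluation, and a synthetic
    filtered-noise token generator for end-to-end testing without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
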