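Package: cellmig
Title: Quantification of Mesenchymal Cell Migration Modes from Label-Mask Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify single-cell mesenchymal migration from segmented
    time-lapse label masks of cells and cell-matrix adhesion complexes (CMACs):
    nearest-neighbour tracking with spline trajectory smoothing, CMAC filtering
    and lifetimes, per-cell organizational features with background-corrected and
    standardized CMAC intensities, membrane protrusion/retraction dynamics over
    multiple time windows with lagged cross-correlation profiles, moving-window
    mean squared displacement with Furth persistent-random-walk fits, and the
    multivariate layer (canonical variates analysis, PCA, Spearman correlation
    networks with permutation nulls, kernel density state-space surfaces) used to
    distinguish Continuous from Discontinuous migration modes. Includes a
    seed-deterministic synthetic-data generator (persistent random walks,
    mode-specific membrane event series, two-mode feature tables, rendered mask
    movies) so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
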