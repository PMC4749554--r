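---
title: "Quantifying mesenchymal migration modes with cellmig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesenchymal migration modes with cellmig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmig)
```

## The problem

Single mesenchymal (lamellipodial) cells migrating on extracellular matrix do
not behave as one homogeneous population: time-lapse imaging of cells
co-expressing a CMAC marker (paxillin) and an F-actin marker (LifeAct)
reveals two co-existing behavioural regimes. In the *Continuous* mode, cells
glide with stable morphology and membrane protrusion tightly leads
retraction; in the *Discontinuous* mode, cells advance step-wise through
cycles of lateral protrusion, polarization and tail retraction, with
retraction-led, temporally decoupled membrane dynamics. `cellmig` implements
the quantitative layer needed to characterize these regimes from segmented
label-mask movies: object tracking, motion statistics, membrane
protrusion/retraction dynamics, organizational features of cell-matrix
adhesion complexes (CMACs), and the multivariate statistics that separate
the modes. Segmentation itself is out of scope: the package consumes label
masks (multi-page TIFF) produced upstream, plus per-observation mode labels
assigned by blinded human classification, for which the package provides the
blinding/randomization support.

## Data model and conventions

* Pixel indices are 0-based `(row, col)`; physical coordinates are
  `index * pixel_size_um` at pixel centers. Defaults mirror the standard
  acquisition: 0.21 µm pixels, 5 min frame interval.
* Label 0 is background. Cell and CMAC layers live in separate label movies.
* CSV is the canonical table format (the schemas are fixed in
  `read_table_csv()`); configuration files are JSON or YAML. The deposited
  table schema of the original datasets is not public, so the CSV schema
  here is this package's own convention.
* Mode labels take values `Discontinuous`, `Continuous` or `null` (dead
  cells, sustained contact); `null` observations are excluded from every
  downstream denominator rather than counted as zeros.

## Tracking and trajectory smoothing

Objects are tracked frame-to-frame by *mutual* nearest-centroid matching
under a distance gate; unmatched objects start or end tracks and there is no
gap closing, so tracks always cover consecutive frames (the published CMAC
rules require consecutive presence). The gate and tie-breaking are not
specified in the source method ("nearest neighbor analysis"), so this
package fixes them: 3 object radii for cells, 2 µm for CMACs, ties broken by
smaller distance then lower label id. Mutual-nearest matching makes the
links symmetric under time reversal, which is tested as a property.

Cell trajectories are smoothed with cubic smoothing splines. The smoothing
parameter `p` follows the penalized-spline convention: `p = 1` interpolates,
`p = 0` returns the least-squares line, and intermediate values balance
residual sum of squares against curvature on the scale of the cube of the
knot spacing (the `csaps` convention), with generalized cross-validation as
the default. Smoothing is applied to cell trajectories only; whether the
original pipeline also smoothed CMAC trajectories is ambiguous, and raw CMAC
centroids are retained here.

CMAC filtering applies three published rules: observations with area at or
below 0.05 µm² are discarded; tracks shorter than 3 consecutive frames are
discarded; and lifetime (`n_frames × frame interval`) is undefined for
tracks present in the first or last movie frame — such tracks still
contribute to all other features, they are only excluded from lifetime
statistics.

## Motion: speed, MSD and the Furth model

Instantaneous speed is the frame-to-frame displacement of the smoothed
trajectory per minute. Mean squared displacement is computed in a moving
window of 24 frames (2 h), averaging over *all* overlapping pairs within the
window, for lags 1–12 (up to 1 h). The window is centered on the reported
frame; truncated windows at track ends are dropped. Each profile is fitted
with the Furth persistent-random-walk model

$$\mathrm{MSD}(t) = 4M\left(t - t_p\left(1 - e^{-t/t_p}\right)\right),$$

with migration coefficient $M$ (µm²/min) and persistence time $t_p$ (min),
under the constraints $M, t_p \ge 0$.

Two numerical choices matter here. First, the fit weights residuals by
$1/\mathrm{MSD}$ (relative error). The sampling standard deviation of an
empirical MSD grows roughly in proportion to its value, so ordinary least
squares lets the noisy large-lag points swamp the short-lag curvature that
identifies $t_p$; with 5-min frames and $t_p = 2$ min this biases the median
recovered $t_p$ about 25% low, while inverse-variance weighting recovers
both reference regimes, $(M, t_p) = (0.5, 2)$ and $(2, 10)$, within 15% from
200 tracks of 96 frames. `weights = "none"` restores plain least squares.
Second, initialization takes $M_0$ from the slope of the last two lags and
$t_{p,0}$ as two frame intervals, with a small multi-start; non-convergence
is flagged rather than silently returned.

Motion measures are binned by empirical quantiles (quintiles of $M$,
tertiles of speed) with linear-interpolation quantile edges, and companion
variables summarized per bin by median and notch interval.

## Membrane protrusion and retraction dynamics

Between two masks of the same cell separated by $w$ frames, protrusion is
the area of gained pixels ($|B \setminus A|$) and retraction the area of
lost pixels ($|A \setminus B|$). Window sizes 1–15 frames (5–75 min at 5-min
sampling) are all computed from the raw masks at $t$ and $t+w$ — no
intermediate accumulation — so each window measures net shape/position
change on its own timescale and `w = 1` coincides with consecutive-frame
analysis.

Event-size distributions are normalized histograms on shared edges (default:
1 µm² bins from 0 to the pooled 99.5th percentile, open top bin — the
original binning is unspecified); distributions are compared by per-bin
subtraction, which sums to zero by construction.

Protrusion–retraction coupling is measured by the mean-removed,
coefficient-normalized cross-covariance at lags −12..+12 frames (±60 min),
with the published sign convention: a peak at a *negative* lag means
protrusion leads retraction. Missing values are imputed by the trajectory
mean before computation, and constant series yield flagged, undefined
profiles. The original routine's normalization is ambiguous; coefficient
normalization (dividing by the product of the series standard deviations)
is used so profiles are comparable across cells. Note that for a finite
series the linear (non-circular) coefficient at the coupling lag is slightly
below 1 even for perfect coupling, because the shifted overlap omits edge
terms; the peak location is exact.

Per cell and window, the absolute cross-correlation values over all 25 lags
are averaged; per condition, cells are averaged with equal weight (the
aggregation weighting is unstated in the source; equal-cell weighting is the
package's choice) with a t-based 95% CI. Mode differences across the 15
window sizes are assessed by a Friedman test with modes as treatments and
window sizes as blocks — the blocking variable is not stated in the source
and this layout ("across the sampled time windows") is the package's
interpretation, recorded here.

## Organizational features and CMAC intensities

The full published catalogue has 55 organizational features, defined in
supplementary material that is not reproduced in the main text; the package
implements a named representative subset (cell area, compactness, CMAC
count/areas/distance-to-border/lifetime, corrected and standardized CMAC
intensities, speed) and exposes a registry (`register_feature()`) for the
remainder. Compactness is defined as $4\pi A / P^2$ (1 for a circle), with
the perimeter estimated from exposed pixel edges under the $\pi/4$
staircase correction; the source never defines its compactness formula, so
this definition is documented and swappable.

CMAC intensities are corrected by subtracting the mean intensity in a 1 µm
annulus around the CMAC, excluding pixels of any other segmented CMAC; an
annulus fully occupied by other CMACs yields a flagged undefined value.
Corrected intensities are standardized per experimental repeat by the median
corrected intensity of reference-size CMACs (0.15–0.2 µm²) in a reference
condition, making values 1-centred and invariant to global linear intensity
scaling within a repeat. The reference condition is dataset-specific (the
original used its low-fibronectin, no-inhibitor condition) and is supplied
by the user here.

Aggregates over zero CMACs are `NA`, never 0.

## Multivariate layer

*CVA.* Canonical variates are eigenvectors of $W^{-1}B$ (pooled
within-group and between-group covariance), sorted by eigenvalue; at most
`groups − 1` non-null variates exist and eigenvalues normalized to their sum
give per-CV variance fractions. Features are z-scored by default (the source
does not say whether they were; z-scoring makes CV1 coefficients comparable
across features, which its feature ranking presupposes), rows are
complete-case, features with more than 20% missing are dropped with a
warning, and a ridge of `1e-6 · trace(W)/p` keeps $W$ invertible. For two
groups CV1 equals the Fisher LDA direction, which is tested against a
closed-form oracle. Group "centers of mass" are arithmetic means of scores;
`cva_separation()` reports the fraction of observations nearest their own
center.

*PCA.* Singular value decomposition of the z-scored ("normalized") data
matrix; zero-variance features are an error naming the feature.

*State-space surfaces.* Gaussian kernel density on the first two component
axes, grid mass normalized to 1. The bandwidth is Silverman's rule × 0.5 per
axis: deliberately smaller than the overall mode distributions so that
valleys and ridges of the surface reflect the data rather than the kernel.
Collinear point sets are flagged as degenerate.

*Correlation networks.* Spearman's rank correlation per cell observation
with pairwise-complete missing handling. To ask whether two modes' networks
differ more than chance, the identity of the correlation values in one
matrix is permuted (which pair each value belongs to) while the other is
held fixed, the absolute differences recomputed, and the pooled null over
100 permutations compared with the observed CDF — a seed-controlled,
reproducible procedure.

*Univariate.* Wilcoxon rank-sum (exact for small untied samples, normal
approximation with tie correction otherwise) and notch intervals
`median ± 1.57·IQR/√n` under linear-interpolation quantiles.

*Speed-coupling catalogue.* Within each cell trajectory (at least 8
observations), Spearman's rs between a feature and speed; the per-mode
summary is the median across cells — the aggregation unit ("medians of
populations values") is ambiguous in the source, and per-cell aggregation is
the package's documented choice. A coupling is non-significant if 0 lies in
the notch interval of the per-cell rs values; across two modes the classes
are `both_positive`, `both_negative`, `one_mode_only`, `inverted`, `ns`.

## The synthetic world

Every pipeline stage is testable without downloads because the `simulate_*`
generators produce data with known ground truth; their defaults are the
stated conditions of the system being emulated, not tuning knobs:

* **Trajectories** are 2-D Ornstein–Uhlenbeck velocity processes with
  relaxation time $t_p$ and stationary per-component velocity variance
  $M/t_p$, discretized *exactly* (the joint position–velocity transition
  over a frame is Gaussian with known covariance), so the ensemble MSD
  equals Furth's formula at every lag — this is what makes the generator a
  legitimate oracle for the fit.
* **Membrane events**: Continuous cells couple retraction to the previous
  frame's protrusion (`r(t) = p(t−1) + noise`, with an AR(1) protrusion
  base); Discontinuous cells draw sparse large retractions (per-frame
  probability 0.08, ~25 µm² against a ~1 µm² baseline, giving the bimodal
  retraction-size distribution) each followed after a 3-frame (15 min) delay
  by elevated protrusion. The delay realizes the reported "large time delay"
  between retraction and subsequent protrusion; 15 min is a choice within
  the reported positive-lag range.
* **Feature tables**: two multivariate Gaussian populations with prescribed
  per-feature mean shifts (SD units) and per-cell latent speed with
  mode-specific coupling signs, so "inverted" couplings exist by
  construction. The default mode-label generator uses the observed baseline
  balance of ~80% Discontinuous observations.
* **Rendered movies**: a deformable disk follows the (rounded) trajectory;
  prescribed retraction pixels are stripped from the boundary and protrusion
  pixels grown outside it, never re-adding just-removed pixels, so measured
  events equal the prescription exactly for a stationary cell and within
  rounding for a moving one. CMAC blobs with known intensity on a known
  background ride inside the cell.

What a green test does *not* establish: the generators make no claim of
biophysical realism (no cell mechanics, no segmentation noise, Gaussian
noise only), so passing them validates the measurement and statistics code,
not the biology; and real-data headline numbers (e.g. exact mode
frequencies under fibronectin titration) require the original deposited
imaging dataset, which is not bundled.

## Worked example

```{r example, eval = FALSE}
cfg <- cellmig_config()

# simulate and render one persistent walker, then re-measure it
tr <- simulate_trajectory(M = 2, t_p = 10, frames = 96, dt = 5, seed = 1)
mv <- render_mask_movie(track = tr, dim = c(400, 400), radius_px = 12,
                        pixel_size_um = cfg$pixel_size_um, seed = 1)
tracks <- smooth_tracks(track_objects(exclude_border_cells(mv$cell)))
msd <- msd_moving_window(tracks$smoothed_x_um, tracks$smoothed_y_um,
                         tracks$frame, window = 24, max_lag = 12)
fit_furth_profiles(msd)   # per-window (M, t_p)

# two-mode membrane dynamics
ev <- simulate_membrane_events("Discontinuous", frames = 96, seed = 2)
plot(protrusion_retraction_xcov(ev$protrusion_um2, ev$retraction_um2))
```

## Known limitations

* No gap closing and no merge/split handling in tracking (out of scope by
  design); heavy over-segmentation upstream will fragment tracks.
* The TIFF layer supports uncompressed grayscale stacks only — sufficient
  for label masks and intensity exports, not a general TIFF reader.
* The feature registry ships a subset of the full 55-feature catalogue; the
  trailing-edge-speed feature family is left to user registration because
  its definition is not in the available text.
* Automated mode classification is deliberately not provided: mode labels
  are inputs, and the package supports the blinded manual workflow instead.
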