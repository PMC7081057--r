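---
title: "Methods: gradient-beam dosimetry and single-cell dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-beam dosimetry and single-cell dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirdose)
```

## The measurement problem

Photobiomodulation experiments ask how low-power near-infrared (NIR) light
changes cellular signalling — here, intracellular calcium and mitochondrial
superoxide reported by fluorescent probes in T cells. Scanning a
two-wavelength dose space (1064 nm and 1270 nm) one irradiance pair at a
time is prohibitively slow. The instrument this package analyses solves
that with two *orthogonal gradient beams*: the 1064 nm irradiance varies
continuously along the image x axis and the 1270 nm irradiance along the y
axis, so every cell in one field of view receives its own dose pair and a
single time-lapse acquisition (one frame before laser exposure, then
frames at fixed delays after it) probes hundreds of dose combinations
simultaneously.

`nirdose` implements the complete analysis chain for such data:

1. **calibration** — turn replicated beam-profiler line scans into
   per-axis polynomial irradiance models and a per-pixel dose map;
2. **detection/tracking** — find individual cells as smoothed local
   intensity maxima, link them across timepoints, and normalise each
   cell's fluorescence to its own pre-exposure baseline;
3. **dose-response** — bin cells into irradiance-combination groups,
   summarise fold changes per group, and test groups against a no-laser
   control (one-way ANOVA + Tukey);
4. **synthetic data** — render fully seeded artificial acquisitions with
   known ground truth, so each stage and the whole pipeline can be
   validated without microscope data.

## Gradient calibration

Each axis is modelled as a polynomial $E(s) = \sum_{k=0}^{d} c_k s^k$ of
the position $s$ (µm) along the gradient, fitted by ordinary least
squares to the pooled replicate scans. The degree is chosen by Akaike's
information criterion in its least-squares form,

$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2k, \qquad k = d + 2,$$

counting the $d+1$ coefficients plus the noise variance. Two numerical
choices matter:

* **RSS floor.** An interpolating fit has RSS at rounding-error level and
  an AIC of $-\infty$. We floor the RSS at
  $n \cdot 10^{-12}\,\overline{y^2}$, so exactly-fitting candidate
  degrees receive finite, directly comparable scores and the parameter
  penalty makes the *lowest* interpolating degree win; remaining exact
  ties also break toward the lowest degree.
* **Basis scaling.** A raw Vandermonde basis on positions up to 1200 µm
  is catastrophically ill-conditioned by degree 6. Fitting is done on
  positions divided by their maximum (QR factorisation), and the
  coefficients and their covariance are transformed back to raw units,
  which is exact in real arithmetic and stable in floating point.
  Evaluation uses Horner's scheme.

The default candidate set is degrees 0–6: wide enough to contain the
quartic (1064 nm) and quadratic (1270 nm) shapes this instrument
produces, with headroom above them. Replicates are pooled as independent
points by default (`pool = "points"`); fitting per-position means instead
is available (`pool = "means"`) since profiler software sometimes exports
only means — for balanced replicates the coefficient estimates coincide,
only the residual bookkeeping differs.

Confidence bands are delta-method bands for the *mean curve*:
$\widehat{E}(s) \pm t_{1-\alpha/2,\,n-d-1}\sqrt{x(s)^\top V x(s)}$ with
$V$ the coefficient covariance. They quantify uncertainty of the
calibration curve itself, not the scatter of future profiler readings,
which is what a calibration needs.

The two fitted axes plus the pixel size compose into an
`irradiance_map`: pixel $(c, r)$, with 0-based indices and pixel size $p$
µm/px, receives the dose pair $(E_x(cp),\, E_y(rp))$. The default pixel
size of 1.6 µm/px reproduces the instrument's geometry, where a 5 × 5 px
detection window corresponds to roughly 8 × 8 µm. Pixels outside the
calibrated field extent are flagged and excluded from binning. Bin
schemes derived from a map span the *exact* attained range of each
polynomial (endpoints plus interior stationary points via `polyroot`),
so the top bin's closed edge captures the true maximum even when it
falls between integer-micron grid points.

## Cell detection, tracking and fold changes

Frames are smoothed with a normalized 3 × 3 Gaussian kernel. Only the
kernel's support is fixed by convention; we use σ = 0.85 px,
the largest value for which the 3 × 3 truncation still holds ≥ 99 % of
the kernel mass, so the kernel is a faithful (not merely cropped)
Gaussian. Borders are edge-replicated, which preserves constants
everywhere.

A pixel is called a cell when its smoothed intensity is (i) ≥ every
smoothed value in its centred 5 × 5 window and (ii) strictly above a
threshold. The ≥ comparison keeps flat-topped spots; to avoid double
counting a plateau, only the first pixel in row-major order is kept among
candidates sharing a window, so no two calls ever lie within one window.
The threshold is "empirical" in practice; the data-driven default is
median + 5 × MAD of the smoothed frame (MAD scaled for Gaussian
consistency), putting the false-call rate on pure background far below
one per 10⁵ pixels. An absolute threshold can be supplied instead.

Tracking is deliberately minimal because the assay requires cells that do
*not* move: each baseline detection is matched to at most one detection
per later frame by greedy mutually-exclusive nearest-neighbour assignment
within a 2 px tolerance (about half a cell diameter), and any baseline
cell that misses a match in any analysed frame is dropped. On separable
instances — which stable cells at this density are — the greedy matching
coincides with the optimal assignment, which the test suite verifies
against an exhaustive oracle.

Fluorescence is *measured* on the unfiltered frames at the called pixel
(the filtered frames serve detection only); measuring on the smoothed
frames is available via `measure = "smoothed"` since the phrase
"prefiltered images" admits both readings. The per-cell fold change at
time $t$ is $I_t / I_{\mathrm{baseline}}$. By default both intensities
have the frame median subtracted first: the median estimates the camera
background (cells occupy a small fraction of pixels), and without this
correction a cell whose signal halves would show a fold change well above
0.5 whenever the background is non-negligible. Cells with non-positive
corrected baseline intensity cannot be normalised and are excluded with a
warning.

## The dose-response grid and inference

Cells are assigned to half-open dose rectangles
$[e_i, e_{i+1}) \times [f_j, f_{j+1})$ — a dose exactly on an interior
edge belongs to the higher bin, and the topmost edge is closed. The
default scheme is 5 equal-width bins per axis (25 groups) spanning the
doses the map actually delivers; the instrument's own grouping into 25
irradiance combinations motivates the 5 × 5 default, while the exact
edges used there are unreported, so equal width is our choice. Each
group is summarised by its mean fold change, SEM ($s/\sqrt{n}$, defined
for $n \ge 2$) and count, per timepoint — the colour-map matrix.

Inference compares every dose group against the no-laser control (cells
outside the beam, or a separate unexposed acquisition): one-way ANOVA
(via `stats::aov`) followed by Tukey's multiple comparison test, with the
Tukey–Kramer standard error for unequal group sizes,
$q_{ij} = |\bar y_i - \bar y_j| / \sqrt{\tfrac{MS_W}{2}(1/n_i + 1/n_j)}$,
and adjusted p values from the studentized-range distribution
(`stats::ptukey`, which integrates the standard double-integral
representation numerically; the test suite checks it against an
independent quadrature to 10⁻⁴). Groups with fewer than 2 members are
excluded from inference with a warning. The familywise level defaults to
α = 0.05. All pairs are computed; the control-contrast subset is what the
pipeline reports, mirroring how such experiments are interpreted.

## What the synthetic generator emulates — and what it does not

A `synthetic_scene` renders, per timepoint,
$\mathrm{background} + \sum_i A_i \,\phi_i(t)\, (1-\beta)^{t_k}
\,\mathrm{PSF}_{\sigma}(x - x_i) + \varepsilon$, clipped and rounded to
the camera bit depth. Defaults, fixed once as a realistic instance of
this experiment class:

| parameter | default | rationale |
|---|---|---|
| field | 1.2 × 1.2 mm at 1.6 µm/px (750 × 750 px) | instrument geometry |
| cells | ≈ 1 per 40 × 40 px (352; density configurable) | sparse single-layer T cells |
| PSF σ | 2 px | ~6 µm apparent cell size under 4× magnification |
| amplitudes | uniform 600–1200 counts over background 100 | bright probe loading, 16-bit camera |
| read noise | Gaussian, sd = 2 % of background | CCD at 1 s exposure; Poisson shot noise optional |
| photobleaching β | 2 % per acquisition | mild bleaching that baseline normalisation cannot remove |
| response | fold 0.85 at 1 min inside 250–400 × 55–65 mW/cm², 1.0 outside; recovery to 1.0 at 5 min | the transient suppression window this instrument class was built to resolve; 0.85 is a generator choice, not a measured effect size |
| between-cell sd | 0.10 | spread comparable to the visible group SEMs |
| min peak separation | 8 px | ≥ the 5 px window, with margin so a bright neighbour's PSF tail cannot shadow a dim cell's maximum |
| jitter | sd 0.3 px per frame | "stable" cells with sub-pixel drift |

Ground truth records each cell's position, dose pair, window membership,
realised biological fold, and the *expected rendered ratio*
(fold × bleaching factor). Recovery checks compare pipeline measurements
against the rendered ratio — that is what the images actually contain;
the bleaching component is common to all groups and cancels in the
control comparisons, which is exactly why ratio-to-baseline designs
tolerate bleaching.

Everything is a pure function of (parameters, seed): the same seed
reproduces byte-identical frames, and each frame's noise stream is
derived deterministically from the scene seed and frame index.

The generator does **not** model fluorophore photochemistry (calcium
binding kinetics, probe leakage), optical aberrations, non-uniform
illumination of the excitation lamp, cell shape, or clumping. Passing
the end-to-end tests therefore demonstrates that the *pipeline* is
correct and well-calibrated on data obeying its stated assumptions — it
does not certify performance on real images, where threshold choice and
cell crowding dominate.

## Validation strategy and problem sizes

The test suite pairs every non-trivial operation with an independent
oracle: direct nested-loop convolution for the smoother; exhaustive
per-pixel neighbourhood search for the detector (random frames up to
64 × 64, with quantised intensities so plateau tie-breaking is
exercised); exhaustive assignment enumeration for the tracker;
hand-computed sums of squares for the ANOVA; and direct numerical
integration of the studentized-range distribution for the Tukey adjusted
p values. Statistical calibration is checked by simulation (2000 null
ANOVA datasets; type-I error within [0.04, 0.06] at α = 0.05). The
end-to-end check runs two exposed acquisitions of 1000 cells each plus a
1000-cell control through the whole chain and requires ≥ 95 % cell
recovery, group means within 3 SEM of the programmed response, the
1-minute grid minimum inside the programmed suppression window, and no
group significantly below control at 5 minutes. These sizes keep the
full suite under a minute on a single core while leaving every group
with enough members (≈ 80) for stable SEMs.

## Worked example

```{r example, eval = FALSE}
map <- irradiance_map(as_beam_fit(gradient_coefficients("1064"), 1064),
                      as_beam_fit(gradient_coefficients("1270"), 1270))
experiment <- simulate_experiment(map, n_runs = 2, n_cells = 1000, seed = 42)
tracks <- analyze_experiment(experiment, map)
dr <- dose_response(tracks, map = map)
print(dr)
plot(dr)
```

## Known limitations

* Detection treats cells as point maxima; touching or overlapping cells
  are merged into one call. Segmentation is out of scope.
* No drift correction: systematic stage drift beyond the 2 px tolerance
  drops cells rather than re-registering frames.
* One fluorescence channel per run; multi-probe experiments are analysed
  as separate runs.
* The 25-group layout assumes equal-width dose bins; equal-count binning
  would change group occupancy but is not implemented because the
  comparison semantics (mean ± SEM per rectangle) presume fixed dose
  rectangles.
* Calibration is empirical: the polynomial degrees carry no beam-physics
  meaning, and extrapolation beyond the profiled field is flagged rather
  than trusted.
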