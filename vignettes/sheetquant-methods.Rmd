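---
title: "Methods: quantifying lateral protein organization on membrane sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lateral protein organization on membrane sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetquant)
```

# The measurement problem

Membrane sheets present the basal plasma membrane as a flat 2D field, so
the lateral organization of a membrane protein reduces to a point-pattern
and intensity-texture problem: puncta ("intensity maxima") stand in for
protein clusters, and the question of whether two proteins associate
becomes a question about cross-channel distances, correlations and
clustering statistics. `sheetquant` implements this pipeline end to end
and, because real micrographs come without ground truth, pairs every
stage with a generative model that does.

# Maxima detection and localization

Detection follows the classic mask-then-peak procedure:

1. a working copy of the image is smoothed with an isotropic Gaussian,
   σ = `blur_sigma_px` (default **1 px**), to suppress single-pixel noise;
2. a binary mask is formed by thresholding the smoothed image at
   `maxima_threshold_au` (default **2 a.u.**; in practice a few a.u.,
   chosen per channel and experiment and always logged);
3. within each connected mask component, local maxima of the smoothed
   image are kept, with a minimum separation of 2 px; plateau ties break
   deterministically to the smallest (row, col);
4. each maximum's intensity is the mean of the *raw* image over a
   5-pixel-diameter circular ROI (the 13-pixel digital disc, matching an
   oval of width 5 px on a pixel grid);
5. the subpixel position is the intensity centre of mass over that disc,
   computed on raw intensities after subtracting the disc minimum. The
   subtraction stops a uniform background from dragging the centroid
   toward the disc centre; numerically it roughly halves the truncation
   bias of the finite disc (0.07 px vs 0.18 px at a 0.3 px offset for a
   σ = 1.5 px spot). The residual bias is inherent to a fixed 5 px
   support and grows toward half-pixel offsets; under Poisson noise with
   a 50-count peak the RMS localization error stays below 0.25 px.

Whether the centre of mass should use smoothed or raw intensities is a
genuinely open choice; raw was chosen so localization is unaffected by
the smoothing scale, and only detection (steps 1–3) depends on σ.

Maxima closer than 2 px to the image border are flagged (`border`) and
not localized. Maxima whose disc mean does not exceed the threshold are
dropped, so every reported maximum satisfies the intensity criterion on
the raw data, not only on the smoothed copy.

## Cluster sizing by line-scan FWHM

A vertical and a horizontal line scan (default **15 × 3 px**, averaged
across the 3 px width) is centred on the pixel maximum and fitted to a
four-parameter Gaussian (offset, amplitude, centre, σ), initialized from
the profile minimum/maximum/argmax and solved by Levenberg–Marquardt.
The FWHM (= 2√(2 ln 2) σ ≈ 2.3548 σ) of the better-fitting direction is
reported in nm. A maximum is excluded when the best R² falls below
`r2_min` (default **0.8**) *or* the fitted centre lies outside the middle
third of the scan. The two exclusion rules are applied independently (a
flat profile is unfittable regardless of centring; an off-centre peak
signals a neighbouring structure contaminating the scan), and the reason
is reported per maximum.

# Cross-channel association and the flipped null

For every query maximum the shortest Euclidean distance to a target
maximum is computed from the subpixel positions (in nm). Subpixel rather
than integer-pixel positions are used because the pipeline computes them
anyway and they remove a ±0.5 px quantization from every distance. The
query/target orientation follows the assay convention (secretase maxima
query against APP targets) and can be swapped.

A query maximum is *closely associated* when its distance is at or below
`close_cutoff_nm` (default **50 nm**). The cutoff reflects imaging
physics: clusters with ~150 nm physical extent imaged at 60–90 nm
resolution will not show zero intermaxima distance even when physically
bound. The close fraction times the query density gives the close
density per μm².

The randomization null flips the target image vertically and
horizontally (a 180° rotation) and repeats detection — the flipped ROI is
analyzed so exactly the same pixels contribute, and the maxima count is
preserved exactly. For a spatially random target field of density λ the
null close fraction has the closed form 1 − exp(−λπr²) (nearest-neighbour
CDF of a Poisson process), which the flipped measurement reproduces; this
is used as an independent check in the test suite. Distance histograms
(default bin width **25 nm**, one STED pixel) truncate only the display
range; the close fraction is always computed on untruncated distances.
No edge correction is applied; for distances small against the ROI size
the bias is negligible, and this matches the field's standard practice.

# Intensity statistics

* **Corrected mean** — mean over the membrane ROI minus the mean over a
  background ROI placed next to the sheet; negative values are reported
  with a warning rather than clipped.
* **PCC** — the plain Pearson correlation of pixel intensities over the
  membrane ROI, with the ROI placed in a reference channel and propagated
  unchanged. No intensity thresholding (no Costes/Manders variants):
  the membrane ROI is the unit of analysis. Zero-variance channels give a
  missing value with a reason rather than an arbitrary number.
* **rSDM** — SD/mean of ROI pixel intensities. It is invariant to
  multiplicative rescaling, zero for a uniform ROI, and increases when
  the same integrated intensity concentrates onto fewer, brighter spots —
  which is what antibody cross-linking produces.
* **Normalization** — per-replicate values are expressed as percent of
  the reference condition's mean (reference = 100% by construction), then
  summarized as mean ± SD across replicates.

# FRAP

Traces are background-corrected frame by frame and normalized to the mean
of the corrected prebleach values (default **3 prebleach frames**;
the standard recording is 3 + 117 frames at 1.77 Hz). Recordings whose
unbleached reference ROI varies by more than **15%** — measured as
(max − min)/mean over the recording — are excluded as focal drift; the
comparison is strict, so exactly 15% is retained. Range/mean was chosen
over SD/mean because a monotone focus drift is a range phenomenon; the
choice is documented here because either reading is defensible.

Traces from one biological replicate are averaged frame-wise and the mean
trace is fitted to the hyperbola `y(t) = offset + R·t/(t + t½)` by
bounded Levenberg–Marquardt least squares. Time is measured from the
bleach event, with the first postbleach frame at one frame interval, so
`y(0) = offset` is the bleach floor. Bounds are offset, R ∈ [0, 1.5] and
t½ ∈ (0, 10 × recording length]; the fit is restarted from three t½
seeds (5%, 20%, 50% of the recording length) and the best sum of squares
kept, which avoids the shallow local minima of hyperbolic fits. A fit
ending at a bound, or a zero-variance trace, is returned flagged rather
than as a number that looks trustworthy.

# Densitometry

Input is a band-intensity table (lane, band, integrated intensity, local
background measured with an identical-area ROI in the same lane) — gel
image segmentation is out of scope since band ROIs are drawn by hand in
acquisition software. The cleavage ratio sums the soluble ectodomain
signal over lysate and supernatant and divides by the full-length signal:
`(sAPPα_Ly + sAPPα_Sn)/(APPm + APPi)`. The ratio is invariant to
lane-wide exposure scaling. Per-replicate ratios are expressed as percent
of the wildtype ratio of the same replicate, then averaged.

# The synthetic-data model

`simulate_sheet()` emulates the statistical structure the analysis
assumes, at the stated imaging conditions:

* 25 nm pixels and an isotropic Gaussian PSF of 75 nm FWHM by default
  (configurable over the 60–90 nm resolution range);
* channel A: cluster centres from a homogeneous Poisson process at
  3/μm² by default (the observed 2.2–4.7/μm² range), each cluster
  carrying 20–30 molecules scattered as a Gaussian with SD = diameter/4
  around the centre, so ~95% of molecules fall within the nominal
  65–85 nm spot. The paper trail gives no intensity profile for clusters;
  the Gaussian scatter is a modeling decision, flagged as such;
* channel B: point emitters at 3/μm²; a planted fraction sits uniformly
  within 40 nm of a *distinct* A cluster centre. Hosts are drawn without
  replacement whenever possible: two planted points on one cluster would
  merge under the PSF, and no detector could then recover the planted
  fraction — the ground truth itself must be resolvable to be a truth;
* emitters are rendered analytically (exact Gaussian patches, no raster
  splatting) and placed with a margin of 2 × PSF FWHM from the field
  edge; densities are defined relative to the placement region, so an
  interior ROI measures the nominal density without border bias;
* Poisson counting noise over a 2 a.u. background by default (additive
  Gaussian noise available). Same seed, same field, bit for bit.

`simulate_crosslink()` models antibody-induced coaggregation: all
channel-A molecules are reassigned to a small number of aggregate sites
(fewer, brighter, more clustered maxima — the rSDM rises in every seed
tested), and a `co_drag_fraction` of channel-B points moves to its
nearest aggregate. `co_drag_fraction = 0` reproduces the
non-coaggregating outcome (no systematic PCC shift); values ≥ 0.5
reproduce the coaggregating outcome (PCC rises in essentially every
seed). The coaggregation simulations use an association-free baseline so
the no-drag arm isolates the effect of aggregation alone.

What the generator does **not** emulate: camera gain/EMCCD noise, STED
depletion physics, acquisition photobleaching, chromatic offsets, membrane
holes and ruffles, or irregular sheet outlines. Passing tests therefore
demonstrate correctness of the measurement chain under the model's
assumptions, not robustness to every artifact of real micrographs —
threshold choice in particular remains an operator decision on real data.

# Problem sizes and numerical choices

Simulated fields are 256 × 256 px (6.4 μm side, ~37 μm² placement
region), a realistic single-sheet field at 25 nm pixels; recovery checks
use 5–20 seeds per condition, 200 seeds for localization error, 50 traces
for FRAP and 100 for densitometry. Detection is deterministic and
order-independent (candidates sorted by intensity, ties by position);
nearest-neighbour search is exact (verified against a brute-force oracle
on random instances); all distances are reported in nm via the pixel
size, and coordinates are 0-based (row, col) with half-open rectangle
ROIs — one stated convention everywhere prevents off-by-one drift.

# Known limitations

* Merged maxima: at 3/μm² and 75 nm PSF, ~5–10% of true emitter pairs
  fall within the resolution limit and are detected as one maximum;
  densities read ~3–10% low and single-field recall can dip just below
  0.9. This is physics, not a bug, and is why density acceptance bands
  are 15%.
* The centre-of-mass localizer carries a truncation bias that grows
  toward half-pixel offsets (up to ~0.1 px noiselessly); unbiased
  subpixel localization would need profile fitting, which is out of scope
  for the 5 px disc procedure implemented here.
* The flip null preserves intensity texture but also preserves any
  global intensity gradient, which a sheet with strongly uneven
  illumination would leak into the null.
* PCC and rSDM are whole-ROI statistics; membrane defects inside the ROI
  dilute both. The membrane polygon ROI is the unit of analysis.
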