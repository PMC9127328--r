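# sheetquant

Quantitative analysis of protein clusters on plasma membrane sheets.

Membrane sheets — flat basal plasma membranes left behind after ultrasound
"unroofing" of adherent cells — turn membrane protein organization into a
2D fluorescence field that can be analyzed punctum by punctum. `sheetquant`
implements the full quantitative pipeline used to ask whether two membrane
proteins (e.g. the amyloid precursor protein APP and its α-secretases
ADAM10/ADAM17) are laterally associated:

- **Maxima detection** — Gaussian pre-smoothing (σ = 1 px), intensity
  thresholding, per-component local maxima ("pixel maxima"), mean intensity
  in a 5-pixel circular ROI, and subpixel localization by intensity centre
  of mass within that ROI.
- **Cluster sizing** — vertical and horizontal 15 × 3 px line scans fitted
  to a Gaussian; the FWHM of the better fit is the cluster size, with
  exclusion of poor (R² < 0.8) and off-centre fits.
- **Density** — maxima per μm² of the analyzed ROI.
- **Cross-channel association** — for each query (secretase) maximum the
  shortest Euclidean distance to a target (APP) maximum; a maximum is
  *closely associated* if that distance is ≤ 50 nm. The null reference is
  the same analysis after flipping the target channel vertically and
  horizontally (180° rotation), which preserves counts and intensity
  texture but destroys registration. For a random (Poisson) target field
  of density λ the null close fraction follows 1 − exp(−λπr²).
- **Coaggregation statistics** — background-corrected mean intensities,
  the Pearson correlation coefficient (PCC) between channels over a
  membrane ROI, and the rSDM (SD/mean of ROI pixels, a scale-free
  clustering readout), normalized per condition to a reference (= 100%).
- **FRAP** — background correction, prebleach normalization, >15%
  reference-drift exclusion, replicate averaging, and least-squares
  fitting of the hyperbolic recovery `y(t) = offset + R·t/(t + t½)`.
- **Densitometry** — background-subtracted western-blot band intensities
  and the cleavage ratio `(sAPPα_Ly + sAPPα_Sn) / (APPm + APPi)`,
  expressed as percent of wildtype.

Every stage is validated against a **synthetic-data module**
(`simulate_sheet()`, `simulate_crosslink()`, `simulate_frap()`,
`simulate_lanes()`) that generates two-channel membrane-sheet images,
recovery traces and lane tables with known ground truth under realistic
imaging conditions (25 nm pixels, 60–90 nm PSF, 2–5 maxima/μm², clusters
of 20–30 molecules on 65–85 nm spots, Poisson counting noise).

## Worked example

Simulate a two-channel sheet in which 30% of secretase maxima are planted
within 40 nm of an APP cluster, then run the association analysis:

```r
library(sheetquant)

spec <- sheet_sim_spec(assoc_fraction = 0.3, rng_seed = 5)
sim  <- simulate_sheet(spec)
cfg  <- analysis_config(maxima_threshold_au = 5)
roi  <- roi_rect(6, 6, 244, 244, "membrane")

detect_maxima(sim$img_a, roi, cfg)
#> <maxima_set> 95 maxima (0 excluded) over 37.21 um^2 -> 2.553 /um^2

associate_channels(sim$img_b, sim$img_a, roi, cfg)
#> <distance_result> 120 query maxima | close fraction 0.350 (flipped 0.017, excess 0.333)
```

95 APP maxima are detected at 2.55/μm² (the field was planted at 3/μm²;
a few true clusters fall within the resolution limit and merge). Of 120
secretase maxima, 35.0% lie within 50 nm of an APP maximum. The flipped
null shows the chance floor is 1.7% — consistent with the Poisson closed
form 1 − exp(−λπr²) ≈ 2% at λ ≈ 2.6/μm², r = 50 nm — so the excess close
fraction of 0.333 recovers the planted 0.30.

FRAP fitting on a noisy simulated trace (true t½ = 10 s):

```r
fit_recovery(normalize_trace(simulate_frap(10, noise_sd = 0.02, seed = 5)))
#> <frap_fit> offset 0.199 | maximal recovery 0.604 | t1/2 9.82 s | R2 0.9706
```

Figure-level analyses are bundled as recipes
(`run_recipe("maxima_association")`, `"crosslink_coaggregation"`,
`"frap"`, `"wb_cleavage"`, ...) that write CSV tables, a JSON summary and
a log of every threshold used.

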