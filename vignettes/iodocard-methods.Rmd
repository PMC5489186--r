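---
title: "Methods: simulating and reading urinary-iodine paper test cards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reading urinary-iodine paper test cards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodocard)
```

## The measurement

A test card carries nine wax-bounded reaction circles: the top row holds
internal iodide standards at 0, 100 and 300 μg I/L, the two lower rows hold
six replicates of the unknown sample. Every circle runs the
Sandell–Kolthoff reaction — the iodide-catalysed reduction of Ce(IV) by
As(III) — with ferroin as redox indicator: a zone without iodide stays blue
(excess Ce(IV) keeps the indicator as ferriin), intermediate iodide gives
purple, and iodide-rich zones turn red as excess arsenite regenerates
ferroin. The quantitative readout of a photographed zone is the
red-minus-blue score

$$S = \bar R - \bar B,$$

the difference of the unweighted mean 8-bit red and blue channel
intensities over the reaction area. Each card is self-calibrating: ordinary
least squares of the three standards' scores against concentration gives a
per-card line $S = a c + b$, inverted as $\hat c = (S - b)/a$ for the
sample zones. The WHO categories are applied with closed-left thresholds:
deficient below 100 μg I/L, adequate in 100–299, excessive at or above 300.

## The colour-response model

No published rate constants describe the reaction as run on paper, so the
generator is deliberately empirical rather than kinetic. Its anchors are
the observed standard colours at the 3-minute read: blue-ish
(60, 70, 190) at 0 μg I/L, purple-ish (150, 70, 150) at 100, red-ish
(190, 70, 60) at 300. Between anchors each channel follows a monotone
(Hyman-filtered) cubic interpolation in concentration; above 300 μg I/L
each channel relaxes exponentially toward a nearby asymptote
(`tail_fraction` = 0.25 of the 100→300 channel step, e-folding scale
150 μg I/L), so the score keeps rising — extrapolated estimates above 300
do occur, as they must in a validation set spanning 0–500 μg I/L — but
saturates, reflecting the assay's loss of sensitivity outside the
50–300 μg I/L window.

Colour development in time is a single multiplicative factor on the
separation from the blank colour,

$$g(t) = \frac{1 - e^{-kt}}{1 - e^{-3k}}, \qquad k = 0.8\ \mathrm{min}^{-1},$$

normalised so the anchors are exact at the 3-minute read. Score separation
is therefore compressed at early reads ($g(1) \approx 0.61$) and nearly
flat over 3–5 minutes, the window in which the standards are best
distinguished. The long-time blue-shift that the 100 μg I/L chemistry can
show (ceric arsenate slowly redissolving) is intentionally not modelled:
the pipeline targets the 3-minute read only.

A `response = "linear"` variant makes every channel exactly linear in
concentration between the blank and 300 anchors (the purple anchor is
replaced by the collinear point). Its purpose is verification: with a
linear response and no noise, calibration inversion must recover every
concentration exactly, which pins down the whole
render → register → extract → calibrate → invert chain. The exactness
tests choose anchor colours with integral channel steps and concentrations
at multiples of 2.5 μg I/L so that 8-bit quantization introduces no error
at all; with arbitrary colours, quantization bounds recovery at roughly
half an intensity unit of score (≈ 0.6 μg I/L), which is invisible in any
noisy setting but would dominate a 10⁻⁶ tolerance.

## The imaging model

Nuisance variation is layered in the order a camera would impose it:

* **zone chemistry noise** — one Gaussian draw per zone added to the
  zone's score (±e/2 on the red and blue channels), sd
  `score_noise_sd = 6` score units by default;
* **geometry** — a similarity transform (rotation about the image centre,
  translation, isotropic scale) standing in for imperfect card placement;
* **illumination** — a multiplicative linear gradient across the card
  width (0 by default: a light box is built precisely to make illumination
  uniform, and the gradient is a stress parameter rather than a default
  condition);
* **pixel noise** — i.i.d. Gaussian per pixel per channel (sd 2 by
  default), then clipping to [0, 255] and rounding to 8 bits.

All randomness flows through one seed; a fixed seed reproduces images
bit for bit. Registration is fiducial-based: dark pixels are grouped into
blobs by single-linkage clustering (equivalent to connected components for
well-separated marks), blob centroids are matched to the layout's four
asymmetric corner fiducials by trying all point correspondences, and the
least-squares similarity transform (Umeyama fit) with the smallest RMS
residual wins. Centroids of ~300-pixel blobs are accurate to a few
hundredths of a pixel, so recovered corners land well within 1 px and
rotations within 0.2° of truth. Zone statistics are then read from discs
eroded by 15% of the zone radius — the reaction area short of the wax
boundary; the erosion fraction is exposed because the exact region a
human analyst would outline is a judgement call. The green channel is
recorded for diagnostics but never enters the score, and the printed
colour-standard patches are read only on request (`read_patches = TRUE`);
no white-balance correction is applied by default.

## Quantification and exclusion rules

The calibration is OLS on exactly three points, leaving one residual
degree of freedom that yields a standard error for the intercept — the
natural scale for judging small negative inversions. A slope below
`slope_epsilon` = 10⁻³ score units per μg I/L flags the card degenerate
(a flat response cannot be inverted); the threshold is an implementation
constant with no physical derivation, set two orders of magnitude below
typical slopes (~0.8).

Inverted estimates are never clipped. Negative estimates carry
`below_range_negative`, estimates above 300 μg I/L carry
`above_range_extrapolated`; both are retained for categorical statistics
and survey medians but excluded from MAE, bias and the precision metrics,
mirroring standard calibration-range bookkeeping (a 60-read study with 17
extrapolated and 8 negative reads analyses 35). Replicate circles are
pooled by the arithmetic mean (median available); a pooled read inherits
any replicate's flag in addition to its own range check — the conservative
choice, since one extrapolated replicate means the pooled value leans on
out-of-range chemistry.

The simulated visual read classifies a sample zone by the nearest of the
three standard colours in raw sRGB (ties toward the lower category). Raw
sRGB rather than a perceptual space is deliberate: the emulated readers
used unaided eyes, and the comparison is between colours on the same card
under the same illumination. Note its decision boundaries sit at
colour-space midpoints between standards, not at the WHO thresholds: with
a response that is steep below 100 μg I/L, the blue/purple midpoint
corresponds to roughly 45 μg I/L, so samples in the 50–100 band read
adequate and the simulated reader under-performs a human who interpolates
("less red than the 100 standard, hence below 100"). Synthetic visual
percent-correct is therefore pessimistic relative to trained readers.

## Validation statistics

Agreement on the three ordered categories is summarised by percent correct
and Cohen's kappa, $K = (P_o - P_e)/(1 - P_e)$, with identity, linear
($1 - |i-j|/2$) or quadratic ($1 - (|i-j|/2)^2$) weights. Published kappa
values for card data of this kind are ambiguous about their weighting —
one printed value matches linear weights on the visual matrix, another
matches the unweighted formula on the computer matrix — so no single
default is "the" kappa: all three weightings are computed and reported
side by side, and the linear weighting (natural for ordered categories) is
the function's default. Inter-operator precision pairs the two analysts'
in-range estimates by solution and averages the absolute differences;
inter-device precision is the standard deviation over replicate cards of
one solution, supplied separately when available. Population status is the
WHO categorization of the survey median (midpoint rule for even n) over
*all* estimates, flags included — dropping excessive reads would bias a
survey median downward.

## Synthetic study conditions

The default validation study mirrors a blind exercise: 30 coded
artificial-urine solutions (matrix: 15,000 ppm urea, 3800 ppm chloride,
1800 ppm sodium, 1200 ppm potassium), two analysts, one card per solution
per analyst, read at 3 minutes, rendered at 150 dpi. The 30 true
concentrations are a uniform grid over 0–500 μg I/L with seeded jitter of
half a grid step: the actual concentrations of any real study are
unpublished, a grid guarantees coverage of all three categories and of the
above-calibration region, and jitter avoids lattice artefacts. Zone score
noise of 6 units was chosen once as "moderate": through a slope of ~0.8 it
propagates to roughly 9 μg I/L per zone, and with the mid-range curvature
bias it produces study MAEs of ~20–30 μg I/L — the same order as published
card accuracy (~40 μg I/L), while keeping categorical agreement high.

`predict_study_error()` is the score-space companion used to check the
imaging pipeline: it adds the configured zone noise directly to the model's
score curve, pushes it through the same calibration and inversion code, and
repeats the whole study (default 200 replicates) to give the sampling
distribution of the in-range MAE. Pixel noise is ignored there because a
zone average over ~2000 pixels contributes only ~0.06 score units. A
rendered study's MAE is expected to land within a few Monte-Carlo standard
deviations of this prediction; that this holds is the package's main
evidence that the image-analysis layer adds no unmodelled error.

What passing synthetic tests does **not** show: robustness to real urine
matrices (interferents are not modelled), to uncontrolled lighting,
perspective distortion or camera post-processing (the imaging model is a
light-box idealisation), or to card-to-card reagent variation beyond the
single zone-noise term. The generator validates the analysis code, not the
chemistry.

## Arsenic accounting

Each circle receives 10 μL of 0.2 M As₂O₃ (two As atoms per formula unit,
74.9216 g/mol), i.e. 0.2997 mg As, 2.697 mg per nine-circle card — a
25-fold reduction against the ~7.5 mg a conventional UV-vis run consumes.
The TCLP models landfill leaching at a 20:1 fluid-to-solid mass ratio
(fluid density 1 g/mL), so leachate ppm = As mg / (20 × card g / 1000).
The default card mass of 4.68 g is exposed as a parameter: it is the solid
mass consistent with a theoretical starting leachate of 28.82 ppm, which
no specification of the card prints directly. Post-remediation
measurements below the method LOD (0.028 ppm = instrument LOD 0.0028 ppm ×
ten-fold dilution) are substituted by the LOD itself, making every summary
a lower bound on remediation performance; the batch summary is the mean of
censored values, classified against the strict 5 ppm EPA limit
(non-hazardous only strictly below). Goethite dose-response is out of
scope; only the constants survive (0.9 g loaded, 0.6 g minimum effective).

## Numerical choices and degenerate inputs

* Thresholds are closed on the left (100 → adequate, 300 → excessive);
  exact visual-tie colours break toward the lower category.
* Negative concentrations categorize as deficient and are flagged, never
  dropped silently.
* A zone mapped outside the frame is flagged per zone; the card fails only
  if a standard zone is unreadable.
* Kappa is undefined (error) when chance agreement is exactly 1
  (degenerate marginals); a flat calibration is a degenerate-card flag,
  not an exception, until inversion is attempted.
* Problem sizes in the test-suite: most image tests run at 100 dpi
  (≈ 236 × 283 px, ~900 px per eroded zone) and the end-to-end study
  checks use 30 × 2 cards at 150 dpi with 200 score-space replicates —
  large enough that Monte-Carlo standard errors are a few μg I/L, small
  enough to iterate on comfortably.
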