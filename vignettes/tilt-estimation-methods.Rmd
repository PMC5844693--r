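---
title: "Methods: normative surface-tilt estimation from stereo images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative surface-tilt estimation from stereo images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltnorm)
```

## The problem and the model

Local 3D surface orientation is parameterized by *tilt* (the direction in
which a surface is rotated away from frontoparallel — the orientation of the
range gradient) and *slant* (the magnitude of that rotation).  Ground planes
have tilt 90°; tree-trunk-like vertical surfaces have tilt 0°/180°.  Because
the sign of the slant direction is rarely recoverable locally, all analyses
here use *unsigned* tilt, tilt modulo 180°, an axial quantity.

`tiltnorm` implements an image-computable normative observer for unsigned
tilt.  Three local image cues are measured directly from a binocular image
pair:

* **luminance cue** — the orientation of the local luminance gradient
  (Gaussian derivatives, space constant `sigma_cue_arcmin`, default
  6 arcmin);
* **disparity cue** — the orientation of the gradient of the horizontal
  disparity map, where disparity is obtained by local windowed normalized
  cross-correlation of the two eyes' images (window space constant equal to
  the derivative operator's) with parabolic sub-pixel refinement;
* **texture cue** — the orientation of the major axis of the local
  amplitude spectrum (Hann-windowed FFT of the central 1°, DC and
  frequencies below 1 cpd removed, principal axis of the amplitude-weighted
  second-moment matrix over frequency coordinates).

Groundtruth tilt is computed from the pixel-registered range map as the
orientation of the Gaussian-smoothed range gradient (`sigma_truth_arcmin`,
default 3 arcmin), `atan2(dr/dy, dr/dx)`, with a y-up convention so the
ground plane maps to 90°.

The estimator is the **estimate cube**: cue triplets are quantized into
uniform half-open bins (64 per cue, 64³ ≈ 260 000 cells) and each cell
stores the conditional sample mean of groundtruth tilt given that cue
triplet.  Under a squared-error cost this conditional mean is the minimum
mean squared error (MMSE) estimate — the posterior mean of tilt given the
cues — with no assumptions about cue independence or the parametric form of
any distribution.  Estimation is pure table lookup.  Because tilt is axial,
"mean" everywhere denotes the circular mean on doubled angles; a cell
containing tilts {10°, 170°} correctly averages to 0°, not 90°.  Cells with
fewer than `min_count` (default 10) training samples fall back to the prior
mean — the circular mean of all training tilts, which is the cue-free MMSE
answer.

## Circular statistics

All summary statistics use circular statistics on the appropriate period:
the complex mean resultant `R`, circular mean `arg(R)`, circular variance
`1 − |R|`, and the wrapped signed error `e = arg exp(j(est − truth))` in
(−90°, 90°] for axial data.  The boundary value is fixed to +period/2 for
deterministic tie-breaking.  Trial-by-trial association uses the
Fisher–Lee (1983) T-linear circular correlation (the field's standard
angle–angle coefficient; the source text does not name one), computed in
O(n) via sum identities, with percentile bootstrap confidence intervals
(1000 resamples, 95% by default).  Bias-corrected errors subtract the
per-truth-bin circular mean error and re-wrap, so per-bin mean corrected
error is zero by construction.

## The synthetic world

The original analysis used ~600 million samples from a laser-scanned
natural-scene stereo database and human psychophysics; neither is publicly
deposited.  The package therefore ships a first-class synthetic world with
two tiers.

**Rendered stereo patches.**  `render_stereo()` ray-casts textured planar
(optionally height-perturbed) surfaces into left/right eye images with a
cyclopean range map.  Eyes are separated by 0.065 m (standard adult IPD;
not stated in the source) with parallel optical axes, so a frontoparallel
plane at distance d yields the textbook uniform disparity b/d radians —
this gives an analytic oracle for the stereo geometry.  Pixel pitch
defaults to 1920 px / 36° ≈ 53.33 px/deg, the display geometry of the
original experiment.  Textures (1/f noise; 3.5 and 5.25 cpd plaids with
randomized component orientations and phases) are painted in "projected
degree" units so nominal frequencies are exact at the patch centre.
Surface bumpiness is Gaussian-filtered noise added along the normal
(`bump_amplitude` meters, `bump_corr_length` degrees); it produces
controllable local *tilt variance* (circular variance of groundtruth tilt
in the central 1°), the departure-from-planarity covariate.  Stimulus sets
are drawn by constrained rejection sampling matching the experiment: slant
> 30°, distance 5–50 m, measured contrast 5–40%, no half-occlusions, 24
tilt bins.

**Simulated cue samples.**  Training a 64³ cube from rendered patches alone
is not feasible at desk scale (the original used 600M samples), so
`sample_cue_database()` simulates (cue triplet, tilt) pairs directly:
tilts come from a cardinal-heavy mixture prior — ground-plane component at
90° (weight 0.5), trunk component at 0°/180° (0.3), uniform oblique
minority (0.2), cardinal components axial von Mises with κ = 8 (≈10° sd),
matching the broad cardinal peaks of the natural tilt prior; each stimulus
draws a base reliability κ ∈ {1, 4, 16} and each cue adds independent
axial von Mises noise at the base κ times a per-cue jitter factor
∈ {0.5, 1, 2}.  Reliability is thus correlated across a stimulus's cues but
not identical, so within-triplet cue consistency carries reliability
information — the mechanism behind the Bayesian signatures the tests check
(cardinal attraction growing with noise, the oblique effect, and
p(truth | estimate) peaking at the estimate).  Cubes in the tests are
trained on 2–4 million simulated samples so that, as in the original
regime, low-count fallback cells are the exception.

**Synthetic observer.**  `synthetic_observer()` wraps estimates in axial
von Mises response noise (concentration on doubled angles), an optional
smooth per-tilt bias, and uniform lapses, standing in for a human
reporting tilt with a probe.

### What a green test does and does not establish

The generator reproduces the *mechanisms* (foreshortening, disparity
geometry, a cardinal-heavy prior, reliability-dependent cue consistency,
planarity violations) but not the photometric richness of natural scenes:
there is no shading, shadowing, occlusion structure, specularity, or
object-boundary statistics.  Passing tests establish that the
implementation is internally correct and that the normative machinery
reproduces the qualitative phenomena under the stated world; they do not
re-establish the original quantitative human–model agreement.

## Numerical and design choices

* **Contrast.**  The printed contrast formula omits a square root while the
  text calls the quantity root-mean-squared; the square root is applied.
  Windowed RMS Weber contrast uses a raised-cosine window over the central
  1°.
* **Luminance-gradient orientation.**  The synthetic textures carry no
  shading, so the literal single-pixel gradient orientation at the centre
  is texture-phase-random.  The cue is therefore estimated as the dominant
  orientation of the structure tensor of the σ-cue Gaussian-derivative
  gradients under a Gaussian pooling window (`lum_pool_sigma`, default
  0.75°), which reduces to the plain gradient orientation for uniform
  fields and recovers the foreshortening anisotropy the cue measures.
  Note the σ-cue derivative is a band-pass: on narrowband plaids it can
  favour the *less* foreshortened component, so plaid luminance cues are
  idiosyncratic; broadband (1/f) textures behave as expected.
* **Vergence.**  Disparity search is centred on the disparity implied by
  the centre-pixel range (emulating fixation on the scene point), then the
  gradient of the absolute disparity map is taken; the offset does not
  affect the cue.
* **Quantization.**  Half-open uniform bins with edge values assigned
  upward; cues reduced mod 180 before binning (the analysis domain is
  unsigned, and the cube absorbs any fixed monotone convention).
* **Degenerate inputs.**  Tilt is masked where the range-gradient magnitude
  falls below 10⁻⁶ m/px; cues are flagged unreliable on vanishing
  gradients, sub-threshold correlation peaks (NCC < 0.3), or near-isotropic
  spectra (eigenvalue ratio < 1.05); unreliable triplets receive the
  prior-mean fallback, flagged.
* **Kernels.**  All Gaussian kernels are truncated at ±3σ with reflected
  boundaries.
* **Tilt-variance sweep.**  The bumpy-scene analysis samples
  `bump_amplitude` uniformly on [0, 0.15] m at 10 m distance and slant 50°,
  which spans tilt variance ≈ 0–0.7.  Beyond ≈0.7 the centre groundtruth
  tilt itself becomes ill-defined in this generator and mean absolute error
  saturates near the uniform-guessing level, so the sweep stays in the
  informative rising regime; slant and distance are held fixed to isolate
  the covariate.
* **Monte Carlo bands.**  Confidence bands on angular bin means use
  ordinary percentile quantiles of the per-repeat circular means; this is
  adequate away from the wrap point but not exact for bins whose means
  straddle 0°/180°.
* **File formats.**  No TIFF library exists in the supported R dependency
  set, so patches and cubes are stored as flat little-endian float64
  binaries with JSON headers (bit-exact round-trips); manifests and trial
  tables are plain CSV with a declared schema; run configuration is JSON.

## Known limitations

* The luminance cue is only weakly informative below ≈45° slant in this
  shading-free world; its 10°-median-accuracy property is asserted at
  slant 60°.
* Plaid textures make the luminance and texture cues depend on the random
  component geometry (see above); worked single-patch examples fix seeds.
* The cue simulator's noise model (axial von Mises with a 3×3
  reliability mixture) is a stylized stand-in for measured natural cue
  statistics; absolute error levels are not comparable to the original
  study, only orderings and signatures.
* Signed-tilt analyses, global (spatially pooled) tilt estimation,
  alternative cue-combination models, and choice-probability analyses are
  out of scope.
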