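# tiltnorm

Normative analysis of local 3D surface-tilt estimation from binocular
images of textured scenes.

## What problem this addresses, and for whom

Surface orientation is parameterized by **tilt** τ (the direction of slant,
i.e. the orientation of the range gradient — 90° for the ground plane, 0°
or 180° for tree-trunk-like surfaces) and **slant** (the magnitude of
rotation out of the frontoparallel plane). Estimating tilt locally from
images is hard in natural scenes, and human estimates there are biased
toward the cardinal tilts that dominate natural-scene statistics. This
package is for vision scientists and computational neuroscientists who
want an *image-computable* Bayes-optimal reference observer for unsigned
tilt (τ mod 180°, an axial variable), together with the psychophysics-style
machinery used to analyze it.

The pipeline:

1. **Synthetic stereo scenes** — ray-cast textured planar or bumpy surfaces
   (1/f noise, 3.5/5.25 cpd plaids) into left/right-eye images with a
   pixel-registered cyclopean range map, under constrained sampling
   (slant > 30°, distance 5–50 m, contrast 5–40%, no half-occlusions).
2. **Groundtruth** — tilt as the orientation of the Gaussian-smoothed range
   gradient, `τ = atan2(∂r/∂y, ∂r/∂x)`; slant; local *tilt variance* (the
   circular variance of tilt in the central 1°, a planarity measure).
3. **Image cues** — orientations of the local luminance gradient, of the
   disparity-map gradient (disparity by windowed normalized
   cross-correlation with sub-pixel refinement), and of the major axis of
   the local amplitude spectrum; plus cosine-windowed RMS contrast
   `C = sqrt( Σ ((I−Ī)/Ī)² W / Σ W )`.
4. **Estimate cube** — the MMSE estimator `τ̂ = E[τ | cues]`, approximated
   nonparametrically as the per-cell circular mean (on doubled angles) of
   groundtruth tilts over a 64×64×64 quantization of the cue triplet, with
   a prior-mean fallback for sparse cells. No independence or
   distributional assumptions.
5. **Evaluation** — circular summary statistics (`R = Σ e^{jτ} / N`,
   mean `arg R`, variance `1 − |R|`), conditional distributions
   `p(τ̂−τ | τ)` and `p(τ | τ̂)`, bias-corrected errors
   `e* = (τ̂−τ) − E[τ̂−τ | τ]`, Fisher–Lee circular correlations with
   bootstrap CIs, slant/distance/tilt-variance effects in quantile bins,
   and Monte Carlo experiment repeats.

See `vignettes/tilt-estimation-methods.Rmd` for the model, parameter
choices, and limitations.

## Worked example

```r
library(tiltnorm)

geom  <- viewing_geometry()                      # 0.065 m IPD, 53.33 px/deg
spec  <- scene_spec(tilt = 90, slant = 60, distance = 10,
                    texture_kind = "onef_noise", contrast = 0.3, seed = 7)
patch <- render_stereo(spec, geom)

truth <- patch_truth(patch)
cues  <- compute_cue_triplet(patch)
cube  <- build_cube(sample_cue_database(2e6, seed = 42))
est   <- estimate_tilt(cube, cues)
```

This prints (numbers produced by the code above):

```
groundtruth: tilt 90.0 deg, slant 60.0 deg, tilt variance 0.0000
cues: luminance 83.0, disparity 89.6, texture 91.8 deg; contrast 0.27
estimate cube: 64^3 cells (231187 populated, 34334 above min_count 10),
               2000000 training samples, prior mean 90.0 deg
MMSE estimate: 88.6 deg (error -1.4 deg)
```

The three cues measured from the images land within a few degrees of the
ground-plane tilt (90°), and the cube lookup returns 88.6°. Presenting the
model with 3600 noisy cue triplets drawn from the cardinal-heavy tilt prior
and summarizing with `summarize_by_tilt()` gives per-bin means near the
identity at cardinal tilts but strong attraction at obliques, e.g. the
26.25° bin's mean estimate is pulled to ~50° with high circular variance
(0.63), a mean absolute error of 12.7°, and 64% of estimates within 7.5° of
a cardinal tilt — the oblique-effect signature that motivates the model.

## Command line

```sh
inst/cli/tiltnorm run --seed 1 --out out/ --n-per-bin 5 --bins 24
inst/cli/tiltnorm train --seed 1 --out out/ --n-train 2000000
inst/cli/tiltnorm estimate --cube out/cube --manifest out/manifest.csv --out out/
inst/cli/tiltnorm evaluate --trials out/trials.csv --out out/
```

Each subcommand exits nonzero with a one-line diagnostic on error; all
randomness derives from `--seed`.

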