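# carostab

Suppression of probe and breathing disturbances for carotid wall motion
estimation in B-mode ultrasound sequences.

## The problem

Speckle tracking of the common carotid artery (CCA) wall measures the
distension and longitudinal motion of the vessel wall over the cardiac
cycle — inputs to arterial stiffness indices used in early atherosclerosis
assessment. During acquisition, probe-handling jitter and the subject's
breathing move the *whole* image; block matching then reports the sum of
the wall's own motion and this global disturbance. `carostab` treats the
disturbance as a common-mode signal: tissue far from the vessel is not
affected by wall pulsation, so registering far-from-wall subimages between
frames recovers the per-frame rigid disturbance, frames are re-aligned by
its inverse, and only then is the wall tracked.

## The method

Per frame *k* against frame 1:

1. **Subimage cutting** — two horizontal bands (top and bottom of the
   frame) away from the wall.
2. **SRAD filtering** — speckle-reducing anisotropic diffusion
   `dI/dt = div(c(q) grad I)`, where the instantaneous coefficient of
   variation `q` (an edge detector for speckle) drives the diffusivity
   `c(q) = 1 / (1 + (q^2 - q0^2)/(q0^2 (1 + q0^2)))` and the speckle scale
   `q0 = sd/mean` of a 20x20 homogeneous region. A longitudinally weighted
   variant doubles the vessel-axis differences in `q` so detail along the
   vessel is preserved.
3. **Monogenic features** — a zero-DC difference-of-Gaussians bandpass
   followed by the Riesz transform (frequency multipliers `-i u/|w|`,
   `-i v/|w|`) gives local amplitude `A`, phase `phi = atan2(|(h*f)|, f)`,
   and orientation `theta = atan(h_y*f / h_x*f)` in `[0, pi)`. The
   registration feature of the full method is the confidence-weighted
   combination `C = sin^2(phi) * theta`, which keeps the orientation's
   geometric information while suppressing its artifacts where the phase is
   degenerate. Phase and orientation are invariant to affine intensity
   changes (`I -> aI + b`).
4. **Rigid registration** — each band is registered to frame 1 by
   maximizing the overlap-only normalized cross-correlation over
   (shift, rotation): exhaustive FFT-based integer search on a 0.5-degree
   rotation grid, then Nelder-Mead refinement to 0.01 px / 0.01 degrees.
   Upper and lower estimates are averaged, which also cancels the spurious
   band-level translation induced by rotation about the image centre.
5. **Alignment and tracking** — frames are resampled through the inverse
   transform, and a fixed 60x80 px reference block straddling the
   blood/wall interface of frame 1 is block-matched (NCC, Eq. below) in
   every aligned frame:

   `NCC = sum (R - mean R)(F - mean F) / sqrt(sum (R - mean R)^2 sum (F - mean F)^2)`

Method variants differ in the registration feature: intensity (BM),
phase (PM), after SRAD (SBM/SPM), after weighted SRAD (SWBM/SWPM),
orientation (SWOM) and the combined image (SWPOM, the full method).

The package also ships a synthetic B-mode simulator (scatterer phantom,
pulsating two-interface wall, convolutional speckle rendering, preset
disturbances with respiratory drift and probe-jitter glitches) so every
step can be validated against known ground truth, plus the evaluation
statistics (normalized RMSE, regression/correlation, Bland-Altman limits
of agreement).

## Worked example

```r
library(carostab)

# simulate a short study: same phantom rendered with and without a
# preset rigid disturbance
p <- sim_profile("fast")
p$n_frames <- 16L
report <- run_study(p, variants = c("BM", "SWPOM"), seed = 1)
print(report)
```

```
simulation study: profile 'fast', 16 frames, seed 1

Disturbance extraction error vs preset (RMSE in mm / deg):
 method rmse_long rmse_rad rmse_rot nrmse_long nrmse_rad nrmse_rot
 NOSUPP  0.184132 0.130124  0.30944         NA        NA        NA
     BM  0.006331 0.003302  0.05609    0.01383  0.008426   0.05571
  SWPOM  0.019139 0.012592  0.16298    0.04180  0.032129   0.16185
...
```

Reading: the preset disturbance has an RMS amplitude of 0.18 mm
longitudinally (the `NOSUPP` row is the error of estimating "no
disturbance"); registration on intensity (BM) or combined-feature images
(SWPOM) recovers it to a few hundredths of a millimetre. The motion table
(second half of the printout) compares wall tracking after each
suppression variant with the preset wall motion and with tracking on the
disturbance-free rendering: `r` near 1 means suppression restored the
trajectory that would have been measured without any disturbance.

Single steps are exposed directly: `srad_filter()`, `make_feature_image()`,
`register_rigid()`, `estimate_disturbance()`, `align_sequence()`,
`track_sequence()`, `nrmse()`, `bland_altman()`, and the simulator
(`make_phantom()`, `render_bmode()`, `simulate_sequence()`). Sequences are
8-bit multi-page TIFFs with a JSON sidecar (`write_sequence()` /
`read_sequence()`); trajectories are plain CSV. A command-line front end
with the same verbs lives at `inst/scripts/carostab`.

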