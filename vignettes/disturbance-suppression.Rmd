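---
title: "Suppressing probe and breathing disturbances before carotid wall tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing probe and breathing disturbances before carotid wall tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carostab)
```

## The model

A B-mode sequence of the common carotid artery contains two superimposed
motions. The wall itself pulsates: a radial distension of a few tenths of a
millimetre per cardiac cycle plus a longitudinal sliding component. On top
of that, probe handling and breathing move the *entire* frame by up to a
millimetre and a degree of rotation over a respiratory cycle, with
short-lived jitter spikes. Block-matching speckle tracking measures the sum
of the two. `carostab` separates them by a common-mode/differential-mode
argument: tissue bands far above and below the vessel feel only the global
disturbance, so registering those bands between frames estimates it, frames
are resampled through its inverse, and the wall is tracked afterwards.

The processing chain per frame (against frame 1 as the fixed reference) is
subimage cutting, SRAD filtering, monogenic feature extraction, rigid
registration of both bands, component-wise averaging of the two band
transforms, alignment, and NCC block matching. Each stage is exposed as an
ordinary function and each has a method variant that bypasses it, giving
the eight named variants in `variant_table()`.

### SRAD

Speckle-reducing anisotropic diffusion solves
`dI/dt = div(c(q) grad I)` with reflective borders, explicit steps
`I <- I + (dt/4) div(c grad I)`, one-sided neighbour differences, and the
south/east neighbour's diffusivity on the forward fluxes. The instantaneous
coefficient of variation

`q^2 = (0.5 |grad I/I|^2 - (1/16)(lap I/I)^2) / (1 + 0.25 lap I/I)^2`

is the speckle edge detector; the diffusivity
`c(q) = 1/(1 + (q^2 - q0^2)/(q0^2(1 + q0^2)))` compares it with the
speckle scale `q0 = sd/mean` (population variance) of a 20 x 20
homogeneous region, re-estimated every iteration. Defaults `dt = 0.1` and
100 iterations. Numerical choices worth noting:

* `c` is clamped to `[0, 1]`: the printed form exceeds 1 wherever
  `q < q0`, which would amplify rather than diffuse and destabilizes the
  explicit scheme at `dt = 0.1`.
* Images are floored at `1e-6 * max(I)` before the `grad I / I` ratios.
* The longitudinally weighted variant (`w = 2`) doubles the vessel-axis
  (column) first differences and adjusts the Laplacian stencil to
  coefficients 2,2,1,1 with centre -6 — *only inside the edge detector
  q*. Longitudinal variation then registers more strongly, the diffusivity
  drops there, and detail along the vessel survives. An alternative
  reading, doubling the longitudinal flux terms in the divergence itself,
  does the opposite (it smooths the longitudinal axis harder) and is not
  used; this is verified by the ramp-preservation test.
* The homogeneous region follows the tissue through the sequence: by the
  preset offsets in a simulation, or automatically from the centroid shift
  and principal-axis rotation of the thresholded frame.

### Monogenic features

A difference-of-Gaussians bandpass (`sigma2 = sqrt(2) sigma1`, both
discrete kernels normalized to unit sum so the DC gain is exactly zero)
isolates one scale band; the Riesz transform (frequency response
`(-i u/|w|, -i v/|w|)`, zero at DC and at the partnerless Nyquist bins of
even grids) supplies the two quadrature components. From `(f, h_x*f,
h_y*f)`: amplitude `A`, phase `phi in [0, pi]` via the two-argument
arctangent, orientation `theta` folded into `[0, pi)` (orientation is
axial), and confidence `sin^2(phi)`. Near-zero-amplitude pixels are given
confidence 0 instead of an arbitrary phase. The combined registration
image is the product `C = sin^2(phi) * theta` — the most literal scalar
reading of a confidence-weighted orientation; a two-plane axial embedding
`(sin^2 phi cos 2 theta, sin^2 phi sin 2 theta)` that avoids the
`theta ~ 0 ~ pi` wrap is available by flag. Phase, orientation and C are
invariant to `I -> aI + b` (a > 0) because the bandpass removes the offset
and the ratios cancel the scale.

Spectral operators run on a mirror-padded copy of the input and are
cropped back. On the 24-33-row subimage bands this matters: periodic FFT
boundaries would otherwise leak structure across the band edges and anchor
the registration to the frame instead of the tissue.

The default `sigma1` is 10 px for full-size images; the simulation study
uses 2.5 px because its bands are only tens of rows high and the feature
scale has to fit inside them (the passband peak sits near wavelength
50 px at `sigma1 = 10`, near 13 px at 2.5).

### Registration, averaging, alignment

Registration maximizes the overlap-only NCC between the float band and the
rigidly transformed reference band. Stage 1 scans rotations in 0.5-degree
steps; at each angle the best integer translation is found exactly by an
FFT-based masked cross-correlation (every term of the NCC — counts, sums,
sums of squares and products over the overlap — is itself a
cross-correlation of masked planes, so invalid pixels from rotation warps
are handled exactly, not approximately). Stage 2 refines (shift, rotation)
by Nelder-Mead on bilinear-interpolated warps. The similarity metric,
optimizer, pivot and band heights are design choices here (NCC is
consistent with the block-matching metric and deterministic; defaults
±30 px, ±5 degrees, bands 30%).

A rotation by `theta` about the image centre appears inside one band as the
same rotation about the *band* centre plus a translation of roughly
`-theta * dy` where `dy` is the band-to-image-centre offset — opposite in
sign for the two bands. Averaging the upper and lower estimates therefore
cancels this bias exactly for symmetric bands; this is the quantitative
reason the pipeline registers two bands rather than one.

Alignment resamples each frame through the inverse transform (rotation
about the image centre, bilinear, zero fill). Tracking then matches the
fixed frame-1 ROI (60 x 80 px, straddling the blood/wall interface, never
updated) by exhaustive integer NCC within ±20 px; ties break toward the
smallest displacement, then row-major. Subpixel parabolic refinement
exists but is off by default — integer matching is the specified
behaviour, and all study numbers use it. Tracking operates on the aligned
intensity frames; a flag allows tracking feature images instead.

## The synthetic study

`simulate_study()` renders the same phantom twice — with and without the
preset rigid disturbance, with identical per-frame speckle jitter — so the
disturbance is the only difference between the two sequences. What the
generator emulates, and its conditions (chosen once; the `default` profile
is the study of record, `fast` the reduced test profile):

* **Geometry.** 224 x 256 px (default; fast 192 x 256) at 0.05 mm/px.
  Lumen radius 1.0 mm (fast 0.7) centred mid-image; intima / media /
  adventitia bands of 0.15 / 0.25 / 0.45 mm with echo multipliers 1.6 /
  0.5 / 1.8 against tissue 1.0 and lumen 0.05. A 1.45 mm perivascular
  margin moves rigidly with the wall with a 0.3 mm taper to static
  tissue: the 60-row tracking block must sit on a coherently moving patch,
  which constrains the desk-scale geometry (clinical vessels are larger
  relative to the ROI).
* **Speckle.** A persistent population of 52000 (fast 45000) scatterers,
  about 50 per resolution cell, splatted bilinearly and convolved with a
  complex point-spread function (axial wavelength 0.30 mm, envelope sds
  0.12/0.25 mm); the envelope is log-compressed over 50 dB to 8 bits
  against a reference calibrated on frame 1. A homogeneous region of the
  pre-compression envelope has point SNR near the Rayleigh value 1.91.
* **Motion.** Four cardiac cycles over one 3.2 s respiratory cycle,
  200 frames (fast 64). Radial distension 0.25 mm peak (outward from the
  lumen centre), longitudinal 0.35 mm, each pulse `sin^2(pi s^p)`-shaped
  so it rises faster than it falls and returns to baseline.
* **Disturbance.** Smooth two-harmonic respiratory drift normalized to
  peaks of (0.40 mm, 0.25 mm, 0.5 deg), plus Poisson glitches (rate
  2.5/s, Gaussian sd 20 ms, peak (0.25 mm, 0.15 mm, 0.4 deg)) emulating
  probe jitter; rotation is applied about the image centre. Frame 1 is
  exactly zero.
* **Decorrelation.** Scatterer persistence between frames is genuinely
  uncertain in vivo; we jitter elevational positions by 0.15 mm sd per
  frame against a 0.35 mm elevational beam sd, which decorrelates the
  speckle texture substantially between distant frames while the
  underlying echogenicity stays put. A per-frame smooth gain field
  (1.5 dB sd, 40 px correlation) adds the brightness/contrast
  nonstationarity of hand-held acquisition. Both affect the disturbed and
  the clean rendering identically.

What the generator does **not** model: acoustic wave propagation and
beamforming (no Field II), depth attenuation and TGC, out-of-plane vessel
curvature, non-rigid tissue deformation, and clinical artifacts such as
shadowing or reverberation. Consequences for interpretation: intensity
registration (BM) faces only the nuisances listed above, all of which are
mild compared with a real scanner, so BM performs close to its theoretical
optimum here and the relative advantage of phase/orientation features seen
on clinical data should *not* be expected to reproduce quantitatively.
Passing the study tests shows the pipeline recovers known rigid
disturbances and restores tracking on data with realistic speckle
statistics — not that any variant ordering on clinical images would be
identical.

The evaluation statistics follow standard definitions: RMSE and NRMSE
(normalized by the reference peak-to-peak range; the normalizer is
selectable because published tables rarely state it), ordinary
least-squares regression with Pearson R, and Bland-Altman mean difference
with `mean ± 1.96 SD` limits (sample SD). The agreement reference is the
wall motion tracked on the disturbance-free rendering, not the preset
trajectory: the question answered is "does suppression leave the motion
measurement unchanged", and the disturbance-free measurement already
carries the tracking quantization.

## Degenerate inputs and tie-breaks

* Zero-variance blocks or feature images raise errors rather than return
  arbitrary matches.
* NCC maps break ties toward the smallest displacement, then row-major,
  so results are deterministic.
* Shifted homogeneous regions that would leave the image are clipped with
  a warning.
* Registration refinement only replaces the grid optimum when it scores at
  least as well; exact integer matches (score 1) skip refinement entirely.

## Problem sizes and determinism

The shipped test suite runs the fast profile (64 frames, 192 x 256) for
the end-to-end ordering checks and the default profile (200 frames,
224 x 256) once for the agreement figure; module tests use small rendered
fixtures of about 100 px per side. All randomness flows through explicit
integer seeds (`make_disturbance()` and `simulate_sequence()` require
one), and a study rerun with the same seed is bit-identical.

## Known limitations

* The rigid-disturbance model cannot represent the non-rigid component of
  breathing-induced tissue motion; on clinical data the residual after
  alignment contains it.
* Integer block matching quantizes trajectories to one pixel (0.05 mm);
  subpixel refinement is available but changes the estimator.
* The combined image inherits the `theta` wrap at 0/pi for near-vertical
  structures; the embedding mode avoids it at the cost of a two-plane
  feature.
* Very thin subimage bands limit the usable monogenic scale; below about
  six times `sigma2` the bandpass is refused.
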