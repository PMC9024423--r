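---
title: "Stereo video vibrometry: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo video vibrometry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stereovibro)
```

## The measurement problem

Vibrations carry much of the information in a spiderweb: prey, intruders
and potential mates all announce themselves through the silk. The
conventional instrument, a laser Doppler vibrometer, measures one point
along one axis and demands painstaking alignment against a strand or a
reflective target. `stereovibro` implements the alternative: film the web
with two synchronized high-speed cameras, extract sub-pixel motion of any
textured image region from each video by phase-based vibrometry, and fuse
the two 2D traces through a calibrated pinhole stereo model into a 3D
displacement trace for that region — no feature tracking, no contact, and
any number of sample points per recording.

## Phase-based motion extraction

A grayscale frame is decomposed with an oriented quadrature filter pair
(the two-orientation restriction of a complex steerable pyramid). With
even tap vector $e[n]$ and odd $o[n]$, the complex response at pixel $x$
is

$$ c(x) = \sum_n (e[n] + i\,o[n])\, I(x+n), $$

whose magnitude is local texture amplitude and whose argument is local
phase. When texture translates by $\delta$ pixels along the filter
orientation, the phase shifts by $2\pi f_c\,\delta$, where $f_c$ is the
filter's centre frequency — the image analogue of the Fourier shift
theorem. The package therefore converts per-frame wrapped phase
differences into pixel velocities by

$$ \delta = \frac{\Delta\varphi}{2\pi f_c} \cdot 2^{\ell}, $$

with $2^{\ell}$ rescaling level-$\ell$ pyramid coordinates to full-frame
pixels. The taps are a 9-point Gabor-style pair at $f_c = 0.25$
cycles/pixel with a Gaussian envelope of $\sigma = 2$ px; the even
filter's residual DC is removed by subtracting a scaled envelope and both
filters are normalized to unit response magnitude at $f_c$, so the phase
of a centre-frequency grating is tracked exactly (the package's tests
verify the shift theorem to well below 1%). Exact tap values are not
load-bearing: every property the pipeline relies on (zero DC, quadrature
phase, shift-theorem response) is asserted by tests rather than assumed
from a tabulated filter.

Phase is meaningless where there is no texture, so each phase-difference
map is smoothed with an amplitude-weighted blur,
$G(a^2\varphi)/G(a^2)$ with $G$ a Gaussian of scale `sigma` (default 2 px),
letting textureless pixels inherit phase from textured neighbours. The
per-pixel velocity series are then band-passed with a zero-phase
(forward–backward) Butterworth filter, 5–100 Hz by default at order 2 per
edge, integrated by cumulative sum (frame 0 anchored at zero), and
averaged over the crop and across pyramid levels with $a^2$ weights.

Two ordering choices deserve note. Filtering before spatial averaging
follows the described processing order; because the spatial weights are
time-invariant and every operator is linear, `filter_per_pixel = FALSE`
(average first, then filter) produces identical traces at a fraction of
the cost, and the test suite asserts that equivalence. Zero-phase
filtering matters because event *timing* is scientific output (wave-speed
delays); a causal filter would bias arrival times by its group delay.

## Stereo model and calibration

A camera is a focal point, a pan rotation about world Y followed by a
tilt about the panned camera X, and intrinsics written as focal distance
(mm) over pixel pitch (mm/px). World frame: X right on the cage front
face, Y up, Z toward the cameras, millimetres everywhere. Image
coordinates are 0-based, u right, v down; v-down maps to world −Y as a
single documented sign flip. These conventions (rotation order included)
are declared, not physically forced — they match a camera on a pan head
carrying a tilt cradle and are used consistently by calibration,
rendering and composition.

Each camera's unknowns reduce to pan, tilt and focal distance: the (x, z)
position is tape-measured, and camera height is eliminated by an origin
convention — any world point at the cameras' height projects exactly onto
one image row (the horizontal epipolar row, the image of the XZ plane
through the focal points), so placing the world origin on that row fixes
camera y = 0. `fit_epipolar_row()` recovers the row as the least-squares
common intersection of image lines whose world counterparts are parallel
to the XZ plane. The remaining three parameters come from
`calibrate_camera()`: an exhaustive grid search minimizing summed squared
reconstruction error (mm²) of known points and known pairwise distances,
all evaluated by intersecting pixel rays with the cage front plane.
Defaults: ±5° in pan and tilt at 41 nodes, ±10% focal at 21 nodes, two
refinement rounds that re-centre on the best node and shrink widths
five-fold — final angular resolution 0.01°, finer than a single dense
pass at a small fraction of its cost, which is why the package prefers
the coarse-to-fine ladder over one very fine grid. Ties break toward the
search centre for stability under symmetric residual landscapes, a
boundary minimum raises a warning to re-centre the initial guess, and
refinement can only improve the best residual (asserted by tests).

For composition, the frame-0 pixel of the analyzed object in each video
is augmented per frame by that video's cumulative displacement estimate
(not frame-to-frame ray chaining), sub-pixel coordinates feed the
continuous pinhole model directly, and the two rays are triangulated as
the midpoint of their common perpendicular — the unique point minimizing
the summed squared distance to both lines. The closest-approach distance
(`gap`) is recorded per frame as a triangulation quality channel; exactly
parallel rays are an error, never an infinity. Pixels that drift outside
the sensor are flagged, not dropped, since the pinhole model extends
continuously beyond the image bounds.

## Signal analytics

* `windowed_power()`: sliding mean of squared 3D displacement magnitude;
  default window 0.2 s, long enough to envelope the 5–100 Hz band at
  1000 fps while keeping event onsets sharp.
* `detect_events()`: maximal runs of power above `threshold_factor`
  (default 5) times the median power, merged when closer than
  `min_separation`; counts are non-increasing in the threshold.
* `first_peak_time()`: the first local maximum of |displacement| in an
  event window whose prominence exceeds a threshold (default 25% of the
  event peak), refined below the frame interval by parabolic
  interpolation over three samples. "First, not largest" is deliberate:
  wave arrival is carried by the leading peak.
* `wave_speed()`: 3D distance between two measurement points divided by
  the first-peak delay, per event; the summary is the arithmetic mean of
  per-event speeds, and acausal (non-positive-delay) events are excluded
  and reported. Delays can be measured on axis-projected or magnitude
  signals; both paths are exercised in tests, and the choice is the
  caller's, recorded by which series they pass.

The configuration validator enforces the sampling limits: an analysis
band reaching the Nyquist frequency (half the framerate) is a hard
error, and anything above a quarter of the framerate draws a warning —
at 1000 fps the recommended ceiling is 250 Hz.

## What the synthetic scenes emulate — and what they do not

`render_stereo()` rasterizes a planar, rigid, textured patch undergoing
commanded 3D motion through each pinhole camera: rays are cast per
supersampled sub-pixel, intersected with the moving patch plane,
bilinearly sampled from the texture, box-averaged down, and only then
given zero-mean Gaussian sensor noise. Commanded sub-pixel motion thus
produces exactly the smooth intensity modulation phase vibrometry reads,
while the generator shares no code path with the filters it validates.
Ground truth (3D positions, per-camera image displacement, calibration
layout) is recorded exactly, and render/projection consistency is
asserted at every render. The default rig mirrors the validation
experiment: 1000 fps, 800 × 600 px, cameras 1 m out and ±15° off the Z
axis (about 0.5 mm/px at the cage), 0.5% sensor noise, band-limited
noise texture whose spatial band (0.10–0.35 cycles/texel) spans the
analysis filter's passband, and decaying-sinusoid "web jerk" events with
20–30 mm peak amplitude directed mostly along Y. Rendered validation
clips are 0.3–0.6 s (300–600 frames) and the packaged scene builder
emits 3 s containing all three events — long enough for every property
under test at a tractable rendering cost.

The renderer deliberately omits what real recordings contain: non-rigid
web deformation, occlusion by silk strands or the spiders, lighting
flicker, lens distortion, rolling shutter, defocus variation across
depth, and non-Gaussian sensor artifacts. Passing tests therefore show
the *pipeline* is correct and meets its noise and accuracy budgets under
ideal imaging; they do not certify accuracy on arbitrary footage, where
texture quality and calibration error dominate.

## Numerical choices and degenerate inputs

* Phase differences are computed as `Arg(curr * Conj(prev))`, inherently
  wrapped to (−π, π]; per-frame texture shifts must stay below half the
  filter wavelength (2 px at level 0, doubling per level). Faster motion
  belongs to coarser levels — one reason the level-fusion weights favour
  whatever level carries amplitude.
* The amplitude-weighted blur guards its denominator with a floor of
  10⁻¹² of its maximum; an identically zero amplitude map returns zeros
  with a flagged warning, and a fully textureless crop yields a flagged
  zero trace rather than an error.
* Down-sampling is a binomial half-band blur followed by 2× decimation,
  floor on odd dimensions; convolution boundaries use replicate padding
  (small crops make circular FFT boundaries unacceptable, which is why
  the blur is a direct separable convolution rather than a spectral one).
* The renderer refuses commanded per-frame steps below a quarter of the
  rasterization quantum `1/(4·supersample)` px, directing the caller to
  raise `supersample` instead of silently rendering under-resolved
  motion.
* The Butterworth band edges ring with a ~30-frame time constant at
  1000 fps; tests and the acceptance script measure steady-state
  behaviour away from series ends.
* Known amplitude bias: converting phase by a fixed $f_c$ assumes the
  local texture frequency equals $f_c$; over a band-limited texture the
  amplitude-weighted mean local frequency sits slightly below it, giving
  a few-percent underestimate of commanded amplitude at level 0 —
  visible in the validation numbers and well inside the accepted 10%
  band. Per-pixel local-frequency normalization would remove it at the
  cost of a noisier estimate, and is left out by design.

## Known limitations

Two orientations only (horizontal/vertical), matching the two-axis
information a camera pair actually adds; no lens-distortion model, so
calibration residuals absorb real-lens distortion; depth-axis noise
grows as vergence shrinks (about 1/tan of the half-angle — at ±15° the
synthetic scenes show several-fold depth-to-lateral noise ratios, the
binocular-vision effect familiar from the physical experiment); and
per-crop averaging reports one trace per region, not a dense field.
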