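# stereovibro

Three-dimensional, non-contact vibration measurement from pairs of
synchronized high-speed videos — built for spiderweb bioacoustics, usable
on any scene where vibration shows up as sub-pixel texture motion.

Spiderwebs hum with information: prey impacts, courtship drumming, and
the large "web jerk" displays western black widows (*Latrodectus
hesperus*) aim at rivals. The standard instrument, a laser Doppler
vibrometer, reads one point along one axis and must be aligned against a
strand or a target suspended in the web. `stereovibro` instead films the
web with two high-speed cameras and recovers, for any textured crop of
the video, a full 3D displacement trace — from the web, a paper target,
or the body of the spider itself.

## Method

Two ingredients, both implemented and tested here:

**Phase-based video vibrometry.** Each cropped frame is filtered with an
oriented quadrature (even/odd) filter pair across a two-level pyramid,
giving a complex response whose argument is local phase. Texture
translation by δ pixels shifts that phase by 2π·f_c·δ (the image-domain
shift theorem), so per-frame phase differences — amplitude-weighted,
spatially denoised, band-passed 5–100 Hz with a zero-phase Butterworth
filter, and integrated — yield crop-averaged displacement traces du(t),
dv(t) with noise floors around a hundredth of a pixel, no feature
tracking required.

**Calibrated stereo composition.** Each camera is a pinhole model (pan,
tilt, focal distance; position tape-measured; height eliminated by
anchoring the world origin on the horizontal epipolar row). The unknown
parameters are fitted by exhaustive grid search minimizing squared
reconstruction error against known calibration points, to sub-millimetre
residuals. Per frame, the frame-0 pixel augmented by (du, dv) is cast as
a ray from each camera; the midpoint of the rays' common perpendicular is
the 3D position, and its closest-approach distance is a per-frame quality
measure.

On top of the 3D traces: projection onto an arbitrary measurement axis
(e.g. a laser's line of sight), sliding-window signal power, event
detection, and wave-speed estimation from first-peak arrival delays
between two points of known 3D separation.

A synthetic scene renderer (`render_stereo()`, `render_calibration()`)
produces ground-truth stereo clips of textured patches under commanded
motion — the whole pipeline is validated end to end without any recorded
footage.

## Worked example

Render a stereo scene of a patch oscillating 5 mm at 15 Hz along world Y
(cameras ±15° off the Z axis, 1000 fps), then recover the motion:

```r
library(stereovibro)

cams <- make_camera_pair()                      # ±15°, 1 m from the cage
motion <- sinusoid_motion(framerate = 1000, duration = 0.5,
                          amplitude = c(0, 5, 0), freq = 15)
scene <- scene_spec(cams, motion, framerate = 1000,
                    texture = make_texture(256, seed = 7), texel_mm = 0.5,
                    noise_sigma = 0.005, supersample = 4, seed = 11)
r <- render_stereo(scene)

tr_a <- motion_trace(r$clip_a, levels = 2, band = c(5, 100))
tr_b <- motion_trace(r$clip_b, levels = 2, band = c(5, 100))
tr3 <- stereo_trace(cams[[1]], tr_a, r$truth$px0_a,
                    cams[[2]], tr_b, r$truth$px0_b)
```

which prints, via the summaries in the example script:

```
initial position: (0.00, 0.00, -150.00) mm
recovered Y amplitude: 5.06 mm (commanded 5.00)
median triangulation gap: 0.0091 mm
peak power: 11.8 mm^2 at t = 0.317 s
```

The triangulated rest position lands on the commanded patch centre, the
recovered amplitude is within about 1% of the command, and the
millimetre-scale `gap` confirms the two rays nearly intersect. Feeding
three per-event speeds into the wave-speed summary:

```r
wave_speed_estimate(data.frame(speed = c(24.2, 17.7, 16.6)))
#> mean speed: 19.5 m/s over 3 event(s)
```

A thin subcommand CLI (`simulate`, `calibrate`, `vibrate`, `stereo`,
`analyze`, `run`) over these functions lives at
`inst/cli/stereovibro.R`; configuration comes from YAML/JSON
(`read_config()`), with flags taking precedence.

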