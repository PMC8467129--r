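# sfdi

Spatial frequency domain imaging (SFDI) measures the optical properties
of turbid samples — the absorption coefficient μa and the reduced
scattering coefficient μs′, both in mm⁻¹ — over a wide field, without
contact, by projecting sinusoidal fringe patterns at several spatial
frequencies and imaging the diffuse reflection. A scattering medium
blurs high-frequency fringes more than low-frequency ones, so the
frequency-dependent modulation transfer Rd(fx) encodes both
coefficients. This package implements the full computational pipeline
for a projector–camera SFDI bench, aimed at food-quality and tissue
applications such as grading fruit surface damage (bruises, scratches,
abrasions) that conventional planar-light imaging struggles to
distinguish.

The pipeline stages, each exposed as package functions:

* **Pattern generation and keystone pre-correction** — pinhole
  projector geometry with pitch/yaw rotation, inverse-perspective
  correction of the trapezoidal distortion, a fringe-uniformity error
  metric, and an angle sweep that locates the true mounting angles.
* **Fringe frequency calibration** — sub-pixel period estimation from
  averaged reflectance profiles, checkerboard pixel-to-mm scaling, and
  a two-step update of the generation-period ratio that removes
  systematic period bias in one iteration.
* **Three-phase demodulation** — per-pixel AC envelope
  `Mac = (2/3)·sqrt((I1−I2)² + (I2−I3)² + (I1−I3)²)` and whiteboard
  calibration `Rd = (Mac/Mac,ref)·Rd,ref`; the planar (fx = 0) channel
  is calibrated as a direct intensity ratio.
* **Diffusion-model inversion** — bounded nonlinear least squares of
  `Rd(fx) = 3Aμs′/μtr / ((μeff′/μtr + 1)(μeff′/μtr + 3A))` per pixel or
  superpixel, giving μa and μs′ maps; linear phantom-based correction
  factors.
* **Phantom references** — Beer–Lambert absorption and Mie-theory
  reduced scattering for the 18-phantom ink/TiO₂ calibration series.
* **Acquisition simulator** — seeded, bit-reproducible rendering of
  sample and whiteboard phase stacks from ground-truth coefficient
  maps, plus labelled fruit-damage scenes.
* **Damage classification** — ROI feature extraction and linear
  discriminant analysis with stratified 5-fold cross-validation,
  comparing the SFDI feature set (μa, μs′) against planar-light
  reflectance.

## Worked example

Calibrate the fringe scale from a checkerboard measurement, then
simulate a noisy acquisition of a homogeneous sample and invert it:

```r
library(sfdi)

# fringe scale: captured period 158.2 px, 5 mm checkerboard cells
# imaged at 78.3 px per cell, generation period 40 px
tr  <- camera_to_actual_period(tc = 158.2, xr = 5, xc_mean = 78.3)
rrp <- period_ratio(tp = 40, tr = tr)
cat(sprintf("actual fringe period: %.1f mm\nperiod ratio: %.0f pixel/m\n",
            tr, rrp * 1000))
#> actual fringe period: 10.1 mm
#> period ratio: 3960 pixel/m

# simulate a sample with mua = 0.03, musp = 1.4 mm^-1 at 1% camera noise
fx <- c(0, 0.042, 0.084, 0.14)
scene  <- scene_spec(matrix(0.03, 12, 12), matrix(1.4, 12, 12), fx,
                     noise_sigma = 0.01, seed = 42)
stacks <- simulate_stack(scene)
demod  <- demodulate_acquisition(stacks$sample, stacks$reference, fx)
rd     <- vapply(demod$rd, median, numeric(1))
round(rd, 4)
#> [1] 0.5254 0.4667 0.3634 0.2574

fit <- invert_point(fx, rd)
cat(sprintf("recovered mua  = %.4f mm^-1 (truth 0.0300)\n", fit$mua))
cat(sprintf("recovered musp = %.3f mm^-1 (truth 1.400)\n", fit$musp))
#> recovered mua  = 0.0301 mm^-1 (truth 0.0300)
#> recovered musp = 1.408 mm^-1 (truth 1.400)
```

The reflectance falls from 0.53 at DC to 0.26 at 0.14 mm⁻¹ — that decay
is the signal the inversion reads: its level sets the scattering, its
slope the absorption. Both coefficients come back within ~1 % here
because the ROI median suppresses the per-pixel noise before the fit.

See `vignettes/sfdi-methods.Rmd` for the model, its assumptions, every
tunable default, and what the simulator does and does not emulate.

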