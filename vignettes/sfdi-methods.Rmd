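---
title: "Methods: SFDI calibration, inversion and the acquisition simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SFDI calibration, inversion and the acquisition simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdi)
```

# The measurement model

Spatial frequency domain imaging (SFDI) projects sinusoidal fringe
patterns of several spatial frequencies $f_x$ onto a turbid sample and
images the diffusely reflected light. A scattering-dominated medium acts
as a spatial low-pass filter: the modulation transfer $R_d(f_x)$ falls
with frequency at a rate governed by the absorption coefficient
$\mu_a$ and the reduced scattering coefficient $\mu_s'$ (both mm$^{-1}$).
Under the diffusion approximation,

$$R_d(f_x) = \frac{3A\,\mu_s'/\mu_{tr}}
  {\left(\mu_{eff}'/\mu_{tr} + 1\right)\left(\mu_{eff}'/\mu_{tr} + 3A\right)},$$

with $\mu_{tr} = \mu_a + \mu_s'$,
$\mu_{eff} = \sqrt{3\mu_a\mu_{tr}}$,
$\mu_{eff}' = \sqrt{\mu_{eff}^2 + (2\pi f_x)^2}$, and the boundary
constant $A = (1 - R_{eff}) / (2(1 + R_{eff}))$ where
$R_{eff} = 0.0636\,n + 0.668 + 0.71/n - 1.44/n^2$ captures internal
reflection at the air--medium interface.

Two numerical notes on these formulae as implemented:

* **The $R_{eff}$ linear coefficient defaults to 0.0636**, the standard
  diffusion-theory value. A coefficient ten times larger produces
  $R_{eff} > 1$ (and a negative $A$) for every realistic refractive
  index, which is unphysical; `effective_reflection_coefficient()`
  therefore validates $R_{eff} \in (0, 1)$ and raises an error outside
  it. The coefficient is an argument for users who want a different
  boundary polynomial.
* **The refractive index defaults to $n = 1.35$** for both aqueous
  phantoms and fruit tissue — a common value for water-rich soft
  biological media. It is configurable per run; all results that depend
  on it are reported with the value used.

At $f_x = 0$ and $\mu_a = 0$ the model collapses analytically to
$R_d = 1$. $R_d$ is strictly decreasing in $f_x$ always. Monotonicity in
$\mu_a$ is a *diffusion-regime* property: it holds when $\mu_s'$
dominates both $\mu_a$ and $2\pi f_x$ (the package asserts it on the
grid $\mu_a \in [0.001, 0.2]$, $\mu_s' \in [0.8, 3]$ mm$^{-1}$,
$f_x \in [0, 0.2]$ mm$^{-1}$). Outside that regime — low scattering at
high frequency — the diffusion approximation itself is unreliable, and
the model's ordering in $\mu_a$ can invert; this is a known limitation
of the forward model, not of the implementation.

# Demodulation and whiteboard calibration

Each modulated frequency is acquired three times with phase shifts of
$0, 2\pi/3, 4\pi/3$. The AC envelope is

$$M_{ac} = \tfrac{2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_1-I_3)^2}.$$

With the $2/3$ coefficient this equals $\sqrt{2}\times$ the true
sinusoid amplitude (the pairwise squared differences of a three-phase
sinusoid of amplitude $a$ sum to $4.5a^2$; the more common convention
uses $\sqrt{2}/3$). The package implements the $2/3$ form deliberately:
the constant cancels exactly in the whiteboard ratio

$$R_d(x, f_x) = \frac{M_{ac}(x,f_x)}{M_{ac,ref}(x,f_x)}\,R_{d,ref},$$

so calibrated reflectance is unaffected. Code using `three_phase_amplitude()`
in isolation must divide by $\sqrt{2}$ to obtain the physical amplitude.
The whiteboard reflectance defaults to $R_{d,ref} = 0.99$.

The planar channel ($f_x = 0$) cannot be demodulated — three identical
phases give a null envelope — so it is calibrated directly as the
intensity ratio to the full-white reference image. Reference pixels
below $10^{-6}$ of the image maximum (a configurable floor) are masked
`NA` rather than divided through; masks propagate to the coefficient
maps. How the original bench handled saturated or dark pixels is not
documented; masking is this package's choice.

# Inversion

`invert_point()` fits the forward model to a calibrated reflectance
spectrum by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), with $\mu_a \in [10^{-6}, 5]$,
$\mu_s' \in [10^{-3}, 10]$ mm$^{-1}$. The fit starts at
$(0.01, 1.0)$ mm$^{-1}$; if the residual suggests a poor optimum it
retries from $(0.1, 0.5)$ and keeps the better of the two. All
available frequencies enter the fit, including the planar channel.
Non-convergence and ill-posed inputs (fewer than two distinct
frequencies) are *flagged* in the returned diagnostics, never thrown,
so per-pixel map inversion continues past bad pixels. A brute-force
$200\times200$ grid search over the bounds serves as an independent
oracle in the tests: the optimiser's residual must not exceed the best
grid residual.

At low absorption the objective valley is shallow along $\mu_a$ — with
four frequencies and 1 % reflectance noise, relative errors on
$\mu_a$ are several times larger than on $\mu_s'$. This conditioning is
inherent to the measurement, and is why the bench protocol uses many
frequencies and a region-of-interest average before inversion.

Systematic linear errors (e.g. scatterer precipitation between phantom
preparation and measurement) are corrected by the mean reference-to-
measured ratio $k = \frac{1}{m}\sum_i \mathrm{ref}_i/\mathrm{meas}_i$,
applied multiplicatively. The two-set phantom design calibrates $k$ for
$\mu_a$ on the absorber-series set and tests it on the scatterer-series
set, and vice versa.

# Projector geometry and keystone correction

The projector is modelled as a pinhole with intrinsics
$(f_u, f_v, c_u, c_v)$ at height $h$ above the target plane, rotated by
pitch $\alpha$ about the horizontal axis and yaw $\beta$ about the
vertical; roll is fixed at zero because the mount constrains it. The
pixel-to-plane map casts the ray through a pixel, rotates it by
$R_x(\alpha)R_y(\beta)$, and intersects the plane; the plane-to-pixel
map is its exact algebraic inverse, and the round trip is enforced to
$10^{-9}$ px in tests. The default geometry is a calibrated bench
instance ($f_u = 2116.8$, $f_v = 2122.4$, $c_u = 670.4$,
$c_v = -186.8$ px, $h = 527$ mm, native $1280\times800$).

Keystone pre-correction inverts the perspective distortion: each
projector pixel is mapped to its landing point on the plane and
assigned the value of the ideal plane-referenced sinusoid there.
Because the ideal pattern is analytic, the package evaluates the
cosine at the exact warped coordinate instead of bilinearly resampling
a rasterised pattern — the resampling step is exact, with zero
interpolation error; bilinear interpolation would only be needed for
non-analytic pattern images. The same analytic composition drives the
projection simulator, which renders what a downward-looking camera sees
when a pattern pre-corrected for *assumed* angles is projected through
the *true* geometry.

The fringe-uniformity error $e_p$ is the mean over image columns of the
per-column standard deviation after min–max normalisation of the
analysed region to $[0,1]$ (fringes run along columns, so a perfectly
corrected image is column-constant and $e_p = 0$). Two conventions
were left open by the metric's verbal definition and are settled here:
normalisation is min–max over the analysed region, and the standard
deviation is the sample ($n-1$) form — R's `sd()` — with the population
form available via an argument. `angle_sweep()` minimises $e_p$ over a
candidate grid (default pitch 12–22° step 1°, yaw 0–1° step 0.1°),
breaking ties toward the lowest pitch then lowest yaw with a warning,
since a flat surface means there is no distortion to correct.

# Fringe frequency calibration

The realised fringe period on the sample plane is measured from a
1-D profile averaged along the fringes: local minima are detected on a
lightly smoothed copy (moving average, half-width 2 samples) and
refined to sub-pixel precision by a parabola through each minimum's
three raw samples; the period is the mean minima spacing. The
checkerboard scale $X_r / X_{c,mean}$ (physical cell length over mean
imaged cell length) converts camera pixels to millimetres:
$T_r = T_c X_r / X_{c,mean}$, and the period ratio $r_{rp} = T_p / T_r$
(projector pixels per mm) converts a required plane period into a
generation period $T_p = r_{rp} T_{re}$.

Generated periods are synthesised at 0.1 px resolution rather than
integer-rounded: integer rounding alone introduces period errors of the
same order the calibration exists to remove (e.g. a 28.3 px target
rounded to 28 px is a 1 % error).

The two-step procedure first uses one global ratio $r_{rp}(0)$ for all
targets and measures the realised periods (step 1), then updates the
ratio per frequency from those measurements, $r_{rp}(k) = T_p/T_v$, and
regenerates (step 2). A frequency-independent multiplicative bias is
eliminated exactly by one update; the simulator-based tests drive a 2 %
bias below 0.1 % this way. A target is measurable only if at least
`min_periods = 2.2` complete fringes fit the field of view — two minima
are needed for a spacing, plus margin so detection succeeds at any
fringe phase. Under the bench's 150 mm field this admits nine of the
fifteen non-planar protocol frequencies; the ratios of the remaining
long-period targets are extrapolated linearly in frequency and flagged,
since no principled measurement exists for them.

# Phantom reference values

Reference absorption uses the Beer–Lambert law on collimated
transmittance, $\mu_a = -\ln(T)/d$. Reference reduced scattering uses
Mie theory for a dilute monodisperse sphere suspension:
$\mu_s' = Q_{sca}\frac{\pi d^2}{4} N (1 - g)$ with number density
$N = 6\,vf/(\pi d^3)$, exactly linear in the volume fraction $vf$ in
the independent-scattering regime (all phantom fractions are
$\le 0.2\,\%$). The Mie series is computed with the
logarithmic-derivative downward recurrence and Wiscombe's truncation
$n_{max} = x + 4x^{1/3} + 2$; an independent implementation via
half-integer-order Bessel functions cross-checks it to machine
precision in the tests.

The 18-phantom series (absorber series #1–#9: TiO$_2$ fixed at 0.1 %,
ink 0.004–0.02 % step 0.002 %; scatterer series #10–#18: ink fixed at
0.006 %, TiO$_2$ 0.04–0.2 % step 0.02 %) is packaged as
`phantom_series()`. The TiO$_2$ particle diameter (500 nm), particle
index (2.49) and the ink extinction spectrum
(`extdata/ink_extinction_synthetic.csv`) are **synthetic fixtures** —
spectrally plausible stand-ins for materials whose optical constants
were never published — so reference values are reproducible in
*structure* (exact linearity, positivity across the six bands
460–675 nm) but not traceable in magnitude.

# The acquisition simulator

`simulate_stack()` renders the forward model into camera intensity
stacks, $I_k = G\,[0.5 + 0.5\,R_d(x,f_x)\cos(2\pi f_x x + 2\pi k/3)]$
plus additive Gaussian noise of standard deviation
`noise_sigma` $\times G$, with the whiteboard rendered at
$R_d = R_{d,ref}$. The spatial scale defaults to 400 px per 26 mm, the
bench ROI scale. All randomness flows through one seeded generator
(restoring the caller's RNG state), so a scene specification renders
bit-identical stacks.

The illumination model is a pure AC/DC sinusoid: no projector
modulation transfer function, vignetting, gamma nonlinearity, specular
reflection or sample curvature. This matches the pipeline's own
assumption that whiteboard normalisation removes the system response —
which is exactly why passing the end-to-end recovery tests demonstrates
the *software chain* is self-consistent, not that a physical instrument
would achieve the same accuracy. Real acquisitions add the above
effects plus inter-frequency registration error, and the paper-style
phantom correction step exists precisely because real systems are not
ideal.

## Damage scenes

`make_damage_scene()` builds ground-truth maps for four surface
classes. Damaged tissue absorbs more and scatters less than sound
tissue. The class geometries follow the damage protocol: a bruise is a
disc spanning most of the 26 mm analysis field (the impact ball is
20 mm); scratches are a few thin strokes crossing the field; abrasion
is a broad speckled patch. The effect sizes are synthetic stand-ins —
no quantitative lesion contrast was ever published — chosen once to
reproduce the *statistical structure* the study reports rather than any
printed number:

* bruise: $+15\,\%\ \mu_a$, $-20\,\%\ \mu_s'$ over the disc;
* scratch: $+22\,\%$, $-30\,\%$ over a smaller footprint, so the
  *region-mean* contrast of bruise and scratch nearly coincide — they
  are both minor damage, and their mutual confusion under a mean-value
  feature is a deliberate property of the generator, mirroring why the
  three-class regrouping exists;
* abrasion: $+40\,\%$, $-20\,\%$ over the largest footprint — the
  serious class, displaced from the minor classes along a *different
  direction* in $(\mu_a, \mu_s')$ than normal-to-minor.

That non-collinearity matters: if every class moved along one common
direction, a single planar-reflectance feature would carry the same
information as the two-coefficient feature set and structured
illumination would buy nothing. Separability between damage *types*
rides substantially on the scattering coefficient, consistent with the
physical picture that skin-removal damage changes microstructure
(scattering) while browning changes pigment absorption. Background
levels default to $\mu_a = 0.025$, $\mu_s' = 1.3$ mm$^{-1}$
(green-band pear flesh scale) with 2 % inter-fruit jitter — a single
purchased batch at equal ripeness — 2 % pixel texture, and 5 % jitter
on the effect sizes.

# Classification

Features are the ROI means of the inverted $\mu_a$ and $\mu_s'$ maps
(full-SFDI set) or of the calibrated planar reflectance (planar set —
a single DC measurement cannot separate the two coefficients, so the
raw reflectance *is* the planar feature). The bench ROI protocol
(400×400 px crop, 2×2 binning to 200×200, then averaging) is
implemented literally; since the mean is invariant to block averaging,
binning affects only processing cost. Classification is linear
discriminant analysis (`MASS::lda`) under stratified 5-fold
cross-validation with seeded fold assignment. The three-class scheme
merges bruised and scratched into "minor damage" (their mean optical
properties are close by construction), keeps normal, and maps abraded
to "serious".

# Problem sizes and numerical choices in the shipped tests

Simulated checks use deliberately small instances chosen to exercise
every code path at interactive speed: 12×12 px homogeneous scenes at
four frequencies for recovery (50 random property draws in
$[0.005, 0.5] \times [0.3, 3]$ mm$^{-1}$), 32×32 px damage scenes with
4×4 superpixel inversion and 20 scenes per class for cohorts, a
120×200 px projector frame with a 48×48 px simulated camera for the
121-point angle sweep, and 1500-sample fringe profiles for period
estimation. Noiseless end-to-end recovery is exact to well below
0.1 %; at 1 % camera noise the median recovery error stays below 5 %
because the ROI median over pixels suppresses per-pixel noise before
inversion, as in the bench protocol.

# Known limitations

* The diffusion approximation degrades for $\mu_s' \lesssim \mu_a$ or
  $\mu_s' \lesssim 2\pi f_x$; no transport-order correction or
  Monte-Carlo lookup table is provided.
* $\mu_a$ is weakly constrained at low absorption; expect asymmetric
  error between the two coefficients at realistic noise.
* Phantom reference magnitudes rest on synthetic material constants
  (see above) and are not traceable.
* The simulator omits instrument non-idealities (MTF, gamma,
  vignetting, curvature), so simulated accuracies bound software
  correctness only.
* Pattern correction handles pitch and yaw; roll is assumed
  mechanically constrained to zero.
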