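---
title: "Quantifying circular dorsal ruffle wave dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circular dorsal ruffle wave dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the measurement problem

Circular dorsal ruffles (CDRs) are ring-shaped actin waves on the dorsal
surface of adherent cells, most prominently fibroblasts. In
phase-contrast time-lapse microscopy the wavefront — the region of
maximal actin density — appears as an *intensity minimum*: a dark,
roughly 5 µm wide closed front on a bright background. CDRs behave like
waves in an active (excitable) medium: they initiate from points, expand,
reverse, and close back; they annihilate on head-on collision (notably
*before* contact, leaving a finite terminal gap); on cells forced into a
disk shape they orbit the nucleus at constant speed and re-fire
periodically; occasionally they rotate as spirals.

`cdrwaves` implements the quantitative pipeline needed to measure those
behaviours from calibrated image stacks: active-contour tracking of the
wavefront, per-point normal velocity and curvature, the velocity versus
normalized-area collapse with extrapolation to zero area, linear and
circular kymographs, spatiotemporal autocorrelation with Radon-based
velocity extraction, and wave-event detection. Because live-cell movies
of this kind are rarely archived, the package ships a first-class
synthetic phantom generator whose defaults *are* the measured study
conditions; every stage of the pipeline is validated end-to-end against
phantom ground truth.

## Wavefront tracking

Tracking follows the classical gradient-vector-flow (GVF) snake of Xu
and Prince. The edge map is the negated, range-normalised intensity
(fronts are minima), optionally pre-blurred by `edge_blur` (default
0.5 µm); its gradient is diffused by fixed-point iteration of

    u <- u + dt * (mu * lap(u) - (u - fx) * (fx^2 + fy^2))

which extends the capture range far beyond the front itself. A closed
contour then evolves under the implicit scheme

    x_new = (I + step * (alpha * K2 + beta * K4))^{-1} (x + step * kappa * F(x))

with cyclic difference matrices `K2` (elasticity) and `K4` (rigidity),
until the maximal per-iteration displacement falls below `tolerance`
(default 0.05 µm) or 200 iterations. The GVF force is magnitude-capped
at 1 to keep the step size meaningful far from the front. The paper
behind this pipeline does not state its snake parameters; the defaults
(`alpha = 0.02` µm⁻², `beta = 0.2` µm⁻⁴, `kappa = 2`, `mu = 0.2`, 400
GVF iterations) were chosen once by validating on noiseless ring
phantoms — tracked radii reproduce the generating parabola with a
root-mean-square error below half a pixel — and are not tuned per
dataset.

Two numerical details matter more than the parameters:

* **Resampling cadence.** Arc-length resampling interpolates linearly
  and therefore moves points onto chords; applied every iteration this
  accumulates into a systematic inward drift of order the chord sagitta
  (≈ 0.02 µm per pass at 10 µm radius) and can collapse the contour
  through the weak-field interior. The snake therefore resamples every
  10 iterations only; the output is resampled once at the end.
* **Cubic-profile relaxation.** The snake's internal energy biases the
  converged contour off the intensity minimum, which would contaminate
  curvature estimates. As a final per-frame step each point samples the
  bilinear intensity along its outward normal over ±2 µm, fits a cubic
  polynomial, and moves to the cubic's within-interval global minimum;
  points with no interior minimum (flat or monotone profiles) and points
  whose profile would leave the image stay put (the latter are flagged).
  On symmetric troughs this relaxation is unbiased and lands within
  ~0.01 px of the true centre.

Contours are stored counter-clockwise (positive shoelace area), so
outward normals — and velocity signs — are well defined. Point spacing
is fixed at 0.8 µm, matching the resolution limit of the 10x objective
used for this kind of data. The "final smoothing with a kernel of the
order of the resolution limit" is implemented as a normalised Gaussian
low-pass (FWHM 0.8 µm) circularly convolved with the coordinate
sequences; a derivative (Sobel-type) kernel would not smooth, and the
low-pass interpretation reproduces the stated intent. Its k = 1 Fourier
attenuation shrinks a 10 µm circle by less than 0.05%.

## Kinematics and the velocity–area collapse

Per-point normal velocity is measured geometrically: from each point of
the contour at time *t* a bidirectional ray is cast along the outward
normal and intersected with the (linearly interpolated) contour at
*t* + Δt; the signed distance over Δt is the local velocity, positive
outward. The nearest intersection wins, ties break outward, and hits
beyond 5 µm are treated as missing. Frame-level mean velocities are
*time-centred* — the forward estimates of frames *i* − 1→*i* and
*i*→*i* + 1 are averaged — because a forward difference refers to
*t* + Δt/2 and pairing it with the area at *t* would bias the collapse
fit by `v0 * dt / (2 * t_rev)` (about 0.004 µm/s under the default
conditions, comparable to the tolerance on the extrapolated velocity).
Endpoints keep their one-sided estimates.

Curvature comes from the circumscribed circle of each point and its
neighbours at ±2.4 µm arc length (three spacings), signed positive where
the contour is convex to the outward normal; on circles of radius ≥ 5 µm
this recovers 1/R within 1%.

For an unperturbed CDR the radius follows a parabola symmetric about the
reversal time: with `R(t) = v0 t − v0 t²/(2 t_rev)` (the minimal
parabola with R(0) = 0) the normalized area `a = (R/R_max)²` and the
front velocity `v = dR/dt` obey the closed form

    a(v) = (1 − (v/v0)²)²   ⇔   v(a) = v0 · sqrt(1 − sqrt(a)),

the unique quartic collapse a parabolic radius implies. Opening-phase
(v > 0) points are pooled, binned in `a` with width 0.05 (bin statistic:
median, of both v and a), and the one-parameter law — linear in `v0` —
is fitted by least squares; `v(0) = v0` is the extrapolated initial
velocity. A free fourth-order polynomial is available as a fallback
(`method = "quartic"`), and a residual RMSE above 10% of the fitted `v0`
flags the collapse as non-parabolic (constant-velocity growth triggers
the flag). `A_max` is taken per wave over its tracked lifetime.

The curvature–velocity cross-correlation pools per-point pairs (Pearson
r) and adds a circular arc-length lag profile per contour. On
curvature-uniform phantoms (expanding, translating circles) |r| stays
below 0.1; a constructed eikonal rule `v = v0 − D·κ` is detected at
r ≤ −0.9.

```{r example-kinematics}
library(cdrwaves)
p <- phantom_params()            # 0.13 µm/s, t_rev 150 s, 5 µm front
ring <- make_ring_stack(p)
seed <- with(ring$ground_truth$frames,
             contour(p$center[1] + (radius_um[7] + 2) * cospi(seq(0, 2, l = 61)[-61]),
                     p$center[2] + (radius_um[7] + 2) * sinpi(seq(0, 2, l = 61)[-61])))
series <- track_sequence(ring$stack, seed, frame_range = 7:34)
kin <- series_kinematics(series)
fit <- fit_extrapolate_v0(velocity_area_collapse(kin))
fit$v0
```

## Kymographs, periods and recovery times

`linear_kymograph()` samples the intensity bilinearly along a line
(step = one pixel) per frame; through a wave origin the two branches of
the ring trace out ±R(t). `circular_kymograph()` samples along a circle
at one-pixel arc steps — the space axis is then periodic, which is the
natural geometry for disk-shaped cells where propagation is quasi
one-dimensional around the nucleus. `roi_min_trace()` smooths each frame
with a Gaussian (σ = 2 µm by default) and records the ROI minimum; wave
passages are negative peaks, and `recovery_times()` measures the
quiescent intervals τ between the end of one threshold-crossing event
and the onset of the next (back-to-back events give τ = 0; the default
threshold is midway between trace median and minimum, standing in for
the visually chosen thresholds of interactive analysis).
`rmax_from_kymograph()` reads each event's maximal radial extension as
half the spread of the dark-trace *centres* (not the raw mask extent,
which would add one front width), and `bin_tau_by_rmax()` produces the
10 µm box statistics relating recovery time to wave size.

## Spatiotemporal statistics

Kymographs are segmented (Otsu by default; wave pixels are dark) and
autocorrelated: `autocorrelation_2d()` computes the mean-subtracted
correlation c(Δs, Δt), circular in Δs (FFT along the periodic axis) and
linear in Δt, each time lag normalised by the energies of its two
overlapping segments, so |c| ≤ 1 everywhere, c(0, 0) = 1 exactly, and
c(−Δs, −Δt) = c(Δs, Δt). The default maximal time lag is half the
record. An FFT-vs-double-loop identity on small inputs is part of the
test suite (agreement to 1e-10).

Propagation velocities come from the Radon transform of the correlation
map: the map is projected along a grid of ridge orientations, and the
orientations maximising the projection variance give the stripe slopes,
converted to µm/s by the axis calibrations (two symmetric orientations
for bidirectional propagation; the per-map speed is the mean |v|). Peak
angles are refined on a 0.05° grid. Significance is assessed against a
*ring-shuffle* null: pixels are permuted within iso-radius annuli about
the origin, which destroys every orientation while preserving the radial
correlation power; a dominant angle must exceed the 99th percentile of
the null's maximal variance, compared on the same coarse angle grid so
the maximum statistics are exchangeable. (A row-shuffle null was
considered and rejected: permuting rows leaves horizontal — zero
velocity — ridges intact, so static patterns could never reach
significance.) Isotropic maps yield a no-velocity result.

The inter-event period is read from the temporal cut c(0, Δt): after the
first negative excursion (the refractory trough), the recurrence peak is
the maximum of the first sustained positive lobe. A plain
"first local maximum" rule is fragile under noise — any bump on the
rising flank qualifies — whereas the lobe maximum is exact on clean cuts
and stays within one bin at realistic noise. The cut is pre-smoothed
with a (1, 2, 1)/4 kernel; the reported lag stays on the original grid.

`detect_events()` turns a segmented kymograph into an event table by
tracing the dark runs of each time column and linking them across
columns by (±1 bin dilated, circularly wrapped) overlap. An unlinked
appearance is an initiation ("<" shape); two approaching traces that
merge, or that disappear simultaneously while approaching, are a
collision (">"), classified `mutual` when nothing survives the
collision window (6 columns) and `one_survives` otherwise; a lone
disappearance is an annihilation. Disappearances within 2 columns of the
record end are ignored (truncation). For mutual collisions with a finite
gap the terminal front-to-front distance is the circular distance of the
two run centres at the last column where both fronts are detectable —
run centres are used because the front position is the trace centre, and
they are robust to the amplitude decay of annihilating fronts.
`count_rotations()` tracks the intensity-weighted circular mean angle of
the dark excess on a sampling circle, unwraps the phase and floors the
total angle (with a 1e-6-rotation guard against floating-point
summation) into a rotation count; gaps in more than 25% of frames are an
error.

## The phantom generator

The generator renders, kinematically (no reaction–diffusion dynamics),
the four geometries the analyses need, each with exported ground truth:

* **Rings** (`make_ring_stack`): dark trough of Gaussian cross-section
  at radius R(t) following the parabola above; optional bright halo
  offset outward by one front width (halos empirically mark decaying
  fronts); optional additive Gaussian noise.
* **Annulus pulses** (`make_annulus_stack`): a disk cell with dark
  nucleus; pulses fire at sites with a set period, split into ± pairs at
  `lateral_speed` along the mid-annulus circle, and on head-on approach
  either freeze at `terminal_gap` and decay over three frames
  (annihilate) or pass through (cross). `firing_period = Inf` gives a
  single orbiting pulse.
* **Spirals** (`make_spiral_stack`): a rigid one-armed Archimedean
  spiral whose single turn spans the annulus, rotating with
  `rotation_period`.
* **Direct kymographs** (`make_kymograph_direct`): stripe, pulse-train
  and collision space–time maps rendered without the imaging step, for
  unit-testing kymograph consumers; `make_collision_ensemble` draws
  labelled annihilate/cross ensembles with jittered speeds, separations
  and gaps.

Default parameters are the study conditions: 0.13 µm/s initial ring
velocity, 0.12 µm/s lateral speed, 5 µm front width, 360 s firing
period, 12 µm terminal gap, 525 s rotation period, 0.5 µm pixels, 10 s
frames. No quantitative noise model for phase-contrast imaging is
available, so `noise_sigma` is free; validation uses 0 (oracle checks)
and 0.05–0.16 (robustness checks, signal-to-noise ≈ 5–16 against the
0.8 trough depth). Identical parameters and seed give bit-identical
output; the RNG state of the caller is never disturbed.

What the phantoms do *not* emulate — and hence what passing tests do not
show about real data: wavefront instabilities and arc break-up, shape
anisotropy from irregular cell boundaries, intensity texture of real
cytoplasm, halo-correlated decay, stage drift, and photobleaching. The
pulse trains used for velocity recovery fire staggered/continuous
trains; synchronous firing of all sites adds a global temporal
oscillation that competes with the stripe orientation in the Radon
projection — visible in real kymographs only as a weak effect, but worth
knowing when interpreting the velocity significance test.

## Problem sizes and runtime

The shipped validation uses 96–128 px frames, 20–35 frame tracking runs,
128-bin kymographs with 150–200 columns, and a 100-kymograph collision
ensemble; the full test suite runs in about a minute on one core, and
the acceptance script in about the same. These sizes put every measured
quantity well inside its quoted tolerance; larger stacks change runtimes
(GVF is the dominant cost, linear in pixels × iterations), not the
conclusions.

## Known limitations

* Initialisation is explicit (a seed polygon); there is no automatic
  CDR detection, mirroring the interactive origin of the method.
* Tracking small rings (radius ≲ 2 µm, a few front widths) collapses —
  the opening and final closure of a wave are not trackable, which is
  why the collapse *extrapolates* to zero area instead of measuring
  there.
* The event tracker assumes fronts thinner than their separation;
  fronts closer than one front width merge in segmentation and are
  reported with gap 0.
* Calibration travels in YAML sidecars; TIFF tags are ignored.
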