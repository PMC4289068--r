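# cdrwaves

Quantitative analysis of **circular dorsal ruffles** (CDRs) — ring-shaped
actin waves on the dorsal surface of adherent cells — and similar
wavefronts in phase-contrast time-lapse microscopy, where the wavefront
(the actin maximum) appears as an intensity *minimum*. The package is
aimed at cell biophysicists who need reproducible wavefront kinematics
from calibrated image stacks, and at method developers who need a
ground-truthed benchmark for wave-analysis pipelines.

## What it computes

* **Wavefront tracking** — gradient-vector-flow (GVF) active contours
  with sub-pixel cubic-profile relaxation onto the intensity minimum,
  fixed 0.8 µm arc-length resampling and low-pass coordinate smoothing
  (`gvf_field`, `evolve_snake`, `relax_contour`, `track_sequence`).
* **Kinematics** — per-point normal velocity by ray intersection with
  the next contour (positive = growth), signed local curvature from
  circumscribed circles, enclosed area, and the velocity versus
  normalized-area collapse. For a parabolic radius evolution
  `R(t) = v0·t − v0·t²/(2·t_rev)` the mean front velocity `v` and the
  normalized area `a = (R/R_max)²` obey the closed-form quartic

  `a(v) = (1 − (v/v0)²)²  ⇔  v(a) = v0·√(1 − √a)`,

  which `fit_extrapolate_v0()` fits to the binned collapse (box medians,
  width 0.05) to extrapolate the initial front velocity `v(a → 0) = v0`.
  A curvature–velocity cross-correlation
  (`curvature_velocity_correlation`) tests eikonal-type coupling.
* **Kymographs** — linear and circular (periodic arc-length) kymographs,
  ROI minimum-intensity traces, recovery times τ between wave events,
  per-event maximal radial extension `R_max`, and τ-by-`R_max` box
  statistics (10 µm bins).
* **Spatiotemporal statistics** — Otsu segmentation, periodic 2-D
  autocorrelation maps `c(Δs, Δt)` (circular in space, unbiased in
  time, `c(0,0) = 1`), Radon-transform extraction of propagation
  velocities from ridge orientations with a ring-shuffle significance
  null, inter-event periods from the `c(0, Δt)` cut, and detection and
  classification of wave events: initiations ("<" shapes),
  annihilations, collisions (">") with *mutual* vs *one-survives*
  outcomes, terminal front-to-front gaps, and spiral rotation counts.
* **Synthetic phantoms** — calibrated ring, annulus-pulse, spiral and
  direct-kymograph generators with exported ground truth
  (`make_ring_stack`, `make_annulus_stack`, `make_spiral_stack`,
  `make_kymograph_direct`, `make_collision_ensemble`). Defaults encode
  the measured study conditions (0.13 µm/s initial ring velocity, 5 µm
  front width, 0.12 µm/s lateral speed, 6 min firing period, 12 µm
  terminal gap, 525 s spiral period).

File formats: multi-page 16-bit TIFF with YAML calibration sidecars for
stacks and kymographs, CSV for contours/events/traces (µm, seconds,
0-based frames). A command-line interface (`cdr_cli()`, launcher in
`inst/cli/cdrwaves`) binds the stages: `simulate`, `track`,
`kinematics`, `kymo`, `stats`, `binarize`.

## Worked example

Track a noiseless parabolic ring phantom at the default study
conditions, collapse its velocity–area relation, and extrapolate the
initial front velocity; then read the firing period off a circular
kymograph:

```r
library(cdrwaves)

p <- phantom_params(frame_interval = 5, shape = c(34L, 128L, 128L))
ring <- make_ring_stack(p)             # v0 = 0.13 µm/s, t_rev = 150 s
th <- 2 * pi * (0:59) / 60
R0 <- ring$ground_truth$frames$radius_um[7] + 2
seed <- contour(p$center[1] + R0 * cos(th), p$center[2] + R0 * sin(th))
series <- track_sequence(ring$stack, seed, frame_range = 7:34)
kin <- series_kinematics(series)
head(kin$per_frame[, c("frame", "time_s", "area_um2", "a", "v_mean_um_s")], 3)
#>   frame time_s area_um2      a v_mean_um_s
#> 1     6     30    37.06 0.1243     0.12104
#> 2     7     35    51.65 0.1733     0.10788
#> 3     8     40    64.78 0.2174     0.09305
fit <- fit_extrapolate_v0(velocity_area_collapse(kin))
#> extrapolated v(a=0) = 0.1318 µm/s (rmse 0.0044, non-parabolic: FALSE)

pk <- phantom_params(frame_interval = 12, shape = c(200L, 1L, 1L))
kymo <- make_kymograph_direct(pk, "pulses", length_um = 64, n_sites = 4)$kymograph
cmap <- autocorrelation_2d(segment_kymograph(kymo), max_lag_t = 90)
period_from_cut(cmap) / 60
#> inter-event period = 6.0 min
table(detect_events(segment_kymograph(kymo))$type)
#> collision (mutual): 28   initiation: 28
```

The extrapolated 0.1318 µm/s recovers the generating 0.13 µm/s within
the tracking pipeline's sub-pixel accuracy; the per-frame mean velocity
falls from ~0.12 µm/s at small normalized area toward zero at reversal,
which is the collapse the quartic law describes. The kymograph's
autocorrelation cut returns the generating 6-minute firing period, and
the event table contains one initiation and one mutual annihilation per
firing site and cycle.

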