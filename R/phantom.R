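# Synthetic phantom generator.
#
# Renders calibrated image stacks and kymographs with the kinematic
# structure of circular dorsal ruffles: closed ring waves whose radius
# follows a parabola in time, azimuthally propagating pulses on the
# annulus between nucleus and cell edge with periodic firing, rigidly
# rotating spiral arms, and head-on collisions that terminate with a
# finite front-to-front gap. Wavefronts are intensity minima on a bright
# background (phase-contrast convention: actin maxima are phase minima),
# with Gaussian cross-section of full width at half depth `front_width`.
# Every rendered wave carries a ground-truth record.

#' Parameters of the synthetic phantom generator
#'
#' Defaults are the study conditions of the analyses this package
#' implements: an extrapolated initial radial speed of 0.13 µm/s for ring
#' waves, lateral pulse speeds of about 0.12 µm/s, a 5 µm front width,
#' a 6 min firing period, and a 12 µm terminal collision gap.
#'
#' @param pixel_size Pixel size in µm/px (> 0).
#' @param frame_interval Frame interval in s (> 0).
#' @param shape Integer `(T, H, W)`: frames, height, width.
#' @param v0 Initial radial speed of ring waves in µm/s.
#' @param t_rev Reversal time of ring waves in s; the radius follows
#'   `R(t) = v0 t - v0 t^2 / (2 t_rev)`, symmetric about `t_rev`.
#' @param front_width Full width at half depth of the intensity trough,
#'   µm.
#' @param front_depth Trough contrast in `[0, 1]` (background is 1).
#' @param halo_amplitude Amplitude of an optional bright halo ring offset
#'   outward from the trough by one front width (>= 0).
#' @param noise_sigma Standard deviation of additive Gaussian noise in
#'   intensity units (>= 0).
#' @param center Wave centre `(x, y)` in µm; defaults to the image
#'   centre.
#' @param nucleus_radius,cell_radius Radii in µm bounding the annulus of
#'   lateral propagation (annulus phantoms).
#' @param lateral_speed Azimuthal pulse speed in µm/s.
#' @param firing_period Interval between firings at a site in s
#'   (`Inf` for a single orbiting pulse).
#' @param terminal_gap Front-to-front distance at which colliding pulses
#'   mutually annihilate, µm.
#' @param rotation_period Period of one full spiral rotation, s.
#' @param rng_seed Integer seed controlling the noise; identical
#'   parameters and seed give bit-identical output.
#'
#' @return A list of class `cdr_phantom_params`.
#' @export
phantom_params <- function(pixel_size = 0.5, frame_interval = 10,
                           shape = c(40L, 128L, 128L),
                           v0 = 0.13, t_rev = 150,
                           front_width = 5, front_depth = 0.8,
                           halo_amplitude = 0, noise_sigma = 0,
                           center = NULL,
                           nucleus_radius = 10, cell_radius = 28,
                           lateral_speed = 0.12, firing_period = 360,
                           terminal_gap = 12, rotation_period = 525,
                           rng_seed = 1L) {
  stopifnot(pixel_size > 0, frame_interval > 0, length(shape) == 3,
            all(shape >= 1), front_width > 0,
            front_depth >= 0, front_depth <= 1,
            halo_amplitude >= 0, noise_sigma >= 0)
  if (is.finite(nucleus_radius) && is.finite(cell_radius) &&
      nucleus_radius >= cell_radius)
    stop("nucleus_radius must be smaller than cell_radius")
  if (is.null(center))
    center <- c((shape[3] - 1) / 2, (shape[2] - 1) / 2) * pixel_size
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval,
         shape = as.integer(shape), v0 = v0, t_rev = t_rev,
         front_width = front_width, front_depth = front_depth,
         halo_amplitude = halo_amplitude, noise_sigma = noise_sigma,
         center = center, nucleus_radius = nucleus_radius,
         cell_radius = cell_radius, lateral_speed = lateral_speed,
         firing_period = firing_period, terminal_gap = terminal_gap,
         rotation_period = rotation_period,
         rng_seed = as.integer(rng_seed)),
    class = "cdr_phantom_params"
  )
}

#' @noRd
sigma_from_fwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Parabolic radius law of ring phantoms
#'
#' `R(t) = v0 t - v0 t^2 / (2 t_rev)`: the minimal parabola with
#' `R(0) = 0`, maximal radius `v0 t_rev / 2` at the reversal time and
#' closure at `2 t_rev`. Negative values (after closure) are clipped to 0.
#'
#' @param t Time(s) in s.
#' @param v0 Initial radial speed, µm/s.
#' @param t_rev Reversal time, s.
#' @return Radius in µm.
#' @export
ring_radius <- function(t, v0, t_rev) {
  pmax(0, v0 * t - v0 / (2 * t_rev) * t^2)
}

## Pixel-centre coordinate grids in µm for an H x W frame.
#' @noRd
frame_grid <- function(params) {
  H <- params$shape[2]
  W <- params$shape[3]
  x <- idx_to_um(seq_len(W), params$pixel_size)
  y <- idx_to_um(seq_len(H), params$pixel_size)
  X <- matrix(x, H, W, byrow = TRUE)
  Y <- matrix(y, H, W)
  list(X = X - params$center[1], Y = Y - params$center[2])
}

#' @noRd
add_stack_noise <- function(img, params) {
  if (params$noise_sigma > 0) {
    img <- img + with_seed(params$rng_seed,
      array(stats::rnorm(length(img), 0, params$noise_sigma), dim(img)))
  }
  img
}

#' Ring-wave phantom with parabolic radius evolution
#'
#' Each frame shows a bright background with a dark circular trough of
#' Gaussian cross-section centred at radius `R(t)` (see [ring_radius()]),
#' an optional bright halo ring offset outward by one front width, and
#' additive Gaussian noise. The ground truth carries the analytic radius
#' and contour for every frame.
#'
#' @param params A [phantom_params()] object with `v0` and `t_rev` set.
#' @return A list with elements `stack` (a [image_stack()]) and
#'   `ground_truth`.
#' @export
make_ring_stack <- function(params) {
  stopifnot(inherits(params, "cdr_phantom_params"))
  if (!is.finite(params$v0) || !is.finite(params$t_rev))
    stop("ring phantoms need v0 and t_rev")
  TT <- params$shape[1]
  times <- (seq_len(TT) - 1) * params$frame_interval
  R <- ring_radius(times, params$v0, params$t_rev)
  sigma <- sigma_from_fwhm(params$front_width)
  margin <- min(params$center[1], params$center[2],
                (params$shape[3] - 1) * params$pixel_size - params$center[1],
                (params$shape[2] - 1) * params$pixel_size - params$center[2])
  reach <- max(R) + 3 * sigma +
    if (params$halo_amplitude > 0) params$front_width else 0
  if (reach > margin)
    stop(sprintf(
      "ring radius reaches %.1f µm but frame margin is only %.1f µm",
      reach, margin))
  g <- frame_grid(params)
  r <- sqrt(g$X^2 + g$Y^2)
  img <- array(1, dim = c(params$shape[2], params$shape[3], TT))
  for (i in seq_len(TT)) {
    f <- 1 - params$front_depth * exp(-(r - R[i])^2 / (2 * sigma^2))
    if (params$halo_amplitude > 0)
      f <- f + params$halo_amplitude *
        exp(-(r - R[i] - params$front_width)^2 / (2 * sigma^2))
    img[, , i] <- f
  }
  img <- add_stack_noise(img, params)
  contours <- lapply(seq_len(TT), function(i) {
    if (R[i] < 0.5) return(NULL)
    np <- max(24L, round(2 * pi * R[i] / 0.4))
    th <- 2 * pi * (seq_len(np) - 1) / np
    contour(params$center[1] + R[i] * cos(th),
            params$center[2] + R[i] * sin(th))
  })
  gt <- structure(
    list(type = "ring",
         frames = data.frame(frame = seq_len(TT) - 1L, time_s = times,
                             radius_um = R),
         contours = contours, v0 = params$v0, t_rev = params$t_rev,
         params = params),
    class = "cdr_ground_truth")
  list(stack = image_stack(img, params$pixel_size, params$frame_interval),
       ground_truth = gt)
}

## --- annulus pulse simulation ------------------------------------------

## Simulate azimuthal pulse kinematics on the mid-annulus circle.
## Returns per-frame pulse states and the event table. Positions are arc
## lengths (µm) on a ring of circumference L.
#' @noRd
simulate_pulses <- function(params, mode, n_sites, TT) {
  r_mid <- (params$nucleus_radius + params$cell_radius) / 2
  L <- 2 * pi * r_mid
  v <- params$lateral_speed
  dt <- params$frame_interval
  P <- params$firing_period
  gap <- params$terminal_gap
  single <- !is.finite(P)
  sites <- L * (seq_len(n_sites) - 1) / n_sites
  pulses <- data.frame(id = integer(), s = numeric(), dir = numeric(),
                       amp = numeric(), frozen = logical(),
                       decay = integer())
  next_id <- 1L
  fired <- numeric()
  events <- data.frame(type = character(), s_um = numeric(),
                       t_s = numeric(), class = character(),
                       gap_um = numeric())
  crossed <- character()
  states <- vector("list", TT)
  if (single) {
    pulses <- data.frame(id = 1L, s = 0, dir = 1, amp = 1,
                         frozen = FALSE, decay = NA_integer_)
    next_id <- 2L
    events <- rbind(events, data.frame(type = "initiation", s_um = 0,
                                       t_s = 0, class = NA, gap_um = NA))
  }
  for (f in seq_len(TT)) {
    t <- (f - 1) * dt
    if (!single) {
      due <- P * (0:floor(t / P + 1e-9))
      for (ft in setdiff(due[due <= t + 1e-9], fired)) {
        for (sk in sites) {
          pulses <- rbind(pulses, data.frame(
            id = next_id + 0:1, s = c(sk, sk), dir = c(1, -1),
            amp = 1, frozen = FALSE, decay = NA_integer_))
          next_id <- next_id + 2L
          events <- rbind(events, data.frame(
            type = "initiation", s_um = sk, t_s = ft, class = NA,
            gap_um = NA))
        }
        fired <- c(fired, ft)
      }
    }
    ## collision handling among live, unfrozen pulses
    live <- which(pulses$amp > 0 & !pulses$frozen)
    if (length(live) >= 2) {
      for (a in live) {
        for (b in live) {
          if (b <= a) next
          if (pulses$frozen[a] || pulses$frozen[b]) next
          d <- wrap_diff(pulses$s[b] - pulses$s[a], L)
          approaching <- sign(d) * (pulses$dir[b] - pulses$dir[a]) < 0
          if (!approaching) next
          sep <- abs(d)
          key <- paste(pulses$id[a], pulses$id[b])
          if (mode == "annihilate" && sep <= gap + v * dt) {
            mid <- (pulses$s[a] + d / 2) %% L
            pulses$s[a] <- (mid - sign(d) * gap / 2) %% L
            pulses$s[b] <- (mid + sign(d) * gap / 2) %% L
            pulses$frozen[c(a, b)] <- TRUE
            pulses$decay[c(a, b)] <- 3L
            events <- rbind(events, data.frame(
              type = "collision", s_um = mid, t_s = t, class = "mutual",
              gap_um = gap))
          } else if (mode == "cross" && sep <= v * dt &&
                     !(key %in% crossed)) {
            crossed <- c(crossed, key)
            events <- rbind(events, data.frame(
              type = "collision", s_um = (pulses$s[a] + d / 2) %% L,
              t_s = t, class = "one_survives", gap_um = 0))
          }
        }
      }
    }
    states[[f]] <- pulses[pulses$amp > 0, , drop = FALSE]
    ## advance / decay
    mv <- pulses$amp > 0 & !pulses$frozen
    pulses$s[mv] <- (pulses$s[mv] + pulses$dir[mv] * v * dt) %% L
    dec <- which(pulses$frozen & pulses$amp > 0)
    if (length(dec)) {
      pulses$decay[dec] <- pulses$decay[dec] - 1L
      pulses$amp[dec] <- pmax(0, pulses$decay[dec] / 3)
    }
  }
  list(states = states, events = events, L = L, r_mid = r_mid)
}

#' Annulus phantom: pulses between nucleus and cell edge
#'
#' Renders a disk-shaped cell with a dark central nucleus. Wave pulses
#' appear at firing sites with period `firing_period`, split into two
#' pulses propagating azimuthally at `+/- lateral_speed` along the
#' mid-annulus circle, and on head-on approach either stop at
#' `terminal_gap` and decay over three frames (`mode = "annihilate"`) or
#' pass through one another (`mode = "cross"`). With
#' `firing_period = Inf` a single pulse orbits the nucleus indefinitely.
#'
#' @param params A [phantom_params()] object with annulus geometry set.
#' @param mode Collision outcome, `"annihilate"` or `"cross"`.
#' @param n_sites Number of equally spaced firing sites.
#' @return A list with `stack`, `ground_truth`.
#' @export
make_annulus_stack <- function(params, mode = c("annihilate", "cross"),
                               n_sites = 1L) {
  stopifnot(inherits(params, "cdr_phantom_params"))
  mode <- match.arg(mode)
  if (!is.finite(params$nucleus_radius) || !is.finite(params$cell_radius))
    stop("annulus phantoms need nucleus_radius and cell_radius")
  r_mid <- (params$nucleus_radius + params$cell_radius) / 2
  if (2 * pi * r_mid < 4 * params$front_width)
    stop("lateral path circumference shorter than 4 front widths")
  TT <- params$shape[1]
  sim <- simulate_pulses(params, mode, n_sites, TT)
  g <- frame_grid(params)
  r <- sqrt(g$X^2 + g$Y^2)
  theta <- atan2(g$Y, g$X)
  sigma_s <- sigma_from_fwhm(params$front_width)
  sigma_r <- (params$cell_radius - params$nucleus_radius) / 4
  base <- 1 -
    0.35 / (1 + exp((r - params$nucleus_radius) / 0.5)) -
    0.10 * exp(-(r - params$cell_radius)^2 / (2 * 0.75^2))
  img <- array(0, dim = c(params$shape[2], params$shape[3], TT))
  for (f in seq_len(TT)) {
    frame <- base
    st <- sim$states[[f]]
    for (k in seq_len(nrow(st))) {
      phi_p <- st$s[k] / sim$r_mid
      d_arc <- r * wrap_diff(theta - phi_p, 2 * pi)
      d_rad <- r - sim$r_mid
      frame <- frame - params$front_depth * st$amp[k] *
        exp(-d_arc^2 / (2 * sigma_s^2) - d_rad^2 / (2 * sigma_r^2))
    }
    img[, , f] <- frame
  }
  img <- add_stack_noise(img, params)
  times <- (seq_len(TT) - 1) * params$frame_interval
  traj <- do.call(rbind, lapply(seq_len(TT), function(f) {
    st <- sim$states[[f]]
    if (!nrow(st)) return(NULL)
    data.frame(frame = f - 1L, time_s = times[f], id = st$id,
               s_um = st$s, dir = st$dir, amp = st$amp)
  }))
  gt <- structure(
    list(type = "annulus", events = sim$events, pulses = traj,
         r_mid = sim$r_mid, circumference = sim$L, mode = mode,
         params = params),
    class = "cdr_ground_truth")
  list(stack = image_stack(img, params$pixel_size, params$frame_interval),
       ground_truth = gt)
}

#' Spiral-wave phantom
#'
#' A one-armed dark Archimedean spiral filling the annulus between
#' `nucleus_radius` and `cell_radius`, rotating rigidly with period
#' `rotation_period`. The ground truth stores the unwrapped arm angle at
#' the mid-annulus radius for every frame.
#'
#' @param params A [phantom_params()] object with `rotation_period` set.
#' @return A list with `stack`, `ground_truth`.
#' @export
make_spiral_stack <- function(params) {
  stopifnot(inherits(params, "cdr_phantom_params"))
  if (!is.finite(params$rotation_period))
    stop("spiral phantoms need rotation_period")
  TT <- params$shape[1]
  r_in <- params$nucleus_radius
  r_out <- params$cell_radius
  b <- (r_out - r_in) / (2 * pi)  # one turn spans the annulus
  omega <- 2 * pi / params$rotation_period
  sigma <- sigma_from_fwhm(params$front_width)
  g <- frame_grid(params)
  r <- sqrt(g$X^2 + g$Y^2)
  theta <- atan2(g$Y, g$X)
  rc <- pmin(pmax(r, r_in), r_out)
  taper <- exp(-(r - rc)^2 / (2 * sigma^2))
  img <- array(0, dim = c(params$shape[2], params$shape[3], TT))
  times <- (seq_len(TT) - 1) * params$frame_interval
  for (f in seq_len(TT)) {
    u <- (theta + omega * times[f]) %% (2 * pi)
    m <- (r - r_in - b * u) %% (2 * pi * b)
    d <- pmin(m, 2 * pi * b - m)
    img[, , f] <- 1 - params$front_depth * taper *
      exp(-d^2 / (2 * sigma^2))
  }
  img <- add_stack_noise(img, params)
  r_mid <- (r_in + r_out) / 2
  angle <- (r_mid - r_in) / b - omega * times  # unwrapped arm angle
  gt <- structure(
    list(type = "spiral",
         tip = data.frame(frame = seq_len(TT) - 1L, time_s = times,
                          angle_rad = angle),
         rotations = abs(angle[TT] - angle[1]) / (2 * pi),
         r_mid = r_mid, params = params),
    class = "cdr_ground_truth")
  list(stack = image_stack(img, params$pixel_size, params$frame_interval),
       ground_truth = gt)
}

#' Directly rendered kymograph phantom
#'
#' Bypasses image formation and renders a space-time intensity map with
#' dark stripes of slope `ds/dt = +/- lateral_speed` on a periodic spatial
#' axis, for unit testing of kymograph consumers.
#'
#' Modes: `"stripes"` renders continuously wrapping stripes of constant
#' velocity; `"pulses"` renders periodic firings at `n_sites` equally
#' spaced sites, each splitting into a counter-propagating pair that
#' annihilates with its neighbours at the inter-site midpoints (the
#' "<" / ">" texture of circular kymographs); `"collision"` renders two
#' converging pulses that either stop with front-to-front distance
#' `terminal_gap` and decay over three frames (`outcome = "annihilate"`)
#' or pass through (`outcome = "cross"`).
#'
#' @param params A [phantom_params()] object (calibration, speed, width,
#'   period, gap, noise).
#' @param mode One of `"stripes"`, `"pulses"`, `"collision"`.
#' @param length_um Circumference of the periodic space axis in µm.
#' @param n_stripes Stripe count for `"stripes"`.
#' @param n_sites Firing-site count for `"pulses"`.
#' @param both_directions For `"stripes"`: also render the mirrored set.
#' @param outcome Collision outcome for `"collision"`.
#' @param start_separation Initial centre separation for `"collision"`,
#'   µm (default half the circumference).
#' @return A list with `kymograph` (a [kymograph()]) and `ground_truth`.
#' @export
make_kymograph_direct <- function(params,
                                  mode = c("stripes", "pulses",
                                           "collision"),
                                  length_um = 64, n_stripes = 1L,
                                  n_sites = 4L,
                                  both_directions = FALSE,
                                  outcome = c("annihilate", "cross"),
                                  start_separation = NULL) {
  stopifnot(inherits(params, "cdr_phantom_params"))
  mode <- match.arg(mode)
  outcome <- match.arg(outcome)
  ds <- params$pixel_size
  dt <- params$frame_interval
  TT <- params$shape[1]
  S <- round(length_um / ds)
  L <- S * ds
  v <- params$lateral_speed
  sigma <- sigma_from_fwhm(params$front_width)
  s_axis <- idx_to_um(seq_len(S), ds)
  times <- (seq_len(TT) - 1) * dt
  vals <- matrix(1, S, TT)
  paint <- function(col, centre, amp = 1) {
    d <- wrap_diff(s_axis - centre, L)
    vals[, col] <<- vals[, col] -
      params$front_depth * amp * exp(-d^2 / (2 * sigma^2))
  }
  events <- data.frame(type = character(), s_um = numeric(),
                       t_s = numeric(), class = character(),
                       gap_um = numeric())
  truth <- list()
  if (mode == "stripes") {
    offs <- L * (seq_len(n_stripes) - 0.5) / n_stripes
    dirs <- if (both_directions) c(1, -1) else 1
    for (f in seq_len(TT))
      for (o in offs)
        for (dd in dirs)
          paint(f, (o + dd * v * times[f]) %% L)
    truth$speed <- v
    truth$offsets <- offs
  } else if (mode == "pulses") {
    sites <- L * (seq_len(n_sites) - 0.5) / n_sites
    life <- L / (2 * n_sites) / v  # time to reach inter-site midpoint
    fires <- seq(0, times[TT], by = params$firing_period)
    for (ft in fires) {
      for (sk in sites) {
        events <- rbind(events, data.frame(
          type = "initiation", s_um = sk, t_s = ft, class = NA,
          gap_um = NA))
        for (dd in c(1, -1)) {
          on <- which(times >= ft & times <= ft + life + 1e-9)
          for (f in on) paint(f, (sk + dd * v * (times[f] - ft)) %% L)
        }
        events <- rbind(events, data.frame(
          type = "collision",
          s_um = (sk + L / (2 * n_sites)) %% L,
          t_s = ft + life, class = "mutual", gap_um = 0))
      }
    }
    truth$period <- params$firing_period
    truth$speed <- v
    truth$sites <- sites
  } else {  # collision
    D0 <- start_separation %||% (L / 2)
    gap <- if (outcome == "annihilate") params$terminal_gap else 0
    p1 <- L / 2 - D0 / 2 + v * times
    p2 <- L / 2 + D0 / 2 - v * times
    sep <- p2 - p1
    if (outcome == "annihilate") {
      hit <- which(sep <= gap)
      if (!length(hit))
        stop("collision phantom: pulses never reach the terminal gap")
      fc <- hit[1]
      amp <- rep(0, TT)
      amp[seq_len(fc - 1)] <- 1
      if (fc <= TT) amp[fc] <- 1          # frozen, full contrast
      if (fc + 1 <= TT) amp[fc + 1] <- 2 / 3
      if (fc + 2 <= TT) amp[fc + 2] <- 1 / 3
      p1[fc:TT] <- L / 2 - gap / 2
      p2[fc:TT] <- L / 2 + gap / 2
      for (f in seq_len(TT)) {
        if (amp[f] <= 0) next
        paint(f, p1[f] %% L, amp[f])
        paint(f, p2[f] %% L, amp[f])
      }
      events <- rbind(events, data.frame(
        type = "collision", s_um = L / 2, t_s = times[fc],
        class = "mutual", gap_um = gap))
      truth$collision_frame <- fc - 1L
    } else {
      for (f in seq_len(TT)) {
        paint(f, p1[f] %% L)
        paint(f, p2[f] %% L)
      }
      fc <- which(sep <= 0)[1]
      events <- rbind(events, data.frame(
        type = "collision", s_um = L / 2,
        t_s = if (is.na(fc)) NA else times[fc], class = "one_survives",
        gap_um = 0))
    }
    truth$gap <- gap
    truth$speed <- v
  }
  if (params$noise_sigma > 0)
    vals <- vals + with_seed(params$rng_seed,
      matrix(stats::rnorm(length(vals), 0, params$noise_sigma),
             nrow(vals)))
  gt <- structure(
    c(list(type = paste0("kymo_", mode), events = events,
           params = params), truth),
    class = "cdr_ground_truth")
  list(kymograph = kymograph(vals, ds = ds, dt = dt, periodic = TRUE),
       ground_truth = gt)
}

#' Labelled ensemble of collision kymographs
#'
#' Generates `n` collision kymographs of which exactly
#' `round(n * fraction_annihilate)` are rendered in annihilate mode
#' (label `"mutual"`) and the rest in cross mode (label
#' `"one_survives"`), in an order shuffled by `seed`. Pulse speeds, start
#' separations and terminal gaps are mildly jittered per kymograph.
#'
#' @param n Number of kymographs (> 0).
#' @param fraction_annihilate Fraction in `[0, 1]` of annihilate-mode
#'   kymographs; 0.79 is the observed share of mutual annihilations.
#' @param seed Integer seed for the shuffle and jitter.
#' @param params Base [phantom_params()].
#' @param length_um Space-axis circumference, µm.
#' @return A list with `kymographs` (list), `labels` (character) and
#'   `table` (per-item parameters).
#' @export
make_collision_ensemble <- function(n, fraction_annihilate, seed = 1L,
                                    params = phantom_params(
                                      shape = c(35L, 1L, 1L)),
                                    length_um = 64) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  stopifnot(fraction_annihilate >= 0, fraction_annihilate <= 1)
  n <- as.integer(n)
  n_a <- round(n * fraction_annihilate)
  labels <- c(rep("mutual", n_a), rep("one_survives", n - n_a))
  jit <- with_seed(seed, {
    labels <- sample(labels)
    data.frame(label = labels,
               speed = params$lateral_speed * stats::runif(n, 0.9, 1.1),
               gap = stats::runif(n, 9, 15),
               sep = length_um / 2 * stats::runif(n, 0.95, 1.05))
  })
  kymos <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$lateral_speed <- jit$speed[i]
    p$terminal_gap <- jit$gap[i]
    p$rng_seed <- params$rng_seed + i
    out <- make_kymograph_direct(
      p, mode = "collision", length_um = length_um,
      outcome = if (jit$label[i] == "mutual") "annihilate" else "cross",
      start_separation = jit$sep[i])
    kymos[[i]] <- out$kymograph
  }
  list(kymographs = kymos, labels = jit$label, table = jit)
}

#' @export
print.cdr_ground_truth <- function(x, ...) {
  cat(sprintf("<cdr_ground_truth> type '%s'\n", x$type))
  if (!is.null(x$events) && nrow(x$events))
    cat(sprintf("  %d events (%s)\n", nrow(x$events),
                paste(unique(x$events$type), collapse = ", ")))
  invisible(x)
}
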