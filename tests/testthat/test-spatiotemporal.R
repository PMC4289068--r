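test_that("Otsu segmentation recovers the generating stripe mask", {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                      shape = c(60L, 1L, 1L), lateral_speed = 0.12,
                      noise_sigma = 0.05, rng_seed = 4)
  k <- make_kymograph_direct(p, "stripes", length_um = 32)
  bin <- segment_kymograph(k$kymograph)
  ## generating mask: Otsu segmentation of the noiseless rendering
  pn <- p; pn$noise_sigma <- 0
  kn <- make_kymograph_direct(pn, "stripes", length_um = 32)
  truth <- segment_kymograph(kn$kymograph)$values > 0.5
  got <- bin$values > 0.5
  jac <- sum(got & truth) / sum(got | truth)
  expect_gt(jac, 0.9)
  ## inverted contrast with the flag gives the same mask
  ki <- k$kymograph
  ki$values <- -ki$values
  bin2 <- segment_kymograph(ki, invert = TRUE)
  expect_identical(bin$values, bin2$values)
  ## a threshold below the minimum is all background (with warning)
  expect_warning(b0 <- segment_kymograph(k$kymograph, threshold = -10),
                 "all-")
  expect_true(all(b0$values == 0))
})

test_that("the FFT autocorrelation equals the brute-force double
           loop", {
  set.seed(42)
  v <- matrix(runif(20 * 14), 20, 14)
  k <- kymograph(v, ds = 1, dt = 1, periodic = TRUE)
  cm <- autocorrelation_2d(k, max_lag_t = 6)
  X <- v - mean(v)
  S <- 20; TT <- 14
  brute <- function(dsl, dtl) {
    i1 <- seq_len(TT - abs(dtl))
    if (dtl >= 0) { t1 <- i1; t2 <- i1 + dtl }
    else { t1 <- i1 - dtl; t2 <- i1 }
    num <- 0
    for (t in seq_along(t1)) for (s in 1:S) {
      s2 <- ((s - 1 + dsl) %% S) + 1
      num <- num + X[s, t1[t]] * X[s2, t2[t]]
    }
    num / sqrt(sum(X[, t1]^2) * sum(X[, t2]^2))
  }
  for (dsl in c(-10, -3, 0, 2, 9)) for (dtl in c(-6, -1, 0, 1, 5)) {
    expect_equal(cm$c[which(cm$ds_lags == dsl),
                      which(cm$dt_lags == dtl)],
                 brute(dsl, dtl), tolerance = 1e-10)
  }
  ## invariants: unit origin, point symmetry, bounded
  expect_identical(cm$c[which(cm$ds_lags == 0),
                        which(cm$dt_lags == 0)], 1)
  expect_true(all(abs(cm$c) <= 1 + 1e-9))
  for (dsl in -9:9) for (dtl in c(-4, 2)) {
    nd <- ((-dsl + 10) %% 20) - 10
    expect_equal(cm$c[which(cm$ds_lags == dsl),
                      which(cm$dt_lags == dtl)],
                 cm$c[which(cm$ds_lags == nd),
                      which(cm$dt_lags == -dtl)], tolerance = 1e-12)
  }
})

test_that("white-noise kymographs decorrelate beyond the origin", {
  set.seed(3)
  k <- kymograph(matrix(rnorm(100 * 200), 100, 200), ds = 1, dt = 1,
                 periodic = TRUE)
  cm <- autocorrelation_2d(k, max_lag_t = 80)
  off <- cm$c
  off[which(cm$ds_lags == 0), which(cm$dt_lags == 0)] <- 0
  expect_lt(max(abs(off)), 0.1)
  ## zero variance errors
  expect_error(autocorrelation_2d(kymograph(matrix(1, 8, 8), 1, 1,
                                            periodic = TRUE)),
               "variance")
})

test_that("temporal stripes produce correlation maxima at multiples of
           the period", {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 12,
                      shape = c(200L, 1L, 1L), lateral_speed = 0.12,
                      firing_period = 360, noise_sigma = 0)
  k <- make_kymograph_direct(p, "pulses", length_um = 64, n_sites = 4)
  cm <- autocorrelation_2d(segment_kymograph(k$kymograph),
                           max_lag_t = 90)
  ct <- correlation_cuts(cm)$ct
  pos <- ct[ct$dt_s >= 0, ]
  near <- function(T0) pos$c[which.min(abs(pos$dt_s - T0))]
  expect_gt(near(360), 0.5)
  expect_gt(near(720), 0.4)
  expect_lt(near(180), 0)  # anti-phase trough between events
})

test_that("averaging identical maps is the identity; four equal sites
           give four spatial maxima", {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 12,
                      shape = c(150L, 1L, 1L), lateral_speed = 0.12,
                      firing_period = 360, noise_sigma = 0)
  k <- make_kymograph_direct(p, "pulses", length_um = 64, n_sites = 4)
  cm <- autocorrelation_2d(segment_kymograph(k$kymograph),
                           max_lag_t = 60)
  avg <- average_correlation(list(cm, cm, cm))
  expect_equal(avg$c, cm$c)
  cs <- correlation_cuts(cm)$cs
  n <- nrow(cs)
  peaks <- which(diff(sign(diff(cs$c))) == -2) + 1
  expect_identical(sum(cs$c[peaks] > 0.1), 3L)  # at lags -16, 0+wrap...
  ## the periodic axis has period L/4 = 16 µm
  expect_gt(cs$c[which.min(abs(cs$ds_um - 16))], 0.3)
  expect_error(average_correlation(list()), "no correlation maps")
})

test_that("period extraction finds the first recurrence maximum", {
  lag <- seq(0, 1200, by = 10)
  expect_equal(period_from_cut(
    data.frame(dt_s = lag, c = cos(2 * pi * lag / 360))), 360)
  expect_true(is.na(period_from_cut(
    data.frame(dt_s = lag, c = exp(-lag / 300)))))
  ## noisy kymograph at signal-to-noise ~5: period within one bin
  for (seed in 1:3) {
    p <- phantom_params(pixel_size = 0.5, frame_interval = 12,
                        shape = c(200L, 1L, 1L), lateral_speed = 0.12,
                        firing_period = 360, noise_sigma = 0.16,
                        rng_seed = seed)
    k <- make_kymograph_direct(p, "pulses", length_um = 64, n_sites = 4)
    cm <- autocorrelation_2d(segment_kymograph(k$kymograph),
                             max_lag_t = 90)
    expect_lt(abs(period_from_cut(cm) - 360), 12 + 1e-9)
  }
})

test_that("Radon velocities are unbiased across speeds and respect
           symmetry", {
  for (v in c(0.05, 0.1, 0.2, 0.4)) {
    p <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                        shape = c(120L, 1L, 1L), lateral_speed = v,
                        noise_sigma = 0)
    k <- make_kymograph_direct(p, "stripes", length_um = 48,
                               n_stripes = 2)
    cm <- autocorrelation_2d(segment_kymograph(k$kymograph),
                             max_lag_t = 40)
    rv <- radon_velocity(cm)
    expect_true(rv$significant)
    expect_lt(abs(rv$velocities_um_s[1] - v) / v, 0.05)
  }
  ## bidirectional stripes give a +/- pair
  p <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                      shape = c(120L, 1L, 1L), lateral_speed = 0.12,
                      noise_sigma = 0)
  k2 <- make_kymograph_direct(p, "stripes", length_um = 48,
                              n_stripes = 2, both_directions = TRUE)
  rv2 <- radon_velocity(autocorrelation_2d(
    segment_kymograph(k2$kymograph), max_lag_t = 40))
  expect_identical(length(rv2$velocities_um_s), 2L)
  expect_equal(sort(rv2$velocities_um_s),
               sort(-rv2$velocities_um_s), tolerance = 0.01)
})

test_that("static stripes give zero velocity; isotropic maps give
           none", {
  p0 <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                       shape = c(120L, 1L, 1L), lateral_speed = 0,
                       noise_sigma = 0)
  k0 <- make_kymograph_direct(p0, "stripes", length_um = 48,
                              n_stripes = 2)
  rv0 <- radon_velocity(autocorrelation_2d(
    segment_kymograph(k0$kymograph), max_lag_t = 40))
  expect_true(rv0$significant)
  expect_equal(rv0$velocities_um_s[1], 0, tolerance = 1e-6)
  ## white noise: no dominant orientation
  set.seed(1)
  kn <- kymograph(matrix(rnorm(64 * 80), 64, 80), ds = 0.5, dt = 10,
                  periodic = TRUE)
  rvn <- radon_velocity(autocorrelation_2d(kn, max_lag_t = 30))
  expect_false(rvn$significant)
  expect_length(rvn$velocities_um_s, 0)
})

test_that("event detection localises initiations and classifies
           collisions", {
  ## single firing site
  p <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                      shape = c(100L, 1L, 1L), lateral_speed = 0.12,
                      firing_period = 600, noise_sigma = 0)
  k <- make_kymograph_direct(p, "pulses", length_um = 48, n_sites = 1)
  ev <- detect_events(segment_kymograph(k$kymograph))
  ini <- ev[ev$type == "initiation", ]
  expect_identical(nrow(ini), 2L)          # two firings
  expect_lt(abs(ini$s_um[1] - 24), 1)      # site +/- 2 bins
  expect_lt(abs(ini$t_s[1] - 0), 21)
  ## annihilate-mode collision: one mutual event
  pc <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                       shape = c(35L, 1L, 1L), lateral_speed = 0.12,
                       terminal_gap = 12, noise_sigma = 0)
  kc <- make_kymograph_direct(pc, "collision", length_um = 64)
  evc <- detect_events(segment_kymograph(kc$kymograph))
  col <- evc[evc$type == "collision", ]
  expect_identical(nrow(col), 1L)
  expect_identical(col$class, "mutual")
  ## cross mode: one pulse survives
  kx <- make_kymograph_direct(pc, "collision", length_um = 64,
                              outcome = "cross")
  evx <- detect_events(segment_kymograph(kx$kymograph))
  expect_identical(evx$class[evx$type == "collision"], "one_survives")
  ## empty segmentation: empty table
  e <- suppressWarnings(detect_events(
    kymograph(matrix(0, 16, 16), 0.5, 10, periodic = TRUE)))
  expect_identical(nrow(e), 0L)
})

test_that("terminal gaps are measured at the last visible columns", {
  base <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                         shape = c(35L, 1L, 1L), lateral_speed = 0.12,
                         noise_sigma = 0)
  for (g in c(12, 5)) {
    p <- base
    p$terminal_gap <- g
    p$front_width <- if (g < 8) 2.5 else 5  # keep fronts distinct
    k <- make_kymograph_direct(p, "collision", length_um = 64)
    expect_lt(abs(terminal_gap(k$kymograph) - g), 0.5)
  }
  p0 <- base
  p0$terminal_gap <- 0
  k0 <- make_kymograph_direct(p0, "collision", length_um = 64)
  expect_lt(abs(terminal_gap(k0$kymograph)), 0.5)
})

test_that("collision classification recovers ensemble labels
           perfectly", {
  ens <- make_collision_ensemble(30, 0.6, seed = 7)
  pred <- vapply(ens$kymographs, function(k) {
    ev <- detect_events(segment_kymograph(k))
    ev <- ev[ev$type == "collision", , drop = FALSE]
    if (!nrow(ev)) return(NA_character_)
    ev$class[1]
  }, "")
  expect_identical(pred, ens$labels)
})

test_that("rotation counting matches the spiral ground truth", {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 21,
                      shape = c(201L, 96L, 96L), nucleus_radius = 4,
                      cell_radius = 20, rotation_period = 525,
                      noise_sigma = 0)
  sp <- make_spiral_stack(p)
  cr <- count_rotations(sp$stack, center = p$center, radius = 12)
  expect_identical(cr$rotations, 8)
  ## half duration: four rotations
  p2 <- p
  p2$shape <- c(101L, 96L, 96L)
  sp2 <- make_spiral_stack(p2)
  expect_identical(
    count_rotations(sp2$stack, center = p$center, radius = 12)$rotations,
    4)
  ## a static pattern does not rotate
  st <- sp$stack
  st$img <- st$img[, , rep(1, 20)]
  expect_identical(
    count_rotations(st, center = p$center, radius = 12)$rotations, 0)
  ## intermittent signal gaps beyond 25% of frames error out
  gappy <- sp$stack
  gappy$img[, , seq(1, 201, by = 2)] <- 1
  expect_error(count_rotations(gappy, center = p$center, radius = 12),
               "missing")
})
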