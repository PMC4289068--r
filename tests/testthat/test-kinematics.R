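test_that("uniform expansion and shrinkage give the exact signed
           velocity", {
  v <- local_normal_velocity(circle_contour(10), circle_contour(11),
                             dt = 10)
  expect_equal(v, rep(0.10, 100), tolerance = 1e-9)
  v2 <- local_normal_velocity(circle_contour(11), circle_contour(10),
                              dt = 10)
  expect_equal(v2, rep(-0.10, 100), tolerance = 1e-9)
})

test_that("translation velocities match the exact ray-circle
           intersection", {
  d <- 0.3
  th <- 2 * pi * (0:199) / 200
  v <- local_normal_velocity(circle_contour(10, 200),
                             circle_contour(10, 200, cx = d), dt = 10)
  ## closed form: (t + R)^2 - 2 (t + R) d cos(th) + d^2 = R^2
  t_exact <- vapply(th, function(a) {
    b <- -2 * d * cos(a)
    u <- (-b + c(1, -1) * sqrt(b^2 - 4 * (d^2 - 100))) / 2
    min(u[u > 0]) - 10
  }, 0)
  expect_lt(max(abs(v - t_exact / 10)), 1e-3)
  ## and the small-d approximation (d / dt) cos(theta) within 2%
  expect_lt(max(abs(v - (d / 10) * cos(th))), 0.02 * d / 10)
})

test_that("unrelated contours raise an error", {
  expect_error(
    local_normal_velocity(circle_contour(2), circle_contour(2, cx = 50),
                          dt = 1, cutoff = 5),
    "unrelated")
})

test_that("curvature recovers circles, lines and ellipse vertices", {
  k <- local_curvature(resample_contour(circle_contour(10, 400), 0.8))
  expect_lt(max(abs(k - 0.1)) / 0.1, 0.01)
  ## circles at and above 5 µm radius stay within 1%
  for (R in c(5, 8, 15)) {
    kr <- local_curvature(resample_contour(circle_contour(R, 600), 0.8))
    expect_lt(max(abs(kr - 1 / R)) * R, 0.01)
  }
  ## straight edges of a rectangle are flat
  rect <- contour(
    c(seq(0, 20, by = 0.4), rep(20, 19), seq(20, 0, by = -0.4),
      rep(0, 19)),
    c(rep(0, 51), seq(0.4, 7.6, by = 0.4), rep(8, 51),
      seq(7.6, 0.4, by = -0.4)))
  kr <- local_curvature(rect, window = 1.2)
  expect_lt(max(abs(kr[20:30])), 1e-6)
  ## ellipse vertex: curvature a / b^2
  a <- 10; b <- 5
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  ell <- resample_contour(contour(a * cos(th), b * sin(th)), 0.2)
  ke <- local_curvature(ell, window = 0.6)
  iv <- which.min((ell$x - a)^2 + ell$y^2)
  expect_lt(abs(ke[iv] - a / b^2) / (a / b^2), 0.02)
  expect_error(local_curvature(circle_contour(5, 50), window = 0.01),
               "window")
})

test_that("enclosed area is the shoelace area of simple polygons", {
  expect_equal(enclosed_area(contour(c(0, 1, 1, 0), c(0, 0, 1, 1))), 1)
  a100 <- enclosed_area(circle_contour(10, 100))
  expect_lt(abs(a100 - pi * 100) / (pi * 100), 0.003)
  expect_error(
    enclosed_area(contour(c(0, 4, 4, 2, 0), c(0, 0, 3, -1, 3))),
    "self-intersecting")
  ## degenerate collinear polygon: zero area, no crossing
  expect_equal(enclosed_area(contour(c(0, 1, 2), c(0, 0, 0))), 0)
})

test_that("series kinematics matches the generating parabola", {
  ## analytic ground-truth contours of a parabolic ring
  p <- phantom_params(pixel_size = 0.5, frame_interval = 5,
                      shape = c(34L, 128L, 128L), v0 = 0.2, t_rev = 100,
                      noise_sigma = 0)
  gt <- make_ring_stack(p)$ground_truth
  idx <- 5:34
  ser <- contour_series(idx - 1L, (idx - 1) * 5, gt$contours[idx],
                        0.5, 5)
  kin <- series_kinematics(ser)
  pf <- kin$per_frame
  va <- p$v0 * (1 - pf$time_s / p$t_rev)
  inner <- 2:(nrow(pf) - 1)  # one-sided endpoint estimates excluded
  expect_lt(max(abs(pf$v_mean_um_s[inner] - va[inner])),
            0.05 * p$v0)
  ## normalized area peaks at exactly 1 at the maximal-area frame
  expect_identical(max(pf$a), 1)
  expect_identical(which.max(pf$a), which.max(pf$area_um2))
  ## divergence-theorem consistency: dA/dt vs perimeter * v_mean
  n <- nrow(pf)
  dA <- (pf$area_um2[3:n] - pf$area_um2[1:(n - 2)]) / (2 * 5)
  per <- vapply(ser$contours, contour_perimeter, 0)[2:(n - 1)]
  ratio <- dA / (per * pf$v_mean_um_s[2:(n - 1)])
  expect_true(all(abs(ratio - 1) < 0.1, na.rm = TRUE))
})

test_that("a static series has zero mean velocity", {
  cons <- replicate(4, circle_contour(8, 120), simplify = FALSE)
  ser <- contour_series(0:3, (0:3) * 10, cons, 0.5, 10)
  kin <- series_kinematics(ser)
  expect_equal(kin$per_frame$v_mean_um_s, rep(0, 4), tolerance = 1e-12)
})

test_that("the velocity-area collapse is monotone and
           median-invariant", {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 5,
                      shape = c(34L, 128L, 128L), v0 = 0.2, t_rev = 100,
                      noise_sigma = 0)
  gt <- make_ring_stack(p)$ground_truth
  idx <- 5:34
  ser <- contour_series(idx - 1L, (idx - 1) * 5, gt$contours[idx],
                        0.5, 5)
  kin <- series_kinematics(ser)
  cu <- velocity_area_collapse(kin)
  b <- cu$bins[cu$bins$n > 0, ]
  expect_true(all(diff(b$v_med) < 1e-9))  # decreasing in a
  ## duplicating the wave leaves the medians unchanged
  cu2 <- velocity_area_collapse(list(kin, kin))
  expect_equal(cu$bins$v_med, cu2$bins$v_med)
  ## bins tile [0, 1]
  expect_equal(cu$bins$bin_lo[1], 0)
  expect_equal(cu$bins$bin_hi[nrow(cu$bins)], 1)
})

test_that("the quartic collapse extrapolates v0 across speeds", {
  for (v0 in c(0.05, 0.2, 0.5)) {
    t_rev <- 25 / v0              # maximal radius 12.5 µm for all v0
    dt <- t_rev / 40
    p <- phantom_params(pixel_size = 0.5, frame_interval = dt,
                        shape = c(47L, 128L, 128L), v0 = v0,
                        t_rev = t_rev, noise_sigma = 0)
    gt <- make_ring_stack(p)$ground_truth
    keep <- which(gt$frames$radius_um > 2.5 &
                    gt$frames$time_s <= t_rev * 1.15)
    ser <- contour_series(keep - 1L, gt$frames$time_s[keep],
                          gt$contours[keep], 0.5, dt)
    fit <- fit_extrapolate_v0(velocity_area_collapse(
      series_kinematics(ser)))
    expect_lt(abs(fit$v0 - v0) / v0, 0.05)
    expect_false(fit$nonparabolic)
  }
})

test_that("constant-velocity growth is flagged as non-parabolic", {
  Rlin <- seq(2, 12, by = 0.5)
  cons <- lapply(Rlin, circle_contour, n = 200)
  ser <- contour_series(seq_along(Rlin) - 1L,
                        (seq_along(Rlin) - 1) * 10, cons, 0.5, 10)
  fit <- fit_extrapolate_v0(velocity_area_collapse(
    series_kinematics(ser)))
  expect_true(fit$nonparabolic)
})

test_that("curvature carries no information about velocity on
           curvature-uniform waves", {
  ## expanding + translating circles: curvature uniform per frame,
  ## velocity angle-dependent
  n <- 40
  cons <- lapply(seq_len(n), function(i)
    circle_contour(8 + 0.05 * i, 150, cx = 0.02 * i))
  ser <- contour_series(seq_len(n) - 1L, (seq_len(n) - 1) * 10, cons,
                        0.5, 10)
  kin <- series_kinematics(ser)
  cv <- curvature_velocity_correlation(kin)
  expect_gt(cv$n, 100)
  expect_lt(abs(cv$r), 0.1)
})

test_that("an eikonal rule v = v0 - D kappa is detected as strong
           anticorrelation", {
  th <- 2 * pi * (0:299) / 300
  r <- 10 + 1.2 * cos(6 * th)
  c1 <- resample_contour(contour(r * cos(th), r * sin(th)), 0.4)
  k1 <- local_curvature(c1, 1.2)
  nor <- contour_normals(c1)
  disp <- (0.1 - 0.3 * k1) * 10
  c2 <- contour(c1$x + disp * nor[, 1], c1$y + disp * nor[, 2])
  ser <- contour_series(0:1, c(0, 10), list(c1, c2), 0.5, 10)
  kin <- series_kinematics(ser)
  cv <- curvature_velocity_correlation(kin, min_pairs = 100)
  expect_lt(cv$r, -0.9)
})

test_that("degenerate velocity fields give an undefined correlation", {
  cons <- lapply(c(10, 11, 12, 13), circle_contour, n = 150)
  ser <- contour_series(0:3, (0:3) * 10, cons, 0.5, 10)
  kin <- series_kinematics(ser)
  expect_error(curvature_velocity_correlation(kin), "variance")
})
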