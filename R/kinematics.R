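# Contour kinematics: per-point normal velocities by ray intersection
# with the next frame's contour, local curvature from circumscribed
# circles, enclosed areas, and the velocity versus normalized-area
# collapse. For a ring wave whose mean radius follows the parabola
# R(t) = v0 t - v0 t^2 / (2 t_rev), the normalized area
# a = (R / R_max)^2 and the mean front velocity v = dR/dt obey the
# closed-form quartic a(v) = (1 - (v/v0)^2)^2, i.e.
# v(a) = v0 sqrt(1 - sqrt(a)); fitting this one-parameter law to the
# binned collapse and evaluating it at a = 0 extrapolates the initial
# front velocity v0.

#' Per-point normal velocity between two contours
#'
#' For each point of `c_t`, casts a bidirectional ray along the local
#' outward normal and intersects it with the polygon `c_next`
#' (interpolating linearly between its points). The signed distance to
#' the nearest intersection divided by the frame interval is the local
#' normal velocity: positive for outward motion (wave growth), negative
#' for shrinkage. Points with no intersection within `cutoff` are
#' returned as `NA` (missing).
#'
#' @param c_t,c_next `cdr_contour` objects (µm).
#' @param dt Time between the contours, s (> 0).
#' @param cutoff Maximal search distance along the ray, µm.
#' @return Numeric vector of velocities (µm/s), one per point of `c_t`,
#'   `NA` where missing.
#' @export
local_normal_velocity <- function(c_t, c_next, dt, cutoff = 5) {
  stopifnot(dt > 0)
  nor <- contour_normals(c_t)
  n2 <- length(c_next$x)
  j <- c(2:n2, 1L)
  ax <- c_next$x
  ay <- c_next$y
  dx <- c_next$x[j] - ax
  dy <- c_next$y[j] - ay
  n <- length(c_t$x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    px <- c_t$x[i]
    py <- c_t$y[i]
    nx <- nor[i, 1]
    ny <- nor[i, 2]
    ## p + t n = a + u d  =>  solve per segment
    den <- nx * dy - ny * dx
    ex <- ax - px
    ey <- ay - py
    tt <- (ex * dy - ey * dx) / den
    uu <- (ex * ny - ey * nx) / den
    ## epsilon admits exact vertex hits despite floating-point jitter
    ok <- is.finite(tt) & is.finite(uu) & uu >= -1e-9 & uu < 1 + 1e-9 &
      abs(tt) <= cutoff
    if (!any(ok)) next
    tc <- tt[ok]
    best <- which(abs(tc) == min(abs(tc)))
    ## tie between inward and outward hit: prefer outward
    out[i] <- max(tc[best]) / dt
  }
  if (all(is.na(out)))
    stop("no ray intersections found: contours appear unrelated")
  out
}

#' Local signed curvature of a contour
#'
#' Curvature at each point from the circumscribed circle through the
#' point and its neighbours at `+/- window` arc length, signed positive
#' where the contour is convex with respect to the outward normal.
#'
#' @param con A resampled `cdr_contour`.
#' @param window Arc-length half-window in µm (default 2.4 µm, i.e.
#'   three 0.8 µm spacings).
#' @return Numeric vector of curvatures (1/µm).
#' @export
local_curvature <- function(con, window = 2.4) {
  n <- length(con$x)
  spacing <- contour_perimeter(con) / n
  if (window < spacing)
    stop("curvature window must be at least one point spacing")
  k <- max(1L, round(window / spacing))
  ip <- ((seq_len(n) - 1 + k) %% n) + 1
  im <- ((seq_len(n) - 1 - k) %% n) + 1
  x1 <- con$x[im]; y1 <- con$y[im]
  x2 <- con$x;     y2 <- con$y
  x3 <- con$x[ip]; y3 <- con$y[ip]
  ## circumscribed circle of three points
  d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  s1 <- x1^2 + y1^2
  s2 <- x2^2 + y2^2
  s3 <- x3^2 + y3^2
  ux <- (s1 * (y2 - y3) + s2 * (y3 - y1) + s3 * (y1 - y2)) / d
  uy <- (s1 * (x3 - x2) + s2 * (x1 - x3) + s3 * (x2 - x1)) / d
  R <- sqrt((x2 - ux)^2 + (y2 - uy)^2)
  cross <- (x2 - x1) * (y3 - y2) - (y2 - y1) * (x3 - x2)
  kappa <- sign(cross) / R
  kappa[!is.finite(kappa)] <- 0  # collinear points: zero curvature
  kappa
}

#' Enclosed area of a simple closed contour
#'
#' Shoelace area; positive for the counter-clockwise orientation
#' enforced by [contour()]. Self-intersecting polygons are rejected.
#'
#' @param con A `cdr_contour`.
#' @return Area in µm².
#' @export
enclosed_area <- function(con) {
  if (!is_simple(con))
    stop("contour is self-intersecting; area undefined")
  shoelace(con$x, con$y)
}

#' Kinematics of a tracked contour series
#'
#' Computes per frame: per-point normal velocities, per-point curvature,
#' enclosed area, mean velocity and the normalized area
#' `a = A / max(A)` over the series (1 exactly at the maximal-area
#' frame). Forward velocities (frame i to i+1) are time-centred by
#' averaging the adjacent forward measurements, so the mean velocity of
#' frame i refers to time t_i rather than t_i + dt/2; the first and last
#' frames keep their one-sided estimates.
#'
#' @param series A [contour_series()] with at least 2 frames.
#' @param cutoff Ray-intersection cutoff per frame step, µm.
#' @param curvature_window Arc-length half-window, µm.
#' @return An object of class `cdr_kinematics`: list with `per_frame`
#'   (data.frame: frame, time_s, area_um2, a, v_mean_um_s, n_missing)
#'   and `per_point` (data.frame: frame, point, velocity_um_s,
#'   curvature_per_um).
#' @export
series_kinematics <- function(series, cutoff = 5, curvature_window = 2.4) {
  nf <- length(series$frames)
  if (nf < 2) stop("need at least 2 frames for kinematics")
  fwd <- vector("list", nf - 1L)
  fwd_mean <- numeric(nf - 1L)
  for (i in seq_len(nf - 1L)) {
    dt <- series$times[i + 1L] - series$times[i]
    v <- local_normal_velocity(series$contours[[i]],
                               series$contours[[i + 1L]], dt, cutoff)
    fwd[[i]] <- v
    fwd_mean[i] <- mean(v, na.rm = TRUE)
  }
  areas <- vapply(series$contours, enclosed_area, 0)
  a <- areas / max(areas)
  v_mean <- numeric(nf)
  v_mean[1] <- fwd_mean[1]
  v_mean[nf] <- fwd_mean[nf - 1L]
  if (nf > 2)
    v_mean[2:(nf - 1L)] <-
      (fwd_mean[1:(nf - 2L)] + fwd_mean[2:(nf - 1L)]) / 2
  pp <- do.call(rbind, lapply(seq_len(nf), function(i) {
    kap <- local_curvature(series$contours[[i]], curvature_window)
    v <- if (i < nf) fwd[[i]] else rep(NA_real_, length(kap))
    if (length(v) != length(kap)) v <- rep(NA_real_, length(kap))
    data.frame(frame = series$frames[i], point = seq_along(kap),
               velocity_um_s = v, curvature_per_um = kap)
  }))
  per_frame <- data.frame(
    frame = series$frames, time_s = series$times, area_um2 = areas,
    a = a, v_mean_um_s = v_mean,
    n_missing = c(vapply(fwd, function(v) sum(is.na(v)), 0L), NA))
  structure(list(per_frame = per_frame, per_point = pp,
                 frame_interval = series$frame_interval),
            class = "cdr_kinematics")
}

#' Velocity versus normalized-area collapse
#'
#' Pools `(a, v_mean)` points of the opening phase (`v_mean > 0`) over
#' one or several tracked waves and bins them in normalized area with a
#' fixed box width, the bin statistic being the median.
#'
#' @param kinematics A `cdr_kinematics` or a list of them.
#' @param bin_width Bin width in normalized area (default 0.05).
#' @param opening_only Keep only frames with positive mean velocity.
#' @return An object of class `cdr_va_curve`: list with `points`
#'   (pooled raw data.frame a, v) and `bins` (data.frame bin_lo, bin_hi,
#'   a_med, v_med, n).
#' @export
velocity_area_collapse <- function(kinematics, bin_width = 0.05,
                                   opening_only = TRUE) {
  if (inherits(kinematics, "cdr_kinematics"))
    kinematics <- list(kinematics)
  pts <- do.call(rbind, lapply(kinematics, function(k)
    k$per_frame[, c("a", "v_mean_um_s")]))
  names(pts) <- c("a", "v")
  if (opening_only) pts <- pts[pts$v > 0, , drop = FALSE]
  pts <- pts[is.finite(pts$a) & is.finite(pts$v), , drop = FALSE]
  if (!nrow(pts)) stop("no opening-phase points to pool")
  edges <- seq(0, 1, by = bin_width)
  idx <- findInterval(pts$a, edges, rightmost.closed = TRUE)
  bins <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    sel <- idx == b
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               a_med = if (any(sel)) stats::median(pts$a[sel]) else NA,
               v_med = if (any(sel)) stats::median(pts$v[sel]) else NA,
               n = sum(sel))
  }))
  structure(list(points = pts, bins = bins), class = "cdr_va_curve")
}

#' Extrapolate the initial front velocity from the collapse
#'
#' Fits the closed-form collapse implied by a parabolic radius
#' evolution, `v(a) = v0 sqrt(1 - sqrt(a))`, to the binned medians by
#' least squares (the model is linear in `v0`) and returns the
#' extrapolated velocity at zero area, `v(0) = v0`. A free fourth-order
#' polynomial fit is available as a fallback (`method = "quartic"`,
#' extrapolation = its intercept). The fit is flagged non-parabolic when
#' the residual RMSE exceeds 10% of the fitted `v0`.
#'
#' @param curve A `cdr_va_curve`.
#' @param method `"closed_form"` (default) or `"quartic"`.
#' @return A list with `v0` (µm/s), `rmse`, `nonparabolic` flag,
#'   `method` and `n_bins`.
#' @export
fit_extrapolate_v0 <- function(curve, method = c("closed_form",
                                                 "quartic")) {
  method <- match.arg(method)
  b <- curve$bins[curve$bins$n > 0, , drop = FALSE]
  if (nrow(b) < 5)
    stop("need at least 5 populated bins for extrapolation")
  a <- b$a_med
  v <- b$v_med
  if (method == "closed_form") {
    g <- sqrt(pmax(0, 1 - sqrt(a)))
    v0 <- sum(v * g) / sum(g^2)
    resid <- v - v0 * g
  } else {
    fit <- stats::lm(v ~ a + I(a^2) + I(a^3) + I(a^4))
    v0 <- unname(stats::coef(fit)[1])
    resid <- stats::residuals(fit)
  }
  rmse <- sqrt(mean(resid^2))
  if (!is.finite(v0)) stop("extrapolation fit did not converge")
  list(v0 = v0, rmse = rmse, nonparabolic = rmse > 0.1 * abs(v0),
       method = method, n_bins = nrow(b))
}

#' Cross-correlation of local curvature and local velocity
#'
#' Pearson correlation of pooled per-point (curvature, velocity) pairs
#' over a tracked series, plus a per-contour circular lag profile: the
#' mean over frames of the correlation between the curvature sequence
#' and the velocity sequence shifted by a number of points along the
#' contour.
#'
#' @param kinematics A `cdr_kinematics`.
#' @param max_lag Maximal shift in points for the lag profile.
#' @param min_pairs Minimal number of pooled pairs required.
#' @return A list with `r` (pooled Pearson coefficient), `n` and
#'   `lag_profile` (data.frame lag, r).
#' @export
curvature_velocity_correlation <- function(kinematics, max_lag = 10L,
                                           min_pairs = 100L) {
  pp <- kinematics$per_point
  ok <- is.finite(pp$velocity_um_s) & is.finite(pp$curvature_per_um)
  pp <- pp[ok, , drop = FALSE]
  if (nrow(pp) < min_pairs)
    stop(sprintf("need at least %d pooled (curvature, velocity) pairs",
                 min_pairs))
  if (stats::sd(pp$velocity_um_s) < 1e-10 ||
      stats::sd(pp$curvature_per_um) < 1e-10)
    stop("zero variance: curvature-velocity correlation undefined")
  r <- stats::cor(pp$curvature_per_um, pp$velocity_um_s)
  frames <- unique(pp$frame)
  lags <- (-max_lag):max_lag
  prof <- vapply(lags, function(L) {
    rs <- vapply(frames, function(f) {
      d <- pp[pp$frame == f, ]
      n <- nrow(d)
      if (n < 8) return(NA_real_)
      sh <- ((seq_len(n) - 1 + L) %% n) + 1
      if (stats::sd(d$velocity_um_s[sh]) == 0 ||
          stats::sd(d$curvature_per_um) == 0) return(NA_real_)
      stats::cor(d$curvature_per_um, d$velocity_um_s[sh])
    }, 0)
    mean(rs, na.rm = TRUE)
  }, 0)
  list(r = r, n = nrow(pp),
       lag_profile = data.frame(lag = lags, r = prof))
}
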