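# Gradient-vector-flow active contours for wavefront tracking.
#
# Wavefronts are intensity minima, so the edge map is the negated,
# range-normalised intensity (optionally pre-blurred); its gradient is
# diffused into a gradient vector flow (GVF) field with extended capture
# range. A closed snake converges in that field under
# elasticity/rigidity internal forces, then a per-point relaxation step
# samples the intensity profile along the local normal, fits a cubic and
# moves each point to the within-interval global minimum of the cubic —
# removing the bias of the snake's bending energy before curvature is
# measured. Contours are finally resampled to fixed arc spacing and
# low-pass smoothed.

#' Snake configuration
#'
#' @param alpha Elasticity weight (first-derivative penalty), 1/µm².
#' @param beta Rigidity weight (second-derivative penalty), 1/µm⁴.
#' @param step Evolution step size (implicit gradient step), µm² per
#'   iteration.
#' @param kappa External (GVF) force weight.
#' @param mu GVF regularisation; larger values give smoother fields.
#' @param gvf_iterations Iterations of the GVF diffusion.
#' @param snake_iterations Iteration cap of the snake evolution.
#' @param tolerance Convergence tolerance: maximal point displacement per
#'   iteration, µm.
#' @param profile_half_length Half-length of the normal intensity profile
#'   used by [relax_contour()], µm.
#' @param spacing Contour resampling spacing, µm (default 0.8 µm).
#' @param smooth_width Width (FWHM) of the final coordinate smoothing
#'   kernel, µm; of the order of the optical resolution limit.
#' @param edge_blur Gaussian blur (µm) applied to the edge map before the
#'   gradient is taken; 0 disables.
#' @return A list of class `cdr_snake_config`.
#' @export
snake_config <- function(alpha = 0.02, beta = 0.2, step = 1, kappa = 2,
                         mu = 0.2, gvf_iterations = 400,
                         snake_iterations = 200, tolerance = 0.05,
                         profile_half_length = 2, spacing = 0.8,
                         smooth_width = 0.8, edge_blur = 0.5) {
  cfg <- list(alpha = alpha, beta = beta, step = step, kappa = kappa,
              mu = mu, gvf_iterations = gvf_iterations,
              snake_iterations = snake_iterations, tolerance = tolerance,
              profile_half_length = profile_half_length,
              spacing = spacing, smooth_width = smooth_width,
              edge_blur = edge_blur)
  if (any(vapply(cfg, function(v) !is.numeric(v) || v < 0, TRUE)) ||
      cfg$spacing <= 0 || cfg$tolerance <= 0)
    stop("snake configuration values must be positive")
  class(cfg) <- "cdr_snake_config"
  cfg
}

## Shift a matrix by one cell with replicated (Neumann) borders.
#' @noRd
shift_up <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
#' @noRd
shift_down <- function(m) m[c(seq_len(nrow(m))[-1], nrow(m)), , drop = FALSE]
#' @noRd
shift_left <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
#' @noRd
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1], ncol(m)), drop = FALSE]

#' Gradient vector flow of an image's edge map
#'
#' Computes the edge map `f = (max(I) - I) / (max(I) - min(I))` (bright
#' at intensity minima), optionally pre-blurred, and diffuses its
#' gradient by fixed-point iteration of the GVF equations
#' `u <- u + dt (mu lap(u) - (u - fx)(fx² + fy²))` (likewise for v).
#' On constant images the field is zero everywhere.
#'
#' @param image Numeric matrix, finite values.
#' @param mu Regularisation parameter.
#' @param iterations Number of diffusion iterations.
#' @param edge_blur Gaussian sigma (px) applied to the edge map first.
#' @param dt Time step of the iteration (stability requires
#'   `dt * mu <= 1/4`).
#' @return A list of class `cdr_gvf` with matrices `u` (x-component,
#'   along columns) and `v` (y-component, along rows), in pixel units.
#' @export
gvf_field <- function(image, mu = 0.2, iterations = 400, edge_blur = 1,
                      dt = 1) {
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (dt * mu > 0.25) stop("unstable GVF iteration: need dt * mu <= 1/4")
  rng <- range(image)
  if (rng[2] > rng[1]) {
    f <- (rng[2] - image) / (rng[2] - rng[1])
  } else {
    f <- matrix(0, nrow(image), ncol(image))
  }
  if (edge_blur > 0) f <- EBImage::gblur(f, sigma = edge_blur)
  fx <- (shift_right(f) - shift_left(f)) / 2   # d/dx: along columns
  fy <- (shift_down(f) - shift_up(f)) / 2      # d/dy: along rows
  b <- fx^2 + fy^2
  u <- fx
  v <- fy
  for (i in seq_len(iterations)) {
    lap_u <- shift_up(u) + shift_down(u) + shift_left(u) +
      shift_right(u) - 4 * u
    lap_v <- shift_up(v) + shift_down(v) + shift_left(v) +
      shift_right(v) - 4 * v
    u <- u + dt * (mu * lap_u - b * (u - fx))
    v <- v + dt * (mu * lap_v - b * (v - fy))
  }
  structure(list(u = u, v = v), class = "cdr_gvf")
}

## Cyclic internal-energy matrix for n points at spacing h:
## I + step * (alpha K2 / h^2 + beta K4 / h^4), returned factorised as its
## inverse for repeated solves.
#' @noRd
snake_internal_inverse <- function(n, cfg) {
  h <- cfg$spacing
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  K <- matrix(0, n, n)
  a <- cfg$alpha / h^2
  b <- cfg$beta / h^4
  for (i in seq_len(n)) {
    K[i, i] <- 2 * a + 6 * b
    K[i, idx(1)[i]] <- K[i, idx(-1)[i]] <- -a - 4 * b
    K[i, idx(2)[i]] <- K[i, idx(-2)[i]] <- b
  }
  solve(diag(n) + cfg$step * K)
}

#' Evolve a snake in a GVF field
#'
#' Iterates the balance of internal (elasticity/rigidity) and external
#' (GVF) forces with an implicit scheme,
#' `x_new = (I + step (alpha K2 + beta K4))^{-1} (x + step kappa F(x))`,
#' resampling to even arc spacing after each iteration, until the maximal
#' point displacement per iteration falls below the tolerance or the
#' iteration cap is reached.
#'
#' Resampling is applied every `resample_every` iterations rather than
#' every step: each linear resampling moves points onto chords and would
#' otherwise accumulate into a systematic inward drift.
#'
#' @param init Initial `cdr_contour` (µm) inside the image.
#' @param field A [gvf_field()] of the frame.
#' @param image The frame (used only for bounds).
#' @param config A [snake_config()].
#' @param pixel_size µm per pixel.
#' @param iterations Optional override of the iteration cap.
#' @param resample_every Iterations between arc-length resamplings.
#' @return The converged `cdr_contour`; attribute `iterations` records
#'   the number used.
#' @export
evolve_snake <- function(init, field, image, config = snake_config(),
                         pixel_size, iterations = NULL,
                         resample_every = 10L) {
  cfg <- config
  it_max <- iterations %||% cfg$snake_iterations
  con <- resample_contour(init, cfg$spacing)
  n_last <- length(con$x)
  Minv <- snake_internal_inverse(n_last, cfg)
  used <- 0L
  for (it in seq_len(it_max)) {
    x <- con$x
    y <- con$y
    rows <- um_to_idx(y, pixel_size)
    cols <- um_to_idx(x, pixel_size)
    fu <- bilinear(field$u, rows, cols)
    fv <- bilinear(field$v, rows, cols)
    fu[is.na(fu)] <- 0
    fv[is.na(fv)] <- 0
    mag <- sqrt(fu^2 + fv^2)
    scale <- ifelse(mag > 1, 1 / mag, 1)  # cap force magnitude at 1
    xf <- x + cfg$step * cfg$kappa * fu * scale * pixel_size
    yf <- y + cfg$step * cfg$kappa * fv * scale * pixel_size
    xn <- as.vector(Minv %*% xf)
    yn <- as.vector(Minv %*% yf)
    disp <- max(sqrt((xn - x)^2 + (yn - y)^2))
    con2 <- tryCatch({
      con_new <- contour(xn, yn)
      if (it %% resample_every == 0L)
        resample_contour(con_new, cfg$spacing)
      else con_new
    }, error = function(e)
      stop("tracking lost: contour collapsed during evolution"))
    if (contour_perimeter(con2) < 3 * cfg$spacing)
      stop("tracking lost: contour collapsed during evolution")
    if (length(con2$x) != n_last) {
      n_last <- length(con2$x)
      Minv <- snake_internal_inverse(n_last, cfg)
    }
    con <- con2
    used <- it
    if (disp < cfg$tolerance) break
  }
  con <- resample_contour(con, cfg$spacing)
  attr(con, "iterations") <- used
  con
}

#' Sub-pixel relaxation of contour points onto the intensity minimum
#'
#' For each point, samples the bilinearly interpolated intensity along
#' the local outward normal over `+/- profile_half_length`, fits a cubic
#' polynomial to the profile and moves the point to the global minimum of
#' that cubic inside the sampled interval. Points whose cubic has no
#' interior minimum (flat or monotone profiles) are left unchanged, as
#' are points whose profile would leave the image; the latter are flagged
#' in the `flagged` attribute.
#'
#' @param con A `cdr_contour` (µm).
#' @param image Frame matrix.
#' @param pixel_size µm per pixel.
#' @param profile_half_length Half-length of the profile, µm.
#' @param n_samples Samples along the profile (odd; default 13).
#' @return The relaxed contour with attribute `flagged` (integer indices
#'   of out-of-bounds points).
#' @export
relax_contour <- function(con, image, pixel_size,
                          profile_half_length = 2, n_samples = 13L) {
  nor <- contour_normals(con)
  n <- length(con$x)
  s <- seq(-profile_half_length, profile_half_length,
           length.out = n_samples)
  S2 <- s^2
  S3 <- s^3
  x <- con$x
  y <- con$y
  flagged <- integer(0)
  for (i in seq_len(n)) {
    px <- con$x[i] + s * nor[i, 1]
    py <- con$y[i] + s * nor[i, 2]
    prof <- bilinear(image, um_to_idx(py, pixel_size),
                     um_to_idx(px, pixel_size))
    if (anyNA(prof)) {
      flagged <- c(flagged, i)
      next
    }
    fit <- stats::lm.fit(cbind(1, s, S2, S3), prof)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    ## critical points of c0 + c1 s + c2 s^2 + c3 s^3
    if (abs(cf[4]) > 1e-12) {
      disc <- 4 * cf[3]^2 - 12 * cf[4] * cf[2]
      if (disc <= 0) next
      roots <- (-2 * cf[3] + c(-1, 1) * sqrt(disc)) / (6 * cf[4])
      mins <- roots[2 * cf[3] + 6 * cf[4] * roots > 0]
    } else if (abs(cf[3]) > 1e-12) {
      r <- -cf[2] / (2 * cf[3])
      mins <- if (cf[3] > 0) r else numeric(0)
    } else {
      next  # flat / linear profile: no interior minimum
    }
    mins <- mins[mins > s[1] & mins < s[n_samples]]
    if (!length(mins)) next
    val <- cf[1] + cf[2] * mins + cf[3] * mins^2 + cf[4] * mins^3
    sm <- mins[which.min(val)]
    x[i] <- con$x[i] + sm * nor[i, 1]
    y[i] <- con$y[i] + sm * nor[i, 2]
  }
  out <- contour(x, y)
  attr(out, "flagged") <- flagged
  out
}

#' Track a wavefront through an image stack
#'
#' Runs, for every frame of `frame_range`, the pipeline
#' [evolve_snake()] then [relax_contour()] then [resample_contour()] then
#' [smooth_contour()], seeding each frame with the previous frame's
#' result. The seed contour initialises the first frame. If tracking is
#' lost the partial series is returned with a warning; the attribute
#' `last_good_frame` records the final tracked frame index.
#'
#' @param stack A [image_stack()].
#' @param seed Seed `cdr_contour` (µm) drawn on the first frame of the
#'   range.
#' @param config A [snake_config()].
#' @param frame_range Integer frame indices (1-based); default all.
#' @return A [contour_series()].
#' @export
track_sequence <- function(stack, seed, config = snake_config(),
                           frame_range = NULL) {
  frame_range <- frame_range %||% seq_len(n_frames(stack))
  ps <- stack$pixel_size
  cur <- seed
  contours <- list()
  done <- integer(0)
  for (fi in frame_range) {
    img <- stack$img[, , fi]
    res <- tryCatch({
      field <- gvf_field(img, mu = config$mu,
                         iterations = config$gvf_iterations,
                         edge_blur = config$edge_blur / ps)
      sn <- evolve_snake(cur, field, img, config, pixel_size = ps)
      rx <- relax_contour(sn, img, ps,
                          profile_half_length = config$profile_half_length)
      rs <- resample_contour(rx, config$spacing)
      smooth_contour(rs, config$smooth_width)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("tracking lost at frame %d: %s", fi,
                      conditionMessage(res)))
      break
    }
    contours[[length(contours) + 1L]] <- res
    done <- c(done, fi)
    cur <- res
  }
  if (!length(done)) stop("tracking failed on the first frame")
  out <- contour_series(done - 1L, (done - 1) * stack$frame_interval,
                        contours, ps, stack$frame_interval)
  attr(out, "last_good_frame") <- done[length(done)] - 1L
  out
}
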