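#' Closed wavefront contour
#'
#' An ordered closed polygon in micrometres describing the position of a
#' wavefront. Contours are stored counter-clockwise (positive shoelace
#' area), so that outward normals — and with them the sign of normal
#' velocities — are well defined. A duplicated closing point is dropped on
#' construction and the orientation is enforced by reversal if needed.
#'
#' @param x,y Numeric coordinates in µm (equal length, >= 3 points).
#' @return An object of class `cdr_contour` with fields `x` and `y`.
#' @export
contour <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (length(x) < 3) stop("a contour needs at least 3 distinct points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("contour coordinates must be finite")
  if (shoelace(x, y) < 0) {
    x <- rev(x)
    y <- rev(y)
  }
  structure(list(x = x, y = y), class = "cdr_contour")
}

#' @noRd
shoelace <- function(x, y) {
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Contour point matrix
#' @param con A `cdr_contour`.
#' @return An `n x 2` matrix of (x, y) in µm.
#' @export
contour_points <- function(con) cbind(x = con$x, y = con$y)

#' Perimeter of a closed contour
#' @param con A `cdr_contour`.
#' @return Perimeter in µm.
#' @export
contour_perimeter <- function(con) {
  j <- c(seq_along(con$x)[-1], 1L)
  sum(sqrt((con$x[j] - con$x)^2 + (con$y[j] - con$y)^2))
}

#' Outward unit normals of a contour
#'
#' Tangents are estimated by central differences over the closed point
#' sequence; for the counter-clockwise orientation enforced by
#' [contour()], the outward normal is the tangent rotated by -90 degrees.
#'
#' @param con A `cdr_contour`.
#' @return An `n x 2` matrix of unit outward normals.
#' @export
contour_normals <- function(con) {
  n <- length(con$x)
  ip <- c(2:n, 1L)
  im <- c(n, 1:(n - 1L))
  tx <- con$x[ip] - con$x[im]
  ty <- con$y[ip] - con$y[im]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(nx = ty / len, ny = -tx / len)
}

#' Test whether a closed polygon is simple
#'
#' Checks all non-adjacent edge pairs for crossings.
#'
#' @param con A `cdr_contour`.
#' @return Logical.
#' @export
is_simple <- function(con) {
  x <- con$x
  y <- con$y
  n <- length(x)
  j <- c(2:n, 1L)
  ax <- x; ay <- y
  bx <- x[j]; by <- y[j]
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]  # edge n wraps to vertex 1, adjacent
    if (!length(ks)) next
    d1x <- bx[i] - ax[i]; d1y <- by[i] - ay[i]
    d2x <- bx[ks] - ax[ks]; d2y <- by[ks] - ay[ks]
    den <- d1x * d2y - d1y * d2x
    ex <- ax[ks] - ax[i]; ey <- ay[ks] - ay[i]
    t1 <- (ex * d2y - ey * d2x) / den
    t2 <- (ex * d1y - ey * d1x) / den
    hit <- is.finite(t1) & is.finite(t2) &
      t1 > 0 & t1 < 1 & t2 > 0 & t2 < 1
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Resample a contour to equidistant arc-length spacing
#'
#' Re-parameterises the closed polygon by arc length and places
#' `round(perimeter / spacing)` points at equal spacing, interpolating
#' linearly along the polygon. The first point is preserved.
#'
#' @param con A `cdr_contour`.
#' @param spacing Target point spacing in µm (default 0.8 µm, matching the
#'   resolution limit of a 10x phase-contrast objective).
#' @return A resampled `cdr_contour`.
#' @export
resample_contour <- function(con, spacing = 0.8) {
  stopifnot(spacing > 0)
  per <- contour_perimeter(con)
  if (per < 3 * spacing)
    stop("contour perimeter shorter than 3 spacings; cannot resample")
  x <- c(con$x, con$x[1])
  y <- c(con$y, con$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  n_out <- max(3L, round(per / spacing))
  s_new <- per * (seq_len(n_out) - 1) / n_out
  xi <- stats::approx(s, x, xout = s_new, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = s_new, ties = "ordered")$y
  out <- contour(xi, yi)
  if (!is_simple(out))
    warning("resampled contour is self-intersecting")
  out
}

#' Smooth contour coordinates with a circular low-pass kernel
#'
#' Applies a wrap-around convolution of the x and y coordinate sequences
#' with a normalised Gaussian kernel whose full width at half maximum is
#' `kernel_width`. A width of zero (or much smaller than the point
#' spacing) leaves the contour unchanged. Used as the final step of the
#' tracking pipeline to suppress point-to-point jitter on the scale of the
#' optical resolution limit.
#'
#' @param con A `cdr_contour` (assumed approximately evenly spaced).
#' @param kernel_width Kernel width (FWHM) in µm.
#' @return A smoothed `cdr_contour`.
#' @export
smooth_contour <- function(con, kernel_width) {
  stopifnot(kernel_width >= 0)
  if (kernel_width == 0) return(con)
  spacing <- contour_perimeter(con) / length(con$x)
  sigma <- kernel_width / (2 * sqrt(2 * log(2)))
  taps <- gaussian_taps(sigma, spacing)
  if (length(taps) == 1L) return(con)
  contour(circ_filter(con$x, taps), circ_filter(con$y, taps))
}

#' @export
print.cdr_contour <- function(x, ...) {
  cat(sprintf("<cdr_contour> %d points, perimeter %.2f µm, area %.2f µm²\n",
              length(x$x), contour_perimeter(x), shoelace(x$x, x$y)))
  invisible(x)
}

#' Series of tracked contours
#'
#' One contour per tracked frame, index-aligned with frame times.
#'
#' @param frames Integer frame indices (0-based, strictly increasing).
#' @param times Frame times in seconds.
#' @param contours List of `cdr_contour` objects.
#' @param pixel_size,frame_interval Calibration shared by the series.
#' @return An object of class `cdr_contour_series`.
#' @export
contour_series <- function(frames, times, contours, pixel_size,
                           frame_interval) {
  stopifnot(length(frames) == length(times),
            length(frames) == length(contours))
  if (any(diff(frames) <= 0))
    stop("frame indices must be strictly increasing")
  structure(
    list(frames = as.integer(frames), times = as.numeric(times),
         contours = contours, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "cdr_contour_series"
  )
}

#' @export
print.cdr_contour_series <- function(x, ...) {
  cat(sprintf("<cdr_contour_series> %d frames (%d..%d), dt %.4g s\n",
              length(x$frames), min(x$frames), max(x$frames),
              x$frame_interval))
  invisible(x)
}

#' @export
length.cdr_contour_series <- function(x) length(x$frames)
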