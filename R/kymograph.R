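# Kymographs: intensity sampled along a fixed line or circle per frame,
# plotted against time. Propagating wavefronts appear as sloped dark
# stripes whose slope encodes the lateral speed. The circular variant has
# a periodic space axis (arc length along the sampling circle).

#' Calibrated kymograph
#'
#' @param values Numeric matrix, space (rows) by time (columns).
#' @param ds Spacing of the space axis in µm (> 0).
#' @param dt Spacing of the time axis in s (> 0).
#' @param periodic Logical; `TRUE` only for circular (arc-length)
#'   sampling.
#' @return An object of class `cdr_kymo`.
#' @export
kymograph <- function(values, ds, dt, periodic = FALSE) {
  stopifnot(is.matrix(values), ds > 0, dt > 0)
  structure(list(values = values, ds = ds, dt = dt,
                 periodic = isTRUE(periodic)),
            class = "cdr_kymo")
}

#' @export
print.cdr_kymo <- function(x, ...) {
  cat(sprintf(
    "<cdr_kymo> %d x %d (space x time), ds %.4g µm, dt %.4g s%s\n",
    nrow(x$values), ncol(x$values), x$ds, x$dt,
    if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Display a kymograph
#' @param x A `cdr_kymo`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cdr_kymo <- function(x, ...) {
  s <- idx_to_um(seq_len(nrow(x$values)), x$ds)
  t <- (seq_len(ncol(x$values)) - 1) * x$dt
  graphics::image(t, s, t(x$values), xlab = "time (s)", ylab = "s (µm)",
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

#' Kymograph along a straight line
#'
#' Samples the image intensity bilinearly along the segment from `p0` to
#' `p1` (µm) in every frame, with a step equal to the pixel size.
#'
#' @param stack A [image_stack()].
#' @param p0,p1 Endpoints `(x, y)` in µm.
#' @return A non-periodic [kymograph()].
#' @export
linear_kymograph <- function(stack, p0, p1) {
  ps <- stack$pixel_size
  len <- sqrt(sum((p1 - p0)^2))
  n <- floor(len / ps) + 1L
  tt <- (seq_len(n) - 1) * ps / len
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  rows <- um_to_idx(ys, ps)
  cols <- um_to_idx(xs, ps)
  H <- dim(stack$img)[1]
  W <- dim(stack$img)[2]
  if (any(rows < 1 | rows > H | cols < 1 | cols > W))
    stop("sampling line leaves the image")
  TT <- n_frames(stack)
  vals <- matrix(NA_real_, n, TT)
  for (f in seq_len(TT))
    vals[, f] <- bilinear(stack$img[, , f], rows, cols)
  kymograph(vals, ds = ps, dt = stack$frame_interval, periodic = FALSE)
}

#' Circular (periodic) kymograph
#'
#' Samples the image intensity along the arc length of a circle in every
#' frame; the space axis is periodic with period `2*pi*radius`. The
#' arc-length step equals one pixel to avoid aliasing.
#'
#' @param stack A [image_stack()].
#' @param center Circle centre `(x, y)` in µm.
#' @param radius Circle radius in µm.
#' @return A periodic [kymograph()].
#' @export
circular_kymograph <- function(stack, center, radius) {
  stopifnot(radius > 0)
  ps <- stack$pixel_size
  n <- max(8L, round(2 * pi * radius / ps))
  th <- 2 * pi * (seq_len(n) - 1) / n
  xs <- center[1] + radius * cos(th)
  ys <- center[2] + radius * sin(th)
  rows <- um_to_idx(ys, ps)
  cols <- um_to_idx(xs, ps)
  H <- dim(stack$img)[1]
  W <- dim(stack$img)[2]
  if (any(rows < 1 | rows > H | cols < 1 | cols > W))
    stop("sampling circle leaves the image")
  TT <- n_frames(stack)
  vals <- matrix(NA_real_, n, TT)
  for (f in seq_len(TT))
    vals[, f] <- bilinear(stack$img[, , f], rows, cols)
  kymograph(vals, ds = 2 * pi * radius / n, dt = stack$frame_interval,
            periodic = TRUE)
}

#' Minimum-intensity trace of a region of interest
#'
#' Smooths the ROI with a Gaussian of standard deviation `sigma` (µm) in
#' every frame and records the minimum intensity, turning wave passages
#' into negative peaks separated by high plateaus (the recovery periods).
#'
#' @param stack A [image_stack()].
#' @param roi `c(x0, y0, x1, y1)` in µm (inclusive rectangle).
#' @param sigma Gaussian standard deviation in µm; 0 for a plain minimum.
#' @return An object of class `cdr_trace`: list with `time_s`, `values`,
#'   `frame_interval`.
#' @export
roi_min_trace <- function(stack, roi, sigma = 2) {
  ps <- stack$pixel_size
  c0 <- max(1L, floor(um_to_idx(roi[1], ps)))
  r0 <- max(1L, floor(um_to_idx(roi[2], ps)))
  c1 <- min(dim(stack$img)[2], ceiling(um_to_idx(roi[3], ps)))
  r1 <- min(dim(stack$img)[1], ceiling(um_to_idx(roi[4], ps)))
  if (r1 < r0 || c1 < c0) stop("empty ROI")
  TT <- n_frames(stack)
  vals <- numeric(TT)
  for (f in seq_len(TT)) {
    ## smooth on the full frame so small ROIs see no border artifacts
    frame <- stack$img[, , f]
    if (sigma > 0)
      frame <- EBImage::gblur(frame, sigma = sigma / ps)
    vals[f] <- min(frame[r0:r1, c0:c1])
  }
  structure(list(time_s = frame_times(stack), values = vals,
                 frame_interval = stack$frame_interval),
            class = "cdr_trace")
}

#' Recovery times between wave events in an intensity trace
#'
#' Events are maximal runs of the trace below `threshold`; the recovery
#' time tau is the quiescent interval from the end of one event to the
#' onset of the next. Back-to-back events give tau = 0.
#'
#' @param trace A `cdr_trace` (or plain numeric vector; then
#'   `frame_interval` must be given).
#' @param threshold Event threshold; default midway between the trace
#'   median and its minimum.
#' @param frame_interval Sampling interval in s when `trace` is a bare
#'   vector.
#' @return A list with `tau` (s), `events`
#'   (data.frame onset/end frame indices, 0-based) and `threshold`.
#' @export
recovery_times <- function(trace, threshold = NULL,
                           frame_interval = NULL) {
  if (inherits(trace, "cdr_trace")) {
    v <- trace$values
    dt <- trace$frame_interval
  } else {
    v <- as.numeric(trace)
    dt <- frame_interval %||% stop("frame_interval required")
  }
  threshold <- threshold %||% ((stats::median(v) + min(v)) / 2)
  below <- v < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(onset = starts[r$values] - 1L,
                   end = ends[r$values] - 1L)
  if (nrow(ev) < 2) {
    if (nrow(ev) < 2) warning("fewer than 2 events; no recovery times")
    return(list(tau = numeric(0), events = ev, threshold = threshold))
  }
  tau <- (ev$onset[-1] - ev$end[-nrow(ev)] - 1L) * dt
  list(tau = tau, events = ev, threshold = threshold)
}

#' Maximal radial extension per event from a linear kymograph
#'
#' For a kymograph sampled along a line through the wave origin, each
#' event (a maximal run of frames containing wave pixels) shows a pair of
#' dark traces at `+/- R(t)`. Per time column the positions of the dark
#' runs are reduced to their centres; the radial extension is half the
#' spread of those centres, and `R_max` is its maximum over the event.
#'
#' @param kymo A [kymograph()] (non-periodic, line through the origin).
#' @param threshold Segmentation threshold; default Otsu.
#' @return data.frame with one row per event: `onset`, `end` (0-based
#'   time indices) and `rmax_um`.
#' @export
rmax_from_kymograph <- function(kymo, threshold = NULL) {
  bin <- segment_kymograph(kymo, threshold %||% "otsu")
  mask <- bin$values > 0
  any_col <- colSums(mask) > 0
  r <- rle(any_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev_on <- starts[r$values]
  ev_end <- ends[r$values]
  if (!length(ev_on))
    return(data.frame(onset = integer(0), end = integer(0),
                      rmax_um = numeric(0)))
  rmax <- mapply(function(a, b) {
    ext <- 0
    for (f in a:b) {
      cc <- run_centres(mask[, f], periodic = FALSE)
      if (length(cc) >= 1)
        ext <- max(ext, (max(cc) - min(cc)) * kymo$ds)
    }
    ext / 2
  }, ev_on, ev_end)
  data.frame(onset = ev_on - 1L, end = ev_end - 1L, rmax_um = rmax)
}

#' Box statistics of recovery time binned by wave size
#'
#' Bins `(R_max, tau)` pairs in `R_max` with a fixed box width and
#' reports median, 25th and 75th percentiles of tau plus counts per bin.
#'
#' @param rmax_um,tau_s Paired observations.
#' @param bin_width Box width in µm (default 10).
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `q25`, `median`,
#'   `q75`; empty bins are kept with `n = 0`.
#' @export
bin_tau_by_rmax <- function(rmax_um, tau_s, bin_width = 10) {
  stopifnot(length(rmax_um) == length(tau_s), length(tau_s) >= 1)
  lo <- floor(min(rmax_um) / bin_width) * bin_width
  hi <- ceiling(max(rmax_um) / bin_width + 1e-12) * bin_width
  edges <- seq(lo, max(hi, lo + bin_width), by = bin_width)
  idx <- findInterval(rmax_um, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    tt <- tau_s[idx == b]
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               n = length(tt),
               q25 = if (length(tt)) unname(stats::quantile(tt, .25)) else NA,
               median = if (length(tt)) stats::median(tt) else NA,
               q75 = if (length(tt)) unname(stats::quantile(tt, .75)) else NA)
  }))
  out
}

## Centres of runs of TRUE in a logical vector (optionally circular);
## returned as fractional 1-based indices (circular runs may wrap).
#' @noRd
run_centres <- function(v, periodic = FALSE) {
  n <- length(v)
  if (!any(v)) return(numeric(0))
  if (all(v)) return(NA_real_)  # degenerate: one run covering the ring
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  runs <- data.frame(start = starts[on], end = ends[on])
  if (periodic && v[1] && v[n]) {
    ## merge wrap-around run
    first <- 1L
    last <- nrow(runs)
    runs$start[first] <- runs$start[last] - n
    runs <- runs[-last, , drop = FALSE]
  }
  (runs$start + runs$end) / 2
}
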