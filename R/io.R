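# File formats. Image stacks and kymographs travel as multi-page 16-bit
# grayscale TIFF plus a YAML sidecar carrying the calibration (pixel
# size in µm, frame interval in s) — calibration lives in the sidecar
# rather than TIFF tags to keep the format dialect-free. Geometry tables
# (contours, events, traces) are CSV in µm and seconds with 0-based
# frame indices.

#' @noRd
sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an image stack as multi-page TIFF with a YAML sidecar
#'
#' Intensities are scaled by the stack maximum and quantised to 16 bits;
#' the scale is recorded in the sidecar so that [read_stack()] restores
#' the values (up to the 16-bit quantisation, which is applied
#' deterministically — writing what was read back is bit-identical).
#'
#' @param stack A [image_stack()].
#' @param path Output TIFF path; the sidecar goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  img <- stack$img
  vmax <- max(img, 1e-12)
  q <- round(pmax(img, 0) / vmax * 65535) / 65535
  pages <- lapply(seq_len(dim(q)[3]), function(i) q[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size,
                        frame_interval_s = stack$frame_interval,
                        value_max = vmax),
                   sidecar_path(path))
  invisible(path)
}

#' Read a calibrated image stack
#'
#' Reads a multi-page grayscale TIFF (8 or 16 bit). Calibration comes
#' from the YAML sidecar written by [write_stack()] or, failing that,
#' from the `pixel_size` / `frame_interval` arguments; a stack without
#' calibration is refused.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval Calibration overrides (µm/px, s).
#' @return A [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, TRUE)))
    stop("non-grayscale TIFF pages are not supported")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d), TRUE)))
    stop("ragged TIFF pages: all frames must share one size")
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  ps <- pixel_size %||% meta$pixel_size_um
  fi <- frame_interval %||% meta$frame_interval_s
  if (is.null(ps) || is.null(fi))
    stop("missing calibration: provide a YAML sidecar or explicit ",
         "pixel_size and frame_interval")
  vmax <- meta$value_max %||% 1
  img <- array(0, dim = c(d, length(pages)))
  for (i in seq_along(pages)) img[, , i] <- pages[[i]] * vmax
  image_stack(img, ps, fi)
}

#' Write a kymograph as TIFF + YAML sidecar
#' @param kymo A [kymograph()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  vmax <- max(kymo$values, 1e-12)
  q <- round(pmax(kymo$values, 0) / vmax * 65535) / 65535
  tiff::writeTIFF(q, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(ds_um = kymo$ds, dt_s = kymo$dt,
                        periodic = kymo$periodic, value_max = vmax),
                   sidecar_path(path))
  invisible(path)
}

#' Read a kymograph written by [write_kymograph()]
#' @param path TIFF path.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  if (!file.exists(sidecar_path(path)))
    stop("missing calibration sidecar for kymograph")
  meta <- yaml::read_yaml(sidecar_path(path))
  v <- tiff::readTIFF(path) * (meta$value_max %||% 1)
  kymograph(v, ds = meta$ds_um, dt = meta$dt_s,
            periodic = isTRUE(meta$periodic))
}

#' Write a contour series as CSV
#'
#' One row per contour point: `frame` (0-based), `time_s`,
#' `point_index` (1-based), `x_um`, `y_um`.
#'
#' @param series A [contour_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_series <- function(series, path) {
  rows <- do.call(rbind, lapply(seq_along(series$frames), function(i) {
    con <- series$contours[[i]]
    data.frame(frame = series$frames[i], time_s = series$times[i],
               point_index = seq_along(con$x), x_um = con$x,
               y_um = con$y)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a contour series CSV
#' @param path CSV written by [write_contour_series()].
#' @param pixel_size,frame_interval Calibration of the originating
#'   stack.
#' @return A [contour_series()].
#' @export
read_contour_series <- function(path, pixel_size = NA,
                                frame_interval = NA) {
  d <- utils::read.csv(path)
  frames <- sort(unique(d$frame))
  contours <- lapply(frames, function(f) {
    di <- d[d$frame == f, ]
    di <- di[order(di$point_index), ]
    contour(di$x_um, di$y_um)
  })
  times <- vapply(frames, function(f) d$time_s[d$frame == f][1], 0)
  if (is.na(frame_interval) && length(frames) > 1)
    frame_interval <- stats::median(diff(times) / diff(frames))
  contour_series(frames, times, contours, pixel_size, frame_interval)
}

#' Read a seed polygon CSV
#'
#' Expects columns `x_um`, `y_um` (or `x`, `y`).
#'
#' @param path CSV path.
#' @return A [contour()].
#' @export
read_seed_contour <- function(path) {
  d <- utils::read.csv(path)
  x <- d$x_um %||% d$x
  y <- d$y_um %||% d$y
  contour(x, y)
}

#' Binarize a stack in x-y-t
#'
#' Thresholds the full stack (wave pixels are intensities below the
#' threshold) for x-y-t visualisation of wave patterns such as spirals.
#' An optional mask zeroes artifact regions — the programmatic
#' replacement for manual artifact removal.
#'
#' @param stack A [image_stack()].
#' @param threshold `"otsu"` or a numeric gray value.
#' @param mask Optional logical/0-1 matrix (`H x W`) or array
#'   (`H x W x T`); `TRUE`/1 marks pixels to zero out.
#' @return A binary [image_stack()] (values 0/1).
#' @export
binarize_xyt <- function(stack, threshold = "otsu", mask = NULL) {
  v <- stack$img
  if (identical(threshold, "otsu")) {
    rng <- range(v)
    thr <- if (rng[2] <= rng[1]) rng[1] else
      rng[1] + EBImage::otsu((v - rng[1]) / (rng[2] - rng[1]),
                             range = c(0, 1)) * (rng[2] - rng[1])
  } else thr <- as.numeric(threshold)
  out <- (v < thr) * 1
  if (!is.null(mask)) {
    md <- dim(mask) %||% stop("mask must be a matrix or array")
    if (length(md) == 2) {
      if (!identical(md, dim(v)[1:2])) stop("mask shape mismatch")
      out <- sweep(out, 1:2, (mask > 0) * 1, function(a, b) a * (1 - b))
    } else if (identical(md, dim(v))) {
      out[mask > 0] <- 0
    } else stop("mask shape mismatch")
  }
  image_stack(out, stack$pixel_size, stack$frame_interval)
}
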