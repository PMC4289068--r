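#' Calibrated time-lapse image stack
#'
#' Container for a grayscale time-lapse sequence together with its spatial
#' and temporal calibration. Frames are stored as an `H x W x T` array of
#' intensities; pixel centres sit on integer indices with the origin at the
#' top-left pixel, x increasing to the right (columns) and y downward
#' (rows). All exported geometry is expressed in micrometres and seconds.
#'
#' @param img Numeric array of dimension `H x W x T` (a single matrix is
#'   promoted to a one-frame stack).
#' @param pixel_size Pixel size in µm per pixel (> 0).
#' @param frame_interval Time between consecutive frames in seconds (> 0).
#'
#' @return An object of class `cdr_stack` with elements `img`,
#'   `pixel_size` and `frame_interval`.
#' @export
image_stack <- function(img, pixel_size, frame_interval) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  stopifnot(is.array(img), length(dim(img)) == 3L)
  if (!all(is.finite(img))) stop("image stack contains non-finite values")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (µm/px)")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive number (s)")
  structure(
    list(img = img, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "cdr_stack"
  )
}

#' Number of frames in a stack
#' @param stack A `cdr_stack`.
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$img)[3L]

#' Extract one frame of a stack as a matrix
#' @param stack A `cdr_stack`.
#' @param i Frame index (1-based).
#' @return An `H x W` intensity matrix.
#' @export
stack_frame <- function(stack, i) {
  stopifnot(i >= 1, i <= n_frames(stack))
  stack$img[, , i]
}

#' Times of the frames of a stack
#' @param stack A `cdr_stack`.
#' @return Numeric vector of frame times in seconds (first frame at 0).
#' @export
frame_times <- function(stack) {
  (seq_len(n_frames(stack)) - 1) * stack$frame_interval
}

#' @export
print.cdr_stack <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf(
    "<cdr_stack> %d x %d px, %d frames, %.4g µm/px, %.4g s/frame\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}
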