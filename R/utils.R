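# Internal helpers shared across modules. All geometry is carried in
# micrometres; pixel indices are 1-based with pixel centres on integers,
# x to the right (columns), y downward (rows).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
um_to_idx <- function(um, pixel_size) um / pixel_size + 1

#' @noRd
idx_to_um <- function(idx, pixel_size) (idx - 1) * pixel_size

## Bilinear interpolation on a matrix at fractional 1-based (row, col)
## positions. Points outside the grid give NA.
#' @noRd
bilinear <- function(m, row, col) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- is.finite(row) & is.finite(col) &
    row >= 1 & row <= nr & col >= 1 & col <= nc
  if (!any(ok)) return(out)
  r <- row[ok]
  cc <- col[ok]
  r0 <- pmin(floor(r), nr - 1L)
  c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0
  fc <- cc - c0
  v00 <- m[cbind(r0, c0)]
  v10 <- m[cbind(r0 + 1, c0)]
  v01 <- m[cbind(r0, c0 + 1)]
  v11 <- m[cbind(r0 + 1, c0 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

## Difference wrapped to [-L/2, L/2); circular distance on a ring of
## circumference L.
#' @noRd
wrap_diff <- function(d, L) ((d + L / 2) %% L) - L / 2

#' @noRd
circ_dist <- function(a, b, L) abs(wrap_diff(a - b, L))

## Evaluate code with a fixed RNG seed without disturbing the caller's
## random-number stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Normalised Gaussian taps at offsets k * spacing, truncated at 3 sigma.
#' @noRd
gaussian_taps <- function(sigma, spacing) {
  m <- ceiling(3 * sigma / spacing)
  if (m < 1) return(1)
  k <- (-m):m
  w <- exp(-(k * spacing)^2 / (2 * sigma^2))
  w / sum(w)
}

## Circular (wrap-around) convolution of a vector with symmetric taps.
#' @noRd
circ_filter <- function(x, taps) {
  n <- length(x)
  m <- (length(taps) - 1L) / 2L
  if (m == 0L) return(x)
  idx <- outer(seq_len(n), (-m):m, function(i, k) ((i + k - 1L) %% n) + 1L)
  as.vector(matrix(x[idx], n) %*% taps)
}
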