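# Spatiotemporal statistics of kymographs: segmentation, periodic 2-D
# autocorrelation maps c(ds, dt), Radon-transform velocity extraction,
# period estimation from temporal cuts, and detection/classification of
# wave events (initiations, annihilations, collisions with terminal
# gaps, spiral rotations).

#' Segment a kymograph into wave and background
#'
#' Wave pixels are intensities below the threshold (wavefronts are dark
#' stripes). `threshold = "otsu"` applies Otsu's method to the intensity
#' histogram; a numeric threshold is used as given. With `invert = TRUE`
#' the kymograph is negated first, so inverted-contrast inputs yield the
#' same mask.
#'
#' @param kymo A [kymograph()].
#' @param threshold `"otsu"` or a numeric intensity.
#' @param invert Negate intensities before thresholding.
#' @return A binary [kymograph()] (values 0/1) with attribute
#'   `threshold`.
#' @export
segment_kymograph <- function(kymo, threshold = "otsu", invert = FALSE) {
  v <- kymo$values
  if (!all(is.finite(v))) stop("kymograph contains non-finite values")
  if (invert) v <- -v
  if (identical(threshold, "otsu")) {
    rng <- range(v)
    if (rng[2] <= rng[1]) {
      thr <- rng[1]
    } else {
      sc <- (v - rng[1]) / (rng[2] - rng[1])
      thr <- rng[1] + EBImage::otsu(sc, range = c(0, 1)) *
        (rng[2] - rng[1])
    }
  } else {
    thr <- as.numeric(threshold)
  }
  mask <- v < thr
  if (all(mask) || !any(mask))
    warning("segmentation is all-wave or all-background")
  out <- kymograph(mask * 1, ds = kymo$ds, dt = kymo$dt,
                   periodic = kymo$periodic)
  attr(out, "threshold") <- thr
  out
}

#' Periodic spatiotemporal autocorrelation map
#'
#' Mean-subtracted, normalised autocorrelation `c(ds, dt)` of a
#' (typically segmented) kymograph: circular along the periodic space
#' axis (computed by FFT) and linear along time, each time lag
#' normalised by the energies of the two overlapping segments so that
#' `|c| <= 1` everywhere and `c(0, 0) = 1` exactly. The map is
#' point-symmetric, `c(-ds, -dt) = c(ds, dt)`.
#'
#' @param kymo A [kymograph()] (binary or gray-valued).
#' @param max_lag_t Maximal time lag in bins (default half the record).
#' @return An object of class `cdr_corrmap`: list with matrix `c`
#'   (rows = space lags ascending, columns = time lags ascending),
#'   `ds_lags` (µm), `dt_lags` (s), and the axis spacings.
#' @export
autocorrelation_2d <- function(kymo, max_lag_t = NULL) {
  X <- kymo$values
  S <- nrow(X)
  TT <- ncol(X)
  X <- X - mean(X)
  if (sum(X^2) == 0) stop("zero variance: autocorrelation undefined")
  L <- max_lag_t %||% floor(TT / 2)
  L <- min(L, TT - 1L)
  F <- stats::mvfft(X)
  cc <- matrix(0, S, L + 1L)
  for (lag in 0:L) {
    i1 <- seq_len(TT - lag)
    i2 <- i1 + lag
    G <- rowSums(Conj(F[, i1, drop = FALSE]) * F[, i2, drop = FALSE])
    raw <- Re(stats::fft(G, inverse = TRUE)) / S
    A <- sum(X[, i1]^2)
    B <- sum(X[, i2]^2)
    cc[, lag + 1L] <- raw / sqrt(A * B)
  }
  ## reorder circular space lags to ascending signed lags
  d <- 0:(S - 1)
  signed <- ((d + floor(S / 2)) %% S) - floor(S / 2)
  ord <- order(signed)
  ds_lags <- signed[ord] * kymo$ds
  pos <- cc[ord, , drop = FALSE]
  ## mirror to negative time lags via point symmetry
  neg <- pos[rev(seq_len(S)), rev(seq_len(L + 1L)), drop = FALSE]
  ## rows of neg correspond to -ds_lags reversed; align to ds_lags grid
  neg_ok <- matrix(NA_real_, S, L)
  ## c(ds, -dt) = c(-ds, dt); the circular space axis maps -ds back
  ## into the signed lag range modulo S
  di <- ((-signed[ord] + floor(S / 2)) %% S) - floor(S / 2)
  m <- match(di, signed[ord])
  for (col in seq_len(L))
    neg_ok[, col] <- pos[m, L + 2L - col]
  full <- cbind(neg_ok, pos)
  dt_lags <- c(-(L:1), 0:L) * kymo$dt
  full <- full / full[which(ds_lags == 0), L + 1L]  # pin c(0,0) = 1
  structure(list(c = full, ds_lags = ds_lags, dt_lags = dt_lags,
                 ds = kymo$ds, dt = kymo$dt),
            class = "cdr_corrmap")
}

#' @export
print.cdr_corrmap <- function(x, ...) {
  cat(sprintf("<cdr_corrmap> %d x %d lags, ds %.4g µm, dt %.4g s\n",
              nrow(x$c), ncol(x$c), x$ds, x$dt))
  invisible(x)
}

#' Element-wise average of correlation maps
#'
#' @param maps List of `cdr_corrmap` objects sharing identical lag
#'   grids.
#' @return The averaged `cdr_corrmap`.
#' @export
average_correlation <- function(maps) {
  if (!length(maps)) stop("no correlation maps to average")
  g <- maps[[1]]
  for (m in maps[-1]) {
    if (!isTRUE(all.equal(m$ds_lags, g$ds_lags)) ||
        !isTRUE(all.equal(m$dt_lags, g$dt_lags)))
      stop("correlation maps must share identical lag grids")
  }
  g$c <- Reduce(`+`, lapply(maps, `[[`, "c")) / length(maps)
  g
}

#' Zero-lag cuts through a correlation map
#'
#' @param cmap A `cdr_corrmap`.
#' @return A list with `ct` (data.frame `dt_s`, `c`: the temporal cut
#'   `c(0, dt)`) and `cs` (data.frame `ds_um`, `c`: the spatial cut
#'   `c(ds, 0)`).
#' @export
correlation_cuts <- function(cmap) {
  r0 <- which(cmap$ds_lags == 0)
  c0 <- which(cmap$dt_lags == 0)
  list(ct = data.frame(dt_s = cmap$dt_lags, c = cmap$c[r0, ]),
       cs = data.frame(ds_um = cmap$ds_lags, c = cmap$c[, c0]))
}

#' Inter-event period from a temporal correlation cut
#'
#' The period is the time lag of the recurrence maximum of `c(0, dt)`
#' after the first negative excursion (the quiescent interval before
#' the next wave at the same position): the maximum of the first
#' sustained positive lobe following that excursion. The cut is
#' smoothed with a narrow (1, 2, 1)/4 kernel first so that single-bin
#' noise bumps are not mistaken for the recurrence peak; the reported
#' lag stays on the original time grid.
#'
#' @param cut Either a `cdr_corrmap` or the `ct` data.frame of
#'   [correlation_cuts()].
#' @return Period in seconds, or `NA` if no qualifying maximum exists.
#' @export
period_from_cut <- function(cut) {
  if (inherits(cut, "cdr_corrmap")) cut <- correlation_cuts(cut)$ct
  keep <- cut$dt_s >= 0
  lag <- cut$dt_s[keep]
  cv <- cut$c[keep]
  o <- order(lag)
  lag <- lag[o]
  cv <- cv[o]
  n <- length(cv)
  if (n >= 3)
    cv <- c(cv[1], (cv[1:(n - 2)] + 2 * cv[2:(n - 1)] + cv[3:n]) / 4,
            cv[n])
  neg <- which(cv < 0)
  if (!length(neg) || neg[1] >= n - 1L) return(NA_real_)
  after <- cv
  after[seq_len(neg[1])] <- NA
  pos <- !is.na(after) & after > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lobes <- which(r$values & r$lengths >= 3L)
  if (!length(lobes)) return(NA_real_)
  i <- starts[lobes[1]]:ends[lobes[1]]
  lag[i[which.max(cv[i])]]
}

## ---- Radon velocity extraction ----------------------------------------

## Variance-of-projection profile of a map over ridge angles (degrees).
## The angle is that of a ridge direction in index units:
## tan(angle) = (rows per column) = (space bins per time bin).
#' @noRd
radon_profile <- function(M, angles_deg, r0, c0) {
  Rmax <- min(r0 - 1, nrow(M) - r0, c0 - 1, ncol(M) - c0)
  rr <- max(3L, floor(Rmax / sqrt(2)))
  p <- -rr:rr
  q <- -rr:rr
  P <- matrix(p, length(p), length(q))
  Q <- matrix(q, length(p), length(q), byrow = TRUE)
  vapply(angles_deg, function(a) {
    th <- a * pi / 180
    cols <- c0 + Q * cos(th) - P * sin(th)
    rows <- r0 + Q * sin(th) + P * cos(th)
    samp <- matrix(bilinear(M, as.vector(rows), as.vector(cols)),
                   nrow(P))
    stats::var(rowMeans(samp, na.rm = TRUE))
  }, 0)
}

#' Dominant propagation velocities via the Radon transform
#'
#' Projects the correlation map along a grid of ridge orientations; the
#' orientation(s) maximising the variance of the projection correspond
#' to the stripe slopes, which the axis calibrations convert to
#' velocities (µm/s). Bidirectional propagation yields two symmetric
#' orientations (+v and -v). An orientation counts as dominant only if
#' its projection variance exceeds the 99th percentile of the maximal
#' variance under ring-shuffled permutations of the map (pixels permuted
#' within iso-radius annuli about the origin, which destroys every
#' orientation while preserving the radial correlation power); an
#' isotropic map therefore yields no velocity.
#'
#' @param cmap A `cdr_corrmap` (at least 16 x 16 lags).
#' @param angles_deg Orientation grid in degrees (ridge angle in index
#'   units; 0 = static, sign = propagation direction).
#' @param max_components Maximal number of reported orientations.
#' @param n_perm Permutations for the significance threshold.
#' @param perm_seed Seed of the permutation draw.
#' @param refine Refine peak angles on a 0.05 degree grid.
#' @return A list with `velocities_um_s` (signed, possibly empty),
#'   `angles_deg`, `significant`, `threshold` and `profile`
#'   (data.frame angle, variance).
#' @export
radon_velocity <- function(cmap, angles_deg = seq(-88, 88, by = 0.5),
                           max_components = 2L, n_perm = 50L,
                           perm_seed = 1L, refine = TRUE) {
  M <- cmap$c
  if (nrow(M) < 16 || ncol(M) < 16)
    stop("correlation map smaller than 16 x 16 lags")
  r0 <- which(cmap$ds_lags == 0)
  c0 <- which(cmap$dt_lags == 0)
  prof <- radon_profile(M, angles_deg, r0, c0)
  ## permutation null: shuffle within iso-radius rings, coarse grid
  coarse <- seq(min(angles_deg), max(angles_deg), by = 4)
  ring <- round(sqrt(outer((seq_len(nrow(M)) - r0)^2,
                           (seq_len(ncol(M)) - c0)^2, `+`)))
  groups <- split(seq_along(ring), ring)
  perm_max <- with_seed(perm_seed, vapply(seq_len(n_perm), function(i) {
    Mp <- M
    for (g in groups) if (length(g) > 1) Mp[g] <- M[sample(g)]
    max(radon_profile(Mp, coarse, r0, c0))
  }, 0))
  thr <- stats::quantile(perm_max, 0.99, names = FALSE)
  ## compare on the same coarse grid as the null to keep the maximum
  ## statistics exchangeable
  if (max(radon_profile(M, coarse, r0, c0)) <= thr)
    return(list(velocities_um_s = numeric(0), angles_deg = numeric(0),
                significant = FALSE, threshold = thr,
                profile = data.frame(angle = angles_deg,
                                     variance = prof)))
  n <- length(prof)
  is_peak <- prof > thr &
    prof >= c(-Inf, prof[-n]) & prof >= c(prof[-1], -Inf)
  cand <- order(prof, decreasing = TRUE)
  cand <- cand[is_peak[cand]]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) >= max_components) break
    if (all(abs(angles_deg[i] - angles_deg[picked]) >= 5))
      picked <- c(picked, i)
  }
  ang <- angles_deg[picked]
  if (length(ang) && refine) {
    step <- if (length(angles_deg) > 1) diff(angles_deg[1:2]) else 1
    ang <- vapply(ang, function(a) {
      fine <- seq(a - step, a + step, by = 0.05)
      fine[which.max(radon_profile(M, fine, r0, c0))]
    }, 0)
  }
  v <- tan(ang * pi / 180) * cmap$ds / cmap$dt
  list(velocities_um_s = v, angles_deg = ang,
       significant = length(ang) > 0, threshold = thr,
       profile = data.frame(angle = angles_deg, variance = prof))
}

## ---- event detection ---------------------------------------------------

## Runs of wave pixels in one time column. Returns a data.frame with
## fractional centre (may be < 1 when wrapping) and the member indices.
#' @noRd
col_runs <- function(mask_col, periodic) {
  n <- length(mask_col)
  if (!any(mask_col))
    return(list())
  if (all(mask_col))
    return(list(list(centre = (1 + n) / 2, members = seq_len(n))))
  r <- rle(mask_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  runs <- lapply(on, function(k) {
    list(centre = (starts[k] + ends[k]) / 2,
         members = starts[k]:ends[k])
  })
  if (periodic && mask_col[1] && mask_col[n] && length(runs) > 1) {
    last <- length(runs)
    wrapped <- c(runs[[last]]$members - n, runs[[1]]$members)
    runs[[1]] <- list(centre = mean(wrapped), members = ((wrapped - 1) %% n) + 1)
    runs[[last]] <- NULL
  }
  runs
}

#' Detect and classify wave events in a segmented kymograph
#'
#' Traces the dark-stripe runs of each time column and links them across
#' columns by overlap. An appearance of an unlinked run is an
#' initiation ("<"-shaped object); the head-on disappearance of two
#' approaching traces, or their merger, is a collision (">"-shaped
#' object), classified `mutual` when no trace continues beyond the
#' collision (recording the terminal front-to-front gap) and
#' `one_survives` when the merged trace persists or splits again. A
#' lone disappearing trace is an annihilation.
#'
#' @param bin A binary [kymograph()] (from [segment_kymograph()]), or a
#'   gray-valued one (then segmented with Otsu first).
#' @param survive_window Columns after a merger within which the merged
#'   trace must vanish to count as mutual.
#' @param approach_window Columns over which approach (decreasing
#'   separation) is checked.
#' @param end_guard Columns at the end of the record within which
#'   disappearances are ignored (truncation, not annihilation).
#' @param gap_max Maximal front-to-front distance (µm) for pairing two
#'   simultaneous disappearances into one collision; default one third
#'   of the space axis.
#' @return An event table: data.frame with columns `type`
#'   (initiation / annihilation / collision), `s_um`, `t_s`, `class`
#'   (mutual / one_survives, collisions only) and `gap_um`.
#' @export
detect_events <- function(bin, survive_window = 6L, approach_window = 3L,
                          end_guard = 2L, gap_max = NULL) {
  if (!all(bin$values %in% c(0, 1)))
    bin <- segment_kymograph(bin)
  mask <- bin$values > 0.5
  S <- nrow(mask)
  TT <- ncol(mask)
  L <- S * bin$ds
  gap_max <- gap_max %||% (L / 3)
  per <- bin$periodic
  events <- list()
  add_event <- function(type, s, t, class = NA_character_,
                        gap = NA_real_) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, s_um = s, t_s = t, class = class, gap_um = gap)
  }
  ## traces: id -> list(cols, centres (index units), alive, parent,
  ##                    merged_into, end_col)
  traces <- list()
  new_trace <- function(col, centre, parent = NA_integer_) {
    id <- length(traces) + 1L
    traces[[id]] <<- list(cols = col, centres = centre, alive = TRUE,
                          parent = parent, merged_into = NA_integer_,
                          end_col = NA_integer_)
    id
  }
  merges <- list()
  terminations <- list()
  prev_runs <- list()
  prev_ids <- integer(0)
  cdist <- function(a, b) {
    d <- abs(a - b)
    if (per) min(d, S - d) else d
  }
  for (t in seq_len(TT)) {
    runs <- col_runs(mask[, t], per)
    nr <- length(runs)
    np <- length(prev_runs)
    if (np && nr) {
      ov <- matrix(0L, np, nr)
      occ_prev <- lapply(prev_runs, function(r) {
        m <- r$members
        if (per) unique(((c(m - 1, m, m + 1) - 1) %% S) + 1)
        else unique(pmin(pmax(c(m - 1, m, m + 1), 1), S))
      })
      for (j in seq_len(nr))
        for (i in seq_len(np))
          ov[i, j] <- length(intersect(occ_prev[[i]], runs[[j]]$members))
    } else {
      ov <- matrix(0L, np, nr)
    }
    cur_ids <- integer(nr)
    ## assign successors
    for (j in seq_len(nr)) {
      preds <- which(ov[, j] > 0)
      if (!length(preds)) {
        cur_ids[j] <- new_trace(t, runs[[j]]$centre)
        add_event("initiation", idx_to_um(((runs[[j]]$centre - 1) %% S) + 1,
                                          bin$ds),
                  (t - 1) * bin$dt)
      } else if (length(preds) == 1L) {
        cur_ids[j] <- prev_ids[preds]
      } else {
        win <- preds[which.max(ov[preds, j])]
        cur_ids[j] <- prev_ids[win]
        losers <- prev_ids[setdiff(preds, win)]
        for (lid in losers) {
          traces[[lid]]$alive <- FALSE
          traces[[lid]]$merged_into <- prev_ids[win]
          traces[[lid]]$end_col <- t - 1L
        }
        merges[[length(merges) + 1L]] <- list(
          col = t, centre = runs[[j]]$centre, winner = prev_ids[win],
          losers = losers, pred_ids = prev_ids[preds])
      }
    }
    ## splits: one predecessor claimed by several current runs
    if (nr) {
      for (id in unique(cur_ids[duplicated(cur_ids)])) {
        js <- which(cur_ids == id)
        pi <- match(id, prev_ids)
        keep <- js[which.max(ov[pi, js])]
        for (j2 in setdiff(js, keep))
          cur_ids[j2] <- new_trace(t, runs[[j2]]$centre, parent = id)
      }
    }
    ## terminations: previous traces with no successor
    gone <- setdiff(prev_ids, cur_ids)
    for (gid in gone) {
      tr <- traces[[gid]]
      if (!is.na(tr$merged_into)) next
      traces[[gid]]$alive <- FALSE
      traces[[gid]]$end_col <- t - 1L
      terminations[[length(terminations) + 1L]] <- list(
        id = gid, col = t - 1L,
        centre = tr$centres[length(tr$centres)])
    }
    ## extend trace histories
    for (j in seq_len(nr)) {
      id <- cur_ids[j]
      if (length(traces[[id]]$cols) == 0 ||
          traces[[id]]$cols[length(traces[[id]]$cols)] != t) {
        traces[[id]]$cols <- c(traces[[id]]$cols, t)
        traces[[id]]$centres <- c(traces[[id]]$centres, runs[[j]]$centre)
      }
    }
    prev_runs <- runs
    prev_ids <- cur_ids
  }
  ## close surviving traces at the record end
  for (id in seq_along(traces))
    if (traces[[id]]$alive)
      traces[[id]]$end_col <- TT
  centre_at <- function(id, col) {
    tr <- traces[[id]]
    k <- match(col, tr$cols)
    if (is.na(k)) NA_real_ else tr$centres[k]
  }
  ## trace history including the parent chain before a split birth
  history_of <- function(id) {
    tr <- traces[[id]]
    cols <- tr$cols
    centres <- tr$centres
    pid <- tr$parent
    while (!is.na(pid)) {
      pt <- traces[[pid]]
      keep <- pt$cols < min(cols)
      cols <- c(pt$cols[keep], cols)
      centres <- c(pt$centres[keep], centres)
      pid <- pt$parent
    }
    list(cols = cols, centres = centres)
  }
  approaching <- function(id1, id2, col) {
    ## compare the separation at `col` with the separation up to
    ## approach_window columns earlier; traces younger than the window
    ## inherit their parent's positions from before the split
    h1 <- history_of(id1)
    h2 <- history_of(id2)
    common <- intersect(h1$cols, h2$cols)
    common <- common[common <= col]
    if (length(common) < 2) return(FALSE)
    b <- max(common)
    a <- max(min(common), b - approach_window)
    if (!(a %in% common)) a <- min(common)
    if (a >= b) return(FALSE)
    at <- function(h, cc) h$centres[match(cc, h$cols)]
    cdist(at(h1, b), at(h2, b)) < cdist(at(h1, a), at(h2, a))
  }
  descendants_alive_after <- function(id, col) {
    last <- traces[[id]]$end_col
    if (!is.na(last) && last > col) return(TRUE)
    for (k in seq_along(traces)) {
      tr <- traces[[k]]
      if (!is.na(tr$parent) && tr$parent == id &&
          (is.na(tr$end_col) || tr$end_col > col))
        return(TRUE)
      if (!is.na(tr$merged_into) && FALSE) next
    }
    FALSE
  }
  ## classify merges
  merge_close <- list()  # winner id -> merge col (for dedup below)
  for (m in merges) {
    ids <- m$pred_ids[1:2]
    app <- tryCatch(approaching(ids[1], ids[2], m$col - 1L),
                    error = function(e) FALSE)
    if (!app) next
    surv <- descendants_alive_after(m$winner, m$col + survive_window)
    add_event("collision",
              idx_to_um(((m$centre - 1) %% S) + 1, bin$ds),
              (m$col - 1) * bin$dt,
              class = if (surv) "one_survives" else "mutual",
              gap = 0)
    if (!surv)
      merge_close[[as.character(m$winner)]] <- m$col
  }
  ## the terminal decay of a mutual merger is part of that collision,
  ## not a separate annihilation
  is_merge_tail <- function(term) {
    mc <- merge_close[[as.character(term$id)]]
    !is.null(mc) && term$col <= mc + survive_window
  }
  ## pair simultaneous head-on disappearances (mutual with finite gap)
  if (length(terminations) > 1) {
    used <- rep(FALSE, length(terminations))
    for (i in seq_along(terminations)) {
      if (used[i]) next
      ti <- terminations[[i]]
      if (ti$col >= TT - end_guard || is_merge_tail(ti)) {
        used[i] <- TRUE
        next
      }
      for (j in seq_along(terminations)) {
        if (j <= i || used[j]) next
        tj <- terminations[[j]]
        if (abs(ti$col - tj$col) > 1 || is_merge_tail(tj)) next
        col <- min(ti$col, tj$col)
        d <- cdist(centre_at(ti$id, col), centre_at(tj$id, col))
        if (!is.finite(d) || d * bin$ds > gap_max) next
        if (!approaching(ti$id, tj$id, col)) next
        mid <- centre_at(ti$id, col) +
          wrap_diff(centre_at(tj$id, col) - centre_at(ti$id, col), S) / 2
        add_event("collision", idx_to_um(((mid - 1) %% S) + 1, bin$ds),
                  (col - 1) * bin$dt, class = "mutual",
                  gap = d * bin$ds)
        used[c(i, j)] <- TRUE
        break
      }
    }
    ## leftover terminations away from the record end: annihilations
    for (i in seq_along(terminations)) {
      if (used[i]) next
      ti <- terminations[[i]]
      if (ti$col >= TT - end_guard || is_merge_tail(ti)) next
      add_event("annihilation",
                idx_to_um(((ti$centre - 1) %% S) + 1, bin$ds),
                (ti$col - 1) * bin$dt)
    }
  } else if (length(terminations) == 1) {
    ti <- terminations[[1]]
    if (ti$col < TT - end_guard && !is_merge_tail(ti))
      add_event("annihilation",
                idx_to_um(((ti$centre - 1) %% S) + 1, bin$ds),
                (ti$col - 1) * bin$dt)
  }
  if (!length(events))
    return(data.frame(type = character(0), s_um = numeric(0),
                      t_s = numeric(0), class = character(0),
                      gap_um = numeric(0)))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out[order(out$t_s, out$s_um), , drop = FALSE]
}

#' Terminal front-to-front gap of a mutual-annihilation collision
#'
#' Measures the spatial separation of the two colliding front positions
#' (run centres of the segmented kymograph) at the last time column in
#' which both fronts are above the detection threshold. Fronts that
#' merged before terminating give a gap of 0.
#'
#' @param kymo The (gray-valued or binary) [kymograph()].
#' @param event Optional row of the [detect_events()] table (a mutual
#'   collision); defaults to the first mutual collision found.
#' @param threshold Segmentation threshold, see [segment_kymograph()].
#' @return Gap in µm.
#' @export
terminal_gap <- function(kymo, event = NULL, threshold = "otsu") {
  bin <- if (all(kymo$values %in% c(0, 1))) kymo
         else segment_kymograph(kymo, threshold)
  if (is.null(event)) {
    ev <- detect_events(bin)
    ev <- ev[ev$type == "collision" & ev$class == "mutual", ,
             drop = FALSE]
    if (!nrow(ev)) stop("no mutual-annihilation collision found")
    event <- ev[1, ]
  }
  if (!is.na(event$gap_um) && event$gap_um == 0) return(0)
  mask <- bin$values > 0.5
  S <- nrow(mask)
  L <- S * bin$ds
  t_e <- round(event$t_s / bin$dt) + 1L
  s_e <- event$s_um
  for (t in rev(seq_len(min(t_e + 3L, ncol(mask))))) {
    cc <- run_centres(mask[, t], periodic = bin$periodic)
    if (length(cc) < 2 || anyNA(cc)) next
    s_cc <- idx_to_um(((cc - 1) %% S) + 1, bin$ds)
    d <- abs(wrap_diff(s_cc - s_e, L))
    near <- order(d)[1:2]
    if (d[near[2]] > L / 3) next
    return(circ_dist(s_cc[near[1]], s_cc[near[2]], L))
  }
  0
}

#' Count full rotations of a spiral wave
#'
#' Tracks the angular position of the wavefront on a sampling circle
#' (the intensity-weighted circular mean of the dark excess per frame),
#' unwraps the phase over time and reports the number of completed
#' rotations, `floor(|total angle| / 2 pi)`.
#'
#' @param x A [image_stack()] (then `center` and `radius` select the
#'   sampling circle) or a periodic [kymograph()] of angular position.
#' @param center,radius Sampling circle (µm) when `x` is a stack.
#' @param threshold Dark threshold; default midway between extremes.
#' @param max_gap_frac Maximal tolerated fraction of frames without
#'   signal.
#' @return A list with `rotations` (integer), `total_angle_rad` and
#'   `angle` (data.frame frame, unwrapped angle).
#' @export
count_rotations <- function(x, center = NULL, radius = NULL,
                            threshold = NULL, max_gap_frac = 0.25) {
  kymo <- if (inherits(x, "cdr_stack")) {
    if (is.null(center) || is.null(radius))
      stop("center and radius required for a stack input")
    circular_kymograph(x, center, radius)
  } else x
  stopifnot(inherits(kymo, "cdr_kymo"), kymo$periodic)
  v <- kymo$values
  thr <- threshold %||% ((max(v) + min(v)) / 2)
  S <- nrow(v)
  th <- 2 * pi * (seq_len(S) - 1) / S
  w <- pmax(thr - v, 0)
  zr <- colSums(w * cos(th))
  zi <- colSums(w * sin(th))
  amp <- sqrt(zr^2 + zi^2)
  valid <- amp > 1e-9
  if (mean(!valid) > max_gap_frac)
    stop(sprintf("signal missing in %.0f%% of frames",
                 100 * mean(!valid)))
  ang <- atan2(zi[valid], zr[valid])
  steps <- wrap_diff(diff(ang), 2 * pi)
  total <- sum(steps)
  unwrapped <- cumsum(c(ang[1], steps))
  list(rotations = floor(abs(total) / (2 * pi) + 1e-6),
       total_angle_rad = total,
       angle = data.frame(frame = which(valid) - 1L,
                          angle_rad = unwrapped))
}
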