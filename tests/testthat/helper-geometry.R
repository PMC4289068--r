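# Shared fixtures: geometry builders and memoised phantoms (built once
# per test run, in code).

circle_contour <- function(R, n = 100, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour(cx + R * cos(th), cy + R * sin(th))
}

radius_of <- function(con, cx = 0, cy = 0) {
  sqrt((con$x - cx)^2 + (con$y - cy)^2)
}

## memoised heavyweight fixtures
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

## noiseless parabolic ring phantom shared by tracking tests
ring_phantom_small <- function() fixture("ring_small", function() {
  p <- phantom_params(pixel_size = 0.5, frame_interval = 10,
                      shape = c(23L, 96L, 96L), v0 = 0.2, t_rev = 100,
                      noise_sigma = 0)
  c(make_ring_stack(p), list(params = p))
})

## tracked series on that phantom (frames 4..23, R from 3.4 µm up)
ring_tracked_small <- function() fixture("ring_tracked", function() {
  ph <- ring_phantom_small()
  gt <- ph$ground_truth$frames
  fr <- 4:23
  seed <- circle_contour(gt$radius_um[fr[1]] + 2, 60,
                         ph$params$center[1], ph$params$center[2])
  suppressWarnings(
    track_sequence(ph$stack, seed, snake_config(), frame_range = fr))
})
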