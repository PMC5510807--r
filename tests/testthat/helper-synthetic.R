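# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Straight horizontal edge at y = 8 um spanning a given pixel width.
straight_edge <- function(width_px = 192L, pixel_size = 0.32, y = 8) {
  edge_polyline(cbind(seq(0, width_px * pixel_size, length.out = 5), rep(y, 5)))
}

# A small noiseless reference movie exercised by several test files:
# 600 frames, 128 x 192 px, 14 Hz beat, 13 um wavelength, 3 beads.
small_movie <- function() {
  cached("small_movie", {
    spec <- synthetic_movie_spec(
      n_frames = 600L, height = 128L, width = 192L,
      edge = straight_edge(),
      bead_entries = data.frame(entry_frame = 1L, y0 = c(10, 18, 28)),
      profile = list(uw = 138.3, h = 87.5), rng_seed = 42L)
    c(generate_movie(spec), list(spec = spec))
  })
}

# A uniform-grey movie built directly (no beating, no beads).
constant_movie <- function(level = 120, n_frames = 128L) {
  arr <- array(level, dim = c(64L, 96L, n_frames))
  frame_stack(arr, frame_rate = 358, pixel_size = 0.32)
}

# A movie whose every pixel carries the same scalar time signal.
signal_movie <- function(signal, frame_rate = 358, level = 128, amp = 1) {
  arr <- array(rep(level + amp * signal, each = 64L * 96L),
               dim = c(64L, 96L, length(signal)))
  frame_stack(arr, frame_rate = frame_rate, pixel_size = 0.32)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
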