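#' Specification of a synthetic ciliated-edge movie
#'
#' Describes a ground-truthed movie emulating a high-speed recording of a
#' beating ciliated edge with suspended micro-beads: an oscillating dark
#' cilia band along the edge polyline carrying a metachronal phase
#' gradient, dark discs advected parallel to the edge following the
#' parabolic profile `V(y0) = Uw * (1 - y0/h)^2`, and optional additive
#' Gaussian pixel noise. Defaults mirror the reference acquisition
#' (358 frames/s, 1800 frames, 256 x 192 px, 0.32 um/px).
#'
#' @param n_frames number of frames.
#' @param frame_rate frames per second.
#' @param height,width frame size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param edge an [edge_polyline()]; default a straight horizontal edge at
#'   y = 10 um spanning the frame width.
#' @param cbf ciliary beat frequency in Hz; must be below `frame_rate / 2`.
#' @param grey_modulation_amplitude peak-to-peak grey-level modulation of
#'   cilia pixels.
#' @param wavelength metachronal wavelength in um (phase `2*pi*s/wavelength`
#'   along the curvilinear abscissa s).
#' @param cilia_density fraction of band pixels rendered as cilia (darker
#'   than background on time average), in `[0, 1]`.
#' @param band_width extent of the cilia band from the polyline on the bead
#'   side, in um (one cilium length by default).
#' @param background_mean background grey level.
#' @param noise_sd per-pixel Gaussian noise SD in grey levels (0 = none).
#' @param bead_radius bead radius in um (4.5 um diameter polystyrene beads
#'   by default).
#' @param bead_grey grey level of a fully covered bead pixel.
#' @param bead_entries data frame with columns `entry_frame` and `y0` (um,
#'   distance from the edge on the bead side, `0 < y0 <= h`).
#' @param profile list with `uw` (wall velocity, um/s) and `h` (stagnant
#'   height, um) of the advection parabola.
#' @param rng_seed integer seed controlling cilia placement and noise.
#' @return a `synthetic_movie_spec` list.
#' @export
synthetic_movie_spec <- function(n_frames = 1800L, frame_rate = 358,
                                 height = 192L, width = 256L, pixel_size = 0.32,
                                 edge = NULL, cbf = 14, grey_modulation_amplitude = 60,
                                 wavelength = 13, cilia_density = 0.84,
                                 band_width = 6, background_mean = 180, noise_sd = 0,
                                 bead_radius = 2.25, bead_grey = 30,
                                 bead_entries = data.frame(entry_frame = 1L,
                                                           y0 = c(10, 20, 35)),
                                 profile = list(uw = 138.3, h = 87.5),
                                 rng_seed = 1L) {
  if (is.null(edge)) {
    w_um <- width * pixel_size
    edge <- edge_polyline(cbind(seq(0, w_um, length.out = 5), rep(10, 5)))
  }
  spec <- list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
               height = as.integer(height), width = as.integer(width),
               pixel_size = pixel_size, edge = edge, cbf = cbf,
               grey_modulation_amplitude = grey_modulation_amplitude,
               wavelength = wavelength, cilia_density = cilia_density,
               band_width = band_width, background_mean = background_mean,
               noise_sd = noise_sd, bead_radius = bead_radius,
               bead_grey = bead_grey, bead_entries = bead_entries,
               profile = profile, rng_seed = as.integer(rng_seed))
  validate_movie_spec(spec)
  structure(spec, class = "synthetic_movie_spec")
}

validate_movie_spec <- function(spec) {
  with(spec, {
    if (cilia_density < 0 || cilia_density > 1) stop("cilia_density must be in [0, 1]")
    if (wavelength <= 0) stop("wavelength must be > 0")
    if (cbf >= frame_rate / 2) stop("cbf must be below the Nyquist frequency frame_rate/2")
    if (profile$h <= 0 || profile$uw < 0) stop("profile needs h > 0 and uw >= 0")
    if (nrow(bead_entries) > 0 &&
        (any(bead_entries$y0 <= 0) || any(bead_entries$y0 > profile$h)))
      stop("every bead y0 must satisfy 0 < y0 <= h")
  })
  invisible(spec)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic movie with ground truth
#'
#' Renders the frame stack described by a [synthetic_movie_spec()]. Cilia
#' pixels (an exact fraction `cilia_density` of band pixels, chosen by the
#' seeded RNG) oscillate as
#' `bg - A/2 * (1 + sin(2*pi*cbf*t - 2*pi*s/wavelength))`, so their time
#' average sits `A/2` below the background. Each bead is rendered as an
#' anti-aliased dark disc (area-coverage over 4x4 sub-pixels) advected
#' parallel to the nearest edge segment at `uw * (1 - y0/h)^2`.
#'
#' @param spec a [synthetic_movie_spec()].
#' @return a list with `stack` (a [frame_stack()]) and `truth`, a list
#'   holding the generating cbf, wavelength, realized cilia density, band
#'   mask (`cilia_zone`), a per-bead table (`y0`, `expected_speed`), the
#'   per-frame bead positions (`bead_paths`), and the advection parabola.
#' @export
generate_movie <- function(spec) {
  validate_movie_spec(spec)
  h_px <- spec$height; w_px <- spec$width; tt <- spec$n_frames
  ps <- spec$pixel_size
  ctr <- pixel_centres(h_px, w_px, ps)
  proj <- polyline_project(spec$edge, cbind(as.vector(ctr$x), as.vector(ctr$y)))
  band <- proj$signed >= 0 & proj$signed <= spec$band_width
  band_idx <- which(band)
  n_band <- length(band_idx)
  n_cilia <- round(spec$cilia_density * n_band)

  res <- with_seed(spec$rng_seed, {
    cilia_sel <- if (n_cilia > 0) sample(band_idx, n_cilia) else integer(0)
    cilia_phase <- 2 * pi * proj$s[cilia_sel] / spec$wavelength
    omega <- 2 * pi * spec$cbf
    dt <- 1 / spec$frame_rate
    amp <- spec$grey_modulation_amplitude

    # bead paths: advance along the tangent of the nearest edge segment
    beads <- spec$bead_entries
    paths <- vector("list", nrow(beads))
    if (nrow(beads) > 0) {
      for (b in seq_len(nrow(beads))) {
        y0 <- beads$y0[b]
        speed <- spec$profile$uw * (1 - y0 / spec$profile$h)^2
        s0 <- spec$bead_radius + 1
        p0 <- polyline_point_at(spec$edge, s0)
        pos <- p0$xy[1L, ] + p0$normal[1L, ] * y0
        ext <- c(w_px, h_px) * ps
        if (any(pos < 0) || pos[1L] > ext[1L] || pos[2L] > ext[2L])
          stop(sprintf("bead %d starts outside the frame at (%.1f, %.1f) um",
                       b, pos[1L], pos[2L]))
        nvis <- tt - beads$entry_frame[b] + 1L
        xy <- matrix(NA_real_, nvis, 2L)
        xy[1L, ] <- pos
        if (nvis > 1) for (t in 2:nvis) {
          pr <- polyline_project(spec$edge, matrix(pos, 1L))
          tg <- c(pr$tx, pr$ty)
          pos <- pos + tg * speed * dt
          xy[t, ] <- pos
        }
        paths[[b]] <- data.frame(frame = beads$entry_frame[b]:tt,
                                 x = xy[, 1L], y = xy[, 2L])
      }
    }

    arr <- array(spec$background_mean, dim = c(h_px, w_px, tt))
    margin <- spec$bead_radius + 1
    for (t in seq_len(tt)) {
      frame <- matrix(spec$background_mean, h_px, w_px)
      tsec <- (t - 1L) * dt
      if (length(cilia_sel))
        frame[cilia_sel] <- spec$background_mean -
          amp / 2 * (1 + sin(omega * tsec - cilia_phase))
      if (nrow(beads) > 0) for (b in seq_len(nrow(beads))) {
        pth <- paths[[b]]
        row <- t - beads$entry_frame[b] + 1L
        if (row < 1L) next
        cx <- pth$x[row]; cy <- pth$y[row]
        ext <- c(w_px, h_px) * ps
        if (cx < -margin || cx > ext[1L] + margin ||
            cy < -margin || cy > ext[2L] + margin) next
        frame <- render_disc(frame, cx, cy, spec$bead_radius,
                             spec$bead_grey, ps)
      }
      if (spec$noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(h_px * w_px, 0, spec$noise_sd), h_px, w_px)
      arr[, , t] <- frame
    }
    arr <- round(pmin(pmax(arr, 0), 255))
    storage.mode(arr) <- "integer"

    cilia_zone <- matrix(FALSE, h_px, w_px)
    cilia_zone[band_idx] <- TRUE
    truth <- list(
      cbf = spec$cbf, wavelength = spec$wavelength,
      cilia_density = if (n_band > 0) n_cilia / n_band else NA_real_,
      cilia_zone = cilia_zone,
      beads = if (nrow(beads) > 0)
        data.frame(bead = seq_len(nrow(beads)), y0 = beads$y0,
                   expected_speed = spec$profile$uw * (1 - beads$y0 / spec$profile$h)^2)
      else data.frame(bead = integer(), y0 = numeric(), expected_speed = numeric()),
      bead_paths = paths,
      profile = spec$profile)
    list(stack = frame_stack(arr, spec$frame_rate, ps), truth = truth)
  })
  res
}

# Blend an anti-aliased dark disc into a frame; coverage from an 8x8
# sub-pixel grid per candidate pixel (sub-0.05 px centroid accuracy).
render_disc <- function(frame, cx, cy, radius, grey, pixel_size) {
  h <- nrow(frame); w <- ncol(frame)
  r_px <- radius / pixel_size
  jc <- cx / pixel_size + 0.5; ic <- cy / pixel_size + 0.5
  j_lo <- max(1L, floor(jc - r_px - 1)); j_hi <- min(w, ceiling(jc + r_px + 1))
  i_lo <- max(1L, floor(ic - r_px - 1)); i_hi <- min(h, ceiling(ic + r_px + 1))
  if (j_lo > j_hi || i_lo > i_hi) return(frame)
  j_rng <- j_lo:j_hi; i_rng <- i_lo:i_hi
  off <- (1:8 - 4.5) / 8
  cov <- matrix(0, length(i_rng), length(j_rng))
  for (oi in off) for (oj in off)
    cov <- cov + (outer((i_rng + oi - ic)^2, (j_rng + oj - jc)^2, `+`) <= r_px^2)
  cov <- cov / 64
  frame[i_rng, j_rng] <- frame[i_rng, j_rng] * (1 - cov) + grey * cov
  frame
}

#' Sample a noisy parabolic velocity profile
#'
#' Draws `V(y) = uw * (1 - y/h)^2 + N(0, noise_sd)` at the requested
#' altitudes, reproducibly by seed. Feeds recovery studies of the
#' parabolic-profile fit.
#'
#' @param parabola list with `uw` (um/s) and `h` (um).
#' @param y_grid altitudes in um, within `[0, h]`.
#' @param noise_sd velocity noise SD: in um/s, or as a fraction of the
#'   local velocity when `proportional = TRUE` (bead-velocity uncertainty
#'   scales with the velocity itself, each per-bead mean averaging a
#'   speed-dependent number of displacement steps).
#' @param proportional whether `noise_sd` is relative to `V(y)`.
#' @param rng_seed integer seed.
#' @return data frame with columns `y0`, `v` and `weight`
#'   (inverse-variance; 1 for noiseless samples).
#' @export
generate_profile_samples <- function(parabola, y_grid, noise_sd = 0,
                                     proportional = FALSE, rng_seed = 1L) {
  if (length(y_grid) == 0L) stop("y_grid must not be empty")
  if (parabola$h <= 0) stop("parabola h must be > 0")
  if (any(y_grid < 0 | y_grid > parabola$h)) stop("y_grid must lie within [0, h]")
  v <- parabola$uw * (1 - y_grid / parabola$h)^2
  sd <- if (proportional) noise_sd * v else rep(noise_sd, length(v))
  if (noise_sd > 0)
    v <- v + with_seed(rng_seed, stats::rnorm(length(y_grid), 0, sd))
  data.frame(y0 = as.numeric(y_grid), v = v,
             weight = ifelse(sd > 0, 1 / pmax(sd, 1e-12)^2, 1))
}

#' Write a synthetic movie and its ground-truth sidecar
#'
#' @param movie result of [generate_movie()].
#' @param tif_path output multi-page TIFF path.
#' @param json_path output JSON sidecar path (ground truth without the
#'   pixel masks and paths).
#' @return `tif_path`, invisibly.
#' @export
save_synthetic_movie <- function(movie, tif_path, json_path = NULL) {
  write_frame_stack(movie$stack, tif_path)
  if (!is.null(json_path)) {
    gt <- movie$truth
    gt$cilia_zone <- NULL
    gt$bead_paths <- NULL
    jsonlite::write_json(gt, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(tif_path)
}
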