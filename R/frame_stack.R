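#' Grey-level movie with acquisition metadata
#'
#' A `frame_stack` holds a high-speed video-microscopy recording as an
#' H x W x T array of grey levels (0-255) together with the frame rate and
#' the pixel size. The reference acquisition is 1800 frames at 358 frames/s,
#' 256 x 192 pixels of 0.32 um.
#'
#' @param data numeric or integer array, H x W x T (frames along the third
#'   dimension), grey levels in `[0, 255]`.
#' @param frame_rate frames per second.
#' @param pixel_size micrometres per pixel (square pixels).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(data, frame_rate, pixel_size) {
  if (length(dim(data)) != 3L) stop("frame stack data must be an H x W x T array")
  if (dim(data)[3L] < 2L) stop("a frame stack needs at least 2 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(data = data, frame_rate = frame_rate, pixel_size = pixel_size),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d frames, %d x %d px, %.5g fps, %.3g um/px (%.1f x %.1f um)\n",
              d[3L], d[2L], d[1L], x$frame_rate, x$pixel_size,
              d[2L] * x$pixel_size, d[1L] * x$pixel_size))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3L]

#' Frame extents in micrometres
#' @param stack a [frame_stack()].
#' @return c(width_um, height_um).
#' @export
frame_extent <- function(stack) {
  d <- dim(stack$data)
  c(width = d[2L] * stack$pixel_size, height = d[1L] * stack$pixel_size)
}

#' Read a multi-page TIFF movie
#'
#' @param path path to an 8/16-bit grey multi-page TIFF.
#' @param frame_rate,pixel_size acquisition metadata (not stored in plain
#'   TIFF tags by this package, so they are supplied here).
#' @return a [frame_stack()] with grey levels rescaled to 0-255.
#' @export
read_frame_stack <- function(path, frame_rate, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # drop colour channels if any
    arr[, , t] <- pg * 255
  }
  frame_stack(arr, frame_rate, pixel_size)
}

#' Write a movie as a multi-page 8-bit grey TIFF
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  tt <- n_frames(stack)
  pages <- vector("list", tt)
  for (t in seq_len(tt))
    pages[[t]] <- pmin(pmax(stack$data[, , t], 0), 255) / 255
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

# Bilinear grey-level samples at fixed um positions, for every frame.
# Returns a T x n matrix. Pixel (i, j) (row, col) has its centre at
# ((j - 0.5) * ps, (i - 0.5) * ps).
grey_series_at <- function(stack, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  d <- dim(stack$data); h <- d[1L]; w <- d[2L]; tt <- d[3L]
  ps <- stack$pixel_size
  gx <- pts[, 1L] / ps + 0.5  # fractional column
  gy <- pts[, 2L] / ps + 0.5  # fractional row
  if (any(gx < 0.5 | gx > w + 0.5 | gy < 0.5 | gy > h + 0.5)) {
    bad <- which(gx < 0.5 | gx > w + 0.5 | gy < 0.5 | gy > h + 0.5)[1L]
    stop(sprintf("sampling point %d at (%.2f, %.2f) um lies outside the image",
                 bad, pts[bad, 1L], pts[bad, 2L]))
  }
  gx <- pmin(pmax(gx, 1), w); gy <- pmin(pmax(gy, 1), h)
  j0 <- pmin(floor(gx), w - 1L); i0 <- pmin(floor(gy), h - 1L)
  fx <- gx - j0; fy <- gy - i0
  lin <- function(i, j) (j - 1L) * h + i           # column-major linear index
  flat <- stack$data
  dim(flat) <- c(h * w, tt)
  w11 <- (1 - fx) * (1 - fy); w21 <- (1 - fx) * fy
  w12 <- fx * (1 - fy);       w22 <- fx * fy
  m <- sweep(t(flat[lin(i0, j0), , drop = FALSE]), 2L, w11, `*`) +
       sweep(t(flat[lin(i0 + 1L, j0), , drop = FALSE]), 2L, w21, `*`) +
       sweep(t(flat[lin(i0, j0 + 1L), , drop = FALSE]), 2L, w12, `*`) +
       sweep(t(flat[lin(i0 + 1L, j0 + 1L), , drop = FALSE]), 2L, w22, `*`)
  m
}

# Pixel-centre coordinate grids in um for an H x W frame.
pixel_centres <- function(h, w, pixel_size) {
  list(x = matrix(((1:w) - 0.5) * pixel_size, h, w, byrow = TRUE),
       y = matrix(((1:h) - 0.5) * pixel_size, h, w))
}

#' Time-averaged frame of a movie
#' @param stack a [frame_stack()].
#' @return an H x W matrix of mean grey levels.
#' @export
mean_frame <- function(stack) {
  d <- dim(stack$data)
  flat <- stack$data
  dim(flat) <- c(d[1L] * d[2L], d[3L])
  matrix(rowMeans(flat), d[1L], d[2L])
}
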