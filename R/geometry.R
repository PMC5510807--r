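#' Ciliated-edge polyline
#'
#' The location of the cilia wall is marked by an operator as 5 points
#' delimiting 4 line segments, in micrometres, with the image convention of
#' x increasing rightward and y increasing downward from the top-left pixel
#' corner. All distances, kymograph abscissae and density zones are referred
#' to this polyline.
#'
#' @param points a 5 x 2 numeric matrix (or data frame) of (x, y) positions
#'   in micrometres, ordered along the edge.
#' @return an object of class `edge_polyline` with components `points`,
#'   per-segment unit `tangents`, segment `lengths` and the cumulative
#'   curvilinear abscissa `cumlen` at each vertex.
#' @examples
#' edge_polyline(cbind(x = c(0, 20, 40, 60, 80), y = rep(10, 5)))
#' @export
edge_polyline <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 5L || ncol(points) != 2L)
    stop("an edge polyline needs exactly 5 (x, y) points")
  if (anyNA(points)) stop("edge polyline points contain NA")
  d <- diff(points)
  lengths <- sqrt(rowSums(d^2))
  if (any(lengths == 0)) stop("consecutive polyline points must be distinct")
  structure(
    list(points   = unname(points),
         tangents = d / lengths,
         lengths  = lengths,
         cumlen   = c(0, cumsum(lengths))),
    class = "edge_polyline")
}

#' @export
print.edge_polyline <- function(x, ...) {
  cat("edge_polyline: 5 points / 4 segments, total length",
      format(polyline_length(x), digits = 4), "um\n")
  invisible(x)
}

#' Total curvilinear length of an edge polyline
#' @param line an [edge_polyline()].
#' @return length in micrometres.
#' @export
polyline_length <- function(line) line$cumlen[5L]

#' Point and local frame at a curvilinear abscissa
#'
#' @param line an [edge_polyline()].
#' @param s curvilinear abscissae in micrometres (vector), clamped to
#'   `[0, polyline_length(line)]`.
#' @return a list with matrices `xy` (position), `tangent` and `normal`.
#'   The normal is the tangent rotated a quarter turn towards increasing y
#'   for a left-to-right segment, i.e. towards the bead side.
#' @export
polyline_point_at <- function(line, s) {
  s <- pmin(pmax(s, 0), polyline_length(line))
  seg <- pmin(findInterval(s, line$cumlen, rightmost.closed = TRUE), 4L)
  tloc <- s - line$cumlen[seg]
  xy <- line$points[seg, , drop = FALSE] + line$tangents[seg, , drop = FALSE] * tloc
  tg <- line$tangents[seg, , drop = FALSE]
  nm <- cbind(-tg[, 2L], tg[, 1L])
  list(xy = xy, tangent = tg, normal = nm, segment = seg)
}

#' Project points onto an edge polyline
#'
#' For each query point the nearest point on the 4 segments is found.
#'
#' @param line an [edge_polyline()].
#' @param pts an n x 2 matrix of (x, y) positions in micrometres.
#' @return a data frame with one row per point: `dist` (unsigned distance,
#'   um), `signed` (positive on the bead side, i.e. the +normal side of the
#'   nearest segment), `s` (curvilinear abscissa of the foot point), and the
#'   nearest segment's index and unit tangent/normal components.
#' @export
polyline_project <- function(line, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(pts)
  best <- list(dist = rep(Inf, n), signed = numeric(n), s = numeric(n),
               seg = integer(n), tx = numeric(n), ty = numeric(n))
  for (i in 1:4) {
    a <- line$points[i, ]; tg <- line$tangents[i, ]; len <- line$lengths[i]
    rx <- pts[, 1L] - a[1L]; ry <- pts[, 2L] - a[2L]
    tproj <- pmin(pmax(rx * tg[1L] + ry * tg[2L], 0), len)
    dx <- rx - tproj * tg[1L]; dy <- ry - tproj * tg[2L]
    d2 <- dx * dx + dy * dy
    upd <- d2 < best$dist^2
    if (any(upd)) {
      best$dist[upd] <- sqrt(d2[upd])
      # sign via the segment normal (-ty, tx): positive below a rightward segment
      best$signed[upd] <- rx[upd] * (-tg[2L]) + ry[upd] * tg[1L]
      best$signed[upd] <- sign(best$signed[upd]) * best$dist[upd]
      best$s[upd] <- line$cumlen[i] + tproj[upd]
      best$seg[upd] <- i
      best$tx[upd] <- tg[1L]; best$ty[upd] <- tg[2L]
    }
  }
  data.frame(dist = best$dist, signed = best$signed, s = best$s,
             segment = best$seg, tx = best$tx, ty = best$ty,
             nx = -best$ty, ny = best$tx)
}

#' Distance from points to the ciliated edge
#'
#' Minimum point-to-segment distance over the 4 segments of the polyline.
#'
#' @inheritParams polyline_project
#' @return numeric vector of distances in micrometres.
#' @export
distance_to_edge <- function(line, pts) polyline_project(line, pts)$dist

#' Resample a polyline at uniform curvilinear steps
#'
#' @param line an [edge_polyline()].
#' @param step target step in micrometres; the actual step divides the total
#'   length exactly.
#' @return list with `xy` (S x 2 positions), `s` (abscissae) and `step` (um).
#' @export
polyline_resample <- function(line, step) {
  stopifnot(step > 0)
  L <- polyline_length(line)
  nseg <- max(2L, ceiling(L / step))
  s <- seq(0, L, length.out = nseg + 1L)
  p <- polyline_point_at(line, s)
  list(xy = p$xy, s = s, step = L / nseg)
}

#' Read landmark points from a JSON file
#'
#' Expects `{"points": [[x, y], ...]}` with coordinates in micrometres,
#' origin at the top-left pixel corner, y increasing downward.
#'
#' @param path JSON file path.
#' @return an n x 2 numeric matrix.
#' @export
read_points_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$points)) stop("JSON landmark file must contain a 'points' key")
  matrix(as.numeric(as.matrix(obj$points)), ncol = 2L)
}
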