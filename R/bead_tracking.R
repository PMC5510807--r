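#' Track filter policy
#'
#' Gates applied during trajectory linking and selection. Beads are sparse
#' and slow (at most ~0.7 um/frame at the reference frame rate), so a tight
#' nearest-neighbour gate keeps the assignment unambiguous. Only beads
#' following straight trajectories essentially parallel to the ciliated
#' edge are retained for the velocity profile.
#'
#' @param max_link_distance maximum frame-to-frame displacement in um.
#' @param min_track_length minimum number of detections per track.
#' @param min_straightness floor on the straightness (R^2 of a total
#'   least-squares line fit to the positions).
#' @param max_vertical_ratio maximum allowed `|mean u_y| / |mean u_x|`
#'   (perpendicular over parallel mean velocity).
#' @return a `track_filter_policy` list.
#' @export
track_filter_policy <- function(max_link_distance = 3, min_track_length = 10L,
                                min_straightness = 0.9, max_vertical_ratio = 0.25) {
  stopifnot(max_link_distance > 0, min_track_length > 0,
            min_straightness > 0, max_vertical_ratio > 0,
            max_vertical_ratio <= 1)
  structure(list(max_link_distance = max_link_distance,
                 min_track_length = as.integer(min_track_length),
                 min_straightness = min_straightness,
                 max_vertical_ratio = max_vertical_ratio),
            class = "track_filter_policy")
}

#' Segment micro-beads in one frame
#'
#' Thresholds the frame (beads are darker than the background), labels
#' connected components, and keeps components within the area gates;
#' components touching the image border are discarded (clipped discs have
#' biased centroids). The
#' centroid is darkness-weighted (weight `threshold - grey`) for sub-pixel
#' accuracy on anti-aliased discs.
#'
#' @param frame an H x W grey-level matrix.
#' @param pixel_size um per pixel.
#' @param threshold grey level; pixels strictly darker belong to beads. Use
#'   `NULL` for an Otsu fallback on the frame histogram.
#' @param area_gates length-2 vector, minimum and maximum component area in
#'   um^2; the default brackets a 4.5 um bead (~15.9 um^2).
#' @return data frame with one row per detection: `x_um`, `y_um`,
#'   `area_um2`.
#' @export
segment_beads <- function(frame, pixel_size, threshold = 80,
                          area_gates = c(8, 32)) {
  if (is.null(threshold)) threshold <- otsu_threshold(frame)
  if (threshold < min(0, min(frame)) || threshold > 255)
    stop("threshold outside the grey range")
  mask <- frame < threshold
  if (!any(mask))
    return(data.frame(x_um = numeric(), y_um = numeric(), area_um2 = numeric()))
  lab <- EBImage::bwlabel(mask)
  px_area <- pixel_size^2
  ids <- seq_len(max(lab))
  out <- lapply(ids, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx) * px_area
    if (area < area_gates[1L] || area > area_gates[2L]) return(NULL)
    # a component touching the border is clipped: its centroid is biased
    if (any(idx[, 1L] %in% c(1L, nrow(frame))) ||
        any(idx[, 2L] %in% c(1L, ncol(frame)))) return(NULL)
    wgt <- threshold - frame[idx]
    wgt <- pmax(wgt, 0); wgt <- wgt / sum(wgt)
    data.frame(x_um = sum((idx[, 2L] - 0.5) * wgt) * pixel_size,
               y_um = sum((idx[, 1L] - 0.5) * wgt) * pixel_size,
               area_um2 = area)
  })
  do.call(rbind, c(out, list(data.frame(x_um = numeric(), y_um = numeric(),
                                        area_um2 = numeric()))))
}

otsu_threshold <- function(frame) {
  g <- pmin(pmax(round(frame), 0), 255)
  cnt <- tabulate(g + 1L, nbins = 256L)
  p <- cnt / sum(cnt)
  w <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256L]
  sb2 <- (mu_t * w - mu)^2 / (w * (1 - w))
  sb2[!is.finite(sb2)] <- 0
  which.max(sb2) - 1L
}

#' Detect beads in every frame of a movie
#'
#' @param stack a [frame_stack()].
#' @inheritParams segment_beads
#' @return data frame with columns `frame`, `x_um`, `y_um`, `area_um2`.
#' @export
detect_beads <- function(stack, threshold = 80, area_gates = c(8, 32)) {
  out <- lapply(seq_len(n_frames(stack)), function(t) {
    d <- segment_beads(stack$data[, , t], stack$pixel_size, threshold, area_gates)
    if (nrow(d)) cbind(frame = t, d) else NULL
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric())
  res
}

#' Link per-frame detections into bead trajectories
#'
#' Greedy nearest-neighbour frame-to-frame assignment: candidate links
#' between tracks active in the previous frame and current detections are
#' taken in order of increasing distance (ties broken deterministically by
#' lowest track then detection index); links longer than the gate are
#' refused; unmatched detections start new tracks; tracks shorter than the
#' minimum length are dropped. No gap closing is attempted.
#'
#' @param detections data frame from [detect_beads()], sorted by frame.
#' @param policy a [track_filter_policy()].
#' @return data frame of the retained detections with a `track_id` column.
#' @export
link_tracks <- function(detections, policy = track_filter_policy()) {
  if (nrow(detections) == 0L)
    return(cbind(detections, track_id = integer(0)))
  detections <- detections[order(detections$frame), , drop = FALSE]
  detections$track_id <- NA_integer_
  next_id <- 1L
  prev_rows <- integer(0)  # row indices of detections in the previous frame
  frames <- sort(unique(detections$frame))
  for (f in frames) {
    cur_rows <- which(detections$frame == f)
    if (length(prev_rows)) {
      dmat <- outer(seq_along(prev_rows), seq_along(cur_rows),
                    function(i, j)
                      sqrt((detections$x_um[prev_rows[i]] - detections$x_um[cur_rows[j]])^2 +
                           (detections$y_um[prev_rows[i]] - detections$y_um[cur_rows[j]])^2))
      cand <- which(dmat <= policy$max_link_distance, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], cand[, 1L], cand[, 2L])
        used_p <- logical(length(prev_rows)); used_c <- logical(length(cur_rows))
        for (kk in ord) {
          i <- cand[kk, 1L]; j <- cand[kk, 2L]
          if (used_p[i] || used_c[j]) next
          used_p[i] <- TRUE; used_c[j] <- TRUE
          detections$track_id[cur_rows[j]] <- detections$track_id[prev_rows[i]]
        }
      }
    }
    new <- cur_rows[is.na(detections$track_id[cur_rows])]
    if (length(new)) {
      detections$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev_rows <- cur_rows
  }
  keep <- table(detections$track_id)
  keep_ids <- as.integer(names(keep)[keep >= policy$min_track_length])
  out <- detections[detections$track_id %in% keep_ids, , drop = FALSE]
  # renumber compactly in order of first appearance
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  out
}

#' Per-step kinematics of linked tracks
#'
#' Instantaneous velocities by forward difference times the frame rate,
#' decomposed into components parallel (`ux`) and perpendicular (`uy`) to
#' the nearest edge segment; the distance to the ciliated edge is the
#' minimum point-to-segment distance over the 4 segments.
#'
#' @param tracks data frame from [link_tracks()].
#' @param edge an [edge_polyline()].
#' @param frame_rate frames per second.
#' @return `tracks` with added columns `dist_um`, `ux_um_s`, `uy_um_s`
#'   (velocity columns are `NA` on the last detection of each track).
#' @export
track_kinematics <- function(tracks, edge, frame_rate) {
  if (nrow(tracks) == 0L) {
    tracks$dist_um <- tracks$ux_um_s <- tracks$uy_um_s <- numeric(0)
    return(tracks)
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  proj <- polyline_project(edge, cbind(tracks$x_um, tracks$y_um))
  tracks$dist_um <- proj$dist
  n <- nrow(tracks)
  same <- c(tracks$track_id[-1L] == tracks$track_id[-n], FALSE)
  dx <- c(diff(tracks$x_um), NA) * frame_rate
  dy <- c(diff(tracks$y_um), NA) * frame_rate
  dframe <- c(diff(tracks$frame), NA)
  dx <- dx / dframe; dy <- dy / dframe
  dx[!same] <- NA; dy[!same] <- NA
  tracks$ux_um_s <- dx * proj$tx + dy * proj$ty
  tracks$uy_um_s <- dx * proj$nx + dy * proj$ny
  rownames(tracks) <- NULL
  tracks
}

# Straightness: R^2 of a total-least-squares (principal axis) line fit,
# 1 - minor/total variance.
tls_straightness <- function(x, y) {
  if (length(x) < 3L) return(NA_real_)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (sum(ev) <= 0) return(NA_real_)
  1 - ev[2L] / sum(ev)
}

#' Per-track summary
#'
#' @param tracks data frame from [track_kinematics()].
#' @return one row per track: mean speed `v_b` (um/s, mean step speed),
#'   mean distance to the edge `y0` (um), mean parallel and perpendicular
#'   velocities, `straightness`, and the track length in frames.
#' @export
summarize_tracks <- function(tracks) {
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(), n = integer(), v_b = numeric(),
                      y0 = numeric(), mean_ux = numeric(), mean_uy = numeric(),
                      straightness = numeric()))
  sp <- split(tracks, tracks$track_id)
  out <- lapply(sp, function(tr) {
    v <- sqrt(tr$ux_um_s^2 + tr$uy_um_s^2)
    data.frame(track_id = tr$track_id[1L], n = nrow(tr),
               v_b = mean(v, na.rm = TRUE),
               y0 = mean(tr$dist_um),
               mean_ux = mean(tr$ux_um_s, na.rm = TRUE),
               mean_uy = mean(tr$uy_um_s, na.rm = TRUE),
               straightness = tls_straightness(tr$x_um, tr$y_um))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the trajectory selection filters
#'
#' Keeps tracks that are straight (`straightness >= min_straightness`) and
#' essentially parallel to the edge
#' (`|mean uy| <= max_vertical_ratio * |mean ux|`). Every rejection is
#' labelled with the failed criterion.
#'
#' @param summary data frame from [summarize_tracks()].
#' @param policy a [track_filter_policy()].
#' @return `summary` with added columns `kept` (logical) and `reason`
#'   (`""`, `"straightness"` or `"vertical"`).
#' @export
filter_tracks <- function(summary, policy = track_filter_policy()) {
  straight <- !is.na(summary$straightness) &
    summary$straightness >= policy$min_straightness
  vert_ok <- abs(summary$mean_uy) <= policy$max_vertical_ratio * abs(summary$mean_ux)
  summary$kept <- straight & vert_ok
  summary$reason <- ifelse(summary$kept, "",
                           ifelse(!straight, "straightness", "vertical"))
  summary
}

#' Track beads in a movie, end to end
#'
#' Convenience wrapper chaining [detect_beads()], [link_tracks()],
#' [track_kinematics()], [summarize_tracks()] and [filter_tracks()].
#'
#' @inheritParams detect_beads
#' @param edge an [edge_polyline()].
#' @param policy a [track_filter_policy()].
#' @return list with `tracks` (per-detection table) and `summary` (per-bead
#'   table with selection flags).
#' @export
track_beads <- function(stack, edge, threshold = 80, area_gates = c(8, 32),
                        policy = track_filter_policy()) {
  det <- detect_beads(stack, threshold, area_gates)
  trk <- link_tracks(det, policy)
  trk <- track_kinematics(trk, edge, stack$frame_rate)
  summ <- filter_tracks(summarize_tracks(trk), policy)
  list(tracks = trk, summary = summ)
}
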