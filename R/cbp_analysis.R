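#' Ciliary beat frequency from the FFT power spectrum
#'
#' The mean grey level sampled along the edge polyline is computed for every
#' frame; the frequency of highest power in the FFT of this signal,
#' restricted to a physiological search band, is taken as the ciliary beat
#' frequency (CBF). Spectral resolution is `frame_rate / n_frames`.
#'
#' @param stack a [frame_stack()].
#' @param line an [edge_polyline()] on the ciliated edge.
#' @param f_min,f_max search band in Hz; the default 0.5-30 Hz covers the
#'   physiological range while excluding DC.
#' @param flatness_k a dominant peak must exceed `flatness_k` times the
#'   median in-band power, otherwise the spectrum is declared flat.
#' @return a list of class `cbf_estimate`: `cbf` (Hz), `power` (data frame
#'   `freq`, `power` over the positive frequencies), `resolution` (Hz).
#' @export
cbf_fft <- function(stack, line, f_min = 0.5, f_max = 30, flatness_k = 10) {
  tt <- n_frames(stack)
  if (tt < 64L) stop("need at least 64 frames for a spectral CBF estimate")
  nyq <- stack$frame_rate / 2
  if (!(0 < f_min && f_min < f_max && f_max < nyq))
    stop("need 0 < f_min < f_max < frame_rate/2")
  rs <- polyline_resample(line, stack$pixel_size)
  sig <- rowMeans(grey_series_at(stack, rs$xy))
  spec <- power_spectrum(sig, stack$frame_rate)
  band <- spec$freq >= f_min & spec$freq <= f_max
  pk <- pick_peak(spec$power[band])
  if (is.null(pk) || max(spec$power[band]) < flatness_k * stats::median(spec$power[band]))
    stop("no dominant frequency: spectrum is flat in the search band")
  structure(list(cbf = spec$freq[band][pk], power = spec,
                 resolution = stack$frame_rate / tt),
            class = "cbf_estimate")
}

power_spectrum <- function(sig, fs) {
  n <- length(sig)
  sig <- sig - mean(sig)
  p <- Mod(stats::fft(sig))^2 / n
  keep <- 2:(floor(n / 2) + 1L)
  data.frame(freq = (keep - 1L) * fs / n, power = p[keep])
}

pick_peak <- function(p) {
  if (all(p <= 0) || !any(is.finite(p))) return(NULL)
  which.max(p)
}

#' @export
print.cbf_estimate <- function(x, ...) {
  cat(sprintf("CBF = %.2f Hz (resolution %.3f Hz)\n", x$cbf, x$resolution))
  invisible(x)
}

#' Build a video-kymograph along the ciliated edge
#'
#' Stacks the grey levels resampled at uniform curvilinear steps along the
#' polyline, one row per frame.
#'
#' @inheritParams cbf_fft
#' @param step resampling step along the polyline in um; defaults to one
#'   pixel.
#' @return an object of class `kymograph`: `matrix` (T x S grey levels),
#'   `abscissa_step` (um), `time_step` (s).
#' @export
build_kymograph <- function(stack, line, step = stack$pixel_size) {
  rs <- polyline_resample(line, step)
  m <- grey_series_at(stack, rs$xy)  # errors if the polyline exits the image
  structure(list(matrix = m, abscissa_step = rs$step,
                 time_step = 1 / stack$frame_rate),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions (step %.3g um, dt %.4g s)\n",
              nrow(x$matrix), ncol(x$matrix), x$abscissa_step, x$time_step))
  invisible(x)
}

#' Ciliary beat frequency from kymograph periodicity
#'
#' The temporal autocorrelation of every kymograph column is averaged; the
#' beating period is the dominant positive-lag peak of this mean
#' autocorrelation, refined to sub-lag precision by quadratic interpolation.
#'
#' @param kymo a [build_kymograph()] result.
#' @param min_peak minimum averaged autocorrelation at the period lag for
#'   the period to count as measurable.
#' @return CBF in Hz.
#' @export
cbf_kymograph <- function(kymo, min_peak = 0.1) {
  m <- kymo$matrix
  tt <- nrow(m)
  max_lag <- floor(tt / 2)
  cols <- sweep(m, 2L, colMeans(m))
  ok <- apply(cols, 2L, stats::sd) > 0
  if (!any(ok)) stop("no measurable period: kymograph has no temporal variation")
  acfs <- vapply(which(ok), function(j)
    stats::acf(cols[, j], lag.max = max_lag, plot = FALSE,
               demean = FALSE)$acf[, 1L, 1L],
    numeric(max_lag + 1L))
  a <- rowMeans(acfs)
  # first local maximum after the zero-lag peak decays
  lag <- local_max_lag(a)
  if (is.null(lag) || a[lag + 1L] < min_peak)
    stop("no measurable period: no autocorrelation peak above threshold")
  # quadratic refinement around the integer lag
  num <- a[lag] - a[lag + 2L]
  den <- a[lag] - 2 * a[lag + 1L] + a[lag + 2L]
  delta <- if (abs(den) > .Machine$double.eps) 0.5 * num / den else 0
  period <- (lag + delta) * kymo$time_step
  1 / period
}

local_max_lag <- function(a) {
  # a[k+1] is autocorrelation at lag k; find the highest interior local max
  n <- length(a) - 1L
  if (n < 3L) return(NULL)
  lags <- 2:(n - 1L)
  is_max <- a[lags + 1L] > a[lags] & a[lags + 1L] >= a[lags + 2L]
  if (!any(is_max)) return(NULL)
  cand <- lags[is_max]
  cand[which.max(a[cand + 1L])]
}

#' Ciliary beat amplitude from tip landmarks
#'
#' The operator marks the cilium base `p0` and the tip positions before the
#' effective and recovery strokes (`p1`, `p2`). The beat amplitude (CBA) is
#' the distance travelled by the tip between its extreme positions,
#' `|p1 p2|`; the cilium length is the mean of `|p0 p1|` and `|p0 p2|`.
#'
#' @param p0,p1,p2 numeric length-2 (x, y) positions in um.
#' @return list with `cba` and `cilium_length`, both in um.
#' @export
measure_cba <- function(p0, p1, p2) {
  pts <- rbind(p0, p1, p2)
  if (anyNA(pts)) stop("landmarks contain NA")
  cba <- sqrt(sum((p1 - p2)^2))
  if (cba == 0) warning("P1 and P2 coincide: degenerate beat with zero amplitude")
  len <- mean(c(sqrt(sum((p1 - p0)^2)), sqrt(sum((p2 - p0)^2))))
  list(cba = cba, cilium_length = len)
}

#' Metachronal wavelength by phase regression along the edge
#'
#' Equally spaced line segments perpendicular to the cilia wall are laid
#' along the polyline (104 segments of 24 pixels by default, centred on the
#' wall). For each segment the phase of its mean grey-level time series at
#' the CBF bin is extracted by FFT, unwrapped along the curvilinear
#' abscissa, and regressed linearly on abscissa: `theta(x) = p x + c`. The
#' wavelength is `lambda = 2*pi/|p|`.
#'
#' @inheritParams cbf_fft
#' @param n_segments number of perpendicular segments.
#' @param segment_len segment length in pixels.
#' @param cbf optional CBF in Hz; computed by [cbf_fft()] when missing.
#' @param min_r2 regression quality floor below which the wavelength is
#'   declared not measurable.
#' @return list with `wavelength` (um), `slope` (rad/um, signed), `r2`, and
#'   the per-segment `phase` data frame.
#' @export
metachronal_wavelength <- function(stack, line, n_segments = 104L,
                                   segment_len = 24L, cbf = NULL,
                                   min_r2 = 0.8) {
  if (n_segments < 3L) stop("need at least 3 segments")
  if (is.null(cbf)) cbf <- cbf_fft(stack, line)$cbf
  tt <- n_frames(stack)
  bin <- round(cbf * tt / stack$frame_rate) + 1L  # index into fft output
  L <- polyline_length(line)
  s_centres <- seq(0, L, length.out = n_segments)
  pf <- polyline_point_at(line, s_centres)
  offsets <- (seq_len(segment_len) - (segment_len + 1) / 2) * stack$pixel_size
  theta <- numeric(n_segments)
  ext <- frame_extent(stack)
  for (i in seq_len(n_segments)) {
    pts <- cbind(pf$xy[i, 1L] + pf$normal[i, 1L] * offsets,
                 pf$xy[i, 2L] + pf$normal[i, 2L] * offsets)
    inside <- pts[, 1L] >= 0 & pts[, 1L] <= ext[1L] &
              pts[, 2L] >= 0 & pts[, 2L] <= ext[2L]
    sig <- rowMeans(grey_series_at(stack, pts[inside, , drop = FALSE]))
    theta[i] <- Arg(stats::fft(sig - mean(sig))[bin])
  }
  theta_u <- unwrap_phase(theta)
  if (diff(range(theta_u)) < 0.1)
    stop("wavelength not measurable: segments beat in phase (no phase gradient)")
  fit <- stats::lm(theta_u ~ s_centres)
  r2 <- summary(fit)$r.squared
  if (is.na(r2) || r2 < min_r2)
    stop(sprintf("wavelength not measurable: phase regression R^2 = %.2f below %.2f",
                 r2, min_r2))
  p <- unname(stats::coef(fit)[2L])
  list(wavelength = 2 * pi / abs(p), slope = p, r2 = r2,
       phase = data.frame(s = s_centres, theta = theta_u))
}

unwrap_phase <- function(theta) {
  d <- diff(theta)
  corr <- cumsum(round(-d / (2 * pi))) * 2 * pi
  theta + c(0, corr)
}

#' Cilia density from grey levels
#'
#' Cilia appear darker than the background; the density is the fraction of
#' pixels of the cilia zone (time-averaged frame) darker than the mean grey
#' level of the background zone. Modeling the ciliated edge as parallel
#' cilia of diameter `e_c` separated by gaps `d_c` gives
#' `rho_c = e_c / (e_c + d_c)`, hence `d_c = e_c (1 - rho_c) / rho_c` and a
#' gap fraction `f_c = 1 - rho_c`.
#'
#' @param stack a [frame_stack()].
#' @param cilia_zone,background_zone disjoint logical H x W masks (>= 100
#'   pixels each).
#' @param e_c cilium diameter in um.
#' @return list with `rho_c`, `d_c` (um; `NA` when `rho_c` is 0), `f_c`,
#'   and the background mean grey level.
#' @export
cilia_density <- function(stack, cilia_zone, background_zone, e_c = 0.2) {
  avg <- mean_frame(stack)
  if (!is.logical(cilia_zone) || !is.logical(background_zone) ||
      any(dim(cilia_zone) != dim(avg)) || any(dim(background_zone) != dim(avg)))
    stop("zones must be logical masks with the frame dimensions")
  if (any(cilia_zone & background_zone)) stop("zones must be disjoint")
  if (sum(cilia_zone) < 100L || sum(background_zone) < 100L)
    stop("each zone needs at least 100 pixels")
  bg <- mean(avg[background_zone])
  rho <- mean(avg[cilia_zone] < bg)
  d_c <- if (rho > 0) e_c * (1 - rho) / rho else NA_real_
  if (rho == 0) message("rho_c = 0: inter-cilia distance d_c is undefined")
  list(rho_c = rho, d_c = d_c, f_c = 1 - rho, background_mean = bg)
}
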