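#' Reference per-edge ciliary beat and velocity-profile parameters
#'
#' Measurements from 24 ciliated edges of nasal brushing samples from 11
#' patients, recorded by high-speed video-microscopy with suspended
#' micro-beads: per edge the number of tracked beads, ciliary beat
#' frequency (Hz), beat amplitude (um), metachronal wavelength (um), cilia
#' density (percent), the stagnant height `h` and wall velocity `Uw`
#' fitted from the parabolic bead-velocity profile (um, um/s), and the
#' reported shear-stress index (mPa).
#'
#' One edge (patient 2, edge 1) reports an index inconsistent with
#' `2*mu*Uw/h` evaluated from its own `h` and `Uw` (an apparent transcription
#' error in `h`); [check_edge_consistency()] flags it.
#'
#' @return a data frame with columns `patient`, `edge`, `n_beads`,
#'   `cbf_hz`, `cba_um`, `lambda_um`, `rho_c_pct`, `h_um`, `uw_um_s`,
#'   `tau_w_mpa`.
#' @export
edge_parameters <- function() {
  path <- system.file("extdata", "edge_parameters.csv", package = "ciliaflow",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Flag edges whose reported index disagrees with its inputs
#'
#' Recomputes `tau_w = 2*mu*Uw/h` for every edge of [edge_parameters()] and
#' compares with the reported value at the printed precision.
#'
#' @param tol agreement tolerance in mPa (half a printed decimal by
#'   default).
#' @param mu dynamic viscosity in Pa s.
#' @return the edge table with added columns `tau_w_recomputed` and
#'   `consistent`.
#' @export
check_edge_consistency <- function(tol = 0.05, mu = 1e-3) {
  tab <- edge_parameters()
  tab$tau_w_recomputed <- shear_stress(tab$uw_um_s, tab$h_um, mu)
  tab$consistent <- abs(tab$tau_w_recomputed - tab$tau_w_mpa) <= tol
  tab
}
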