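#' Fit the parabolic velocity profile
#'
#' Least-squares fit of `V(y) = Uw * (1 - y/h)^2` to effective-velocity
#' samples. This functional form satisfies `V(0) = Uw`, `V(h) = 0` and
#' `dV/dy(h) = 0` (no momentum flux into the stagnant fluid above `h`), and
#' its wall shear is `mu |dV/dy|(0) = 2 mu Uw / h` - the factor 2 of the
#' efficiency index. `h` is read as the x-intercept of the fit and `Uw` as
#' the extrapolated velocity at the ciliated wall.
#'
#' @param samples data frame with columns `y0` (um) and `v` (um/s), and
#'   optionally `weight`.
#' @return list of class `parabola_fit` with `uw` (um/s), `h` (um),
#'   `r2`, `sigma` (residual SD), `n`, and the `fit` object. All-zero
#'   velocities give `uw = 0`, `h = NA` and `degenerate = TRUE`.
#' @export
fit_parabola <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("y0", "v") %in% names(samples)))
  samples <- samples[is.finite(samples$y0) & is.finite(samples$v), , drop = FALSE]
  if (length(unique(samples$y0)) < 3L)
    stop("need at least 3 samples with distinct altitudes")
  w <- if ("weight" %in% names(samples)) samples$weight else rep(1, nrow(samples))
  if (all(samples$v == 0)) {
    warning("all velocities are zero: Uw = 0 and h is indeterminate")
    return(structure(list(uw = 0, h = NA_real_, r2 = NA_real_,
                          sigma = 0, n = nrow(samples), degenerate = TRUE,
                          fit = NULL), class = "parabola_fit"))
  }
  # starting values from the quadratic regression v ~ 1 + y + y^2:
  # v = uw - (2 uw / h) y + (uw / h^2) y^2
  q <- stats::lm(v ~ y0 + I(y0^2), data = samples, weights = w)
  cf <- stats::coef(q)
  uw0 <- max(cf[[1L]], max(samples$v) / 2, 1e-6)
  h0 <- if (is.finite(cf[[2L]]) && cf[[2L]] < 0) -2 * cf[[1L]] / cf[[2L]] else
    2 * max(samples$y0)
  if (!is.finite(h0) || h0 <= 0) h0 <- 2 * max(samples$y0)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ uw * (1 - y0 / h)^2, data = samples,
                      start = list(uw = uw0, h = h0), weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("parabolic fit did not converge (start uw = %.3g, h = %.3g): %s",
                   uw0, h0, conditionMessage(e))))
  est <- stats::coef(fit)
  res <- stats::resid(fit)
  ss_tot <- sum(w * (samples$v - stats::weighted.mean(samples$v, w))^2)
  structure(list(uw = unname(est[["uw"]]), h = unname(est[["h"]]),
                 r2 = if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else NA_real_,
                 sigma = sqrt(sum(w * res^2) / max(1, nrow(samples) - 2)),
                 n = nrow(samples), degenerate = FALSE, fit = fit),
            class = "parabola_fit")
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("parabolic profile fit: Uw = %.4g um/s, h = %.4g um (R^2 = %.3f, n = %d)\n",
              x$uw, x$h, x$r2, x$n))
  invisible(x)
}

#' Wall shear-stress efficiency index
#'
#' `tau_w = 2 mu Uw / h`, the steady tangential stress the ciliated edge
#' exerts on the fluid, from the extrapolated wall velocity `Uw` and the
#' x-intercept `h` of the parabolic velocity profile. Proposed as a global
#' index of ciliary beating efficiency.
#'
#' @param uw extrapolated wall velocity in um/s.
#' @param h profile x-intercept (stagnant height) in um.
#' @param mu dynamic viscosity in Pa s (water by default).
#' @return shear stress in mPa.
#' @export
shear_stress <- function(uw, h, mu = 1e-3) {
  if (any(h <= 0)) stop("h must be > 0")
  # (um/s) / um = 1/s; times Pa s = Pa; times 1000 = mPa
  2 * mu * uw / h * 1000
}

#' Couette-flow shear stress
#'
#' `tau = mu V / e` for plane Couette flow between parallel plates at
#' distance `e` and relative velocity `V`. Putting `e = h` and `V = Uw`
#' shows the efficiency index differs only by the factor 2 carried by the
#' parabolic (rather than linear) profile.
#'
#' @param v relative plate velocity in um/s.
#' @param e plate distance in um.
#' @param mu dynamic viscosity in Pa s.
#' @return shear stress in mPa.
#' @export
couette_stress <- function(v, e, mu = 1e-3) {
  if (any(e <= 0)) stop("plate distance e must be > 0")
  mu * v / e * 1000
}

#' Patient-level summary of per-edge shear stresses
#'
#' @param tau_w numeric vector of per-edge indices in mPa (>= 1 value).
#' @return list with `mean` and `sd` (sample SD, n - 1 denominator; `NA`
#'   for a single edge), both in mPa, and `n_edges`.
#' @export
patient_summary <- function(tau_w) {
  if (length(tau_w) == 0L) stop("need at least one edge")
  list(mean = mean(tau_w),
       sd = if (length(tau_w) > 1L) stats::sd(tau_w) else NA_real_,
       n_edges = length(tau_w))
}

#' Multiple linear regression of effective velocity on beat parameters
#'
#' Ordinary least squares of per-bead effective velocity on the five
#' exploratory variables: CBF (Hz), cilia density (fraction), CBA (um),
#' distance to the edge y0 (um) and metachronal wavelength (um), with an
#' intercept.
#'
#' @param beads data frame with columns `v_eff`, `cbf`, `rho_c`, `cba`,
#'   `y0`, `lambda` (>= 10 rows, non-collinear).
#' @return list with `coefficients` (named, incl. `(Intercept)`), `r2`,
#'   `f_pvalue`, `t_pvalues`, and the `fit`.
#' @export
fit_veff_regression <- function(beads) {
  need <- c("v_eff", "cbf", "rho_c", "cba", "y0", "lambda")
  stopifnot(all(need %in% names(beads)))
  if (nrow(beads) < 10L) stop("need at least 10 beads")
  fit <- stats::lm(v_eff ~ cbf + rho_c + cba + y0 + lambda, data = beads)
  if (fit$rank < 6L) stop("rank-deficient design: exploratory variables are collinear")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = stats::coef(fit), r2 = sm$r.squared,
       f_pvalue = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE)),
       t_pvalues = sm$coefficients[, 4L], fit = fit)
}

#' Median-split comparison of bead velocities
#'
#' Beads are split into a near and a far group at the median distance to
#' the ciliated edge; the two velocity groups are compared with a
#' two-sided Mann-Whitney U test (exact null for combined n <= 20 without
#' ties, normal approximation with tie correction otherwise).
#'
#' @param beads data frame with columns `v_b` (um/s) and `y0` (um), >= 4
#'   rows.
#' @return list with per-group `mean` and `sem`, group sizes, the `U`
#'   statistic (near group) and the two-sided `p` value.
#' @export
median_split_test <- function(beads) {
  stopifnot(all(c("v_b", "y0") %in% names(beads)))
  if (nrow(beads) < 4L) stop("need at least 4 beads")
  med <- stats::median(beads$y0)
  near <- beads$v_b[beads$y0 <= med]
  far <- beads$v_b[beads$y0 > med]
  if (length(near) == 0L || length(far) == 0L)
    stop("median split left one group empty")
  n <- length(near) + length(far)
  exact <- n <= 20 && !anyDuplicated(c(near, far))
  wt <- suppressWarnings(
    stats::wilcox.test(near, far, exact = exact, correct = TRUE))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(near = list(mean = mean(near), sem = sem(near), n = length(near)),
       far = list(mean = mean(far), sem = sem(far), n = length(far)),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Bland-Altman agreement between measured and simulated velocities
#'
#' @param pairs data frame (or 2-column matrix) of paired velocities, e.g.
#'   measured `v_b` and simulated `v_eff`.
#' @return list with `bias` (mean difference first minus second), `sd` of
#'   the differences, `limits` (bias +/- 1.96 SD) and the per-pair table
#'   (`mean`, `difference`).
#' @export
bland_altman <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L || ncol(pairs) != 2L) stop("need >= 2 pairs of velocities")
  d <- pairs[, 1L] - pairs[, 2L]
  m <- rowMeans(pairs)
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s, limits = bias + c(-1.96, 1.96) * s,
       table = data.frame(mean = m, difference = d))
}

#' Mean force per cilium implied by the shear stress
#'
#' Plain division of the wall shear stress by an areal cilia density
#' (airway epithelium carries about 5-8 cilia per um^2). The result
#' carries a caveat flag: this conversion spreads the steady wall stress
#' uniformly over the cilia and is not comparable to oscillatory
#' single-cilium force measurements.
#'
#' @param tau_w shear stress in mPa.
#' @param areal_density cilia per um^2 (> 0).
#' @return list with `force_pn` (pN per cilium) and `caveat`.
#' @export
per_cilium_force <- function(tau_w, areal_density = 5) {
  if (any(areal_density <= 0)) stop("areal density must be > 0")
  # mPa = 1e-3 N/m^2; density in um^-2 = 1e12 m^-2; N -> pN = 1e12
  force_pn <- (tau_w * 1e-3) / (areal_density * 1e12) * 1e12
  list(force_pn = force_pn,
       caveat = paste("steady wall stress divided uniformly over cilia;",
                      "not comparable to oscillatory single-cilium forces"))
}
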