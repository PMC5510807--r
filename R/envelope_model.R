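#' Envelope-model configuration
#'
#' Parameters of the 2D cilia-driven flow model. The tips of the cilia are
#' replaced by a continuous undulating envelope: the tip anchored at
#' abscissa `xi` follows the elliptic orbit
#' `X = xi - a*cos(omega*t - 2*pi*xi/lambda)`,
#' `Y = beta*a*sin(omega*t - 2*pi*xi/lambda)`,
#' with `2a` the major (horizontal) axis, `2*beta*a` the minor axis, and a
#' metachronal phase travelling along the edge (for `beta > 0` the tip
#' orbits clockwise). The envelope velocity drives an incompressible
#' Stokes flow in the strip `0 <= y <= h` through a porous-wall boundary
#' condition at `y = 0` (Navier slip of length `phi` on the tangential
#' velocity, exact matching of the normal velocity); the fluid is stagnant
#' above `h`. The slip length models the partial momentum transfer of a
#' partially covered wall and is tied to the cilia density by
#' `phi = Lambda * (1 - rho_c)^2 / rho_c` (see [phi_calc()]).
#'
#' @param cbf_hz ciliary beat frequency in Hz (`omega = 2*pi*cbf`).
#' @param cba_um beat amplitude in um (`a = cba/2`).
#' @param lambda_um metachronal wavelength in um.
#' @param rho_c cilia density as a fraction in (0, 1]; used to derive the
#'   slip length when `phi_um` is not given.
#' @param h_um channel height in um (stagnant fluid above).
#' @param lw_um observation window length in um (default the 256-pixel
#'   field of view, 81.92 um).
#' @param beta ellipse axis ratio, sign giving the orbit direction; 0.14
#'   by default.
#' @param mu_pa_s dynamic viscosity in Pa s (water by default).
#' @param lambda_const_um proportionality constant of the slip-length
#'   relation, in um.
#' @param phi_um slip length in um, overriding the value derived from
#'   `rho_c`.
#' @param wave_direction +1 for a metachronal wave travelling towards +x,
#'   -1 for the opposite.
#' @return an `envelope_model_config` list (with derived `a_um`,
#'   `omega_rad_s`, `k_um` and `phi_um`).
#' @export
envelope_model_config <- function(cbf_hz = 14, cba_um = 7.5, lambda_um = 13,
                                  rho_c = 0.84, h_um = 87.5, lw_um = 81.92,
                                  beta = 0.14, mu_pa_s = 1e-3,
                                  lambda_const_um = 750, phi_um = NULL,
                                  wave_direction = 1) {
  stopifnot(cbf_hz >= 0, cba_um >= 0, lambda_um > 0, h_um > 0, lw_um > 0,
            mu_pa_s > 0, lambda_const_um > 0, abs(beta) <= 1,
            wave_direction %in% c(-1, 1))
  if (is.null(phi_um)) phi_um <- phi_calc(rho_c, lambda_const_um)
  if (phi_um < 0) stop("slip length must be >= 0")
  structure(list(cbf_hz = cbf_hz, cba_um = cba_um, lambda_um = lambda_um,
                 rho_c = rho_c, h_um = h_um, lw_um = lw_um, beta = beta,
                 mu_pa_s = mu_pa_s, lambda_const_um = lambda_const_um,
                 phi_um = phi_um, wave_direction = wave_direction,
                 a_um = cba_um / 2, omega_rad_s = 2 * pi * cbf_hz,
                 k_um = 2 * pi / lambda_um),
            class = "envelope_model_config")
}

#' Read an envelope-model configuration from JSON
#'
#' Accepts the keys `cbf_hz`, `cba_um`, `lambda_um`, `rho_c`, `h_um`,
#' `lw_um`, `beta`, `mu_pa_s`, `lambda_const_um`, `phi_um`,
#' `wave_direction` (missing keys fall back to the defaults of
#' [envelope_model_config()]).
#'
#' @param path JSON file path.
#' @return an `envelope_model_config`.
#' @export
read_envelope_config <- function(path) {
  obj <- jsonlite::fromJSON(path)
  do.call(envelope_model_config, obj)
}

#' Position of the envelope above an anchoring abscissa
#'
#' @param xi anchoring abscissa in um (vector).
#' @param t time in s (scalar or vector conformable with `xi`).
#' @param cfg an [envelope_model_config()].
#' @return matrix with columns `x`, `y` in um.
#' @export
envelope_position <- function(xi, t, cfg) {
  th <- cfg$omega_rad_s * t - cfg$wave_direction * cfg$k_um * xi
  cbind(x = xi - cfg$a_um * cos(th), y = cfg$beta * cfg$a_um * sin(th))
}

#' Slip length from the cilia density
#'
#' `phi = Lambda * (1 - rho_c)^2 / rho_c`: sparse cilia (low density) leave
#' free-slip gaps and transfer momentum poorly, giving a large slip length;
#' full coverage recovers the no-slip wall.
#'
#' @param rho_c cilia density as a fraction in (0, 1].
#' @param lambda_const proportionality constant in um (750 um by default).
#' @return slip length in um.
#' @export
phi_calc <- function(rho_c, lambda_const = 750) {
  if (any(rho_c <= 0)) stop("rho_c = 0 gives an infinite slip length (undefined)")
  if (any(rho_c > 1)) stop("rho_c must be <= 1")
  lambda_const * (1 - rho_c)^2 / rho_c
}

#' Stokes number of a spherical bead in an oscillatory flow
#'
#' `St_k = (2/9) * R^2 * rho_b * omega / mu`. For a 4.5 um polystyrene
#' bead in water at ~10 Hz this is of order 1e-4, so the beads follow the
#' fluid as massless tracers.
#'
#' @param radius_m bead radius in metres.
#' @param rho_b_kg_m3 bead density in kg/m^3.
#' @param omega_rad_s flow pulsation in rad/s.
#' @param mu_pa_s dynamic viscosity in Pa s.
#' @return dimensionless Stokes number.
#' @export
stokes_number <- function(radius_m, rho_b_kg_m3, omega_rad_s, mu_pa_s) {
  stopifnot(radius_m >= 0, rho_b_kg_m3 >= 0, omega_rad_s >= 0, mu_pa_s > 0)
  (2 / 9) * radius_m^2 * rho_b_kg_m3 * omega_rad_s / mu_pa_s
}

# Single-harmonic biharmonic solve on the strip.
# Stream function psi = Re(f(y) e^{i(omega t - q x)}) with
# f(y) = (A + B y) e^{-|q| y} + (C + D y) e^{|q| (y - h)} (scaled to avoid
# overflow for large |q| h). Velocities u = f'(y), v = i q f(y) (times the
# harmonic factor). Boundary conditions: u = v = 0 at y = h; at y = 0 the
# porous-wall condition: Navier slip on the tangential component and exact
# kinematic (no-penetration) matching of the normal component:
#   f'(0) - phi f''(0) = Uhat
#   i q f(0)           = Vhat
solve_strip_mode <- function(uhat, vhat, q, phi, h) {
  kq <- abs(q)
  fb  <- function(y) c(exp(-kq * y), y * exp(-kq * y),
                       exp(kq * (y - h)), y * exp(kq * (y - h)))
  fbp <- function(y) c(-kq * exp(-kq * y), (1 - kq * y) * exp(-kq * y),
                       kq * exp(kq * (y - h)), (1 + kq * y) * exp(kq * (y - h)))
  fbpp <- function(y) c(kq^2 * exp(-kq * y), (kq^2 * y - 2 * kq) * exp(-kq * y),
                        kq^2 * exp(kq * (y - h)), (kq^2 * y + 2 * kq) * exp(kq * (y - h)))
  M <- rbind(fbp(h), fb(h),
             fbp(0) - phi * fbpp(0),
             1i * q * fb(0))
  coef <- solve(M * (1 + 0i), c(0, 0, uhat, vhat))
  list(coef = coef,
       f = function(y) vapply(y, function(yy) sum(coef * fb(yy)), complex(1)),
       fp = function(y) vapply(y, function(yy) sum(coef * fbp(yy)), complex(1)),
       fpp = function(y) vapply(y, function(yy) sum(coef * fbpp(yy)), complex(1)))
}

#' Solve the envelope-driven Stokes flow
#'
#' Computes the incompressible Stokes flow in the strip `0 <= y <= h`,
#' x-periodic with the metachronal wavelength, driven at `y = 0` by the
#' envelope velocity (boundary data linearized onto the mean line) through
#' a porous-wall condition - Navier slip of length `phi` on the tangential
#' component, exact kinematic matching of the normal component - and
#' vanishing at `y = h`. The field has
#' two parts, both closed-form once the mode coefficients are solved:
#'
#' * the oscillatory first-order field, a single travelling harmonic
#'   obtained from a biharmonic stream-function solve in y;
#' * the steady second-order mean flow: expanding the boundary condition
#'   from the moving envelope onto the mean line yields an effective steady
#'   wall velocity `U_eff = <-(X-xi) du/dx - Y du/dy>` at `y = 0`, which
#'   drives the parabolic profile `U0 (1 - y/h)^2` (zero velocity and zero
#'   shear at the stagnant interface `y = h`), with
#'   `U0 = U_eff / (1 + 2 phi / h)` from the slip condition.
#'
#' @param cfg an [envelope_model_config()].
#' @param steady_wall_velocity optional prescribed steady wall velocity in
#'   um/s replacing the streaming-derived `U_eff` (used to check the solver
#'   against closed-form solutions).
#' @return an object of class `flow_field`: `velocity(x, y, t)` returning a
#'   matrix with columns `ux`, `uy` in um/s; the steady amplitude
#'   `u0_um_s`; the effective steady wall velocity `u_eff_um_s`; mode
#'   functions; and `residuals(n)` computing boundary/divergence residuals
#'   relative to the wall velocity scale on an n-point grid.
#' @export
solve_flow <- function(cfg, steady_wall_velocity = NULL) {
  a <- cfg$a_um; om <- cfg$omega_rad_s
  q <- cfg$wave_direction * cfg$k_um
  phi <- cfg$phi_um; h <- cfg$h_um
  uhat <- complex(real = 0, imaginary = -1) * a * om  # u_w = a om sin(theta)
  vhat <- cfg$beta * a * om + 0i                      # v_w = beta a om cos(theta)
  mode <- if (a > 0 && om > 0) solve_strip_mode(uhat, vhat, q, phi, h) else NULL

  if (is.null(steady_wall_velocity)) {
    u_eff <- if (is.null(mode)) 0 else {
      # <-(X - xi) du1/dx - Y du1/dy> at y = 0; products of two harmonics
      # average to Re(P conj(Q))/2
      dx_amp <- -a + 0i                    # X - xi = Re(-a e^{i theta})
      dy_amp <- complex(imaginary = -1) * cfg$beta * a  # Y = Re(-i beta a e^{i theta})
      dudx <- complex(imaginary = -1) * q * mode$fp(0)
      dudy <- mode$fpp(0)
      -0.5 * Re(dx_amp * Conj(dudx) + dy_amp * Conj(dudy))
    }
  } else u_eff <- steady_wall_velocity
  u0 <- u_eff / (1 + 2 * phi / h)

  velocity <- function(x, y, t) {
    n <- max(length(x), length(y), length(t))
    x <- rep_len(x, n); y <- rep_len(y, n); t <- rep_len(t, n)
    ph <- exp(complex(imaginary = 1) * (om * t - q * x))
    if (!is.null(mode)) {
      fy <- mode$f(y); fpy <- mode$fp(y)
      ux <- Re(fpy * ph); uy <- Re(complex(imaginary = 1) * q * fy * ph)
    } else ux <- uy <- numeric(n)
    inside <- y >= 0 & y <= h
    ux <- ifelse(inside, ux + u0 * (1 - y / h)^2, 0)
    uy <- ifelse(inside, uy, 0)
    cbind(ux = ux, uy = uy)
  }

  residuals <- function(n = 64L) {
    scale <- max(abs(uhat), abs(vhat), abs(u_eff), 1e-12)
    xg <- seq(0, cfg$lambda_um, length.out = n)
    tg <- if (om > 0) seq(0, 2 * pi / om, length.out = 8L) else 0
    top <- slip <- divg <- 0
    for (t in tg) {
      vt <- velocity(xg, rep(h, n), t)
      top <- max(top, max(abs(vt)))
      # slip residual: u - phi du/dy - u_w at y = 0 (x component), with the
      # steady part included via its effective wall velocity
      if (!is.null(mode)) {
        ph <- exp(complex(imaginary = 1) * (om * t - q * xg))
        r_tan <- Re((mode$fp(0) - phi * mode$fpp(0)) * ph) - Re(uhat * ph)
        r_nrm <- Re(1i * q * mode$f(0) * ph) - Re(vhat * ph)
        slip <- max(slip, max(abs(r_tan)), max(abs(r_nrm)))
      }
      r_steady <- abs(u0 * (1 + 2 * phi / h) - u_eff)
      slip <- max(slip, r_steady)
      # divergence by central differences at mid-height
      eps <- 1e-4
      yj <- rep(h / 2, n)
      dudx <- (velocity(xg + eps, yj, t)[, 1L] - velocity(xg - eps, yj, t)[, 1L]) / (2 * eps)
      dvdy <- (velocity(xg, yj + eps, t)[, 2L] - velocity(xg, yj - eps, t)[, 2L]) / (2 * eps)
      divg <- max(divg, max(abs(dudx + dvdy)) * cfg$lambda_um)
    }
    c(top_boundary = top / scale, slip = slip / scale, divergence = divg / scale)
  }

  structure(list(cfg = cfg, u0_um_s = u0, u_eff_um_s = u_eff, mode = mode,
                 velocity = velocity, residuals = residuals),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: steady wall amplitude U0 = %.3g um/s (U_eff = %.3g), h = %.3g um, phi = %.3g um\n",
              x$u0_um_s, x$u_eff_um_s, x$cfg$h_um, x$cfg$phi_um))
  invisible(x)
}

#' Advect a massless tracer through the flow
#'
#' Integrates `dX/dt = u(X, t)` from `(0, y0)` until the tracer has crossed
#' the observation window (`|x| = L_w`; the exit side follows the transport
#' direction). Beads have Stokes numbers of order 1e-4 so no inertia term
#' is included.
#'
#' @param field a [solve_flow()] result.
#' @param y0 entry altitude in um, `0 < y0 < h`.
#' @param t_max integration-time cap in s; exceeding it raises a "stalled
#'   tracer" error.
#' @param rtol,atol integrator tolerances (adaptive LSODA with root
#'   stopping).
#' @param maxsteps integrator step budget per output interval.
#' @return list with `tau` (crossing time, s), `v_eff` (`L_w / tau`, um/s,
#'   positive), `direction` (+1/-1), and the `path` data frame (t, x, y).
#' @export
advect_tracer <- function(field, y0, t_max = 600, rtol = 1e-8, atol = 1e-8,
                          maxsteps = 1e5) {
  cfg <- field$cfg
  if (y0 <= 0 || y0 >= cfg$h_um) stop("tracer must start strictly inside (0, h)")
  lw <- cfg$lw_um
  rhs <- function(t, state, parms) {
    v <- field$velocity(state[1L], state[2L], t)
    list(c(v[1L, 1L], v[1L, 2L]))
  }
  rootfun <- function(t, state, parms)
    c(abs(state[1L]) - lw, state[2L], state[2L] - cfg$h_um)
  # output times only matter for the stored path; the root stops the solve
  times <- seq(0, t_max, length.out = 201L)
  sol <- deSolve::lsodar(y = c(x = 0, y = y0), times = times, func = rhs,
                         rootfunc = rootfun, rtol = rtol, atol = atol,
                         maxsteps = maxsteps)
  last <- sol[nrow(sol), ]
  if (abs(abs(last[["x"]]) - lw) > 1e-6 * lw) {
    if (last[["y"]] <= 1e-9 || last[["y"]] >= cfg$h_um - 1e-9)
      stop(sprintf("tracer exited the strip at (%.2f, %.2f) um", last[["x"]], last[["y"]]))
    stop(sprintf("stalled tracer: |x| = %.2f um after %.1f s (window %.1f um)",
                 abs(last[["x"]]), last[["time"]], lw))
  }
  tau <- last[["time"]]
  list(tau = tau, v_eff = lw / tau, direction = sign(last[["x"]]),
       path = data.frame(t = sol[, "time"], x = sol[, "x"], y = sol[, "y"]))
}

#' Effective velocity profile of the simulated flow
#'
#' Computes the effective speed `V_eff(y0) = L_w / tau(y0)` (window length
#' over tracer crossing time) at each entry altitude, i.e. the observable
#' measured on real micro-beads, by advecting massless tracers through the
#' solved flow.
#'
#' @param cfg an [envelope_model_config()].
#' @param y_grid entry altitudes in um, strictly inside `(0, h)`.
#' @param ... passed to [advect_tracer()].
#' @return data frame with columns `y0` and `v_eff` (um/s, magnitudes),
#'   with the transport direction as attribute `direction`. A vanishing
#'   beat (`a = 0`) reports zero velocities.
#' @export
effective_velocity_profile <- function(cfg, y_grid, ...) {
  if (any(y_grid <= 0 | y_grid >= cfg$h_um)) stop("y_grid must lie inside (0, h)")
  field <- solve_flow(cfg)
  if (cfg$a_um == 0 || cfg$omega_rad_s == 0) {
    out <- data.frame(y0 = y_grid, v_eff = 0)
    attr(out, "direction") <- 0
    return(out)
  }
  res <- lapply(y_grid, function(y0) advect_tracer(field, y0, ...))
  out <- data.frame(y0 = as.numeric(y_grid),
                    v_eff = vapply(res, `[[`, numeric(1), "v_eff"))
  attr(out, "direction") <- res[[1L]]$direction
  out
}
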