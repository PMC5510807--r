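test_that("the envelope tip traces the prescribed ellipse", {
  cfg <- envelope_model_config(cbf_hz = 10, cba_um = 7, beta = 0.14)
  a <- cfg$a_um
  expect_equal(envelope_position(0, 0, cfg)[1, ], c(x = -a, y = 0))
  t_quarter <- (pi / 2) / cfg$omega_rad_s
  expect_equal(envelope_position(0, t_quarter, cfg)[1, ],
               c(x = 0, y = cfg$beta * a), tolerance = 1e-12)
  # one full period: an ellipse of semi-axes (a, beta*a), traversed clockwise
  ts <- seq(0, 1 / cfg$cbf_hz, length.out = 200)
  orb <- envelope_position(0, ts, cfg)
  expect_equal(max(abs(orb[, 1])), a, tolerance = 1e-3)
  expect_equal(max(abs(orb[, 2])), cfg$beta * a, tolerance = 1e-3)
  expect_equal(max(abs((orb[, 1] / a)^2 + (orb[, 2] / (cfg$beta * a))^2 - 1)),
               0, tolerance = 1e-9)
  cross_z <- orb[-200, 1] * diff(orb[, 2]) - orb[-200, 2] * diff(orb[, 1])
  expect_true(all(cross_z < 0))  # decreasing polar angle = clockwise
})

test_that("slip length follows the density relation", {
  expect_equal(phi_calc(1), 0)
  expect_equal(phi_calc(0.5), 375)
  expect_equal(phi_calc(0.84), 750 * 0.16^2 / 0.84, tolerance = 1e-12)
  expect_equal(phi_calc(0.84), 22.857, tolerance = 1e-4)
  expect_error(phi_calc(0), "infinite")
})

test_that("micro-beads are massless tracers by Stokes number", {
  st <- stokes_number(2.25e-6, 1000, 2 * pi * 10, 1e-3)
  expect_equal(st, 7.07e-5, tolerance = 1e-3)
  expect_lte(st, 1e-4)
  expect_equal(stokes_number(2.25e-6, 1000, 0, 1e-3), 0)
  expect_equal(stokes_number(4.5e-6, 1000, 2 * pi * 10, 1e-3) / st, 4)
})

test_that("the flow solve meets its boundary contracts", {
  cfg <- envelope_model_config()
  fl <- solve_flow(cfg)
  expect_lt(max(fl$residuals(64L)), 1e-6)
  # no beating: identically zero field
  fl0 <- solve_flow(envelope_model_config(cba_um = 0))
  v <- fl0$velocity(c(0, 5, 10), c(1, 10, 40), 0.1)
  expect_equal(max(abs(v)), 0)
  # near-perfect slip transmits almost none of the tangential wall motion
  # (beta = 0: purely tangential oscillation)
  fl_slip <- solve_flow(envelope_model_config(beta = 0, phi_um = 1e6))
  wall_scale <- cfg$a_um * cfg$omega_rad_s
  v_slip <- fl_slip$velocity(seq(0, 13, 1), rep(2, 14), 0.01)
  expect_lt(max(abs(v_slip)) / wall_scale, 1e-3)
})

test_that("a prescribed steady wall velocity yields the analytic strip profile", {
  cfg <- envelope_model_config(cba_um = 0, h_um = 60, phi_um = 0)
  fl <- solve_flow(cfg, steady_wall_velocity = 50)
  y <- seq(0, 60, 5)
  v <- fl$velocity(rep(0, length(y)), y, 0)
  expect_equal(v[, 1], 50 * (1 - y / 60)^2, tolerance = 1e-12)
  expect_equal(max(abs(v[, 2])), 0)
  # with slip the wall value is reduced by 1 + 2*phi/h
  fl2 <- solve_flow(envelope_model_config(cba_um = 0, h_um = 60, phi_um = 30),
                    steady_wall_velocity = 50)
  expect_equal(fl2$u0_um_s, 50 / (1 + 2 * 30 / 60), tolerance = 1e-12)
})

test_that("the oscillatory field is linear in the envelope amplitude", {
  c1 <- envelope_model_config(cba_um = 4)
  c2 <- envelope_model_config(cba_um = 8)
  f1 <- solve_flow(c1); f2 <- solve_flow(c2)
  pts <- cbind(x = c(0, 3, 7), y = c(2, 10, 25))
  osc <- function(f, t) {
    tot <- f$velocity(pts[, 1], pts[, 2], t)
    tot[, 1] <- tot[, 1] - f$u0_um_s * (1 - pts[, 2] / f$cfg$h_um)^2
    tot
  }
  for (t in c(0, 0.013, 0.05))
    expect_equal(osc(f2, t), 2 * osc(f1, t), tolerance = 1e-9)
})

test_that("no net vertical flux crosses any horizontal line", {
  cfg <- envelope_model_config()
  fl <- solve_flow(cfg)
  xg <- seq(0, cfg$lambda_um, length.out = 257)[-257]
  for (y in c(3, 15, 40)) for (t in c(0, 0.02)) {
    flux <- mean(fl$velocity(xg, rep(y, length(xg)), t)[, 2]) * cfg$lambda_um
    expect_lt(abs(flux), 1e-8 * cfg$a_um * cfg$omega_rad_s)
  }
})

test_that("tracer advection matches closed-form crossing times", {
  cfg <- envelope_model_config(h_um = 60, lw_um = 40)
  # uniform translation: tau = Lw / U (fake field with the package contract)
  uni <- structure(list(cfg = cfg,
                        velocity = function(x, y, t)
                          cbind(ux = rep(10, length(x)), uy = rep(0, length(x)))),
                   class = "flow_field")
  out <- advect_tracer(uni, 20)
  expect_equal(out$tau, 4, tolerance = 1e-6)
  expect_equal(out$v_eff, 10, tolerance = 1e-6)
  expect_equal(max(abs(out$path$y - 20)), 0, tolerance = 1e-9)
  # steady parabolic field: V_eff(y0) equals the profile value exactly
  fl <- solve_flow(envelope_model_config(cba_um = 0, h_um = 60, lw_um = 40,
                                         phi_um = 0),
                   steady_wall_velocity = 80)
  for (y0 in c(10, 30)) {
    res <- advect_tracer(fl, y0)
    expect_equal(res$v_eff, 80 * (1 - y0 / 60)^2, tolerance = 1e-6)
  }
  # standing oscillation on top of a drift: V_eff ~ drift for Lw >> A/omega
  om <- 2 * pi * 10
  osc <- structure(list(cfg = cfg,
                        velocity = function(x, y, t)
                          cbind(ux = 8 + 30 * sin(om * t), uy = rep(0, length(x)))),
                   class = "flow_field")
  res <- advect_tracer(osc, 20)
  # oracle: X(t) = 8 t + 30/om (1 - cos(om t)); amplitude 30/om = 0.48 um
  expect_equal(res$v_eff, 8, tolerance = 30 / om / 40 * 2)
  # stalled tracer and strip exit are reported
  slow <- structure(list(cfg = cfg,
                         velocity = function(x, y, t)
                           cbind(ux = rep(1e-4, length(x)), uy = rep(0, length(x)))),
                    class = "flow_field")
  expect_error(advect_tracer(slow, 20, t_max = 5), "stalled")
  sink_f <- structure(list(cfg = cfg,
                           velocity = function(x, y, t)
                             cbind(ux = rep(1, length(x)), uy = rep(-5, length(x)))),
                      class = "flow_field")
  expect_error(advect_tracer(sink_f, 10), "exited")
})

test_that("a vanishing beat gives a zero effective-velocity profile", {
  prof <- effective_velocity_profile(envelope_model_config(cba_um = 0),
                                     c(10, 30))
  expect_equal(prof$v_eff, c(0, 0))
})

test_that("configuration JSON round-trips", {
  cfg <- envelope_model_config(cbf_hz = 9.4, cba_um = 7, lambda_um = 15.5,
                               rho_c = 0.8, h_um = 91.5)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(cbf_hz = 9.4, cba_um = 7, lambda_um = 15.5,
                            rho_c = 0.8, h_um = 91.5),
                       tmp, auto_unbox = TRUE)
  back <- read_envelope_config(tmp)
  expect_equal(back$phi_um, cfg$phi_um)
  expect_equal(back$omega_rad_s, 2 * pi * 9.4)
  unlink(tmp)
})
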