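test_that("noiseless parabolic samples are recovered to high precision", {
  s <- generate_profile_samples(list(uw = 138.3, h = 87.5), seq(5, 80, by = 8))
  fit <- fit_parabola(s)
  expect_equal(fit$uw, 138.3, tolerance = 1e-6)
  expect_equal(fit$h, 87.5, tolerance = 1e-6)
  expect_error(fit_parabola(data.frame(y0 = c(1, 2), v = c(3, 2))), "3 samples")
  expect_warning(z <- fit_parabola(data.frame(y0 = c(1, 2, 3), v = c(0, 0, 0))),
                 "indeterminate")
  expect_true(z$degenerate)
  expect_equal(z$uw, 0)
})

test_that("the fit-then-stress chain is scale covariant", {
  s <- generate_profile_samples(list(uw = 80, h = 60), seq(4, 55, by = 5),
                                noise_sd = 4, rng_seed = 8L)
  f1 <- fit_parabola(s)
  s2 <- s; s2$v <- 3 * s2$v
  f2 <- fit_parabola(s2)
  expect_equal(shear_stress(f2$uw, f2$h), 3 * shear_stress(f1$uw, f1$h),
               tolerance = 1e-6)
})

test_that("the shear-stress index evaluates 2*mu*Uw/h in mPa", {
  expect_equal(shear_stress(138.3, 87.5), 3.2, tolerance = 0.05)
  expect_equal(shear_stress(85.4, 139.7), 1.2, tolerance = 0.05)
  expect_equal(shear_stress(58.9, 51.2), 2.3, tolerance = 0.05)
  expect_equal(shear_stress(0, 50), 0)
  expect_error(shear_stress(100, 0), "h must be")
})

test_that("the Couette stress is half the index at matched inputs", {
  expect_equal(couette_stress(50, 50), 1.0)
  expect_equal(couette_stress(0, 10), 0)
  expect_error(couette_stress(10, 0), "> 0")
  uw <- 138.3; h <- 87.5
  expect_equal(couette_stress(uw, h), shear_stress(uw, h) / 2, tolerance = 1e-12)
})

test_that("per-edge indices aggregate with the sample-SD convention", {
  tab <- edge_parameters()
  p1 <- tab[tab$patient == 1, ]
  tau1 <- shear_stress(p1$uw_um_s, p1$h_um)
  s1 <- patient_summary(tau1)
  expect_lt(abs(s1$mean - 5.8), 0.05)
  expect_lt(abs(s1$sd - 4.1), 0.05)
  # the population-SD alternative does not reproduce the reported spread
  pop_sd <- sqrt(mean((tau1 - mean(tau1))^2))
  expect_gt(abs(pop_sd - 4.1), 0.3)
  p11 <- tab[tab$patient == 11, ]
  s11 <- patient_summary(shear_stress(p11$uw_um_s, p11$h_um))
  expect_lt(abs(s11$mean - 2.1), 0.05)
  expect_lt(abs(s11$sd - 0.3), 0.05)
  single <- patient_summary(2.3)
  expect_equal(single$mean, 2.3)
  expect_true(is.na(single$sd))
  expect_error(patient_summary(numeric(0)), "at least one")
})

test_that("one reference edge is internally inconsistent, the rest agree", {
  chk <- check_edge_consistency()
  expect_equal(nrow(chk), 24L)
  expect_equal(sum(!chk$consistent), 1L)
  bad <- chk[!chk$consistent, ]
  expect_equal(bad$patient, 2)
  expect_equal(bad$edge, 1)
  expect_lt(max(abs(chk$tau_w_recomputed[chk$consistent] -
                    chk$tau_w_mpa[chk$consistent])), 0.05 + 1e-9)
})

test_that("the velocity regression recovers known linear coefficients", {
  set.seed(21)
  n <- 80
  beads <- data.frame(cbf = runif(n, 3.5, 15), rho_c = runif(n, 0.58, 0.98),
                      cba = runif(n, 4, 8.8), y0 = runif(n, 0.3, 70),
                      lambda = runif(n, 10, 28))
  truth <- c(6.96, 230.6, 11.95, -1.22, -0.83)
  beads$v_eff <- -243.35 + as.matrix(beads) %*% truth
  # noiseless by construction: summary.lm warns about the perfect fit
  fit <- suppressWarnings(fit_veff_regression(beads))
  expect_equal(unname(fit$coefficients),
               c(-243.35, truth), tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # independent response: slopes vanish in expectation
  beads2 <- beads; beads2$v_eff <- rnorm(n, 50, 1e-6)
  fit2 <- fit_veff_regression(beads2)
  expect_lt(max(abs(fit2$coefficients[-1])), 1e-4)
  # noise consistency: coefficient bias shrinks with n
  est_bias <- function(n) {
    d <- data.frame(cbf = runif(n, 3.5, 15), rho_c = runif(n, 0.58, 0.98),
                    cba = runif(n, 4, 8.8), y0 = runif(n, 0.3, 70),
                    lambda = runif(n, 10, 28))
    d$v_eff <- -243.35 + as.matrix(d) %*% truth + rnorm(n, 0, 20)
    mean(abs(stats::coef(fit_veff_regression(d)$fit)[-1] - truth))
  }
  expect_lt(median(replicate(10, est_bias(2000))),
            median(replicate(10, est_bias(50))))
  # rank deficiency is reported
  beads3 <- beads; beads3$lambda <- beads3$cbf * 2
  expect_error(fit_veff_regression(beads3), "collinear")
})

test_that("median-split Mann-Whitney matches exhaustive enumeration", {
  beads <- data.frame(v_b = c(10, 11, 12, 1, 2, 3),
                      y0 = c(1, 2, 3, 10, 11, 12))
  res <- median_split_test(beads)
  expect_equal(res$U, 9)  # near group wins every comparison
  expect_equal(res$p, mw_exact_p(c(10, 11, 12), c(1, 2, 3)))
  expect_equal(res$p, 0.1)
  # identical groups: p = 1 under the exact convention
  same <- data.frame(v_b = c(5, 7, 5, 7), y0 = c(1, 2, 10, 11))
  expect_equal(median_split_test(same)$p, 1)
  # random small samples against the brute-force null
  set.seed(33)
  for (i in 1:5) {
    x <- sample(100, 4); y <- sample(100, 4)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(wt$p.value, mw_exact_p(x, y))
  }
})

test_that("near beads move significantly faster on a parabolic profile", {
  set.seed(99)
  n <- 195
  y0 <- runif(n, 0.5, 70)
  v <- 120 * (1 - y0 / 80)^2 + rnorm(n, 0, 8)
  res <- median_split_test(data.frame(v_b = v, y0 = y0))
  expect_gt(res$near$mean, res$far$mean)
  expect_lt(res$p, 0.05)
})

test_that("Bland-Altman agreement summarises paired velocities", {
  same <- cbind(c(10, 20, 30), c(10, 20, 30))
  ba <- bland_altman(same)
  expect_equal(ba$bias, 0)
  expect_equal(ba$limits, c(0, 0))
  off <- cbind(c(10, 20, 30), c(10, 20, 30) - 2.5)
  ba2 <- bland_altman(off)
  expect_equal(ba2$bias, 2.5)
  expect_equal(ba2$sd, 0)
  expect_equal(ba2$table$mean, c(10, 20, 30) - 1.25)
})

test_that("per-cilium force divides the stress over the areal density", {
  expect_equal(per_cilium_force(0)$force_pn, 0)
  expect_equal(per_cilium_force(5, 5)$force_pn, 1e-3)
  expect_equal(per_cilium_force(5, 2.5)$force_pn,
               2 * per_cilium_force(5, 5)$force_pn)
  expect_error(per_cilium_force(5, 0), "> 0")
  expect_match(per_cilium_force(1)$caveat, "not comparable")
})
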