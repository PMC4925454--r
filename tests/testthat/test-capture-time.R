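geom_ref <- new_scaled_geometry(a_bar = 1, R_bar = sqrt(3), Rstar_bar = 3)

test_that("coefficients match the arbitrary-precision linear solve", {
  sol <- solve_coefficients(geom_ref)
  expect_equal(sol$A_inner, oracle_A_inner, tolerance = 1e-13)
  expect_equal(sol$B_inner, oracle_B_inner, tolerance = 1e-13)
  expect_identical(sol$B_outer, 0)
  expect_equal(sol$A_outer, exp(geom_ref$R_bar^2 / 2))
})

test_that("coefficients enforce the boundary conditions", {
  for (g in list(geom_ref,
                 scaled_geometry(tether_model(N = 50)),
                 scaled_geometry(tether_model(N = 2000)),
                 scaled_geometry(tether_model(N = 10, a = 2)))) {
    sol <- solve_coefficients(g)
    cmax <- max(abs(concentration_value(
      seq(g$a_bar, g$Rstar_bar, length.out = 50), sol)))
    # absorbing condition at the capture sphere
    expect_lt(abs(concentration_value(g$a_bar, sol)) / cmax, 1e-12)
    # injection-shell value reached from both sides
    expect_equal(concentration_value(g$R_bar, sol), 1, tolerance = 1e-10)
    expect_equal(exp((g$R_bar^2 - g$R_bar^2) / 2), 1) # outer form at R_bar
    expect_gt(sol$B_inner, 0)
  }
})

test_that("the current-carrying coefficient diverges as a_bar -> R_bar", {
  eps <- c(0.1, 0.01, 0.001)
  B <- vapply(eps, function(e) {
    solve_coefficients(new_scaled_geometry(sqrt(3) - e, sqrt(3), 3))$B_inner
  }, numeric(1))
  expect_true(all(diff(B) > 0))
  expect_gt(B[3], 100)
  expect_error(solve_coefficients(new_scaled_geometry(sqrt(3), sqrt(3), 3)),
               "Degenerate")
})

test_that("the steady-state current is radially conserved and vanishes outside", {
  g <- scaled_geometry(tether_model(N = 25))
  sol <- solve_coefficients(g)
  # inner region: x^2 J(x) constant
  xs <- seq(g$a_bar, g$R_bar, length.out = 9)
  tot <- xs^2 * concentration_current(xs, sol)
  expect_lt(max(abs(tot - tot[1])), 1e-10 * abs(tot[1]))
  expect_equal(tot[1], -sol$B_inner, tolerance = 1e-10)
  # outer region carries no current, including the reflecting boundary
  xo <- seq(g$R_bar + 1e-9, g$Rstar_bar, length.out = 5)
  expect_true(all(concentration_current(xo, sol) == 0))
  expect_identical(concentration_current(g$Rstar_bar, sol), 0)
  expect_error(concentration_current(g$Rstar_bar + 1, sol), "outside")
})

test_that("annihilation flux equals the conserved current and scales with D", {
  m <- tether_model(N = 25)
  g <- scaled_geometry(m)
  sol <- solve_coefficients(g)
  FF <- annihilation_flux(sol, r0 = m$r0, D = m$D)
  # cross-check against -4 pi r0 D (x^2 J) at the capture sphere
  expect_equal(FF,
               -4 * pi * m$r0 * m$D * g$a_bar^2 *
                 concentration_current(g$a_bar, sol),
               tolerance = 1e-10)
  expect_equal(annihilation_flux(sol, r0 = m$r0, D = 7), 7 * FF)
  zero <- sol
  zero$B_inner <- 0
  expect_equal(annihilation_flux(zero, r0 = m$r0), 0)
})

test_that("shell integrals agree with their closed forms", {
  d <- delta_integrals(geom_ref)
  expect_equal(d$delta1, oracle_delta1, tolerance = 1e-12)
  expect_equal(d$delta2, oracle_delta2, tolerance = 1e-12)
  expect_lt(abs(d$delta1 - gaussian_shell_integral(1, sqrt(3))), 1e-10)
  expect_lt(abs(d$delta3 - gaussian_shell_integral(sqrt(3), 3)), 1e-10)
  # empty intervals
  dd <- delta_integrals(new_scaled_geometry(1, 1, 1))
  expect_identical(unlist(dd), c(delta1 = 0, delta2 = 0, delta3 = 0))
  # full Gaussian moment: integral_0^Inf z^2 e^{-z^2/2} dz = sqrt(pi/2)
  dfull <- delta_integrals(new_scaled_geometry(1e-8, 40, 40))
  expect_equal(dfull$delta1, sqrt(pi / 2), tolerance = 1e-9)
  expect_equal(gaussian_shell_integral(0, Inf), sqrt(pi / 2))
})

test_that("steady-state population equals direct quadrature of the profile", {
  for (n in c(5, 80)) {
    m <- tether_model(N = n)
    g <- scaled_geometry(m)
    sol <- solve_coefficients(g)
    pop <- steady_state_population(sol, g, r0 = m$r0)
    direct <- stats::integrate(
      function(x) x^2 * concentration_value(x, sol),
      g$a_bar, g$Rstar_bar, rel.tol = 1e-10, subdivisions = 600L
    )$value * 4 * pi * m$r0^3
    expect_equal(pop, direct, tolerance = 1e-8)
    expect_gt(pop, 0)
  }
})

test_that("removing the outer shell removes exactly the A_outer term", {
  m <- tether_model(N = 30)
  g <- scaled_geometry(m)
  sol <- solve_coefficients(g)
  g_no <- new_scaled_geometry(g$a_bar, g$R_bar, g$R_bar, r0 = g$r0)
  pop <- steady_state_population(sol, g, r0 = m$r0)
  pop_no <- steady_state_population(sol, g_no, r0 = m$r0)
  expect_equal(pop - pop_no,
               4 * pi * m$r0^3 * tetheravidity:::outer_population_term(g),
               tolerance = 1e-10)
})

test_that("mean capture time reproduces the reference values", {
  for (ns in names(oracle_tau)) {
    res <- mean_capture_time(tether_model(N = as.numeric(ns)))
    expect_equal(res$tau_scaled, unname(oracle_tau[ns]), tolerance = 1e-10)
    expect_equal(res$mean_time, res$population / res$flux)
    expect_equal(res$tau_scaled, res$mean_time / res$model$tau0)
  }
})

test_that("degenerate and invalid start radii are handled", {
  res1 <- mean_capture_time(tether_model(N = 1))
  expect_identical(res1$mean_time, 0)
  expect_identical(res1$tau_scaled, 0)
  expect_error(mean_capture_time(tether_model(N = 4, a = 3)),
               "capture sphere")
})

test_that("capture time is monotone in N and follows the 3/2 power law", {
  tbl <- capture_time(N = c(1, 2, 5, 10, 50, 200, 1000))
  expect_true(all(diff(tbl$tau_scaled) > 0))
  # tau(10^6)/tau(10^4) -> 10^3 in the asymptotic regime
  ratio <- mean_capture_time(tether_model(N = 1e6))$tau_scaled /
    mean_capture_time(tether_model(N = 1e4))$tau_scaled
  expect_equal(log10(ratio), 3, tolerance = 0.01)
})

test_that("capture works for a != b", {
  # general capture-to-Kuhn ratio: dual-route check against the
  # backward-equation quadrature
  for (ab in c(0.5, 2)) {
    m <- tether_model(N = 40, a = ab)
    g <- scaled_geometry(m)
    analytic <- mean_capture_time(m)$mean_time
    oracle <- mfpt_quadrature(g$R_bar, g) * m$r0^2 / m$D
    expect_equal(analytic, oracle, tolerance = 1e-6)
  }
})

test_that("scaling regression recovers exponents", {
  # synthetic pure power law fed through the regressor
  Ns <- exp(seq(log(10), log(1000), length.out = 8))
  fake <- tibble::tibble(N = Ns, tau_scaled = 2.7 * Ns^1.23)
  fit <- stats::lm(log(tau_scaled) ~ log(N), data = fake)
  expect_equal(unname(coef(fit)[2]), 1.23, tolerance = 1e-10)
  expect_error(scaling_exponent(N_grid = c(10, 10, 10)), "distinct")
  expect_error(scaling_exponent(N_grid = c(10, 20)), "distinct")
  sl <- scaling_exponent(N_grid = exp(seq(log(1e3), log(1e4),
                                          length.out = 8)))
  expect_equal(sl$exponent, 1.5, tolerance = 0.02)
})

test_that("concentration profile is physical", {
  tbl <- concentration_profile(tether_model(N = 12), n = 120)
  expect_true(all(tbl$c >= -1e-12))
  expect_equal(tbl$c[1], 0, tolerance = 1e-10)
  expect_equal(tbl$current[nrow(tbl)], 0)
  expect_equal(max(abs(tbl$current[tbl$x > sqrt(3)])), 0)
})

test_that("competitive-binding cutoff follows the -1/2 law", {
  m <- tether_model(N = 2, c_inf = 1e-6)
  ct <- tau_cutoff(m)
  expect_equal(ct$N_star, 100)
  expect_error(tau_cutoff(tether_model(N = 2)), "c_inf")
  expect_error(tau_cutoff(tether_model(N = 2, c_inf = 2)), "dilute")
  phis <- 10^seq(-6, -12, length.out = 7)
  tmax <- vapply(phis, function(p) {
    tau_cutoff(tether_model(N = 2, c_inf = p))$tau_max_scaled
  }, numeric(1))
  slope <- unname(coef(stats::lm(log(tmax) ~ log(phis)))[2])
  expect_equal(slope, -0.5, tolerance = 0.02)
  expect_true(all(diff(tmax) > 0)) # tau_max falls as c_inf rises
})
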