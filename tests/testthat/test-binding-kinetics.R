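test_that("rate validation and the dissociation constant", {
  r <- kinetic_rates(r_on = 2, r_off = 1, r_off_double = 0.01, tau = 0.5)
  expect_equal(r$Kd, 0.5)
  expect_equal(r$r_capture, 2)
  expect_warning(kinetic_rates(1, 1, 2, tau = 1), "r_off_double")
  expect_error(kinetic_rates(1, 1, 0.01), "r_capture|tau")
  expect_error(kinetic_rates(1, 1, 0.01, r_capture = 1, tau = 1), "one of")
  expect_error(kinetic_rates(0, 1, 0.01, tau = 1), "r_on")
  expect_error(kinetic_rates(1, -1, 0.01, tau = 1), "r_off")
  expect_error(kinetic_rates(1, 1, 0.01, tau = 1, Kd = 3), "Kd")
  # tau = 0 means instantaneous capture
  expect_identical(kinetic_rates(1, 1, 0.01, tau = 0)$r_capture, Inf)
})

test_that("steady state solves the balance equations", {
  p <- steady_state(suppressWarnings(kinetic_rates(1, 1, 1, r_capture = 1)))
  expect_equal(unlist(p), c(P_I = 0.5, P_II = 0.25, P_III = 0.25))
  for (i in 1:20) {
    rr <- random_rate_sets(1, seed = 300 + i)
    r <- suppressWarnings(kinetic_rates(rr$r_on, rr$r_off, rr$r_off_double,
                                        tau = rr$tau + 0.01))
    p <- steady_state(r)
    expect_equal(p$P_I + p$P_II + p$P_III, 1, tolerance = 1e-12)
    # balance: I <-> II and II -> III flows
    expect_lt(abs(p$P_I * r$r_on - p$P_II * (r$r_off + r$r_capture)), 1e-12)
    expect_lt(abs(p$P_III * r$r_off_double - p$P_II * r$r_capture), 1e-12)
    # null space of the full generator
    Q <- tetheravidity:::rate_matrix(r)
    expect_lt(max(abs(Q %*% unlist(p))), 1e-12)
  }
})

test_that("degenerate chains resolve to their exact limits", {
  # no capture channel: two-state equilibrium, nothing doubly bound
  p0 <- steady_state(kinetic_rates(2, 1, 0.01, r_capture = 0))
  expect_identical(p0$P_III, 0)
  expect_equal(p0$P_I / p0$P_II, 1 / 2)
  # no escape from the doubly-bound state: it absorbs everything
  p1 <- steady_state(suppressWarnings(
    kinetic_rates(1, 1, 0, r_capture = 2)))
  expect_identical(p1$P_III, 1)
  # instantaneous capture: singly-bound state empties
  p2 <- steady_state(kinetic_rates(1, 1, 0.1, r_capture = Inf))
  expect_identical(p2$P_II, 0)
  expect_equal(p2$P_III / p2$P_I, 1 / 0.1)
  # one-way two-state chain with no unbinding: everything singly bound
  p3 <- steady_state(suppressWarnings(
    kinetic_rates(1, 0, 0, r_capture = 0)))
  expect_identical(p3$P_II, 1)
})

test_that("closed-form bound ratio equals the linear-solve ratio", {
  expect_equal(bound_ratio(kinetic_rates(1, 1, 0.1, tau = 0)), 10)
  expect_equal(bound_ratio(kinetic_rates(1, 1, 0.1, tau = 1)), 5)
  expect_error(bound_ratio(suppressWarnings(
    kinetic_rates(1, 1, 0, tau = 1))), "diverges")
  sets <- random_rate_sets(100, seed = 77)
  for (i in seq_len(nrow(sets))) {
    r <- suppressWarnings(kinetic_rates(sets$r_on[i], sets$r_off[i],
                                        sets$r_off_double[i],
                                        tau = sets$tau[i]))
    p <- steady_state(r)
    expect_equal(bound_ratio(r), p$P_III / p$P_I, tolerance = 1e-10)
  }
})

test_that("transient evolution conserves probability and relaxes", {
  r <- kinetic_rates(1, 1, 0.05, tau = 0.5)
  ss <- steady_state(r)
  # fixed point stays fixed
  traj0 <- evolve(r, ss, seq(0, 5, by = 1))
  expect_lt(max(abs(unlist(traj0[nrow(traj0), -1]) - unlist(ss))), 1e-8)
  # from all-free, the chain relaxes to the steady state
  traj <- evolve(r, c(1, 0, 0), seq(0, 400, length.out = 41))
  expect_lt(max(abs(rowSums(traj[, -1]) - 1)), 1e-10)
  expect_lt(max(abs(unlist(traj[nrow(traj), -1]) - unlist(ss))), 1e-8)
  # eigen-decomposition oracle for the full transient
  Q <- tetheravidity:::rate_matrix(r)
  eg <- eigen(Q)
  a0 <- solve(eg$vectors, c(1, 0, 0))
  for (tt in c(0.5, 2, 10)) {
    pt <- Re(eg$vectors %*% (a0 * exp(eg$values * tt)))
    pe <- unlist(evolve(r, c(1, 0, 0), c(0, tt))[2, -1])
    expect_equal(pe, c(P_I = pt[1], P_II = pt[2], P_III = pt[3]),
                 tolerance = 1e-8)
  }
  expect_error(evolve(r, c(0.7, 0.2, 0.2), 0:3), "summing to 1")
  expect_error(evolve(kinetic_rates(1, 1, 0.05, tau = 0), c(1, 0, 0), 0:3),
               "finite")
})

test_that("enhancement factor: closed form, limits and bounds", {
  expect_equal(enhancement(Kd = 1, r_on = 1, tau = 0), 2)
  expect_equal(enhancement(Kd = 1, r_on = 1, tau = 1), 1)
  expect_equal(enhancement(Kd = 4, r_on = 1, tau = 0.5), 5 / 3)
  expect_error(enhancement(Kd = 0, r_on = 1, tau = 1), "Kd")
  # 1 <= R <= 1 + Kd whenever r_on * tau <= 1, monotone decreasing in tau
  for (kd in c(0.2, 1, 8)) {
    taus <- seq(0, 1, length.out = 11)
    R <- enhancement(kd, r_on = 1, tau = taus)
    expect_true(all(R >= 1 - 1e-12 & R <= 1 + kd + 1e-12))
    expect_true(all(diff(R) < 0))
    expect_equal(R[1], 1 + kd)
  }
})

test_that("steady-state route reproduces the closed-form enhancement", {
  sets <- expand.grid(Kd = c(0.1, 1, 10), tau = c(0, 0.2, 1),
                      r_on = c(0.5, 2))
  for (i in seq_len(nrow(sets))) {
    expect_equal(
      enhancement_from_states(sets$Kd[i], sets$r_on[i], sets$tau[i]),
      enhancement(sets$Kd[i], sets$r_on[i], sets$tau[i]),
      tolerance = 1e-10
    )
  }
})

test_that("effective concentration composes with the enhancement", {
  expect_equal(effective_concentration(10, 1), 10)
  expect_equal(effective_concentration(10, 2), 20)
  expect_equal(effective_concentration(3, enhancement(Kd = 2, 1, 0)),
               3 * (1 + 2))
  expect_error(effective_concentration(-1, 1), ">= 0")
})
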