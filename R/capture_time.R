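#' Solve the boundary-value problem for the concentration coefficients
#'
#' The steady-state ligand concentration is a piecewise combination
#' `c(x) = A exp(-x^2/2) + B f(x)` on the inner shell (`a_bar <= x <= R_bar`,
#' between the absorbing capture sphere and the injection shell) and the
#' outer shell (`R_bar <= x <= Rstar_bar`, up to the reflecting boundary at
#' full tether extension). Boundary conditions: `c(a_bar) = 0` (absorption),
#' `c(R_bar) = 1` (injection shell, concentration fixed to 1 without loss of
#' generality) and zero current at `Rstar_bar`.
#'
#' The reflecting condition forces `B_outer = 0` (the equilibrium basis
#' carries no current), so `A_outer = exp(R_bar^2/2)`. The inner coefficients
#' are
#' `B_inner = 1 / (f(R_bar) - f(a_bar) * exp(-(R_bar^2 - a_bar^2)/2))` and
#' `A_inner = -f(a_bar) * exp(a_bar^2/2) * B_inner`.
#'
#' `A_outer` is stored as its logarithm `log_A_outer = R_bar^2 / 2` as well,
#' and downstream code uses the fused product `A_outer * Delta3` (see
#' [steady_state_population()]) so that nothing overflows for large `R_bar`.
#'
#' @param geometry A [scaled_geometry()] with `a_bar < R_bar`.
#' @return An object of class `"concentration_solution"`: list with
#'   `A_inner`, `B_inner`, `A_outer`, `log_A_outer`, `B_outer` (exactly 0)
#'   and the `geometry`.
#' @export
solve_coefficients <- function(geometry) {
  stopifnot(inherits(geometry, "scaled_geometry"))
  ab <- geometry$a_bar
  Rb <- geometry$R_bar
  if (ab >= Rb * (1 - 1e-14)) {
    stop("Degenerate geometry: a_bar = R_bar (zero-time capture); ",
         "handled by mean_capture_time(), not by the coefficient solve.",
         call. = FALSE)
  }
  denom <- basis_f(Rb) - basis_f(ab) * exp(-(Rb^2 - ab^2) / 2)
  if (abs(denom) < .Machine$double.eps * max(abs(basis_f(Rb)), 1)) {
    stop("Numerical conditioning failure: coefficient denominator is ",
         "within machine epsilon of zero.", call. = FALSE)
  }
  B_inner <- 1 / denom
  A_inner <- -basis_f(ab) * exp(ab^2 / 2) * B_inner
  log_A_outer <- Rb^2 / 2
  structure(
    list(
      A_inner = A_inner,
      B_inner = B_inner,
      A_outer = if (log_A_outer < 700) exp(log_A_outer) else Inf,
      log_A_outer = log_A_outer,
      B_outer = 0,
      geometry = geometry
    ),
    class = "concentration_solution"
  )
}

#' Evaluate the steady-state concentration profile
#'
#' @param x Dimensionless radii in `[a_bar, Rstar_bar]`.
#' @param solution A `"concentration_solution"` from [solve_coefficients()].
#' @return `c(x)`; the inner expansion is used for `x <= R_bar`, the outer
#'   (pure equilibrium, rescaled to 1 at the injection shell) beyond.
#' @export
concentration_value <- function(x, solution) {
  stopifnot(inherits(solution, "concentration_solution"))
  g <- solution$geometry
  if (any(x < g$a_bar - 1e-12) || any(x > g$Rstar_bar + 1e-12)) {
    stop("`x` outside [a_bar, Rstar_bar].", call. = FALSE)
  }
  inner <- x <= g$R_bar
  out <- numeric(length(x))
  out[inner] <- solution$A_inner * exp(-x[inner]^2 / 2) +
    solution$B_inner * basis_f(x[inner])
  # outer: A_outer e^{-x^2/2} = e^{(R_bar^2 - x^2)/2}, overflow-free
  out[!inner] <- exp((g$R_bar^2 - x[!inner]^2) / 2)
  out
}

#' Radial concentration current of the steady-state solution
#'
#' The scaled radial current is `J(x) = -(c'(x) + x c(x))` (diffusive plus
#' advective part in units where `D = r0 = 1`). The equilibrium basis
#' carries none, so the outer solution has `J = 0` everywhere, while the
#' inner solution carries a constant total current: `x^2 J(x)` is
#' independent of `x`.
#'
#' @param x Dimensionless radii in `[a_bar, Rstar_bar]`.
#' @param solution A `"concentration_solution"`.
#' @return The scaled radial current at each `x` (negative values flow
#'   inward, towards the capture sphere).
#' @export
concentration_current <- function(x, solution) {
  stopifnot(inherits(solution, "concentration_solution"))
  g <- solution$geometry
  if (any(x < g$a_bar - 1e-12) || any(x > g$Rstar_bar + 1e-12)) {
    stop("`x` outside [a_bar, Rstar_bar].", call. = FALSE)
  }
  inner <- x <= g$R_bar
  out <- numeric(length(x))
  if (any(inner)) {
    xi <- x[inner]
    cv <- solution$A_inner * exp(-xi^2 / 2) + solution$B_inner * basis_f(xi)
    cp <- solution$A_inner * (-xi * exp(-xi^2 / 2)) +
      solution$B_inner * basis_f_deriv(xi)
    out[inner] <- -(cp + xi * cv)
  }
  out[!inner] <- 0
  out
}

#' Particle annihilation rate at the capture sphere
#'
#' In raw units the steady current absorbed by the capture sphere is
#' `F = 4 * pi * D * B_inner * r0`: the `f` basis carries a constant total
#' current `-4 * pi * B_inner` (scaled), and only it contributes.
#'
#' @param solution A `"concentration_solution"`.
#' @param r0 Thermal tether length (defaults to the geometry's `r0`).
#' @param D Diffusion constant. Default 1.
#' @return The annihilation rate (1 / time).
#' @export
annihilation_flux <- function(solution, r0 = solution$geometry$r0, D = 1) {
  stopifnot(inherits(solution, "concentration_solution"))
  4 * pi * D * solution$B_inner * r0
}

#' The three shell integrals of the steady-state population
#'
#' `Delta1 = integral_{a_bar}^{R_bar} z^2 exp(-z^2/2) dz`,
#' `Delta2 = integral_{a_bar}^{R_bar} z^2 (f(z) + 1/z) dz`,
#' `Delta3 = integral_{R_bar}^{Rstar_bar} z^2 exp(-z^2/2) dz`.
#'
#' All three are computed by adaptive quadrature. The `Delta2` integrand is
#' evaluated as `z^2 * sqrt(2) * dawson(z / sqrt(2))` — identical to
#' `z^2 (f(z) + 1/z)` but with the `1/z` singularity removed analytically.
#' `Delta1` and `Delta3` have the closed form
#' `-z exp(-z^2/2) + sqrt(pi/2) erf(z/sqrt(2))` evaluated at the endpoints,
#' exposed as [gaussian_shell_integral()] for cross-checking.
#'
#' @param geometry A [scaled_geometry()].
#' @param rel_tol Relative quadrature tolerance. Default `1e-11`.
#' @return Named list with `delta1`, `delta2`, `delta3`.
#' @export
delta_integrals <- function(geometry, rel_tol = 1e-11) {
  stopifnot(inherits(geometry, "scaled_geometry"))
  quad <- function(fun, lo, hi) {
    if (hi <= lo) return(0)
    res <- stats::integrate(fun, lo, hi, rel.tol = rel_tol,
                            abs.tol = rel_tol, subdivisions = 2000L)
    if (res$message != "OK") {
      stop("Quadrature failed on [", lo, ", ", hi, "]: ", res$message,
           call. = FALSE)
    }
    res$value
  }
  list(
    delta1 = quad(function(z) z^2 * exp(-z^2 / 2),
                  geometry$a_bar, geometry$R_bar),
    delta2 = quad(function(z) z^2 * sqrt(2) * dawson(z / sqrt(2)),
                  geometry$a_bar, geometry$R_bar),
    delta3 = quad(function(z) z^2 * exp(-z^2 / 2),
                  geometry$R_bar, geometry$Rstar_bar)
  )
}

#' Closed form of the Gaussian shell integral
#'
#' `integral_{lo}^{hi} z^2 exp(-z^2/2) dz` via the antiderivative
#' `-z exp(-z^2/2) + sqrt(pi/2) erf(z/sqrt(2))`. Used as the independent
#' cross-check of the `Delta1`, `Delta3` quadratures.
#'
#' @param lo,hi Integration limits, `0 <= lo <= hi` (Inf allowed for `hi`).
#' @return The integral value.
#' @export
gaussian_shell_integral <- function(lo, hi) {
  anti <- function(z) {
    # erf(z / sqrt(2)) = 2 pnorm(z) - 1
    ifelse(is.infinite(z),
           sqrt(pi / 2),
           -z * exp(-z^2 / 2) + sqrt(pi / 2) * (2 * stats::pnorm(z) - 1))
  }
  anti(hi) - anti(lo)
}

# Fused overflow-safe product A_outer * Delta3
#   = integral_{R_bar}^{Rstar_bar} z^2 exp((R_bar^2 - z^2)/2) dz;
# the integrand is <= z^2 on the domain, so no exponential is materialized.
outer_population_term <- function(geometry, rel_tol = 1e-11) {
  Rb <- geometry$R_bar
  Rsb <- geometry$Rstar_bar
  if (Rsb <= Rb) return(0)
  # integrand decays like exp(-(z^2 - Rb^2)/2); truncate the infinite-looking
  # tail for quadrature robustness
  hi <- min(Rsb, sqrt(Rb^2 + 4 * 709))
  res <- stats::integrate(function(z) z^2 * exp((Rb^2 - z^2) / 2), Rb, hi,
                          rel.tol = rel_tol, abs.tol = rel_tol,
                          subdivisions = 2000L)
  if (res$message != "OK") {
    stop("Quadrature failed for the outer population term: ", res$message,
         call. = FALSE)
  }
  res$value
}

#' Steady-state particle number between the capture and reflecting spheres
#'
#' Integrates the assembled concentration profile over the shell
#' `a <= r <= Rstar`:
#' `N = 4 pi r0^3 [A_inner Delta1 + B_inner Delta2 + A_outer Delta3
#'                 - (B_inner / 2) (R_bar^2 - a_bar^2)]`.
#' The `A_outer * Delta3` product is computed as the fused integral
#' `integral z^2 exp((R_bar^2 - z^2)/2) dz` so that `exp(R_bar^2/2)` is never
#' materialized on its own.
#'
#' @param solution A `"concentration_solution"`.
#' @param geometry The matching [scaled_geometry()] (defaults to the one in
#'   `solution`).
#' @param r0 Thermal tether length (defaults to the geometry's `r0`).
#' @return The particle count, `>= 0`.
#' @export
steady_state_population <- function(solution,
                                    geometry = solution$geometry,
                                    r0 = geometry$r0) {
  stopifnot(inherits(solution, "concentration_solution"))
  d <- delta_integrals(geometry)
  bracket <- solution$A_inner * d$delta1 +
    solution$B_inner * d$delta2 +
    outer_population_term(geometry) -
    solution$B_inner / 2 * (geometry$R_bar^2 - geometry$a_bar^2)
  pop <- 4 * pi * r0^3 * bracket
  if (pop < -1e-10 * abs(4 * pi * r0^3)) {
    stop("Negative steady-state population: numerical pathology.",
         call. = FALSE)
  }
  max(pop, 0)
}

#' Mean time to capture for a tethered ligand
#'
#' Solves the steady-state advection-diffusion problem for a ligand injected
#' at the rms end-to-end distance `Rrms = b sqrt(N)`, pulled towards the
#' absorbing capture sphere (radius `a`) by the tether's harmonic potential
#' and reflected at the maximal extension `N b`. The mean time to capture is
#' the steady-state population divided by the annihilation flux,
#' `T = N_ss / F`, which equals the mean first-passage time from `Rrms` to
#' the capture sphere.
#'
#' The `N = 1, a = b` case is degenerate (the start radius coincides with
#' the capture radius) and returns `mean_time = 0` exactly, with the
#' divergent flux and the population reported as `NA`.
#'
#' @param model A [tether_model()].
#' @return An object of class `"capture_time_result"`: list with `flux`,
#'   `population`, `mean_time` (= `population / flux`), `tau_scaled`
#'   (= `mean_time / tau0`), `deltas` (the three shell integrals), plus the
#'   `geometry`, `solution` and `model` used.
#' @examples
#' res <- mean_capture_time(tether_model(N = 10))
#' res$tau_scaled # ~ 6.7465
#' @export
mean_capture_time <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  if (model$a > model$Rrms * (1 + 1e-12)) {
    stop("Start radius Rrms = b * sqrt(N) lies inside the capture sphere ",
         "(a > Rrms): no capture problem to solve.", call. = FALSE)
  }
  geom <- scaled_geometry(model)
  if (geom$a_bar >= geom$R_bar * (1 - 1e-12)) {
    # start radius equals capture radius: captured immediately
    return(structure(
      list(flux = NA_real_, population = NA_real_,
           mean_time = 0, tau_scaled = 0,
           deltas = list(delta1 = 0, delta2 = 0,
                         delta3 = delta_integrals(geom)$delta3),
           geometry = geom, solution = NULL, model = model),
      class = "capture_time_result"
    ))
  }
  sol <- solve_coefficients(geom)
  d <- delta_integrals(geom)
  flux <- annihilation_flux(sol, r0 = model$r0, D = model$D)
  pop <- steady_state_population(sol, geom, r0 = model$r0)
  mean_time <- pop / flux
  structure(
    list(flux = flux, population = pop, mean_time = mean_time,
         tau_scaled = mean_time / model$tau0,
         deltas = d, geometry = geom, solution = sol, model = model),
    class = "capture_time_result"
  )
}

#' @export
print.capture_time_result <- function(x, ...) {
  cat("<capture_time_result>\n")
  cat(sprintf("  N = %g: tau = %g (tau/tau0 = %g)\n",
              x$model$N, x$mean_time, x$tau_scaled))
  cat(sprintf("  flux F = %g, population N_ss = %g\n", x$flux, x$population))
  invisible(x)
}

#' Capture-time curve over a grid of tether lengths
#'
#' Tidy front end to [mean_capture_time()]: evaluates the mean capture time
#' for each polymerization index in `N` and returns one row per value.
#'
#' @param N Vector of polymerization indices (each `>= 1`).
#' @param b,a,D,T_temp Physical parameters, see [tether_model()].
#' @return A tibble with columns `N`, `tau_scaled`, `mean_time`, `flux`,
#'   `population`, `delta1`, `delta2`, `delta3`.
#' @examples
#' capture_time(N = c(2, 10, 100))
#' @export
capture_time <- function(N, b = 1, a = b, D = 1, T_temp = 1) {
  purrr::map_dfr(N, function(n) {
    res <- mean_capture_time(tether_model(N = n, b = b, a = a, D = D,
                                          T_temp = T_temp))
    tibble::tibble(
      N = n,
      tau_scaled = res$tau_scaled,
      mean_time = res$mean_time,
      flux = res$flux,
      population = res$population,
      delta1 = res$deltas$delta1,
      delta2 = res$deltas$delta2,
      delta3 = res$deltas$delta3
    )
  })
}

#' Steady-state concentration profile as a tidy table
#'
#' @param model A [tether_model()] with `N > 1` (or `a < b sqrt(N)`).
#' @param n Number of radial grid points. Default 200.
#' @return A tibble with columns `x` (radius in units of `r0`), `c`
#'   (concentration, 1 at the injection shell) and `current` (scaled radial
#'   current; 0 in the outer region).
#' @export
concentration_profile <- function(model, n = 200) {
  stopifnot(inherits(model, "tether_model"))
  geom <- scaled_geometry(model)
  sol <- solve_coefficients(geom)
  x <- seq(geom$a_bar, geom$Rstar_bar, length.out = n)
  tibble::tibble(
    x = x,
    c = concentration_value(x, sol),
    current = concentration_current(x, sol)
  )
}

#' Large-N scaling exponent of the capture time
#'
#' Fits `log(tau_scaled) ~ log(N)` by ordinary least squares over a
#' log-spaced grid in the asymptotic regime; the capture time approaches
#' `tau ~ tau0 * N^(3/2)`, so the slope tends to 1.5.
#'
#' @param N_grid Polymerization indices; default 24 log-spaced points in
#'   `[1e3, 1e5]`. At least 3 distinct values required.
#' @param b,a,D,T_temp Physical parameters, see [tether_model()].
#' @return A one-row tibble with `exponent`, `std_error`, `r_squared`, `n`.
#' @export
scaling_exponent <- function(N_grid = exp(seq(log(1e3), log(1e5),
                                              length.out = 24)),
                             b = 1, a = b, D = 1, T_temp = 1) {
  if (length(unique(N_grid)) < 3) {
    stop("Need at least 3 distinct N values for the scaling regression.",
         call. = FALSE)
  }
  tbl <- capture_time(N_grid, b = b, a = a, D = D, T_temp = T_temp)
  fit <- stats::lm(log(tau_scaled) ~ log(N), data = tbl)
  sm <- summary(fit)
  tibble::tibble(
    exponent = unname(stats::coef(fit)[2]),
    std_error = sm$coefficients[2, 2],
    r_squared = sm$r.squared,
    n = length(N_grid)
  )
}

#' Competitive-binding cutoff of the capture time
#'
#' At finite ambient ligand concentration `c_inf`, free ligands outcompete
#' the tethered one once the tether is longer than the mean inter-ligand
#' spacing: `N* b ~ c_inf^(-1/3)`. The capture time is therefore bounded by
#' `tau_max = tau(N*) ~ tau0 * (b^3 c_inf)^(-1/2)`.
#'
#' @param model A [tether_model()] whose `c_inf` is set, with
#'   `b^3 * c_inf < 1` (dilute regime).
#' @return A one-row tibble with `N_star`, `tau_max` and `tau_max_scaled`
#'   (`tau_max / tau0`).
#' @export
tau_cutoff <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  if (is.null(model$c_inf) || model$c_inf <= 0) {
    stop("`c_inf` must be set (and > 0) to compute the cutoff.",
         call. = FALSE)
  }
  phi <- model$b^3 * model$c_inf
  if (phi >= 1) {
    stop("Non-dilute regime (b^3 * c_inf >= 1): outside model validity.",
         call. = FALSE)
  }
  N_star <- phi^(-1 / 3)
  res <- mean_capture_time(tether_model(N = N_star, b = model$b,
                                        a = model$a, D = model$D,
                                        T_temp = model$T_temp))
  tibble::tibble(N_star = N_star,
                 tau_max = res$mean_time,
                 tau_max_scaled = res$tau_scaled)
}
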