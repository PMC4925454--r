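#' Mean first-passage time by backward-equation quadrature
#'
#' Independent check of the steady-state route: for 1-D radial diffusion in
#' the potential `x^2/2` (units of the thermal energy), with an absorbing
#' boundary at `a_bar` and a reflecting boundary at `Rstar_bar`, the mean
#' first-passage time from `r_start` is the classical double quadrature
#' `T(x0) = integral_{a_bar}^{x0} dy exp(y^2/2) / y^2 *
#'          integral_y^{Rstar_bar} z^2 exp(-z^2/2) dz`.
#' The inner integral is evaluated in closed form
#' ([gaussian_shell_integral()]); the outer one by adaptive quadrature.
#'
#' @param r_start Dimensionless start radius in `[a_bar, Rstar_bar]`.
#' @param geometry A [scaled_geometry()].
#' @param rel_tol Quadrature tolerance. Default `1e-11`.
#' @return The mean first-passage time in units of `r0^2 / D`. Zero at
#'   `r_start = a_bar`, monotonically increasing in `r_start`.
#' @examples
#' g <- new_scaled_geometry(a_bar = 1, R_bar = sqrt(3), Rstar_bar = 3)
#' mfpt_quadrature(sqrt(3), g)
#' @export
mfpt_quadrature <- function(r_start, geometry, rel_tol = 1e-11) {
  stopifnot(inherits(geometry, "scaled_geometry"))
  ab <- geometry$a_bar
  Rsb <- geometry$Rstar_bar
  if (r_start < ab - 1e-12 || r_start > Rsb + 1e-12) {
    stop("`r_start` outside [a_bar, Rstar_bar].", call. = FALSE)
  }
  if (r_start <= ab) return(0)
  integrand <- function(y) {
    exp(y^2 / 2) / y^2 * gaussian_shell_integral(y, Rsb)
  }
  res <- stats::integrate(integrand, ab, r_start, rel.tol = rel_tol,
                          abs.tol = rel_tol, subdivisions = 800L)
  if (res$message != "OK") {
    stop("MFPT quadrature failed: ", res$message, call. = FALSE)
  }
  res$value
}

#' Brownian dynamics estimate of the mean capture time
#'
#' Stochastic oracle for [mean_capture_time()]: overdamped Langevin
#' trajectories in three dimensions, integrated by the Euler-Maruyama
#' scheme. Each step displaces the ligand by
#' `-(D / r0^2) * r * dt + sqrt(2 D dt) * xi`, with `xi` a vector of three
#' independent standard normal draws (the drift is the Hookean tether force
#' times the mobility). Trajectories start uniformly distributed on the
#' sphere of radius `Rrms`, are absorbed when they touch the capture sphere
#' (`|r| <= a`) and are reflected radially (`|r| -> 2 Rstar - |r|`) at the
#' maximal tether extension.
#'
#' The simulator uses its own xoshiro256++ generator seeded by `seed`, so a
#' run is reproducible bit-for-bit regardless of R's RNG state.
#'
#' @param model A [tether_model()] with a non-degenerate geometry
#'   (`Rrms > a`).
#' @param dt Time step in units of `tau0`. Default `1e-4`.
#' @param n_traj Number of trajectories. Default 2000.
#' @param seed Integer seed; required, no silent default.
#' @param max_steps Safety cap per trajectory. Defaults to enough steps to
#'   cover 200 times the analytic mean capture time; a warning is emitted if
#'   a user-supplied cap covers less than 100 times.
#' @param return_times If `TRUE`, attach the vector of first-passage times.
#' @return An object of class `"fpt_sample"`: list with `mean`, `stderr`
#'   (both in raw time units), `mean_scaled`, `stderr_scaled` (units of
#'   `tau0`), `n_absorbed`, `n_censored`, `dt`, `seed` and optionally
#'   `times`. Censored trajectories (cap reached) trigger a warning and are
#'   excluded from the mean.
#' @export
simulate_fpt <- function(model, dt = 1e-4, n_traj = 2000, seed,
                         max_steps = NULL, return_times = FALSE) {
  stopifnot(inherits(model, "tether_model"))
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  seed <- as.integer(seed)
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be > 0.", call. = FALSE)
  n_traj <- as.integer(n_traj)
  if (n_traj < 1) stop("`n_traj` must be >= 1.", call. = FALSE)
  if (model$Rrms <= model$a * (1 + 1e-12)) {
    stop("Degenerate geometry (Rrms <= a): nothing to simulate.",
         call. = FALSE)
  }
  analytic <- mean_capture_time(model)
  dt_abs <- dt * model$tau0
  needed <- analytic$mean_time / dt_abs
  if (is.null(max_steps)) {
    max_steps <- ceiling(200 * needed)
  } else if (max_steps * dt_abs < 100 * analytic$mean_time) {
    warning("`max_steps * dt` covers less than 100x the analytic mean ",
            "capture time; censoring is likely.", call. = FALSE)
  }
  times <- bd_first_passage(
    a = model$a, rstar = model$Rstar, rstart = model$Rrms,
    r0sq = model$r0^2, D = model$D, dt = dt_abs,
    n_traj = n_traj, max_steps = as.double(max_steps),
    seed = seed
  )
  censored <- is.na(times)
  n_cens <- sum(censored)
  if (n_cens == n_traj) {
    stop("All trajectories censored at max_steps.", call. = FALSE)
  }
  if (n_cens > 0) {
    warning(n_cens, " trajectories censored at max_steps.", call. = FALSE)
  }
  tt <- times[!censored]
  m <- mean(tt)
  se <- stats::sd(tt) / sqrt(length(tt))
  structure(
    list(mean = m, stderr = se,
         mean_scaled = m / model$tau0, stderr_scaled = se / model$tau0,
         n_absorbed = n_traj - n_cens, n_censored = n_cens,
         dt = dt, seed = seed,
         times = if (return_times) times else NULL),
    class = "fpt_sample"
  )
}

#' @export
print.fpt_sample <- function(x, ...) {
  cat("<fpt_sample>\n")
  cat(sprintf("  mean FPT = %g +/- %g (tau0 units: %g +/- %g)\n",
              x$mean, x$stderr, x$mean_scaled, x$stderr_scaled))
  cat(sprintf("  %d absorbed, %d censored (dt = %g tau0, seed = %d)\n",
              x$n_absorbed, x$n_censored, x$dt, x$seed))
  invisible(x)
}
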