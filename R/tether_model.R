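#' Define a tethered-ligand capture model
#'
#' Bundles the physical parameters of the tethered-ligand problem: a ligand
#' held by a Gaussian polymer of `N` Kuhn segments of length `b`, diffusing
#' with constant `D` in the entropic harmonic potential of the tether, towards
#' an absorbing capture sphere of radius `a` centred on the already-bound
#' partner. Temperature is given in energy units (Boltzmann constant = 1).
#'
#' Derived scales are computed once and stored:
#' * spring constant `kappa = 3 * T_temp / (b^2 * N)`,
#' * thermal tether length `r0 = sqrt(T_temp / kappa) = b * sqrt(N / 3)`,
#' * diffusion time `tau0 = a^2 / D`,
#' * rms end-to-end distance `Rrms = b * sqrt(N)` (the injection radius),
#' * maximal extension `Rstar = N * b` (the reflecting outer boundary).
#'
#' @param N Polymerization index (number of Kuhn segments), a real `>= 1`.
#'   Real values are accepted so that scaling studies can use log-spaced
#'   grids.
#' @param b Kuhn length of the tether (length units). Default 1.
#' @param a Capture-sphere radius (length units). Defaults to `b`, the
#'   molecular-scale choice used throughout the analysis.
#' @param D Ligand diffusion constant (length^2 / time). Default 1.
#' @param T_temp Temperature in energy units with `k_B = 1`. Default 1.
#' @param c_inf Optional ambient ligand number density (1 / length^3), used
#'   only by [tau_cutoff()] for the competitive-binding cutoff.
#'
#' @return An object of class `"tether_model"`: a list with the validated
#'   parameters and the derived scales `kappa`, `r0`, `tau0`, `Rrms`,
#'   `Rstar`, and mobility `mu = D / T_temp`.
#' @examples
#' m <- tether_model(N = 10)
#' m$kappa          # 3 T / (b^2 N)
#' m$Rrms / m$r0    # sqrt(3), always
#' @seealso [scaled_geometry()], [mean_capture_time()]
#' @export
tether_model <- function(N, b = 1, a = b, D = 1, T_temp = 1, c_inf = NULL) {
  check_positive_scalar <- function(x, name, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", name, "` must be a single finite number.", call. = FALSE)
    }
    if (strict && x <= 0) {
      stop("`", name, "` must be > 0.", call. = FALSE)
    }
    as.numeric(x)
  }
  N <- check_positive_scalar(N, "N")
  if (N < 1) stop("`N` must be >= 1.", call. = FALSE)
  b <- check_positive_scalar(b, "b")
  a <- check_positive_scalar(a, "a")
  D <- check_positive_scalar(D, "D")
  T_temp <- check_positive_scalar(T_temp, "T_temp")
  if (!is.null(c_inf)) {
    c_inf <- check_positive_scalar(c_inf, "c_inf", strict = FALSE)
    if (c_inf < 0) stop("`c_inf` must be >= 0.", call. = FALSE)
  }
  Rstar <- N * b
  # a == Rstar is the fully degenerate N = 1, a = b shell (zero-time capture);
  # only a beyond the maximal extension is unphysical
  if (a > Rstar) {
    stop("Degenerate geometry: capture radius `a` must not exceed the ",
         "maximal tether extension N * b.", call. = FALSE)
  }
  kappa <- 3 * T_temp / (b^2 * N)
  structure(
    list(
      N = N, b = b, a = a, D = D, T_temp = T_temp, c_inf = c_inf,
      kappa = kappa,
      r0 = sqrt(T_temp / kappa),
      tau0 = a^2 / D,
      Rrms = b * sqrt(N),
      Rstar = Rstar,
      mu = D / T_temp
    ),
    class = "tether_model"
  )
}

#' @export
print.tether_model <- function(x, ...) {
  cat("<tether_model>\n")
  cat(sprintf("  N = %g segments, b = %g, a = %g, D = %g, T = %g\n",
              x$N, x$b, x$a, x$D, x$T_temp))
  cat(sprintf("  kappa = %g, r0 = %g, tau0 = %g, Rrms = %g, Rstar = %g\n",
              x$kappa, x$r0, x$tau0, x$Rrms, x$Rstar))
  if (!is.null(x$c_inf)) cat(sprintf("  c_inf = %g\n", x$c_inf))
  invisible(x)
}

#' Entropic spring constant of the tether
#'
#' A Gaussian coil of `N` segments acts as a Hookean spring with
#' `kappa = 3 * T / (b^2 * N)`: stiffness falls off as 1/N.
#'
#' @param model A [tether_model()].
#' @return The spring constant (energy / length^2).
#' @examples
#' spring_constant(tether_model(N = 3)) # 1 in default units
#' @export
spring_constant <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  model$kappa
}

#' Dimensionless geometry of the capture problem
#'
#' Rescales all radii by the thermal tether length `r0 = b * sqrt(N / 3)`
#' (the distance at which stretching the tether costs one unit of thermal
#' energy). The ligand is injected at the rms end-to-end distance, so
#' `R_bar = Rrms / r0 = sqrt(3)` for every `N`; the capture radius becomes
#' `a_bar = a / r0` and the reflecting boundary `Rstar_bar = N * b / r0`.
#'
#' @param model A [tether_model()].
#' @return An object of class `"scaled_geometry"`: list with `a_bar`,
#'   `R_bar`, `Rstar_bar` and the scale `r0`.
#' @examples
#' scaled_geometry(tether_model(N = 3)) # a_bar = 1, R_bar = sqrt(3)
#' @export
scaled_geometry <- function(model) {
  stopifnot(inherits(model, "tether_model"))
  r0 <- model$r0
  geom <- new_scaled_geometry(
    a_bar = model$a / r0,
    R_bar = model$Rrms / r0,
    Rstar_bar = model$Rstar / r0,
    r0 = r0
  )
  geom
}

#' Construct a dimensionless geometry directly
#'
#' Low-level constructor used by [scaled_geometry()] and by tests that probe
#' geometries not tied to a physical model. Radii are in units of the thermal
#' tether length `r0`.
#'
#' @param a_bar Absorbing (capture) radius, `> 0`.
#' @param R_bar Injection radius, `>= a_bar`.
#' @param Rstar_bar Reflecting outer radius, `>= R_bar`.
#' @param r0 The length scale the radii were scaled by (default 1).
#' @return A `"scaled_geometry"` object.
#' @export
new_scaled_geometry <- function(a_bar, R_bar, Rstar_bar, r0 = 1) {
  vals <- c(a_bar = a_bar, R_bar = R_bar, Rstar_bar = Rstar_bar)
  if (any(!is.finite(vals)) || a_bar <= 0) {
    stop("Geometry radii must be finite and a_bar > 0.", call. = FALSE)
  }
  tol <- 1e-12 * max(1, R_bar)
  if (a_bar > R_bar + tol || R_bar > Rstar_bar + tol) {
    stop("Degenerate geometry: need a_bar <= R_bar <= Rstar_bar.",
         call. = FALSE)
  }
  structure(
    list(a_bar = a_bar, R_bar = R_bar, Rstar_bar = Rstar_bar, r0 = r0),
    class = "scaled_geometry"
  )
}

#' @export
print.scaled_geometry <- function(x, ...) {
  cat(sprintf("<scaled_geometry> a_bar = %g, R_bar = %g, Rstar_bar = %g (r0 = %g)\n",
              x$a_bar, x$R_bar, x$Rstar_bar, x$r0))
  invisible(x)
}
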