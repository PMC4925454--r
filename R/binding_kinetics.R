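#' Rates of the three-state tethered-ligand binding model
#'
#' The tethered ligand pair occupies one of three states: (I) free, (II)
#' singly bound, (III) doubly bound. Transitions: I -> II at `r_on`,
#' II -> I at `r_off`, II -> III at `r_capture = 1 / tau(N)` (the inverse
#' mean capture time of the second ligand), III -> I at the slow unbinding
#' rate `r_off_double`. The III -> II back-transition is neglected, being
#' slower still.
#'
#' @param r_on Single-ligand on rate (1/time), `> 0`. Already scaled by the
#'   receptor concentration, so the dissociation constant
#'   `Kd = r_off / r_on` is dimensionless.
#' @param r_off Single-ligand off rate (1/time), `>= 0`.
#' @param r_off_double Doubly-bound off rate (1/time), `>= 0`. Expected to
#'   be much smaller than `r_off`; a warning is given otherwise.
#' @param r_capture II -> III capture rate (1/time); `Inf` is accepted as
#'   the instantaneous-capture limit. Give either this or `tau`.
#' @param tau Mean capture time; `r_capture = 1/tau` (`tau = 0` means
#'   instantaneous capture).
#' @param Kd Optional dissociation constant; if supplied it must equal
#'   `r_off / r_on`.
#' @return An object of class `"kinetic_rates"`.
#' @examples
#' kinetic_rates(r_on = 1, r_off = 1, r_off_double = 0.01, tau = 2)
#' @export
kinetic_rates <- function(r_on, r_off, r_off_double, r_capture = NULL,
                          tau = NULL, Kd = NULL) {
  chk <- function(x, name, allow_inf = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
      (allow_inf || is.finite(x))
    if (!ok) stop("`", name, "` must be a single number >= 0.", call. = FALSE)
    as.numeric(x)
  }
  r_on <- chk(r_on, "r_on")
  r_off <- chk(r_off, "r_off")
  r_off_double <- chk(r_off_double, "r_off_double")
  if (is.null(r_capture)) {
    if (is.null(tau)) stop("Give `r_capture` or `tau`.", call. = FALSE)
    tau <- chk(tau, "tau")
    r_capture <- if (tau == 0) Inf else 1 / tau
  } else {
    r_capture <- chk(r_capture, "r_capture", allow_inf = TRUE)
    if (!is.null(tau)) stop("Give only one of `r_capture`, `tau`.",
                            call. = FALSE)
  }
  if (r_on <= 0) stop("`r_on` must be > 0.", call. = FALSE)
  if (r_off_double >= r_off && r_off > 0) {
    warning("Expected r_off_double << r_off (the doubly bound state should ",
            "be the stable one).", call. = FALSE)
  }
  kd <- r_off / r_on
  if (!is.null(Kd) && abs(Kd - kd) > 1e-8 * max(1, kd)) {
    stop("Inconsistent `Kd`: must equal r_off / r_on = ", signif(kd, 6),
         ".", call. = FALSE)
  }
  structure(
    list(r_on = r_on, r_off = r_off, r_off_double = r_off_double,
         r_capture = r_capture, Kd = kd),
    class = "kinetic_rates"
  )
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat(sprintf("<kinetic_rates> r_on = %g, r_off = %g, r_off_double = %g, r_capture = %g (Kd = %g)\n",
              x$r_on, x$r_off, x$r_off_double, x$r_capture, x$Kd))
  invisible(x)
}

# generator matrix Q (columns sum to 0): dP/dt = Q %*% P, P = (P_I, P_II, P_III)
rate_matrix <- function(rates) {
  with(rates, matrix(c(
    -r_on,  r_off,                r_off_double,
     r_on, -(r_off + r_capture),  0,
     0,     r_capture,           -r_off_double
  ), nrow = 3, byrow = TRUE))
}

#' Steady state of the three-state binding model
#'
#' Solves the balance equations (time derivatives set to zero) with the
#' normalization `P_I + P_II + P_III = 1`. The stationary weights are
#' `w_I = (r_off + r_capture) * r_off_double`, `w_II = r_on * r_off_double`,
#' `w_III = r_on * r_capture`. Degenerate chains are resolved as exact
#' limits: `r_off_double = 0` with `r_capture > 0` makes state III
#' absorbing (`P_III = 1`); `r_capture = 0` gives the two-state equilibrium
#' with `P_III = 0`; `r_capture = Inf` (instantaneous capture) gives
#' `P_II = 0` with `P_III / P_I = r_on / r_off_double`.
#'
#' @param rates A [kinetic_rates()].
#' @return A one-row tibble with columns `P_I`, `P_II`, `P_III` summing
#'   to 1.
#' @examples
#' steady_state(kinetic_rates(1, 1, 1, r_capture = 1)) # 0.5, 0.25, 0.25
#' @export
steady_state <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  with(rates, {
    if (r_off_double == 0 && r_capture == 0) {
      # two-state chain between I and II; III unreachable
      w <- c(r_off, r_on, 0)
    } else if (is.infinite(r_capture)) {
      # instantaneous capture: weights divided by r_capture
      w <- c(r_off_double, 0, r_on)
    } else {
      w <- c((r_off + r_capture) * r_off_double,
             r_on * r_off_double,
             r_on * r_capture)
    }
    if (sum(w) == 0) stop("All rates zero: no stationary state.",
                          call. = FALSE)
    p <- w / sum(w)
    tibble::tibble(P_I = p[1], P_II = p[2], P_III = p[3])
  })
}

#' Transient relaxation of the three-state binding model
#'
#' Integrates the linear master equation `dP/dt = Q P` on a time grid.
#' Probability is conserved identically (the columns of `Q` sum to zero);
#' the trajectory converges to [steady_state()] for irreducible chains.
#'
#' @param rates A [kinetic_rates()] with finite `r_capture`.
#' @param p0 Initial probabilities: numeric length-3 vector or a one-row
#'   data frame with columns `P_I`, `P_II`, `P_III`; must sum to 1.
#' @param t_grid Increasing vector of output times starting at 0 (0 is
#'   prepended if absent).
#' @return A tibble with columns `time`, `P_I`, `P_II`, `P_III`.
#' @examples
#' r <- kinetic_rates(1, 1, 0.05, tau = 0.5)
#' evolve(r, c(1, 0, 0), seq(0, 10, by = 0.5))
#' @export
evolve <- function(rates, p0, t_grid) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (is.infinite(rates$r_capture)) {
    stop("Transient integration needs a finite `r_capture`.", call. = FALSE)
  }
  if (is.data.frame(p0)) p0 <- unlist(p0[1, c("P_I", "P_II", "P_III")])
  p0 <- as.numeric(p0)
  if (length(p0) != 3 || any(p0 < -1e-12) ||
      abs(sum(p0) - 1) > 1e-8) {
    stop("`p0` must be 3 nonnegative probabilities summing to 1.",
         call. = FALSE)
  }
  if (t_grid[1] > 0) t_grid <- c(0, t_grid)
  Q <- rate_matrix(rates)
  sol <- deSolve::ode(
    y = p0, times = t_grid,
    func = function(t, y, parms) list(as.vector(parms %*% y)),
    parms = Q, method = "lsoda", rtol = 1e-10, atol = 1e-12
  )
  if (any(sol[, -1] < -1e-8)) {
    stop("Integration produced negative probabilities beyond tolerance.",
         call. = FALSE)
  }
  tibble::tibble(time = sol[, 1], P_I = sol[, 2], P_II = sol[, 3],
                 P_III = sol[, 4])
}

#' Doubly-bound to free occupancy ratio
#'
#' Closed-form steady-state ratio
#' `P_III / P_I = (r_on / r_off_double) * 1 / (1 + tau * r_off)`, where
#' `tau` is the mean capture time of the second ligand
#' (`r_capture = 1/tau`). Equals the ratio of the corresponding
#' concentrations in steady state.
#'
#' @param rates A [kinetic_rates()] with `r_off_double > 0`.
#' @param tau Mean capture time, `>= 0`; overrides the `r_capture` stored
#'   in `rates` (default: `1 / rates$r_capture`).
#' @return The ratio `P_III / P_I`.
#' @examples
#' r <- kinetic_rates(r_on = 1, r_off = 1, r_off_double = 0.1, tau = 1)
#' bound_ratio(r) # 5
#' @export
bound_ratio <- function(rates, tau = NULL) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (rates$r_off_double <= 0) {
    stop("`r_off_double` must be > 0 (the ratio diverges otherwise).",
         call. = FALSE)
  }
  if (is.null(tau)) {
    tau <- if (is.infinite(rates$r_capture)) 0 else 1 / rates$r_capture
  }
  if (tau < 0) stop("`tau` must be >= 0.", call. = FALSE)
  (rates$r_on / rates$r_off_double) / (1 + tau * rates$r_off)
}

#' Avidity enhancement factor of the tether
#'
#' Ratio of the doubly-bound occupancy of tethered ligand pairs to that of
#' untethered pairs (for which the second binding proceeds at `r_on` instead
#' of `1/tau`):
#' `R = (1 + Kd) / (1 + r_on * tau * Kd)`,
#' with `Kd = r_off / r_on` the dimensionless single-bond dissociation
#' constant. Bounded by `1 <= R <= 1 + Kd` whenever `r_on * tau <= 1`; the
#' upper bound is reached at instantaneous capture (`tau = 0`).
#'
#' @param Kd Dimensionless dissociation constant, `> 0`.
#' @param r_on Single-ligand on rate (1/time), `> 0`.
#' @param tau Mean capture time of the tethered second ligand, `>= 0`.
#' @return The enhancement factor.
#' @examples
#' enhancement(Kd = 1, r_on = 1, tau = 0) # 2, the upper bound 1 + Kd
#' @export
enhancement <- function(Kd, r_on, tau) {
  if (any(Kd <= 0) || any(r_on <= 0) || any(tau < 0)) {
    stop("Need Kd > 0, r_on > 0, tau >= 0.", call. = FALSE)
  }
  (1 + Kd) / (1 + r_on * tau * Kd)
}

#' Enhancement factor from two steady-state solves
#'
#' Route independent of the closed form: builds the full three-state model
#' twice — once with the tethered capture rate `r_capture = 1/tau`, once
#' with the untethered reference `r_capture = r_on` — solves each for its
#' steady state, and returns the ratio of the two `P_III / P_I` ratios.
#' Agrees with [enhancement()] to rounding error; the doubly-bound off rate
#' cancels.
#'
#' @param Kd Dimensionless dissociation constant, `> 0`.
#' @param r_on Single-ligand on rate, `> 0`.
#' @param tau Mean capture time, `>= 0` (0 = instantaneous capture).
#' @param r_off_double Doubly-bound off rate used in both solves (cancels
#'   in the ratio). Default `1e-3 * r_on`.
#' @return The enhancement factor.
#' @export
enhancement_from_states <- function(Kd, r_on, tau,
                                    r_off_double = 1e-3 * r_on) {
  if (Kd <= 0 || r_on <= 0 || tau < 0) {
    stop("Need Kd > 0, r_on > 0, tau >= 0.", call. = FALSE)
  }
  ratio_at <- function(r_capture) {
    p <- steady_state(suppressWarnings(
      kinetic_rates(r_on = r_on, r_off = Kd * r_on,
                    r_off_double = r_off_double, r_capture = r_capture)
    ))
    p$P_III / p$P_I
  }
  tethered <- ratio_at(if (tau == 0) Inf else 1 / tau)
  untethered <- ratio_at(r_on)
  tethered / untethered
}

#' Effective untethered concentration of a tethered ligand dose
#'
#' A concentration `c0` of tethered ligand pairs doubly binds like a
#' concentration `R * c0` of untethered pairs.
#'
#' @param c0 Tethered ligand concentration, `>= 0`.
#' @param R Enhancement factor from [enhancement()], `>= 0`.
#' @return `R * c0`.
#' @export
effective_concentration <- function(c0, R) {
  if (any(c0 < 0) || any(R < 0)) stop("Need c0 >= 0, R >= 0.", call. = FALSE)
  R * c0
}
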