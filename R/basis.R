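#' Dawson integral
#'
#' `dawson(u) = exp(-u^2) * integral_0^u exp(t^2) dt` for `u >= 0`. Evaluated
#' by Rybicki's sampling method — the principal-value Gaussian sum
#' `dawson(u) = (1/sqrt(pi)) * sum_{n odd} exp(-(u - n h)^2) / n` with
#' `h = 0.2`, whose truncation error is below machine precision — and, for
#' `u >= 15`, by the cancellation-free asymptotic series
#' `1/(2u) * sum_k (2k-1)!! / (2u^2)^k`, already fully converged there.
#'
#' @param u Numeric vector, `>= 0`.
#' @return `dawson(u)`, same shape as `u`.
#' @keywords internal
dawson <- function(u) {
  out <- numeric(length(u))
  small <- u < 15
  if (any(small)) {
    h <- 0.2
    out[small] <- vapply(u[small], function(x) {
      n0 <- 2 * floor(x / (2 * h)) + 1 # odd sampling index nearest x/h
      n <- seq(n0 - 60, n0 + 60, by = 2)
      sum(exp(-(x - n * h)^2) / n) / sqrt(pi)
    }, numeric(1))
  }
  if (any(!small)) {
    ul <- u[!small]
    inv2u2 <- 1 / (2 * ul^2)
    term <- rep(1, length(ul))
    s <- term
    for (k in 1:10) {
      term <- term * (2 * k - 1) * inv2u2
      s <- s + term
    }
    out[!small] <- s / (2 * ul)
  }
  out
}

#' Current-carrying basis solution f(x)
#'
#' The steady-state radial concentration equation
#' `c''(x) + (2/x + x) c'(x) + 3 c(x) = 0` has two independent solutions: the
#' equilibrium Boltzmann profile `exp(-x^2/2)` (zero current) and
#' `f(x) = sqrt(pi/2) exp(-x^2/2) erfi(x/sqrt(2)) - 1/x`, which carries a
#' constant radial current (`x^2` times the current is independent of `x`).
#'
#' Numerically, `f` is evaluated as `sqrt(2) * dawson(x/sqrt(2)) - 1/x`,
#' which is mathematically identical but immune to the overflow of
#' `erfi(x/sqrt(2))` at large `x`; for `x >= 10` the difference of the two
#' terms is itself replaced by its asymptotic series
#' `sum_k (2k-1)!! / x^(2k+1)` to avoid cancellation.
#'
#' @param x Dimensionless radius, `> 0`. Vectorized.
#' @return `f(x)`.
#' @examples
#' basis_f(1) # -0.2752215...
#' @export
basis_f <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`x` must be positive and finite.", call. = FALSE)
  }
  out <- numeric(length(x))
  small <- x < 10
  if (any(small)) {
    xs <- x[small]
    out[small] <- sqrt(2) * dawson(xs / sqrt(2)) - 1 / xs
  }
  if (any(!small)) {
    xl <- x[!small]
    # f(x) = 1/x^3 + 3/x^5 + 15/x^7 + ...; converged by k ~ 20 for x >= 10
    invx2 <- 1 / xl^2
    term <- invx2 / xl
    s <- term
    for (k in 1:20) {
      term <- term * (2 * k + 1) * invx2
      s <- s + term
    }
    out[!small] <- s
  }
  out
}

#' Derivative of the current-carrying basis solution
#'
#' Uses the identity `f'(x) = 1/x^2 - x * f(x)` (equivalently
#' `f' + x f = 1/x^2`, the statement that `exp(x^2/2) x^2` times the current
#' of `f` is constant).
#'
#' @param x Dimensionless radius, `> 0`.
#' @return `f'(x)`.
#' @export
basis_f_deriv <- function(x) {
  1 / x^2 - x * basis_f(x)
}

#' Residual of the radial steady-state equation
#'
#' Evaluates `c'' + (2/x + x) c' + 3 c`, which vanishes for any solution of
#' the steady-state advection-diffusion equation in the harmonic tether
#' potential. Intended for verifying candidate solutions.
#'
#' @param x Dimensionless radius, `> 0`. Vectorized.
#' @param c,c_prime,c_dprime Values of the function and its first two
#'   derivatives at `x`.
#' @return The residual, 0 (to numerical accuracy) for true solutions.
#' @examples
#' x <- 1.3
#' ode_residual(x, exp(-x^2 / 2), -x * exp(-x^2 / 2), (x^2 - 1) * exp(-x^2 / 2))
#' @export
ode_residual <- function(x, c, c_prime, c_dprime) {
  if (any(x <= 0)) stop("`x` must be positive.", call. = FALSE)
  c_dprime + (2 / x + x) * c_prime + 3 * c
}
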