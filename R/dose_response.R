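#' Theoretical tether-length dose-response curve
#'
#' Percent metabolic-activity enhancement as a function of the
#' polymerization index of the tether:
#' `dM(N) = (beta - gamma * N^(3/2)) / (1 + gamma * N^(3/2))`.
#' The `N^(3/2)` follows from the large-N scaling of the capture time
#' entering the avidity enhancement factor; `beta` sets the short-tether
#' amplitude and `gamma` the decay scale. Strictly decreasing in `N` for
#' `gamma > 0` and `beta > -1`, with floor `-1` as `N -> Inf`.
#'
#' @param N Polymerization index, `>= 0`. Vectorized.
#' @param beta Amplitude parameter (percent units). Default 78.5, the
#'   reference fit value.
#' @param gamma Scale parameter multiplying `N^(3/2)`, `>= 0`. Default
#'   0.00063, the reference fit value.
#' @return `dM(N)` in percent.
#' @examples
#' dm_theory(c(1, 45, 454))
#' @export
dm_theory <- function(N, beta = 78.5, gamma = 0.00063) {
  if (any(N < 0)) stop("`N` must be >= 0.", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be >= 0.", call. = FALSE)
  g <- gamma * N^1.5
  (beta - g) / (1 + g)
}

#' Dose-response from the kinetic model
#'
#' Mechanistic bridge between the three-state kinetics and the empirical
#' dose-response form: the metabolic enhancement is taken proportional to
#' the excess doubly-bound occupancy, `dM = alpha * (R - 1)` with `R` the
#' avidity [enhancement()] factor. With `tau` proportional to `N^(3/2)`
#' this reproduces the rational form of [dm_theory()].
#'
#' @param alpha Proportionality between doubly-bound occupancy and percent
#'   metabolic enhancement, `>= 0`.
#' @param Kd Dimensionless dissociation constant, `> 0`.
#' @param r_on Single-ligand on rate (1/time), `> 0`.
#' @param tau Mean capture time, `>= 0`. Vectorized.
#' @return Percent metabolic enhancement.
#' @export
dm_from_kinetics <- function(alpha, Kd, r_on, tau) {
  if (alpha < 0) stop("`alpha` must be >= 0.", call. = FALSE)
  alpha * (enhancement(Kd, r_on, tau) - 1)
}

#' Synthetic tether-length dose-response dataset
#'
#' Generates `(N, dM)` records on the theoretical curve [dm_theory()] with
#' independent homoscedastic Gaussian noise — a stand-in emulating
#' metabolic-activity measurements over the experimentally probed tether
#' range (N = 1 to 454).
#'
#' @param n_values Polymerization indices of the records. Default: nine
#'   log-spaced values spanning 1 to 454.
#' @param beta,gamma Curve parameters; defaults are the reference values
#'   78.5 and 0.00063.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   percent metabolic-activity units. Default 5.
#' @param seed Integer seed; required, no silent default.
#' @return A tibble with columns `N`, `dM` and `dM_true` (the noiseless
#'   curve value).
#' @examples
#' synth_dataset(seed = 1)
#' @export
synth_dataset <- function(n_values = default_n_values(),
                          beta = 78.5, gamma = 0.00063,
                          noise_sd = 5, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (length(n_values) == 0) stop("`n_values` is empty.", call. = FALSE)
  if (any(n_values < 1)) stop("`n_values` must be >= 1.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  truth <- dm_theory(n_values, beta, gamma)
  # draw noise under the given seed without disturbing the caller's RNG state
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  tibble::tibble(
    N = as.numeric(n_values),
    dM = truth + stats::rnorm(length(n_values), sd = noise_sd),
    dM_true = truth
  )
}

#' Default sampling grid of tether lengths
#'
#' Nine log-spaced polymerization indices spanning the experimental range
#' 1 to 454.
#' @return Integer-valued numeric vector of length 9.
#' @export
default_n_values <- function() {
  round(exp(seq(log(1), log(454), length.out = 9)))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Fit the dose-response curve to (N, dM) data
#'
#' Two-parameter nonlinear least squares of [dm_theory()] against a
#' dataset, minimizing `sum_i (dM_i - dM(N_i; beta, gamma))^2`
#' (Levenberg-Marquardt, `gamma` bounded below by 0). If a `sigma` column
#' is present, weighted least squares with weights `1/sigma^2` is used.
#'
#' @param data A data frame with numeric columns `N` and `dM` (and
#'   optionally `sigma`); at least 3 records and 2 distinct `N` after
#'   exclusions.
#' @param init Optional named list/vector with starting values `beta`,
#'   `gamma`. Default: `beta = max(dM)`, `gamma = 1 / median(N)^(3/2)` — a
#'   safe basin since the curve is monotone in both arguments.
#' @param exclude_n Optional vector of `N` values to drop before fitting
#'   (e.g. `exclude_n = 1` to drop the shortest tether, where the
#'   Gaussian-coil model breaks down).
#' @return An object of class `"dose_response_fit"`: list with `params`
#'   (named vector `beta`, `gamma`), `residual_sum_sq`, `covariance`
#'   (2 x 2), `n_points`, `data` (rows used) and the underlying `fit`
#'   object. Supports [generics::tidy()], [generics::glance()],
#'   [generics::augment()] and [ggplot2::autoplot()].
#' @examples
#' d <- synth_dataset(seed = 42)
#' fit_dose_response(d)
#' @export
fit_dose_response <- function(data, init = NULL, exclude_n = NULL) {
  if (!is.data.frame(data) || !all(c("N", "dM") %in% names(data))) {
    stop("`data` must have columns `N` and `dM`.", call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  if (!is.null(exclude_n)) d <- d[!(d$N %in% exclude_n), , drop = FALSE]
  if (!all(is.finite(d$N)) || !all(is.finite(d$dM))) {
    stop("`N` and `dM` must be finite numbers.", call. = FALSE)
  }
  if (nrow(d) < 3) {
    stop("Fitting requires at least 3 records.", call. = FALSE)
  }
  if (length(unique(d$N)) < 2) {
    stop("Non-identifiable: all records share a single `N` value.",
         call. = FALSE)
  }
  if (is.null(init)) {
    init <- list(beta = max(d$dM), gamma = 1 / stats::median(d$N)^1.5)
  } else {
    init <- as.list(init)
    if (!all(c("beta", "gamma") %in% names(init)) ||
        !all(vapply(init[c("beta", "gamma")], is.finite, logical(1)))) {
      stop("`init` must supply finite `beta` and `gamma`.", call. = FALSE)
    }
  }
  w <- if ("sigma" %in% names(d)) 1 / d$sigma^2 else rep(1, nrow(d))
  fit <- minpack.lm::nlsLM(
    dM ~ (beta - gamma * N^1.5) / (1 + gamma * N^1.5),
    data = d,
    start = init[c("beta", "gamma")],
    lower = c(beta = -Inf, gamma = 0),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!fit$convInfo$isConv) {
    stop("Dose-response fit did not converge: ",
         fit$convInfo$stopMessage, call. = FALSE)
  }
  covm <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 2, 2, dimnames = list(c("beta", "gamma"),
                                           c("beta", "gamma")))
  })
  structure(
    list(
      params = stats::coef(fit),
      residual_sum_sq = sum(stats::residuals(fit)^2),
      covariance = covm,
      n_points = nrow(d),
      data = d,
      fit = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit>\n")
  cat(sprintf("  beta = %g, gamma = %g (n = %d, RSS = %g)\n",
              x$params["beta"], x$params["gamma"], x$n_points,
              x$residual_sum_sq))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) object$params

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a dose-response fit
#'
#' @param x A [fit_dose_response()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.dose_response_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' One-row summary of a dose-response fit
#'
#' @param x A [fit_dose_response()] result.
#' @param ... Unused.
#' @return A one-row tibble with `sigma` (residual standard deviation),
#'   `rss`, `df.residual`, `nobs`, `converged`.
#' @export
glance.dose_response_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    sigma = sm$sigma,
    rss = x$residual_sum_sq,
    df.residual = stats::df.residual(x$fit),
    nobs = x$n_points,
    converged = x$fit$convInfo$isConv
  )
}

#' Augment dose-response data with fitted values and residuals
#'
#' @param x A [fit_dose_response()] result.
#' @param ... Unused.
#' @return The fitted data with `.fitted` and `.resid` columns appended.
#' @export
augment.dose_response_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = dm_theory(.data$N, x$params["beta"], x$params["gamma"]),
    .resid = .data$dM - .data$.fitted
  )
}
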