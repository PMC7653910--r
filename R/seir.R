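#' Approximate SEIR compartments as functions of the susceptible fraction
#'
#' Under the approximation that the third time derivative of the recovered
#' fraction vanishes, the SEIR susceptible equation reduces to the same
#' Bernoulli differential equation as in the SIR model, but with the rates
#' scaled by the stretch factor `alpha = sigma/(sigma + gamma)`. This yields
#' closed forms along a trajectory:
#' `e = 1 - i0 - alpha*s0 + (alpha - 1) * (s - log(s/s0)/r0)` and
#' `i = i0 - alpha*(s - s0) + (alpha/r0) * log(s/s0)`,
#' while `r = log(s0/s)/r0` remains exact. With `alpha = 1` (SIR limit) the
#' expressions collapse to the exact SIR relations. These are approximations:
#' against the ODE reference they are accurate to a few times 1e-2 at moderate
#' `r0` (see the methods vignette for calibrated error bounds).
#'
#' @inheritParams sir_recovered
#' @return Numeric vector of fractions.
#' @seealso [sir_infectious()], [seir_time()], [seir_peak()]
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, sigma = 0.5, i0 = 1e-4)
#' seir_exposed(p$s0, p)   # e0
#' seir_infectious(0.6, p)
#' @export
seir_exposed <- function(s, params) {
  stopifnot(inherits(params, "epi_params"))
  s <- .check_s(s, params$s0)
  with(params,
       1 - i0 - alpha * s0 + (alpha - 1) * (s - log(s / s0) / r0))
}

#' @rdname seir_exposed
#' @export
seir_infectious <- function(s, params) {
  stopifnot(inherits(params, "epi_params"))
  s <- .check_s(s, params$s0)
  with(params, i0 - alpha * (s - s0) + (alpha / r0) * log(s / s0))
}

#' @rdname seir_exposed
#' @export
seir_recovered <- function(s, params) {
  # exact, identical to the SIR relation
  sir_recovered(s, params)
}

#' Time at which the susceptible fraction reaches a given value (SEIR)
#'
#' Approximate semi-analytic time integral for the SEIR model,
#' `t - t0 = integral_{s0}^{s} ds' / (s' * (beta(-i0 + alpha(s' - s0)) - alpha gamma log(s'/s0)))`.
#' With `alpha = 1` the integrand is identical to the exact SIR one
#' ([sir_time()]).
#'
#' @inheritParams sir_time
#' @return A tibble with columns `s`, `time`, `abs_error`.
#' @export
seir_time <- function(s, params, quad = quad_control()) {
  stopifnot(inherits(params, "epi_params"))
  .semi_time_vec(s, params, alpha = params$alpha, quad = quad)
}

#' Scaled time to the infectious peak (SEIR)
#'
#' The semi-analytic infectious curve is maximised at `s = 1/r0`; the peak time
#' `delta_t` is the time integral evaluated there. Because `alpha * gamma`
#' factors out of the dimensionless form of that integral, the scaled peak time
#' `alpha * gamma * delta_t` depends (approximately) only on `r0` and `i0` —
#' the approximately universal timescale of the SEIR family. Note the
#' semi-analytic `delta_t` inherits the error of the underlying approximation
#' (tens of percent at `alpha ~ 0.5`); peak times measured on the integrated
#' ODE ([integrate_seir()] + [find_peak()]) are the quantitative reference.
#'
#' @inheritParams sir_peak
#' @return A one-row tibble: `delta_t`, `peak_value`, `scaled_delta_t`.
#' @export
seir_peak <- function(params, quad = quad_control(), drop_i0 = FALSE) {
  stopifnot(inherits(params, "epi_params"))
  .semi_peak(params, alpha = params$alpha, infectious_fun = seir_infectious,
             quad = quad, drop_i0 = drop_i0)
}

#' Early-time closed-form SEIR solution
#'
#' Linearising the logarithm in the time integrand gives the SEIR analogue of
#' the early-time SIR solution, with growth rate `lambda` from
#' [seir_growth_rate()]:
#' `s(t) = lambda / (alpha gamma (r0 - 1/s0) + (gamma r0 i0 / s0) exp(lambda t))`,
#' `i(t) = i0 + alpha (s0 - 1/r0) - (1 - 1/(s0 r0)) alpha s(t)`.
#'
#' @inheritParams sir_early
#' @return A tibble with columns `time`, `s`, `i`.
#' @export
seir_early <- function(times, params) {
  stopifnot(inherits(params, "epi_params"), all(times >= 0))
  lam <- seir_growth_rate(params)
  s <- with(params,
            lam / (alpha * gamma * (r0 - 1 / s0) +
                     (gamma * r0 * i0 / s0) * exp(lam * times)))
  i <- with(params,
            i0 + alpha * (s0 - 1 / r0) - (1 - 1 / (s0 * r0)) * alpha * s)
  tibble(time = times, s = s, i = i)
}

#' Growth-rate relations for the SEIR model
#'
#' The approximate semi-analytic solution implies the early growth rate
#' `lambda = gamma r0 (i0 + alpha s0) - alpha gamma` (for `s0 ~ 1`, `i0 << 1`
#' this is `alpha gamma (r0 - 1)`: SEIR epidemics grow `1/alpha` times slower
#' than SIR ones at the same `gamma`). Inverting gives
#' `r0 = (alpha + lambda d_inf) / (i0 + alpha s0)`
#' (`r0_from_growth_approx()`). The exact linearised-system relation is
#' `r0 = (1 + lambda d_inc)(1 + lambda d_inf)` (`r0_from_growth_exact()`),
#' which accounts for the convolution of the exponentially distributed
#' incubation and infectious stages; the approximate relation lacks the term
#' `lambda^2 d_inc d_inf` and so corresponds to an exponentially distributed
#' generation time of mean `d_inc + d_inf`. `seir_growth_rate_exact()` solves
#' the exact relation for `lambda` given the parameters.
#'
#' @inheritParams sir_recovered
#' @return `seir_growth_rate()`, `seir_growth_rate_exact()`: rate per day.
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, sigma = 0.5, i0 = 1e-4)
#' seir_growth_rate(p)                        # ~ 0.25 /d
#' seir_growth_rate_exact(p)                  # ~ 0.207 /d
#' r0_from_growth_exact(0.25, 2, 2)           # (1.5)(1.5) = 2.25
#' @export
seir_growth_rate <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  with(params, gamma * r0 * (i0 + alpha * s0) - alpha * gamma)
}

#' @rdname seir_growth_rate
#' @export
seir_growth_rate_exact <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  d <- params$d_inf; dp <- params$d_inc
  if (dp == 0) return(params$gamma * (params$r0 - 1))
  # positive root of lambda^2 d dp + lambda (d + dp) + 1 - r0 = 0
  (-(d + dp) + sqrt((d + dp)^2 + 4 * d * dp * (params$r0 - 1))) / (2 * d * dp)
}

#' @rdname seir_growth_rate
#' @param lambda Growth rate, per day.
#' @param d_inf Infectious period, days (> 0).
#' @param d_inc Incubation period, days (>= 0; 0 gives the SIR relation).
#' @param s0,i0 Initial susceptible/infectious fractions (defaults 1 and 0
#'   give the small-seed limit `r0 ~ 1 + lambda (d_inf + d_inc)`).
#' @return `r0_from_growth_approx()`, `r0_from_growth_exact()`: dimensionless
#'   basic reproduction number.
#' @export
r0_from_growth_approx <- function(lambda, d_inf, d_inc = 0, s0 = 1, i0 = 0) {
  if (any(d_inf <= 0) || any(d_inc < 0)) {
    abort("`d_inf` must be > 0 and `d_inc` >= 0.",
          class = "seirshape_error_parameter")
  }
  alpha <- d_inf / (d_inf + d_inc)
  (alpha + lambda * d_inf) / (i0 + alpha * s0)
}

#' @rdname seir_growth_rate
#' @export
r0_from_growth_exact <- function(lambda, d_inf, d_inc = 0) {
  if (any(d_inf <= 0) || any(d_inc < 0)) {
    abort("`d_inf` must be > 0 and `d_inc` >= 0.",
          class = "seirshape_error_parameter")
  }
  (1 + lambda * d_inc) * (1 + lambda * d_inf)
}
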