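#' Exact SIR compartments as functions of the susceptible fraction
#'
#' The SIR system can be integrated once analytically: along a trajectory the
#' recovered fraction is `r = (gamma/beta) log(s0/s) = log(s0/s)/r0`, and the
#' infectious fraction follows from conservation,
#' `i = s0 + i0 - s + log(s/s0)/r0`. Both are exact; only the map from `s`
#' back to time ([sir_time()]) needs a numerical quadrature.
#'
#' @param s Susceptible fraction(s), in `(0, s0]`.
#' @param params An [epi_params()] object (the exposed stage is ignored; these
#'   are the SIR relations).
#' @return Numeric vector of fractions.
#' @seealso [sir_time()], [sir_peak()], [seir_infectious()]
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4)
#' sir_recovered(p$s0, p)      # 0
#' sir_infectious(1 / p$r0, p) # the peak infectious fraction
#' @export
sir_recovered <- function(s, params) {
  stopifnot(inherits(params, "epi_params"))
  s <- .check_s(s, params$s0)
  log(params$s0 / s) / params$r0
}

#' @rdname sir_recovered
#' @export
sir_infectious <- function(s, params) {
  stopifnot(inherits(params, "epi_params"))
  s <- .check_s(s, params$s0)
  params$s0 + params$i0 - s + log(s / params$s0) / params$r0
}

#' Time at which the susceptible fraction reaches a given value (SIR)
#'
#' Evaluates the exact semi-analytic time integral
#' `t - t0 = integral_{s0}^{s} ds' / (s' * (beta (s' - s0 - i0) - gamma log(s'/s0)))`.
#' The integral has no closed form and is computed by adaptive quadrature; the
#' result is exact for the SIR model up to quadrature error.
#'
#' @inheritParams sir_recovered
#' @param quad A [quad_control()] object.
#' @return A tibble with columns `s`, `time` (days since t0) and `abs_error`
#'   (quadrature error estimate, days).
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4)
#' sir_time(c(0.9, 0.5), p)
#' @export
sir_time <- function(s, params, quad = quad_control()) {
  stopifnot(inherits(params, "epi_params"))
  .semi_time_vec(s, params, alpha = 1, quad = quad)
}

#' Time and height of the infectious peak (SIR)
#'
#' The infectious curve peaks where `di/dt = 0`, i.e. at `s = 1/r0`. The peak
#' time is the semi-analytic time integral evaluated there, and `gamma *
#' delta_t` — the peak time in units of the infectious period — depends only on
#' `r0` and `i0`. If `r0 * s0 <= 1` there is no interior peak: the no-peak
#' convention returns `delta_t = 0` with `peak_value = i0`.
#'
#' @inheritParams sir_time
#' @param drop_i0 If `TRUE`, evaluate the idealised `i0`-free integrand instead
#'   (the printed dimensionless form). That integrand is logarithmically
#'   divergent at `s = s0`, so it is regularised by starting the integral at
#'   `s0 * (1 - i0)`; it exists only to demonstrate that `gamma` factors out of
#'   the peak time and should not be used for quantitative work.
#' @return A one-row tibble: `delta_t` (days), `peak_value`,
#'   `scaled_delta_t` (`alpha*gamma*delta_t`; `alpha = 1` for SIR, so this is
#'   `gamma*delta_t`).
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4)
#' sir_peak(p)
#' @export
sir_peak <- function(params, quad = quad_control(), drop_i0 = FALSE) {
  stopifnot(inherits(params, "epi_params"))
  .semi_peak(params, alpha = 1, infectious_fun = sir_infectious,
             quad = quad, drop_i0 = drop_i0)
}

# Shared peak-time engine for the alpha-carrying family.
.semi_peak <- function(params, alpha, infectious_fun, quad, drop_i0) {
  if (params$r0 * params$s0 <= 1) {
    return(tibble(delta_t = 0, peak_value = params$i0, scaled_delta_t = 0))
  }
  s_pk <- 1 / params$r0
  if (drop_i0) {
    p0 <- params
    p0$i0 <- 0
    s_start <- params$s0 * (1 - params$i0)
    u0 <- log(params$s0 / s_start)
    u1 <- log(params$s0 / s_pk)
    res <- integrate(function(u) 1 / .semi_denom(u, p0, alpha),
                     u0, u1, rel.tol = quad$rel_tol, abs.tol = quad$abs_tol,
                     subdivisions = quad$subdivisions)
    dt <- res$value
  } else {
    dt <- .semi_time_scalar(s_pk, params, alpha, quad)$value
  }
  tibble(delta_t = dt,
         peak_value = infectious_fun(s_pk, params),
         scaled_delta_t = alpha * params$gamma * dt)
}

#' Early-time closed-form SIR solution
#'
#' During early exponential growth the logarithm in the time integrand can be
#' linearised, which makes the integral elementary and yields a logistic-type
#' closed form for `s(t)` with growth rate `lambda = gamma (r0 - 1)`
#' (see [sir_growth_rate()]). Valid while the outbreak is still small.
#'
#' @param times Numeric vector of times (days since t0).
#' @inheritParams sir_recovered
#' @return A tibble with columns `time`, `s`, `i`.
#' @export
sir_early <- function(times, params) {
  stopifnot(inherits(params, "epi_params"), all(times >= 0))
  lam <- sir_growth_rate(params)
  s <- with(params,
            lam / (gamma * (r0 - 1 / s0) +
                     (gamma * r0 * i0 / s0) * exp(lam * times)))
  i <- with(params, 1 - 1 / r0 - (1 - 1 / (s0 * r0)) * s)
  tibble(time = times, s = s, i = i)
}

#' Epidemic growth rate and its inverse relation (SIR)
#'
#' In the SIR model the early epidemic growth rate is
#' `lambda = gamma (r0 - 1)`; inverting gives the classic estimator
#' `r0 = 1 + lambda * d_inf` from an observed growth rate and the infectious
#' period.
#'
#' @inheritParams sir_recovered
#' @return `sir_growth_rate()`: growth rate per day.
#' @examples
#' sir_growth_rate(epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4)) # 0.5
#' r0_from_growth(0.5, d_inf = 2)                              # 2
#' @export
sir_growth_rate <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  with(params, gamma * (r0 - 1))
}

#' @rdname sir_growth_rate
#' @param lambda Growth rate, per day.
#' @param d_inf Infectious period, days.
#' @return `r0_from_growth()`: dimensionless basic reproduction number.
#' @export
r0_from_growth <- function(lambda, d_inf) {
  if (any(d_inf <= 0)) abort("`d_inf` must be > 0.",
                             class = "seirshape_error_parameter")
  1 + lambda * d_inf
}

#' Ultimate susceptible fraction (final size)
#'
#' Solves the final-size relation `1 - s = log(s0/s)/r0` (recovered fraction at
#' `e = i = 0`) for the limiting susceptible fraction `s_inf`. The relation is
#' the same for the SIR and SEIR systems because `r = log(s0/s)/r0` holds
#' exactly in both; `s_inf` does not depend on the incubation period.
#'
#' @inheritParams sir_recovered
#' @return The limiting susceptible fraction, in `(0, min(1/r0, s0))`.
#' @examples
#' final_size(epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4))
#' @export
final_size <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  f <- function(s) 1 - s - log(params$s0 / s) / params$r0
  # f(s0 e^{-r0}) = -s0 e^{-r0} < 0 and f(s0) = i0 + e0 > 0 bracket the root
  uniroot(f, c(params$s0 * exp(-params$r0), params$s0), tol = 1e-14)$root
}
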