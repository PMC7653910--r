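#' Control settings for the semi-analytic time quadrature
#'
#' The time-of-susceptible integral is evaluated with adaptive quadrature
#' ([stats::integrate()], QUADPACK) after the substitution `u = log(s0/s)`,
#' which tames the boundary layer of width ~ `i0` next to the starting point
#' when the seed is tiny.
#'
#' @param rel_tol,abs_tol Requested relative/absolute error (days).
#' @param subdivisions Maximum number of adaptive subintervals.
#' @return A list of class `quad_control`.
#' @export
quad_control <- function(rel_tol = 1e-10, abs_tol = 1e-10,
                         subdivisions = 2000L) {
  if (rel_tol <= 0 || abs_tol <= 0) {
    abort("quadrature tolerances must be positive.",
          class = "seirshape_error_parameter")
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 subdivisions = as.integer(subdivisions)),
            class = "quad_control")
}

# Validate 0 < s <= s0 (with a relative slack for round-off).
.check_s <- function(s, s0) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s > s0 * (1 + 1e-12))) {
    abort("`s` must lie in (0, s0].", class = "seirshape_error_domain")
  }
  pmin(s, s0)
}

# Scaled infectious fraction entering the time integrand: for the general
# (alpha-carrying) solution, ds/dt = -beta * s * i_semi(s), so the integrand
# of t(s) is 1/(s * beta * i_semi) and beta*i_semi is the denominator below.
# In u = log(s0/s): denom(u) = beta*i0 + alpha*beta*s0*(1 - exp(-u)) - alpha*gamma*u.
.semi_denom <- function(u, params, alpha) {
  with(params, beta * i0 + alpha * beta * s0 * (1 - exp(-u)) - alpha * gamma * u)
}

# t(s) - t0 for one s, by adaptive quadrature in u. Returns value + error
# estimate. `alpha` is passed explicitly so the SIR functions can force 1.
.semi_time_scalar <- function(s, params, alpha, quad) {
  u_max <- log(params$s0 / s)
  if (u_max == 0) return(list(value = 0, abs_error = 0))
  # the integrand blows up where the semi-analytic I reaches 0 (final size)
  if (.semi_denom(u_max, params, alpha) <= 0) {
    abort("`s` lies at or beyond the semi-analytic final size; t(s) diverges.",
          class = "seirshape_error_domain")
  }
  res <- integrate(function(u) 1 / .semi_denom(u, params, alpha),
                   lower = 0, upper = u_max,
                   rel.tol = quad$rel_tol, abs.tol = quad$abs_tol,
                   subdivisions = quad$subdivisions, stop.on.error = FALSE)
  ok <- res$message == "OK" ||
    res$abs.error <= max(quad$abs_tol, quad$rel_tol * abs(res$value)) * 10
  if (!ok) {
    abort(sprintf(
      "time quadrature did not reach the requested error (achieved %.3e): %s",
      res$abs.error, res$message), class = "seirshape_error_quadrature")
  }
  list(value = res$value, abs_error = res$abs.error)
}

.semi_time_vec <- function(s, params, alpha, quad) {
  s <- .check_s(s, params$s0)
  out <- lapply(s, .semi_time_scalar, params = params, alpha = alpha, quad = quad)
  tibble(s = s,
         time = vapply(out, `[[`, numeric(1), "value"),
         abs_error = vapply(out, `[[`, numeric(1), "abs_error"))
}
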