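#' Stretch factor relating SEIR to SIR time scales
#'
#' The SEIR epidemic curves are, to a good approximation, SIR curves stretched
#' in time by `1/alpha` where `alpha = sigma / (sigma + gamma)`. Equivalently
#' `1/alpha = 1 + d_inc/d_inf`, the ratio of the generation time to the
#' infectious period. The SIR model is the special case `alpha = 1`, reached
#' when the incubation period vanishes (`sigma = Inf`).
#'
#' @param sigma Incubation rate, per day (`1/sigma` is the incubation period).
#'   Use `Inf` for the SIR limit.
#' @param gamma Recovery rate, per day (`1/gamma` is the infectious period).
#' @return Dimensionless stretch factor in `(0, 1]`. Vectorised over both
#'   arguments.
#' @examples
#' stretch_factor(0.5, 0.5)       # 0.5
#' stretch_factor(Inf, 0.25)      # SIR limit: 1
#' stretch_factor(1 / 3, 1 / 4)   # d_inc = 3 d, d_inf = 4 d: 4/7
#' @export
stretch_factor <- function(sigma, gamma) {
  if (any(!is.numeric(sigma)) || any(is.na(sigma)) || any(sigma <= 0)) {
    abort("`sigma` must be a positive rate (or Inf for the SIR limit).",
          class = "seirshape_error_parameter")
  }
  if (any(!is.numeric(gamma)) || any(is.na(gamma)) ||
      any(gamma <= 0) || any(!is.finite(gamma))) {
    abort("`gamma` must be a positive, finite rate.",
          class = "seirshape_error_parameter")
  }
  ifelse(is.infinite(sigma), 1, sigma / (sigma + gamma))
}

#' Define one SIR/SEIR model instance
#'
#' Bundles the rates and initial fractions that define a single compartmental
#' epidemic: basic reproduction number `r0`, recovery rate `gamma` (infectious
#' period `1/gamma`), incubation rate `sigma` (`Inf` selects the SIR limit,
#' i.e. no exposed stage), and the initial infectious and exposed fractions.
#' The initial recovered fraction is always zero, so `s0 = 1 - i0 - e0`. The
#' transmission rate is `beta = r0 * gamma`.
#'
#' A strictly positive seed `i0 > 0` is required: a zero seed never ignites an
#' epidemic, and the semi-analytic time integrals need `i0 > 0` to stay regular
#' at the starting point.
#'
#' @param r0 Basic reproduction number (dimensionless, > 0).
#' @param gamma Recovery rate, per day.
#' @param sigma Incubation rate, per day; `Inf` (default) gives the SIR model.
#' @param i0 Initial infectious fraction, in (0, 1).
#' @param e0 Initial exposed fraction, in \[0, 1); must be 0 in the SIR limit.
#' @return An object of class `epi_params`: a list with fields `r0`, `gamma`,
#'   `sigma`, `i0`, `e0`, `s0`, `beta`, `alpha`, `d_inf`, `d_inc`.
#' @examples
#' epi_params(r0 = 2, gamma = 0.5, sigma = 0.5, i0 = 1e-4)
#' epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4) # SIR
#' @export
epi_params <- function(r0, gamma, sigma = Inf, i0 = 1e-4, e0 = 0) {
  chk_scalar <- function(x, name, allow_inf = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x))) {
      abort(paste0("`", name, "` must be a single finite number."),
            class = "seirshape_error_parameter")
    }
  }
  chk_scalar(r0, "r0"); chk_scalar(gamma, "gamma")
  chk_scalar(sigma, "sigma", allow_inf = TRUE)
  chk_scalar(i0, "i0"); chk_scalar(e0, "e0")
  if (r0 <= 0) abort("`r0` must be > 0.", class = "seirshape_error_parameter")
  if (gamma <= 0) abort("`gamma` must be > 0.", class = "seirshape_error_parameter")
  if (sigma <= 0) abort("`sigma` must be > 0 (use Inf for the SIR limit).",
                        class = "seirshape_error_parameter")
  if (i0 <= 0 || i0 >= 1) abort("`i0` must lie in (0, 1): a zero seed never ignites.",
                                class = "seirshape_error_parameter")
  if (e0 < 0 || e0 >= 1) abort("`e0` must lie in [0, 1).",
                               class = "seirshape_error_parameter")
  if (i0 + e0 >= 1) abort("`i0` + `e0` must be < 1.",
                          class = "seirshape_error_parameter")
  if (is.infinite(sigma) && e0 > 0) {
    abort("`e0` must be 0 in the SIR limit (`sigma = Inf`).",
          class = "seirshape_error_parameter")
  }
  structure(
    list(
      r0 = r0, gamma = gamma, sigma = sigma, i0 = i0, e0 = e0,
      s0 = 1 - i0 - e0, beta = r0 * gamma,
      alpha = stretch_factor(sigma, gamma),
      d_inf = 1 / gamma,
      d_inc = if (is.infinite(sigma)) 0 else 1 / sigma
    ),
    class = "epi_params"
  )
}

#' @export
print.epi_params <- function(x, ...) {
  kind <- if (is_sir(x)) "SIR" else "SEIR"
  cat(sprintf("<epi_params: %s>\n", kind))
  cat(sprintf("  r0 = %g, gamma = %g /d (d_inf = %g d)", x$r0, x$gamma, x$d_inf))
  if (!is_sir(x)) cat(sprintf(", sigma = %g /d (d_inc = %g d)", x$sigma, x$d_inc))
  cat(sprintf("\n  alpha = %.6g, beta = %g /d\n", x$alpha, x$beta))
  cat(sprintf("  s0 = %g, e0 = %g, i0 = %g, r0_init = 0\n", x$s0, x$e0, x$i0))
  invisible(x)
}

#' Is this parameter set the SIR special case?
#'
#' @param params An [epi_params()] object.
#' @return `TRUE` if the incubation period is zero (`sigma = Inf`).
#' @export
is_sir <- function(params) {
  stopifnot(inherits(params, "epi_params"))
  is.infinite(params$sigma)
}

#' @method tidy epi_params
#' @export
tidy.epi_params <- function(x, ...) {
  tibble(
    term = c("r0", "gamma", "sigma", "i0", "e0", "s0", "beta", "alpha",
             "d_inf", "d_inc"),
    value = c(x$r0, x$gamma, x$sigma, x$i0, x$e0, x$s0, x$beta, x$alpha,
              x$d_inf, x$d_inc)
  )
}
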