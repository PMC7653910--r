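#' Control settings for the reference ODE integrator
#'
#' @param rel_tol,abs_tol Local error tolerances passed to the solver; both
#'   must lie in (0, 1e-3]. The defaults make the integration the high-accuracy
#'   reference against which the semi-analytic formulas are judged.
#' @param t_max Integration horizon, days.
#' @param dense_output_step Output grid spacing, days. A fixed step gives
#'   reproducible grids across parameter draws for peak refinement and curve
#'   comparison.
#' @param stop_after_decline If `TRUE` (default), stop early once the
#'   infectious fraction has fallen below `i0/10` — which can only happen after
#'   the peak — so that slow epidemics (small `alpha * gamma`) do not waste
#'   effort on the long tail while fast ones are not truncated.
#' @return A list of class `integrator_control`.
#' @export
integrator_control <- function(rel_tol = 1e-10, abs_tol = 1e-12,
                               t_max = 1000, dense_output_step = 0.05,
                               stop_after_decline = TRUE) {
  if (rel_tol <= 0 || rel_tol > 1e-3 || abs_tol <= 0 || abs_tol > 1e-3) {
    abort("integrator tolerances must lie in (0, 1e-3].",
          class = "seirshape_error_parameter")
  }
  if (t_max <= 0 || dense_output_step <= 0 || dense_output_step >= t_max) {
    abort("`t_max` and `dense_output_step` must be positive with step < t_max.",
          class = "seirshape_error_parameter")
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, t_max = t_max,
                 dense_output_step = dense_output_step,
                 stop_after_decline = stop_after_decline),
            class = "integrator_control")
}

.sir_rhs <- function(t, y, p) {
  list(c(-p$beta * y[3] * y[1],
         0,
         p$beta * y[3] * y[1] - p$gamma * y[3],
         p$gamma * y[3]))
}

.seir_rhs <- function(t, y, p) {
  inf <- p$beta * y[3] * y[1]
  list(c(-inf,
         inf - p$sigma * y[2],
         p$sigma * y[2] - p$gamma * y[3],
         p$gamma * y[3]))
}

.new_trajectory <- function(df, params) {
  out <- as_tibble(df)
  class(out) <- c("epi_trajectory", class(out))
  attr(out, "params") <- params
  out
}

.integrate_core <- function(params, control, times = NULL) {
  rhs <- if (is_sir(params)) .sir_rhs else .seir_rhs
  y0 <- c(s = params$s0, e = params$e0, i = params$i0, r = 0)
  stop_early <- is.null(times) && isTRUE(control$stop_after_decline)
  if (is.null(times)) {
    times <- seq(0, control$t_max, by = control$dense_output_step)
  }
  sol <- if (stop_early) {
    deSolve::lsodar(y0, times, rhs, parms = params,
                    rtol = control$rel_tol, atol = control$abs_tol,
                    rootfunc = function(t, y, p) y[3] - p$i0 / 10)
  } else {
    deSolve::lsoda(y0, times, rhs, parms = params,
                   rtol = control$rel_tol, atol = control$abs_tol)
  }
  istate <- attr(sol, "istate")[1]
  if (is.null(istate) || istate < 0) {
    abort(sprintf("ODE integration failed (istate = %s).", istate),
          class = "seirshape_error_numeric")
  }
  df <- as.data.frame(sol)
  names(df) <- c("time", "s", "e", "i", "r")
  cons <- max(abs(df$s + df$e + df$i + df$r - 1))
  if (cons > 1e-9) {
    abort(sprintf("conservation violated by %.3e (> 1e-9); tighten tolerances.",
                  cons), class = "seirshape_error_numeric")
  }
  .new_trajectory(df, params)
}

#' Integrate the SIR / SEIR equations numerically
#'
#' High-accuracy reference integration of the compartmental equations
#' (`ds/dt = -beta i s`, `de/dt = beta i s - sigma e`,
#' `di/dt = sigma e - gamma i` — the `e` equation absent and
#' `di/dt = beta i s - gamma i` in the SIR limit, `dr/dt = gamma i`) with
#' `deSolve::lsoda`/`lsodar` at tight tolerances. Output is sampled on a fixed
#' dense grid; when `stop_after_decline` is set the run ends once the
#' infectious fraction has dropped below a tenth of its seed (after the peak).
#'
#' @param params An [epi_params()] object ([integrate_sir()] requires the SIR
#'   limit `sigma = Inf`; [integrate_seir()] requires finite `sigma`).
#' @param control An [integrator_control()] object.
#' @return An `epi_trajectory`: a tibble with columns `time, s, e, i, r`
#'   (the `e` column is identically zero for SIR) and the parameters attached
#'   as an attribute. Conservation `s + e + i + r = 1` holds within 1e-9 at
#'   every output point.
#' @examples
#' p <- epi_params(r0 = 2, gamma = 0.5, i0 = 1e-4)
#' traj <- integrate_sir(p)
#' find_peak(traj)
#' @export
integrate_sir <- function(params, control = integrator_control()) {
  stopifnot(inherits(params, "epi_params"))
  if (!is_sir(params)) {
    abort("`params` has a finite incubation rate; use integrate_seir().",
          class = "seirshape_error_parameter")
  }
  .integrate_core(params, control)
}

#' @rdname integrate_sir
#' @export
integrate_seir <- function(params, control = integrator_control()) {
  stopifnot(inherits(params, "epi_params"))
  if (is_sir(params)) {
    abort("`params` is the SIR limit; use integrate_sir().",
          class = "seirshape_error_parameter")
  }
  .integrate_core(params, control)
}

# Integrate at user-specified output times (no early stopping); used when
# pairing the ODE reference with semi-analytic time points.
.integrate_at <- function(params, times, control = integrator_control()) {
  stopifnot(all(diff(times) > 0), times[1] >= 0)
  ts <- if (times[1] > 0) c(0, times) else times
  out <- .integrate_core(params, control = control, times = ts)
  if (times[1] > 0) out <- out[-1, ]
  out
}

#' Locate a compartment's peak on an integrated trajectory
#'
#' Finds the discrete argmax of the requested compartment and refines it with a
#' three-point quadratic (parabolic) interpolation through the neighbouring
#' grid points, so the peak time is accurate to far better than the output
#' step. The scaled peak time uses the trajectory's own `alpha` and `gamma`.
#'
#' @param traj An `epi_trajectory` (from [integrate_sir()],
#'   [integrate_seir()] or [semianalytic_trajectory()]).
#' @param compartment One of `"s"`, `"e"`, `"i"`, `"r"`.
#' @param params Parameters used for the scaled time; defaults to those
#'   attached to `traj`.
#' @return A one-row tibble: `compartment`, `delta_t` (days from t0 to the
#'   maximum), `peak_value`, `scaled_delta_t` (`alpha * gamma * delta_t`).
#' @export
find_peak <- function(traj, compartment = "i", params = NULL) {
  compartment <- arg_match(compartment, c("s", "e", "i", "r"))
  params <- params %||% attr(traj, "params")
  if (is.null(params)) {
    abort("no parameters attached to `traj`; supply `params`.",
          class = "seirshape_error_parameter")
  }
  y <- traj[[compartment]]
  t <- traj[["time"]]
  k <- which.max(y)
  n <- length(y)
  if (k == n && n > 1) {
    abort("maximum attained at the end of the trajectory; run longer (t_max).",
          class = "seirshape_error_truncation")
  }
  if (k == 1) {
    dt <- 0
    pk <- y[1]
  } else {
    # vertex of the parabola through (t_{k-1}, y_{k-1}), (t_k, y_k), (t_{k+1}, y_{k+1})
    fit <- .parabola_vertex(t[(k - 1):(k + 1)], y[(k - 1):(k + 1)])
    dt <- fit$x
    pk <- fit$y
    if (!is.finite(dt) || dt < t[k - 1] || dt > t[k + 1]) {
      dt <- t[k]
      pk <- y[k]
    }
  }
  tibble(compartment = compartment, delta_t = dt, peak_value = pk,
         scaled_delta_t = params$alpha * params$gamma * dt)
}

.parabola_vertex <- function(x, y) {
  # exact vertex of the interpolating quadratic (general, unequal spacing)
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d2 - d1) / (x[3] - x[1])
  if (a == 0) return(list(x = x[2], y = y[2]))
  xv <- (x[1] + x[2]) / 2 - d1 / (2 * a)
  yv <- y[1] + d1 * (xv - x[1]) + a * (xv - x[1]) * (xv - x[2])
  list(x = xv, y = yv)
}
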