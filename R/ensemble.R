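#' Specify a seeded ensemble of SEIR models
#'
#' Defines the random-parameter experiment behind the curve-collapse and
#' peak-time-universality analyses: `n_draws` independent draws of the
#' incubation and infectious *periods* (not the rates), each uniform on its
#' interval — by default `[2, 5]` days, the illustrative range of the
#' reference experiments — combined with one or more values of the basic
#' reproduction number and a fixed seed fraction. The whole downstream
#' pipeline is a pure function of this specification (seed included).
#'
#' @param n_draws Number of period draws (>= 2).
#' @param d_inc_range,d_inf_range Intervals (days) for the incubation and
#'   infectious periods.
#' @param r0 Basic reproduction number; a scalar or a grid of values (each
#'   combined with every draw).
#' @param i0 Initial infectious fraction.
#' @param e0 Initial exposed fraction (default 0).
#' @param seed Integer RNG seed.
#' @return A list of class `ensemble_spec`.
#' @examples
#' spec <- ensemble_spec(n_draws = 10, r0 = 2, i0 = 1e-4, seed = 1)
#' draw_ensemble(spec)
#' @export
ensemble_spec <- function(n_draws = 100L, d_inc_range = c(2, 5),
                          d_inf_range = c(2, 5), r0 = 2, i0 = 1e-4,
                          e0 = 0, seed = 1L) {
  chk_range <- function(x, name) {
    if (length(x) != 2L || any(!is.finite(x)) || any(x <= 0) || x[1] > x[2]) {
      abort(paste0("`", name, "` must be an ordered positive interval."),
            class = "seirshape_error_parameter")
    }
  }
  if (n_draws < 2) abort("`n_draws` must be >= 2.",
                         class = "seirshape_error_parameter")
  chk_range(d_inc_range, "d_inc_range"); chk_range(d_inf_range, "d_inf_range")
  if (any(r0 <= 0)) abort("`r0` must be > 0.", class = "seirshape_error_parameter")
  if (i0 <= 0 || i0 + e0 >= 1 || e0 < 0) {
    abort("`i0` must be > 0 and `i0 + e0` < 1.",
          class = "seirshape_error_parameter")
  }
  structure(list(n_draws = as.integer(n_draws), d_inc_range = d_inc_range,
                 d_inf_range = d_inf_range, r0 = r0, i0 = i0, e0 = e0,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Draw the ensemble parameters
#'
#' Draws `n_draws` pairs of incubation/infectious periods uniformly from the
#' specified intervals under the specification's seed, and crosses them with
#' the `r0` grid. Identical specifications yield identical draws.
#'
#' @param spec An [ensemble_spec()].
#' @return A tibble with one row per (r0, draw): columns `r0`, `draw`,
#'   `d_inc`, `d_inf`, `sigma`, `gamma`, `alpha`, `i0`, `e0`.
#' @export
draw_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  periods <- withr::with_seed(spec$seed, {
    tibble(
      draw = seq_len(spec$n_draws),
      d_inc = runif(spec$n_draws, spec$d_inc_range[1], spec$d_inc_range[2]),
      d_inf = runif(spec$n_draws, spec$d_inf_range[1], spec$d_inf_range[2])
    )
  })
  out <- tidyr::crossing(r0 = spec$r0, periods) |>
    mutate(sigma = 1 / .data$d_inc, gamma = 1 / .data$d_inf,
           alpha = stretch_factor(.data$sigma, .data$gamma),
           i0 = spec$i0, e0 = spec$e0) |>
    arrange(.data$r0, .data$draw)
  out
}

#' Integrate every ensemble member and measure its infectious peak
#'
#' Runs the reference SEIR integration for each row of an ensemble draw table
#' and extracts the infectious peak ([find_peak()]). Draws with no interior
#' peak (`r0 * s0 <= 1`) are recorded with the no-peak convention
#' (`delta_t = 0`, `peak_value = i0`, `peaked = FALSE`).
#'
#' @param draws A tibble from [draw_ensemble()] (columns `r0`, `d_inc`,
#'   `d_inf`, `i0`, `e0`, ...).
#' @param control An [integrator_control()].
#' @return An `ensemble_result` tibble: the draw columns plus `delta_t`,
#'   `gamma_delta_t` (`gamma * delta_t`), `scaled_delta_t`
#'   (`alpha * gamma * delta_t`), `peak_value`, `peaked`. Summarise with
#'   [glance()].
#' @examples
#' ensemble_spec(n_draws = 3, seed = 1) |>
#'   draw_ensemble() |>
#'   run_ensemble()
#' @export
run_ensemble <- function(draws, control = integrator_control()) {
  needed <- c("r0", "d_inc", "d_inf", "i0", "e0")
  if (!all(needed %in% names(draws))) {
    abort(paste("`draws` must contain columns:", paste(needed, collapse = ", ")),
          class = "seirshape_error_parameter")
  }
  res <- purrr::pmap(
    list(draws$r0, draws$d_inc, draws$d_inf, draws$i0, draws$e0),
    function(r0, d_inc, d_inf, i0, e0) {
      p <- epi_params(r0 = r0, gamma = 1 / d_inf, sigma = 1 / d_inc,
                      i0 = i0, e0 = e0)
      if (p$r0 * p$s0 <= 1) {
        return(tibble(delta_t = 0, peak_value = i0, scaled_delta_t = 0,
                      peaked = FALSE))
      }
      pk <- find_peak(integrate_seir(p, control), "i")
      tibble(delta_t = pk$delta_t, peak_value = pk$peak_value,
             scaled_delta_t = pk$scaled_delta_t, peaked = TRUE)
    }
  ) |> bind_rows()
  out <- dplyr::bind_cols(as_tibble(draws), res) |>
    mutate(gamma_delta_t = .data$gamma * .data$delta_t, .before = "scaled_delta_t")
  class(out) <- c("ensemble_result", class(out))
  out
}

#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  cv <- function(v) if (length(v) < 2 || mean(v) == 0) 0 else
    stats::sd(v) / mean(v)
  x |>
    as_tibble() |>
    group_by(.data$r0) |>
    summarise(
      n_draws = n(),
      n_peaked = sum(.data$peaked),
      mean_scaled = mean(.data$scaled_delta_t[.data$peaked]),
      sd_scaled = ifelse(sum(.data$peaked) > 1,
                         stats::sd(.data$scaled_delta_t[.data$peaked]), 0),
      cv_scaled = cv(.data$scaled_delta_t[.data$peaked]),
      mean_unscaled = mean(.data$gamma_delta_t[.data$peaked]),
      sd_unscaled = ifelse(sum(.data$peaked) > 1,
                           stats::sd(.data$gamma_delta_t[.data$peaked]), 0),
      cv_unscaled = cv(.data$gamma_delta_t[.data$peaked]),
      .groups = "drop"
    ) |>
    arrange(.data$r0)
}

#' Scaled peak time as a function of the basic reproduction number
#'
#' For each value of `r0` on the grid, integrates every period draw of the
#' ensemble and summarises the distribution of the scaled peak time
#' `alpha * gamma * delta_t` (and of the unscaled `gamma * delta_t` for
#' contrast). If the scaling is (approximately) universal, the coefficient of
#' variation of the scaled version is far below that of the unscaled one, and
#' the mean traces a single curve in `r0` for each `i0`.
#'
#' @param spec An [ensemble_spec()] whose `r0` field is the grid of values.
#' @param control An [integrator_control()].
#' @return A tibble of class `peak_curve`, one row per `r0`, with the
#'   [glance()] summary columns; the per-draw results are kept in attribute
#'   `"draws"`.
#' @examples
#' \donttest{
#' curve <- peak_scaling_curve(ensemble_spec(n_draws = 20, r0 = c(2, 4, 7)))
#' }
#' @export
peak_scaling_curve <- function(spec, control = integrator_control()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  res <- run_ensemble(draw_ensemble(spec), control)
  out <- glance(res)
  attr(out, "draws") <- res
  attr(out, "spec") <- spec
  class(out) <- c("peak_curve", class(out))
  out
}

#' Integrate every ensemble member, keeping the full trajectories
#'
#' @inheritParams run_ensemble
#' @return A list of `epi_trajectory` objects, one per row of `draws`.
#' @export
ensemble_trajectories <- function(draws, control = integrator_control()) {
  purrr::pmap(
    list(draws$r0, draws$d_inc, draws$d_inf, draws$i0, draws$e0),
    function(r0, d_inc, d_inf, i0, e0) {
      p <- epi_params(r0 = r0, gamma = 1 / d_inf, sigma = 1 / d_inc,
                      i0 = i0, e0 = e0)
      integrate_seir(p, control)
    }
  )
}

#' Rescale a trajectory's time axis to dimensionless form
#'
#' Multiplies the time column by `alpha * gamma`, the operation under which
#' the SEIR curve family (approximately) collapses onto a single master
#' curve. Compartment values are untouched.
#'
#' @param traj An `epi_trajectory`.
#' @param params Parameters providing `alpha` and `gamma`; defaults to those
#'   attached to `traj`.
#' @return The trajectory with `time` in units of `1/(alpha * gamma)`.
#' @export
rescale_time <- function(traj, params = NULL) {
  params <- params %||% attr(traj, "params")
  if (is.null(params)) {
    abort("no parameters attached to `traj`; supply `params`.",
          class = "seirshape_error_parameter")
  }
  traj$time <- traj$time * params$alpha * params$gamma
  traj
}

#' Sup-norm spread of a family of curves
#'
#' Resamples each trajectory's compartment onto a common `n_grid`-point time
#' grid spanning the intersection of their supports (linear interpolation) and
#' returns the maximum over the grid of the spread (max minus min across
#' trajectories) — the sup-norm width of the curve bundle. Identical curves
#' give 0; applying this to time-rescaled trajectories quantifies the curve
#' collapse.
#'
#' @param trajs A list of (rescaled or raw) `epi_trajectory` objects, length
#'   >= 2.
#' @param compartment One of `"s"`, `"e"`, `"i"`, `"r"`.
#' @param n_grid Number of common grid points.
#' @return A single non-negative number.
#' @export
collapse_metric <- function(trajs, compartment = "i", n_grid = 2000L) {
  compartment <- arg_match(compartment, c("s", "e", "i", "r"))
  if (!is.list(trajs) || length(trajs) < 2) {
    abort("`trajs` must be a list of at least two trajectories.",
          class = "seirshape_error_parameter")
  }
  t_lo <- max(vapply(trajs, function(x) min(x$time), numeric(1)))
  t_hi <- min(vapply(trajs, function(x) max(x$time), numeric(1)))
  if (t_hi <= t_lo) {
    abort("trajectory time supports do not overlap.",
          class = "seirshape_error_domain")
  }
  grid <- seq(t_lo, t_hi, length.out = n_grid)
  vals <- vapply(trajs,
                 function(x) approx(x$time, x[[compartment]], xout = grid)$y,
                 numeric(n_grid))
  max(apply(vals, 1, max) - apply(vals, 1, min))
}
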