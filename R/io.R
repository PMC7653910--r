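#' Write a trajectory to CSV
#'
#' Header `t,S,E,I,R`, one row per grid point, `E` identically zero for SIR;
#' comma separators, `.` decimals, LF line endings.
#'
#' @param traj An `epi_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(
    tibble(t = traj$time, S = traj$s, E = traj$e, I = traj$i, R = traj$r),
    path)
  invisible(path)
}

#' Write ensemble results to CSV (and optionally a JSON summary)
#'
#' The CSV has header `r0,draw,d_inc,d_inf,alpha,delta_t,scaled_delta_t,i_peak`;
#' the JSON summary carries the per-`r0` mean/sd/cv of the scaled and unscaled
#' peak times.
#'
#' @param result An `ensemble_result` from [run_ensemble()].
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_ensemble <- function(result, csv_path, json_path = NULL) {
  readr::write_csv(
    tibble(r0 = result$r0, draw = result$draw, d_inc = result$d_inc,
           d_inf = result$d_inf, alpha = result$alpha,
           delta_t = result$delta_t, scaled_delta_t = result$scaled_delta_t,
           i_peak = result$peak_value),
    csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(glance(result), json_path, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}
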