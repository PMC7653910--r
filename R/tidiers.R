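#' Tidy a trajectory into long format
#'
#' @param x An `epi_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `compartment`, `fraction`.
#' @method tidy epi_trajectory
#' @export
tidy.epi_trajectory <- function(x, ...) {
  x |>
    as_tibble() |>
    tidyr::pivot_longer(c("s", "e", "i", "r"),
                        names_to = "compartment", values_to = "fraction") |>
    mutate(compartment = factor(.data$compartment, levels = c("s", "e", "i", "r")))
}

#' One-row summary of a trajectory
#'
#' @param x An `epi_trajectory` with parameters attached.
#' @param ... Unused.
#' @return A tibble with the infectious peak (`delta_t`, `peak_value`,
#'   `scaled_delta_t`), the final susceptible fraction reached (`s_end`), the
#'   time span (`t_end`) and the worst conservation defect
#'   (`max_conservation_err`).
#' @method glance epi_trajectory
#' @export
glance.epi_trajectory <- function(x, ...) {
  pk <- find_peak(x, "i")
  tibble(
    delta_t = pk$delta_t,
    peak_value = pk$peak_value,
    scaled_delta_t = pk$scaled_delta_t,
    s_end = x$s[nrow(x)],
    t_end = x$time[nrow(x)],
    max_conservation_err = max(abs(x$s + x$e + x$i + x$r - 1))
  )
}
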