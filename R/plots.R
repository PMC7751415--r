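#' Plot concentration snapshots
#'
#' Raster maps of the voxel concentration at a few snapshot times
#' (default: four evenly spaced including start and end).
#'
#' @param object An `mnp_trajectory`.
#' @param times Snapshot times to show (nearest snapshots used).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mnp_trajectory <- function(object, times = NULL, ...) {
  if (is.null(times)) {
    times <- object$times[unique(round(seq(1, length(object$times),
                                           length.out = 4)))]
  }
  df <- tidy(object, times = times)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 100, y = .data$y * 100,
                                   fill = .data$concentration)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~round(.data$time), labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  fill = "concentration") +
    ggplot2::theme_minimal()
}

#' Scree plot of a POD basis
#'
#' Singular-value spectrum with the cumulative captured energy and the
#' retained rank.
#'
#' @param object A `pod_basis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pod_basis <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$energy,
                                   fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_energy)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_energy)) +
    ggplot2::geom_hline(yintercept = object$energy_target,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "grey75")) +
    ggplot2::labs(x = "POD mode", y = "energy fraction",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' Step plot of a current schedule
#'
#' @param object A [current_schedule()].
#' @param ... Unused.
#' @return A ggplot with one line per coil.
#' @export
autoplot.current_schedule <- function(object, ...) {
  df <- tidy(object)
  # repeat the last level so the final step is drawn
  df2 <- dplyr::bind_rows(
    df,
    dplyr::mutate(dplyr::filter(df, .data$segment == max(.data$segment)),
                  t_start = .data$t_end)
  )
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$t_start, y = .data$current,
                                    colour = factor(.data$coil))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "current (A)", colour = "coil") +
    ggplot2::theme_minimal()
}

#' Plot an optimized solution
#'
#' Target-voxel concentration over time under the best currents, with the
#' optimized schedule shown as steps on a secondary panel-free overlay is
#' avoided: this returns the concentration curve; use
#' `autoplot(solution$schedule)` for the currents.
#'
#' @param object An `oc_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oc_solution <- function(object, ...) {
  met <- summarize_concentration(object$trajectory,
                                 targets = object$targets)
  ggplot2::ggplot(met, ggplot2::aes(x = .data$time, y = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "target voxel concentration") +
    ggplot2::theme_minimal()
}
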