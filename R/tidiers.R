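#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a concentration trajectory
#'
#' @param x An `mnp_trajectory`.
#' @param times Optional subset of snapshot times to keep (nearest
#'   snapshots are used).
#' @param ... Unused.
#' @return Long tibble: `time` (s), voxel indices `i`, `j`, `k`
#'   (0-based), center coordinates `x`, `y` (m), `concentration`.
#' @export
tidy.mnp_trajectory <- function(x, times = NULL, ...) {
  keep <- if (is.null(times)) {
    seq_along(x$times)
  } else {
    unique(vapply(times, function(tt) which.min(abs(x$times - tt)),
                  integer(1)))
  }
  vc <- voxel_centers(x$grid)
  times_vec <- x$times   # avoid the data mask: vc has an `x` column
  states <- x$states
  purrr::map_dfr(keep, function(s) {
    dplyr::mutate(vc, time = times_vec[s],
                  concentration = states[, s], .before = 1)
  })
}

#' @rdname tidy.mnp_trajectory
#' @export
glance.mnp_trajectory <- function(x, ...) {
  mass <- colSums(x$states)
  tibble::tibble(
    n_states = nrow(x$states), n_snapshots = length(x$times),
    t_f = max(x$times), mass = x$mass0,
    mass_drift = max(abs(mass - x$mass0)) / x$mass0,
    min_concentration = min(x$states)
  )
}

#' Tidy a POD basis
#'
#' @param x A `pod_basis`.
#' @param ... Unused.
#' @return Tibble with one row per singular value: `mode`, `sigma`,
#'   `energy` (this mode's squared-singular-value fraction),
#'   `cumulative_energy`, `retained`.
#' @export
tidy.pod_basis <- function(x, ...) {
  s2 <- x$singular_values^2
  tibble::tibble(
    mode = seq_along(x$singular_values),
    sigma = x$singular_values,
    energy = s2 / sum(s2),
    cumulative_energy = cumsum(s2) / sum(s2),
    retained = seq_along(s2) <= x$rank
  )
}

#' @rdname tidy.pod_basis
#' @export
glance.pod_basis <- function(x, ...) {
  tibble::tibble(rank = x$rank, d = length(x$singular_values),
                 energy = x$energy, energy_target = x$energy_target)
}

#' Tidy a current schedule
#'
#' @param x A [current_schedule()].
#' @param ... Unused.
#' @return Long tibble: `segment`, `t_start`, `t_end` (s), `coil`,
#'   `current` (A).
#' @export
tidy.current_schedule <- function(x, ...) {
  seg_len <- x$t_f / x$n_t
  tidyr::expand_grid(segment = seq_len(x$n_t),
                     coil = seq_len(x$n_u)) |>
    dplyr::mutate(
      t_start = (.data$segment - 1) * seg_len,
      t_end = .data$segment * seg_len,
      current = purrr::map2_dbl(.data$coil, .data$segment,
                                function(i, k) x$u[i, k])
    ) |>
    dplyr::select("segment", "t_start", "t_end", "coil", "current")
}

#' Tidy a DMS solution
#'
#' @param x A `dms_solution`.
#' @param ... Unused.
#' @return The optimized schedule in long form (see
#'   [tidy.current_schedule()]).
#' @export
tidy.dms_solution <- function(x, ...) tidy(x$schedule)

#' @rdname tidy.dms_solution
#' @export
glance.dms_solution <- function(x, ...) {
  tibble::tibble(cost = x$cost, guess_cost = x$guess_cost,
                 improvement = x$guess_cost - x$cost,
                 status = x$status, feasible = x$feasible,
                 outer_iterations = nrow(x$history))
}

#' Tidy an alternating POD-DMS solution
#'
#' @param x An `oc_solution`.
#' @param ... Unused.
#' @return The best schedule in long form (see
#'   [tidy.current_schedule()]).
#' @export
tidy.oc_solution <- function(x, ...) tidy(x$schedule)

#' @rdname tidy.oc_solution
#' @export
glance.oc_solution <- function(x, ...) {
  final <- summarize_concentration(
    x$trajectory$states[, ncol(x$trajectory$states)],
    grid = x$grid, targets = x$targets)
  tibble::tibble(
    cost = x$cost, guess_cost = x$guess_cost,
    improvement = x$guess_cost - x$cost,
    final_target_concentration = final$target,
    pod_rank = if (is.null(x$pod)) NA_integer_ else x$pod$rank,
    outer_iterations = nrow(x$history),
    max_current = max(abs(x$schedule$u))
  )
}
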