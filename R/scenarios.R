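#' Gaussian initial particle distribution
#'
#' Isotropic Gaussian blob sampled at voxel centers and renormalized to
#' `total_mass`; strictly nonnegative. A `sigma` at or below `dx / 10`
#' degenerates to a single-voxel spike at the nearest voxel center.
#'
#' @param grid A [grid_2d()].
#' @param center Blob center `c(x, y)` (m), inside the sample.
#' @param sigma Standard deviation (m), > 0.
#' @param total_mass Total dimensionless mass, default 1.
#' @return Concentration vector of length `grid$n`.
#' @export
make_initial_blob <- function(grid, center, sigma, total_mass = 1) {
  stopifnot(sigma > 0, total_mass > 0)
  lo <- grid$origin
  hi <- grid$origin + c(grid$nx, grid$ny) * grid$dx
  if (center[1] < lo[1] || center[1] > hi[1] ||
      center[2] < lo[2] || center[2] > hi[2]) {
    stop("blob center outside the sample", call. = FALSE)
  }
  cc <- numeric(grid$n)
  if (sigma <= grid$dx / 10) {
    cc[voxel_at(grid, center[1], center[2])] <- total_mass
    return(cc)
  }
  vc <- voxel_centers(grid)
  cc <- exp(-((vc$x - center[1])^2 + (vc$y - center[2])^2) /
              (2 * sigma^2))
  cc * (total_mass / sum(cc))
}

#' Default scenario configuration
#'
#' The nominal steering study: an 8 cm x 8 cm sample on a 31 x 31 voxel
#' grid (961 states), four reference coils, 400 nm magnetite particles
#' (Ms = 4.78e5 A/m) in a blood-viscosity stationary fluid, current bound
#' 13 A, horizon 10000 s in 4 zero-order-hold segments (2500 s each), POD
#' energy threshold 0.98. The initial blob (sigma 5 mm) sits near the
#' bottom wall at (0, -3 cm) and the target voxel at (0 cm, 1 cm).
#'
#' @param scale `"paper"` (31 x 31 grid, n_t = 4, full horizon) or `"ci"`
#'   (15 x 15 grid, n_t = 2, halved horizon) for fast runs.
#' @return List of class `scenario_config`. Fields are plain scalars and
#'   vectors (SI units throughout) so the configuration round-trips
#'   losslessly through the YAML file written by [write_scenario()]:
#'   sample/grid geometry, coil geometry, particle and fluid parameters,
#'   control horizon and bounds, reduction settings, blob and target
#'   coordinates, scheme flags.
#' @seealso [steering_scenario()], [holding_scenario()], [run_scenario()]
#' @export
default_setup <- function(scale = c("paper", "ci")) {
  scale <- match.arg(scale)
  ci <- scale == "ci"
  structure(list(
    # sample & grid
    side_x = 0.08, side_y = 0.08,
    nx = if (ci) 15L else 31L, ny = if (ci) 15L else 31L,
    # coils (reference four-coil ring; see reference_coils())
    coil_standoff = 0.08, coil_radius = 0.08, coil_turns = 6000L,
    # particle
    core_diameter = 400e-9, saturation_magnetization = 4.78e5,
    temperature = 300, hydrodynamic_radius = 200e-9,
    # fluid: diffusion NA -> Stokes-Einstein default
    viscosity = 3e-3, diffusion = NA_real_, flow = c(0, 0),
    # control
    u_max = 13, t_f = if (ci) 5000 else 10000, n_t = if (ci) 2L else 4L,
    # reduction / outer loop (rank NA -> energy criterion)
    energy_target = 0.98, rank = NA_integer_, n_opt = 2L,
    # initial distribution and target (coordinates in m)
    blob_center = c(0, -0.03), blob_sigma = 0.005, blob_mass = 1,
    target = c(0, 0.01),
    guess_fraction = 0.5,
    # numerics
    scheme = "central", n_snapshots = 101L, seed = 1L
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %dx%d grid, t_f = %g s, n_t = %d, u_max = %g A\n",
    x$nx, x$ny, x$t_f, x$n_t, x$u_max))
  cat(sprintf("  blob (%.3g, %.3g) m sigma %.3g m -> target (%.3g, %.3g) m, flow (%.3g, %.3g) m/s\n",
              x$blob_center[1], x$blob_center[2], x$blob_sigma,
              x$target[1], x$target[2], x$flow[1], x$flow[2]))
  invisible(x)
}

#' Packaged steering scenario (stationary fluid)
#'
#' A concentrated blob near the bottom wall is steered to a target voxel
#' in a stationary fluid. `target = c(0, 0.01)` by default; the
#' alternative target `c(-0.01, 0.015)` mirrors the second packaged case.
#'
#' @inheritParams default_setup
#' @param target Target coordinates `c(x, y)` (m).
#' @return A `scenario_config`.
#' @export
steering_scenario <- function(scale = c("paper", "ci"),
                              target = c(0, 0.01)) {
  cfg <- default_setup(scale)
  cfg$target <- target
  cfg
}

#' Packaged holding / moving scenario (uniform flow)
#'
#' A uniform background flow carries the blob away unless countered; with
#' the default `target = NULL` the target voxel is the center of the
#' initial distribution (holding against the stream).
#'
#' @inheritParams default_setup
#' @param flow Uniform flow `c(vx, vy)` (m/s), default vertical 3 um/s.
#' @param target Target coordinates (m) or `NULL` for the blob center.
#' @return A `scenario_config`.
#' @export
holding_scenario <- function(scale = c("paper", "ci"),
                             flow = c(0, 3e-6), target = NULL) {
  cfg <- default_setup(scale)
  cfg$flow <- as.numeric(flow)
  cfg$target <- if (is.null(target)) cfg$blob_center else target
  cfg
}

#' Instantiate model components from a configuration
#'
#' @param config A `scenario_config`.
#' @return List with `grid`, `coils`, `particle`, `fluid`, `x0`
#'   (initial concentration), `targets` (1-based voxel positions),
#'   `q_diag`.
#' @export
scenario_components <- function(config) {
  grid <- grid_2d(config$nx, config$ny, config$side_x, config$side_y)
  coils <- reference_coils(standoff = config$coil_standoff,
                           radius = config$coil_radius,
                           turns = config$coil_turns)
  particle <- particle_spec(
    core_diameter = config$core_diameter,
    saturation_magnetization = config$saturation_magnetization,
    temperature = config$temperature,
    hydrodynamic_radius = config$hydrodynamic_radius
  )
  fluid <- fluid_spec(
    viscosity = config$viscosity,
    diffusion = if (is.na(config$diffusion)) NULL else config$diffusion,
    flow = config$flow, particle = particle
  )
  x0 <- make_initial_blob(grid, config$blob_center, config$blob_sigma,
                          config$blob_mass)
  targets <- voxel_at(grid, config$target[1], config$target[2])
  list(grid = grid, coils = coils, particle = particle, fluid = fluid,
       x0 = x0, targets = targets,
       q_diag = build_cost(grid, targets))
}

#' Write / read a scenario configuration file
#'
#' The configuration is stored as a human-readable YAML key-value file
#' (SI units); `read_scenario(write_scenario(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config A `scenario_config`.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns the `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_setup()
  int_fields <- c("nx", "ny", "coil_turns", "n_t", "rank", "n_opt",
                  "n_snapshots", "seed")
  for (nm in names(cfg)) {
    if (!nm %in% names(raw)) {
      stop(sprintf("missing configuration key `%s`", nm), call. = FALSE)
    }
    val <- raw[[nm]]
    cfg[[nm]] <- if (nm %in% int_fields) {
      if (is.null(val) || all(is.na(val))) NA_integer_ else as.integer(val)
    } else if (nm == "scheme") {
      as.character(val)
    } else {
      as.numeric(val)
    }
  }
  class(cfg) <- "scenario_config"
  cfg
}

#' Run a scenario end to end
#'
#' Builds all model components from the configuration and runs the
#' alternating POD-DMS optimization ([alternating_pod_dms()]); with no
#' coil current allowed (`u_max = 0`) or `n_opt = 0` it degenerates to a
#' pure full-order simulation under the (zero) guess. When `out_dir` is
#' given, writes `trajectory.tsv`, `schedule.tsv`, `metrics.tsv`,
#' `history.tsv`, `config.yaml`, and `run.log` there.
#'
#' @param config A `scenario_config`.
#' @param out_dir Optional output directory (created if needed).
#' @param control A [dms_control()].
#' @return List of class `scenario_result`: `solution` (an
#'   `oc_solution`, or `NULL` for a pure simulation), `trajectory`,
#'   `metrics` (per-snapshot summary tibble), `config`, `components`.
#' @export
run_scenario <- function(config, out_dir = NULL,
                         control = dms_control()) {
  set.seed(config$seed)   # pipeline is deterministic; fixed for hygiene
  cmp <- scenario_components(config)
  simulate_only <- config$u_max <= 0 || config$n_opt < 1
  if (simulate_only) {
    sched <- current_schedule(matrix(0, nrow(cmp$coils), config$n_t),
                              config$t_f)
    traj <- integrate_transport(cmp$x0, sched, cmp$grid, cmp$coils,
                                cmp$particle, cmp$fluid,
                                n_snapshots = config$n_snapshots,
                                scheme = config$scheme)
    sol <- NULL
    best_sched <- sched
  } else {
    sol <- alternating_pod_dms(
      cmp$x0, cmp$grid, cmp$coils, cmp$particle, cmp$fluid,
      targets = cmp$targets, q_diag = cmp$q_diag,
      t_f = config$t_f, n_t = config$n_t, u_max = config$u_max,
      guess_fraction = config$guess_fraction,
      n_opt = config$n_opt, energy_target = config$energy_target,
      rank = if (is.na(config$rank)) NULL else config$rank,
      n_snapshots = config$n_snapshots, scheme = config$scheme,
      control = control
    )
    traj <- sol$trajectory
    best_sched <- sol$schedule
  }
  metrics <- summarize_concentration(traj, targets = cmp$targets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
    write_schedule(best_sched, file.path(out_dir, "schedule.tsv"))
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sol)) {
      utils::write.table(sol$history, file.path(out_dir, "history.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_scenario(config, file.path(out_dir, "config.yaml"))
    log_lines <- c(
      sprintf("grid: %d x %d (%d states)", config$nx, config$ny,
              cmp$grid$n),
      sprintf("mode: %s",
              if (simulate_only) "simulation" else "optimization"),
      if (!is.null(sol)) sprintf("cost: %.8g (guess %.8g)", sol$cost,
                                 sol$guess_cost),
      sprintf("final target concentration: %.8g",
              metrics$target[nrow(metrics)]),
      sprintf("mass drift: %.3g",
              abs(metrics$mass[nrow(metrics)] - metrics$mass[1]) /
                metrics$mass[1])
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  structure(list(solution = sol, trajectory = traj, metrics = metrics,
                 config = config, components = cmp),
            class = "scenario_result")
}
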