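#' Define a set of circular electromagnet coils
#'
#' Each coil is an infinitely thin circular filament with `turns` windings,
#' described by its center, the unit vector of its symmetry axis, and its
#' radius. A `coil_set` is a tibble with one row per coil, so the usual
#' dplyr verbs apply.
#'
#' @param x,y,z Coil center coordinates (m). `z` defaults to 0 (coils
#'   coplanar with the sample).
#' @param axis_x,axis_y,axis_z Components of the coil axis; normalized to a
#'   unit vector, which must be possible (non-zero length).
#' @param radius Coil radius a (m), > 0.
#' @param turns Number of windings N, a positive integer.
#' @return A tibble of class `coil_set` with columns `x, y, z, axis_x,
#'   axis_y, axis_z, radius, turns`.
#' @seealso [reference_coils()] for the packaged four-coil setup.
#' @examples
#' coil_set(x = c(-0.1, 0.1), y = 0, axis_x = c(1, -1), axis_y = 0,
#'          radius = 0.05, turns = 100)
#' @export
coil_set <- function(x, y, z = 0, axis_x, axis_y, axis_z = 0,
                     radius, turns) {
  tb <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    axis_x = as.numeric(axis_x), axis_y = as.numeric(axis_y),
    axis_z = as.numeric(axis_z),
    radius = as.numeric(radius), turns = as.integer(turns)
  )
  nrm <- sqrt(tb$axis_x^2 + tb$axis_y^2 + tb$axis_z^2)
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop("coil axis must have non-zero length", call. = FALSE)
  }
  tb$axis_x <- tb$axis_x / nrm
  tb$axis_y <- tb$axis_y / nrm
  tb$axis_z <- tb$axis_z / nrm
  if (any(tb$radius <= 0)) stop("coil radius must be > 0", call. = FALSE)
  if (any(tb$turns < 1)) stop("coil turns must be >= 1", call. = FALSE)
  class(tb) <- c("coil_set", class(tb))
  tb
}

#' Reference four-coil steering setup
#'
#' Four identical coils placed symmetrically on the +/- x and +/- y axes
#' around the sample, axes pointing at the sample center, coplanar with the
#' sample. The geometry (radius 0.08 m, 6000 turns, centers `standoff`
#' = 0.08 m from the origin) is calibrated so that a saturated 400 nm
#' magnetite particle at the maximum current of 13 A drifts at a few um/s
#' across an 8 cm dish, i.e. travels on the order of centimeters over a
#' 10^4 s horizon. See the methods vignette for the calibration argument.
#'
#' @param standoff Distance from sample center to each coil center (m).
#' @param radius Coil radius (m).
#' @param turns Windings per coil.
#' @return A `coil_set` with 4 rows, ordered +x, -x, +y, -y.
#' @export
reference_coils <- function(standoff = 0.08, radius = 0.08, turns = 6000) {
  coil_set(
    x = c(standoff, -standoff, 0, 0),
    y = c(0, 0, standoff, -standoff),
    axis_x = c(-1, 1, 0, 0),
    axis_y = c(0, 0, -1, 1),
    radius = radius, turns = turns
  )
}

#' Magnetic nanoparticle specification
#'
#' Physical parameters of a single-domain superparamagnetic particle. The
#' magnetic core volume is derived from the core diameter as pi d^3 / 6.
#' Defaults are the 400 nm magnetite particles used in the packaged
#' scenarios (saturation magnetization 4.78e5 A/m); temperature defaults
#' to 300 K and the hydrodynamic radius to the core radius.
#'
#' @param core_diameter Magnetic core diameter d (m).
#' @param saturation_magnetization Ms (A/m).
#' @param temperature T (K).
#' @param hydrodynamic_radius R_p (m), used in the Stokes drag 6 pi eta R_p.
#' @return List of class `particle_spec` with fields `core_diameter`,
#'   `core_volume`, `hydrodynamic_radius`, `saturation_magnetization`,
#'   `temperature`.
#' @export
particle_spec <- function(core_diameter = 400e-9,
                          saturation_magnetization = 4.78e5,
                          temperature = 300,
                          hydrodynamic_radius = core_diameter / 2) {
  stopifnot(core_diameter > 0, saturation_magnetization > 0,
            temperature > 0, hydrodynamic_radius > 0)
  structure(
    list(
      core_diameter = core_diameter,
      core_volume = pi * core_diameter^3 / 6,
      hydrodynamic_radius = hydrodynamic_radius,
      saturation_magnetization = saturation_magnetization,
      temperature = temperature
    ),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat("<particle_spec>\n")
  cat(sprintf("  core diameter      : %.3g m\n", x$core_diameter))
  cat(sprintf("  core volume        : %.4g m^3\n", x$core_volume))
  cat(sprintf("  hydrodynamic radius: %.3g m\n", x$hydrodynamic_radius))
  cat(sprintf("  Ms                 : %.4g A/m\n", x$saturation_magnetization))
  cat(sprintf("  temperature        : %g K\n", x$temperature))
  invisible(x)
}

#' Carrier fluid specification
#'
#' @param viscosity Dynamic viscosity eta (Pa s). Default 3e-3 (blood-like).
#' @param diffusion Particle diffusion coefficient D (m^2/s). `NULL` (the
#'   default) selects the Stokes-Einstein value kB T / (6 pi eta R_p) for
#'   the given particle.
#' @param flow Background fluid velocity: either a length-2 numeric
#'   `c(vx, vy)` (uniform flow, m/s) or a function `f(x, y)` returning a
#'   2-column matrix of velocities at arbitrary points.
#' @param particle `particle_spec` used for the Stokes-Einstein default.
#' @return List of class `fluid_spec` with fields `viscosity`, `diffusion`,
#'   `flow`.
#' @export
fluid_spec <- function(viscosity = 3e-3, diffusion = NULL,
                       flow = c(0, 0), particle = particle_spec()) {
  stopifnot(viscosity > 0)
  if (is.null(diffusion)) {
    diffusion <- .kB * particle$temperature /
      (6 * pi * viscosity * particle$hydrodynamic_radius)
  }
  stopifnot(diffusion >= 0)
  if (is.numeric(flow)) {
    stopifnot(length(flow) == 2, all(is.finite(flow)))
  } else if (!is.function(flow)) {
    stop("`flow` must be a length-2 numeric or a function", call. = FALSE)
  }
  structure(list(viscosity = viscosity, diffusion = diffusion, flow = flow),
            class = "fluid_spec")
}

#' Uniform background flow field
#'
#' Convenience constructor for the uniform flows of the packaged scenarios,
#' e.g. `make_uniform_flow(0, 3e-6)` for a vertical 3 um/s stream.
#'
#' @param vx,vy Flow components (m/s), finite scalars.
#' @return Length-2 named numeric vector `c(vx, vy)`.
#' @export
make_uniform_flow <- function(vx, vy) {
  stopifnot(is.finite(vx), is.finite(vy))
  c(vx = vx, vy = vy)
}
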