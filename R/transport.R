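#' Zero-order-hold current schedule
#'
#' Piecewise-constant coil currents: column `k` of `u` is held over the
#' k-th of `n_t` equal segments of the horizon `[0, t_f]`.
#'
#' @param u n_u x n_t numeric matrix of current levels (A); a plain vector
#'   is taken as a single segment.
#' @param t_f Horizon length (s), > 0.
#' @return List of class `current_schedule` with fields `u`, `t_f`, `n_t`,
#'   `n_u`.
#' @export
current_schedule <- function(u, t_f) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 1)
  stopifnot(t_f > 0, all(is.finite(u)))
  structure(list(u = u, t_f = t_f, n_t = ncol(u), n_u = nrow(u)),
            class = "current_schedule")
}

#' @export
print.current_schedule <- function(x, ...) {
  cat(sprintf("<current_schedule> %d coil(s), %d segment(s) of %g s\n",
              x$n_u, x$n_t, x$t_f / x$n_t))
  print(round(x$u, 4))
  invisible(x)
}

# index of the active segment at time t (right-open segments)
schedule_segment <- function(schedule, t) {
  pmin(floor(t / (schedule$t_f / schedule$n_t)) + 1L, schedule$n_t)
}

#' Precompute unit-current face fields
#'
#' Caches, for every coil, the field and Jacobian per unit current at the
#' midpoints of all interior voxel faces. The field is linear in the
#' currents, so any current vector's face field is a weighted sum of these
#' maps; only the (nonlinear) force evaluation remains per call. Build one
#' cache per (grid, coils) pair and pass it to [drift_field()] /
#' [assemble_operator()] callers for a large speedup.
#'
#' @param grid A [grid_2d()].
#' @param coils A [coil_set()].
#' @return Opaque list of class `field_cache`.
#' @export
make_field_cache <- function(grid, coils) {
  faces <- grid_faces(grid)
  px <- cbind(faces$x$px, faces$x$py)
  py <- cbind(faces$y$px, faces$y$py)
  per_coil <- lapply(seq_len(nrow(coils)), function(ci) {
    fx <- coil_field(coils[ci, ], 1, px)
    fy <- coil_field(coils[ci, ], 1, py)
    list(Hx = fx$H, Jx = fx$jacobian, Hy = fy$H, Jy = fy$jacobian)
  })
  structure(list(per_coil = per_coil, faces = faces,
                 n_coils = nrow(coils),
                 n_fx = length(faces$x$px), n_fy = length(faces$y$px)),
            class = "field_cache")
}

# weighted-sum face field for a current vector
cache_field <- function(cache, currents) {
  stopifnot(length(currents) == cache$n_coils)
  nfx <- cache$n_fx
  nfy <- cache$n_fy
  Hx <- matrix(0, nfx, 3); Jx <- matrix(0, nfx, 9)
  Hy <- matrix(0, nfy, 3); Jy <- matrix(0, nfy, 9)
  for (ci in seq_along(currents)) {
    uc <- currents[ci]
    if (uc == 0) next
    pc <- cache$per_coil[[ci]]
    Hx <- Hx + uc * pc$Hx; Jx <- Jx + uc * pc$Jx
    Hy <- Hy + uc * pc$Hy; Jy <- Jy + uc * pc$Jy
  }
  list(x = structure(list(H = Hx, jacobian = Jx), class = "field_sample"),
       y = structure(list(H = Hy, jacobian = Jy), class = "field_sample"))
}

#' Total drift velocity on voxel faces
#'
#' Evaluates the magnetic drift `F_m / zeta` at every interior face
#' midpoint for the given currents (the field superposes linearly in the
#' currents; the force is nonlinear through `g(|H|) grad(H^2)`), and adds
#' the fluid flow. Only the face-normal component enters the finite-volume
#' flux, so that is what is stored.
#'
#' @inheritParams make_field_cache
#' @param currents Current vector (A), one per coil.
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_spec()].
#' @param cache Optional [make_field_cache()] result for this (grid, coils).
#' @return List of class `drift_field`: `vx` (normal velocity at x-faces,
#'   length `(nx-1) ny`), `vy` (y-faces, length `nx (ny-1)`), `drag`
#'   (zeta, N s/m), `max_speed` (m/s).
#' @export
drift_field <- function(grid, coils, currents, particle, fluid,
                        cache = NULL) {
  if (is.null(cache)) cache <- make_field_cache(grid, coils)
  fs <- cache_field(cache, currents)
  zeta <- 6 * pi * fluid$viscosity * particle$hydrodynamic_radius
  Fx <- magnetic_force(fs$x, particle)
  Fy <- magnetic_force(fs$y, particle)
  faces <- cache$faces
  flow_at <- function(px, py, comp) {
    if (is.function(fluid$flow)) {
      fl <- fluid$flow(px, py)
      fl[, comp]
    } else {
      fluid$flow[comp]
    }
  }
  vx <- Fx[, 1] / zeta + flow_at(faces$x$px, faces$x$py, 1)
  vy <- Fy[, 2] / zeta + flow_at(faces$y$px, faces$y$py, 2)
  if (!all(is.finite(vx)) || !all(is.finite(vy))) {
    stop("non-finite drift velocity", call. = FALSE)
  }
  structure(list(vx = vx, vy = vy, drag = zeta,
                 max_speed = max(abs(c(vx, vy, 0)))),
            class = "drift_field")
}

#' Assemble the transport operator A
#'
#' Finite-volume discretization of the advection-diffusion equation
#' `dc/dt = div(D grad c) - div(v c)` on the voxel grid, in the state-space
#' form `dc/dt = A c`. For each interior face the flux is
#' `-D (c_R - c_L)/dx + v_face (c_L + c_R)/2` (central scheme, matching
#' second-order central differences in the interior) or the first-order
#' upwind variant; each face flux enters the two adjacent voxel balances
#' with opposite signs, and boundary faces carry zero flux
#' (`n . (D grad c - v c) = 0`), so every column of A sums to zero and
#' total mass is conserved exactly.
#'
#' @param grid A [grid_2d()].
#' @param drift A [drift_field()] on the same grid.
#' @param D Diffusion coefficient (m^2/s), >= 0.
#' @param scheme `"central"` (default) or `"upwind"` for the advective
#'   flux. The central scheme can oscillate (and go slightly negative) in
#'   strongly advection-dominated runs; values are deliberately not
#'   clipped, which would break mass conservation.
#' @return Sparse `dgCMatrix` (1/s), n x n with at most 5 nonzeros per row.
#' @export
assemble_operator <- function(grid, drift, D,
                              scheme = c("central", "upwind")) {
  scheme <- match.arg(scheme)
  stopifnot(D >= 0)
  if (!all(is.finite(drift$vx)) || !all(is.finite(drift$vy))) {
    stop("non-finite drift", call. = FALSE)
  }
  faces <- grid_faces(grid)
  if (length(drift$vx) != length(faces$x$left) ||
      length(drift$vy) != length(faces$y$left)) {
    stop("drift field does not match the grid", call. = FALSE)
  }
  dx <- grid$dx
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add_faces <- function(left, right, v) {
    i <- integer(0); j <- integer(0); x <- numeric(0)
    if (D > 0) {
      dcoef <- D / dx^2
      i <- c(left, left, right, right)
      j <- c(left, right, right, left)
      x <- c(rep(-dcoef, length(left)), rep(dcoef, length(left)),
             rep(-dcoef, length(left)), rep(dcoef, length(left)))
    }
    if (scheme == "central") {
      a <- v / (2 * dx)
      i <- c(i, left, left, right, right)
      j <- c(j, left, right, left, right)
      x <- c(x, -a, -a, a, a)
    } else {
      pos <- v >= 0
      a <- v / dx
      # v >= 0: flux v c_L ; v < 0: flux v c_R
      i <- c(i, left[pos], right[pos], left[!pos], right[!pos])
      j <- c(j, left[pos], left[pos], right[!pos], right[!pos])
      x <- c(x, -a[pos], a[pos], -a[!pos], a[!pos])
    }
    list(i = i, j = j, x = x)
  }
  tx <- add_faces(faces$x$left, faces$x$right, drift$vx)
  ty <- add_faces(faces$y$left, faces$y$right, drift$vy)
  Matrix::sparseMatrix(
    i = c(tx$i, ty$i), j = c(tx$j, ty$j), x = c(tx$x, ty$x),
    dims = c(grid$n, grid$n)
  )
}

# stable RK4 sub-step for the linear operator; recomputed per segment
rk4_substep <- function(grid, D, max_speed, safety = 0.4) {
  lim <- Inf
  if (D > 0) lim <- min(lim, grid$dx^2 / (4 * D))
  if (max_speed > 0) lim <- min(lim, grid$dx / max_speed)
  safety * lim
}

# RK4 steps of dc/dt = A c over an interval, fixed n steps
rk4_advance <- function(A, c0, interval, n_steps) {
  h <- interval / n_steps
  cc <- c0
  for (s in seq_len(n_steps)) {
    k1 <- as.numeric(A %*% cc)
    k2 <- as.numeric(A %*% (cc + h / 2 * k1))
    k3 <- as.numeric(A %*% (cc + h / 2 * k2))
    k4 <- as.numeric(A %*% (cc + h * k3))
    cc <- cc + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  cc
}

#' Integrate the concentration field over a current schedule
#'
#' Within each constant-current segment the operator `A(u)` is assembled
#' once and the linear system `dc/dt = A c` is advanced by classical RK4
#' with a fixed sub-step `safety * min(dx^2/(4D), dx/max|v|)`. Snapshots
#' are returned on a uniform time grid including `t = 0` and `t = t_f`.
#'
#' @param c0 Initial concentration vector (length `grid$n`), dimensionless.
#' @param schedule A [current_schedule()] covering `[0, t_f]`.
#' @inheritParams drift_field
#' @param D Diffusion coefficient override (m^2/s); default
#'   `fluid$diffusion`.
#' @param n_snapshots Number of uniform snapshots (>= 2), default 101.
#' @param scheme Advective flux scheme, see [assemble_operator()].
#' @param safety RK4 sub-step safety factor in (0, 1].
#' @return Object of class `mnp_trajectory`: list with `times` (length
#'   n_snapshots), `states` (`grid$n` x n_snapshots matrix; column s is
#'   c(times[s])), `grid`, `schedule`, `mass0`.
#' @export
integrate_transport <- function(c0, schedule, grid, coils, particle, fluid,
                                D = fluid$diffusion, n_snapshots = 101,
                                cache = NULL, scheme = "central",
                                safety = 0.4) {
  stopifnot(length(c0) == grid$n, n_snapshots >= 2)
  if (is.null(cache)) cache <- make_field_cache(grid, coils)
  t_f <- schedule$t_f
  snap_times <- seq(0, t_f, length.out = n_snapshots)
  seg_bounds <- seq(0, t_f, length.out = schedule$n_t + 1)
  # union grid so every RK4 run stays inside one constant-current segment
  knots <- sort(unique(signif(c(snap_times, seg_bounds), 12)))
  states <- matrix(0, grid$n, n_snapshots)
  states[, 1] <- c0
  norm0 <- sqrt(sum(c0^2))
  cc <- c0
  snap_idx <- 2L
  seg_cur <- -1L
  A <- NULL
  dt_seg <- Inf
  for (kn in seq_len(length(knots) - 1)) {
    t0 <- knots[kn]; t1 <- knots[kn + 1]
    seg <- schedule_segment(schedule, t0)
    if (seg != seg_cur) {
      dr <- drift_field(grid, coils, schedule$u[, seg], particle, fluid,
                        cache = cache)
      A <- assemble_operator(grid, dr, D, scheme = scheme)
      dt_seg <- rk4_substep(grid, D, dr$max_speed, safety)
      seg_cur <- seg
    }
    len <- t1 - t0
    n_steps <- if (is.finite(dt_seg)) max(1L, ceiling(len / dt_seg)) else 1L
    cc <- rk4_advance(A, cc, len, n_steps)
    if (!all(is.finite(cc)) || sqrt(sum(cc^2)) > 1e6 * max(norm0, 1e-300)) {
      stop(sprintf(paste0("integration unstable in segment %d ",
                          "(sub-step %.3g s); reduce `safety`"),
                   seg, len / n_steps), call. = FALSE)
    }
    while (snap_idx <= n_snapshots &&
           abs(snap_times[snap_idx] - t1) <= 1e-9 * max(t_f, 1)) {
      states[, snap_idx] <- cc
      snap_idx <- snap_idx + 1L
    }
  }
  structure(list(times = snap_times, states = states, grid = grid,
                 schedule = schedule, mass0 = sum(c0)),
            class = "mnp_trajectory")
}

#' @export
print.mnp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mnp_trajectory> %d states, %d snapshots over [0, %g] s, mass %.6g\n",
    nrow(x$states), length(x$times), max(x$times), x$mass0))
  invisible(x)
}

#' Concentration summary metrics
#'
#' Mass-weighted centroid, RMS spread about it, total mass, and (if target
#' voxels are given) the summed target-voxel concentration -- per snapshot
#' for a trajectory, or for a single concentration vector.
#'
#' @param x An `mnp_trajectory`, or a numeric concentration vector (then
#'   `grid` is required).
#' @param grid A [grid_2d()]; taken from the trajectory if omitted.
#' @param targets Optional integer vector of 1-based voxel positions.
#' @return Tibble with columns `time` (NA for a bare vector), `mass`,
#'   `centroid_x`, `centroid_y`, `spread` (m) and, when `targets` is
#'   given, `target`.
#' @export
summarize_concentration <- function(x, grid = NULL, targets = NULL) {
  if (inherits(x, "mnp_trajectory")) {
    grid <- x$grid
    states <- x$states
    times <- x$times
  } else {
    if (is.null(grid)) stop("`grid` is required for a bare vector",
                            call. = FALSE)
    states <- matrix(as.numeric(x), ncol = 1)
    times <- NA_real_
  }
  vc <- voxel_centers(grid)
  one <- function(cc) {
    mass <- sum(cc)
    if (mass == 0) stop("zero-mass concentration field", call. = FALSE)
    cx <- sum(cc * vc$x) / mass
    cy <- sum(cc * vc$y) / mass
    sp2 <- sum(cc * ((vc$x - cx)^2 + (vc$y - cy)^2)) / mass
    tibble::tibble(mass = mass, centroid_x = cx, centroid_y = cy,
                   spread = sqrt(pmax(sp2, 0)),
                   target = if (is.null(targets)) NA_real_ else
                     sum(cc[targets]))
  }
  out <- purrr::map_dfr(seq_len(ncol(states)),
                        function(s) one(states[, s]))
  out <- tibble::add_column(out, time = times, .before = 1)
  if (is.null(targets)) out$target <- NULL
  out
}
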