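#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the equilibrium magnetization curve of a
#' superparamagnetic moment. Odd, bounded by 1 in magnitude, with
#' `L(0) = 0`. A Taylor branch `x/3 - x^3/45` is used for `|x| < 1e-4`
#' to avoid catastrophic cancellation near the origin.
#'
#' @param x Dimensionless argument, any finite numeric vector.
#' @return `L(x)`, same shape as `x`.
#' @examples
#' langevin(c(0, 1, 1e4))
#' @export
langevin <- function(x) {
  stopifnot(all(is.finite(x)))
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  dim(out) <- dim(x)
  out
}

#' Equilibrium particle magnetization
#'
#' `M(H) = Ms L(mu0 Ms V H / (kB T))` for a single-domain particle of core
#' volume V at temperature T. Monotone nondecreasing in H and bounded by
#' the saturation magnetization Ms.
#'
#' @param H_mag Applied field magnitude(s) (A/m), >= 0.
#' @param particle A [particle_spec()].
#' @return Magnetization (A/m), same shape as `H_mag`.
#' @export
magnetization <- function(H_mag, particle) {
  stopifnot(all(H_mag >= 0))
  Ms <- particle$saturation_magnetization
  arg <- .mu0 * Ms * particle$core_volume * H_mag /
    (.kB * particle$temperature)
  Ms * langevin(arg)
}

#' Moment coefficient g(H)
#'
#' The aligned single-particle moment is written `m = g(H) H` with
#' `g(H) = V M(H) / H` for `H > 0` and the analytic limit
#' `g(0) = mu0 Ms^2 V^2 / (3 kB T)`, making g continuous at 0. Units are
#' m^3 times a dimensionless factor so that `g(H) H` is a moment (A m^2).
#'
#' @inheritParams magnetization
#' @return g(H) (m^3-scaled), same shape as `H_mag`; nonnegative.
#' @export
moment_coefficient <- function(H_mag, particle) {
  stopifnot(all(H_mag >= 0))
  V <- particle$core_volume
  Ms <- particle$saturation_magnetization
  beta <- .mu0 * Ms * V / (.kB * particle$temperature)  # Langevin slope arg
  out <- numeric(length(H_mag))
  # below this field the Langevin argument is < 1e-4: use the linear limit
  hsmall <- H_mag * beta < 1e-4
  out[hsmall] <- V * Ms * beta / 3
  hh <- H_mag[!hsmall]
  out[!hsmall] <- V * Ms * langevin(beta * hh) / hh
  dim(out) <- dim(H_mag)
  out
}

# Normalize points to an n x 3 matrix (z = 0 padded).
as_points3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  if (ncol(points) != 3) stop("points must have 2 or 3 columns",
                              call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Magnetic field and gradient of a circular coil
#'
#' Field H (A/m) and spatial Jacobian dH_i/dx_j of an infinitely thin
#' circular loop with N turns carrying `current`, evaluated from the
#' semi-analytic loop expressions in cylindrical coordinates and
#' transformed to cartesian axes. The expressions involve the complete
#' elliptic integrals K(m) and E(m) in the modulus-squared convention
#' `m = k^2`; the Jacobian is obtained analytically from
#' `dK/dm = -K/(2m) - E/(2m(m-1))` and `dE/dm = (E-K)/(2m)` plus the
#' coordinate transform. Within `1e-9` m of the axis the closed-form
#' on-axis limit is used (the cylindrical form is 0/0 there). Points on
#' the filament itself are singular and rejected.
#'
#' @param coil One coil: a one-row [coil_set()] (or any list with fields
#'   `x, y, z, axis_x, axis_y, axis_z, radius, turns`).
#' @param current Coil current (A).
#' @param points Evaluation points: length-2/3 vector or n x 2/3 matrix (m).
#' @return List of class `field_sample`: `H` (n x 3, A/m), `jacobian`
#'   (n x 9, column `i + 3(j-1)` holding dH_i/dx_j, A/m per m), and
#'   `B = mu0 H` (n x 3, T).
#' @examples
#' co <- coil_set(0, 0, 0, axis_x = 0, axis_y = 0, axis_z = 1,
#'                radius = 0.05, turns = 100)
#' coil_field(co, 1, c(0, 0, 0))$H   # N I / (2 a) = 1000 A/m along z
#' @export
coil_field <- function(coil, current, points) {
  if (inherits(coil, "coil_set") || is.data.frame(coil)) {
    coil <- as.list(coil[1, ])
  }
  stopifnot(is.finite(current))
  pts <- as_points3(points)
  if (!all(is.finite(pts))) stop("non-finite evaluation point",
                                 call. = FALSE)
  n <- nrow(pts)
  if (n == 0) {
    return(structure(list(H = matrix(0, 0, 3), jacobian = matrix(0, 0, 9),
                          B = matrix(0, 0, 3)), class = "field_sample"))
  }
  a <- coil$radius
  NI <- coil$turns * current

  ax <- c(coil$axis_x, coil$axis_y, coil$axis_z)
  ce <- c(coil$x, coil$y, coil$z)
  d <- sweep(pts, 2, ce)
  zc <- as.vector(d %*% ax)                       # axial coordinate
  rvec <- d - outer(zc, ax)                       # radial vector
  rho <- sqrt(rowSums(rvec^2))

  # singularity: distance to the filament circle
  filament_dist <- sqrt((rho - a)^2 + zc^2)
  if (any(filament_dist <= 1e-9)) {
    stop("evaluation point lies on the coil filament", call. = FALSE)
  }

  Hrho <- Hz <- dHr_dr <- dHr_dz <- dHz_dr <- dHz_dz <- Hr_over_r <-
    numeric(n)

  on_axis <- rho < 1e-9
  if (any(on_axis)) {
    z0 <- zc[on_axis]
    s2 <- a^2 + z0^2
    Hz[on_axis] <- NI * a^2 / (2 * s2^1.5)
    dHz_dz[on_axis] <- -3 * NI * a^2 * z0 / (2 * s2^2.5)
    # div H = 0 and axisymmetry: dHr/dr = Hr/r = -dHz/dz / 2 on the axis
    dHr_dr[on_axis] <- -dHz_dz[on_axis] / 2
    Hr_over_r[on_axis] <- dHr_dr[on_axis]
  }

  off <- !on_axis
  if (any(off)) {
    r <- rho[off]
    z <- zc[off]
    C <- NI / (2 * pi)
    al2 <- (a + r)^2 + z^2
    be2 <- (a - r)^2 + z^2
    m <- 4 * a * r / al2
    ke <- pracma::ellipke(m)
    K <- ke$k
    E <- ke$e
    Kp <- E / (2 * m * (1 - m)) - K / (2 * m)     # dK/dm
    Ep <- (E - K) / (2 * m)                       # dE/dm

    P1 <- a^2 - r^2 - z^2
    P2 <- a^2 + r^2 + z^2
    s <- 1 / sqrt(al2)
    G <- K + P1 * E / be2
    Tt <- -K + P2 * E / be2

    al2_r <- 2 * (a + r); al2_z <- 2 * z
    be2_r <- -2 * (a - r); be2_z <- 2 * z
    m_r <- (4 * a * al2 - 4 * a * r * al2_r) / al2^2
    m_z <- -4 * a * r * al2_z / al2^2
    s_r <- -0.5 * s^3 * al2_r
    s_z <- -0.5 * s^3 * al2_z

    G_r <- Kp * m_r + (-2 * r * E + P1 * Ep * m_r) / be2 -
      P1 * E * be2_r / be2^2
    G_z <- Kp * m_z + (-2 * z * E + P1 * Ep * m_z) / be2 -
      P1 * E * be2_z / be2^2
    T_r <- -Kp * m_r + (2 * r * E + P2 * Ep * m_r) / be2 -
      P2 * E * be2_r / be2^2
    T_z <- -Kp * m_z + (2 * z * E + P2 * Ep * m_z) / be2 -
      P2 * E * be2_z / be2^2

    Hz[off] <- C * s * G
    Hrho[off] <- C * z * s * Tt / r
    dHz_dr[off] <- C * (s_r * G + s * G_r)
    dHz_dz[off] <- C * (s_z * G + s * G_z)
    dHr_dr[off] <- C * z * (-s * Tt / r^2 + (s_r * Tt + s * T_r) / r)
    dHr_dz[off] <- C * (s * Tt + z * (s_z * Tt + s * T_z)) / r
    Hr_over_r[off] <- Hrho[off] / r
  }

  # cartesian assembly: H = Hrho rhat + Hz nhat
  rhat <- rvec
  rr <- pmax(rho, 1e-300)
  rhat <- rhat / rr
  rhat[on_axis, ] <- 0                            # Hrho = 0 there anyway
  H <- rhat * Hrho + outer(Hz, ax)

  # J[i,j] = dHi/dxj = dHr_dr rhat_i rhat_j + dHr_dz rhat_i n_j
  #        + (Hr/r)(delta_ij - n_i n_j - rhat_i rhat_j)
  #        + dHz_dr n_i rhat_j + dHz_dz n_i n_j
  jac <- matrix(0, n, 9)
  for (i in 1:3) {
    for (j in 1:3) {
      col <- i + 3 * (j - 1)
      jac[, col] <- dHr_dr * rhat[, i] * rhat[, j] +
        dHr_dz * rhat[, i] * ax[j] +
        Hr_over_r * ((i == j) - ax[i] * ax[j] - rhat[, i] * rhat[, j]) +
        dHz_dr * ax[i] * rhat[, j] +
        dHz_dz * ax[i] * ax[j]
    }
  }

  structure(list(H = H, jacobian = jac, B = .mu0 * H),
            class = "field_sample")
}

#' Superposed field of several coils
#'
#' Sums per-coil fields and Jacobians; the total field is linear in the
#' current vector.
#'
#' @param coils A [coil_set()].
#' @param currents Numeric vector, one current (A) per coil.
#' @param points Evaluation points as in [coil_field()].
#' @return A `field_sample` (see [coil_field()]).
#' @export
total_field <- function(coils, currents, points) {
  if (nrow(coils) != length(currents)) {
    stop("length(currents) must equal the number of coils", call. = FALSE)
  }
  pts <- as_points3(points)
  H <- matrix(0, nrow(pts), 3)
  jac <- matrix(0, nrow(pts), 9)
  for (ci in seq_len(nrow(coils))) {
    if (currents[ci] == 0) next
    fs <- coil_field(coils[ci, ], currents[ci], pts)
    H <- H + fs$H
    jac <- jac + fs$jacobian
  }
  structure(list(H = H, jacobian = jac, B = .mu0 * H),
            class = "field_sample")
}

#' Magnetic force on a particle
#'
#' Magnetic charge model for an aligned point dipole:
#' `F = (m . grad) B = mu0 g(|H|) [dH/dx]^T H`, which for the curl-free
#' coil field equals `(mu0/2) g(|H|) grad(H^2)` -- the force points toward
#' regions of higher field magnitude.
#'
#' @param sample A `field_sample` from [coil_field()] or [total_field()].
#' @param particle A [particle_spec()].
#' @return n x 3 matrix of forces (N).
#' @export
magnetic_force <- function(sample, particle) {
  H <- sample$H
  J <- sample$jacobian
  Hmag <- sqrt(rowSums(H^2))
  g <- moment_coefficient(Hmag, particle)
  Fx <- rowSums(H * J[, 1:3, drop = FALSE])
  Fy <- rowSums(H * J[, 4:6, drop = FALSE])
  Fz <- rowSums(H * J[, 7:9, drop = FALSE])
  .mu0 * g * cbind(Fx, Fy, Fz, deparse.level = 0)
}

#' Inertialess particle drift velocity
#'
#' Balances the magnetic force against Stokes drag `zeta = 6 pi eta R_p`:
#' `v = F / zeta + v_f`. The particle responds instantaneously (inertia
#' neglected).
#'
#' @param force n x d matrix or length-d vector of forces (N).
#' @param viscosity Fluid dynamic viscosity eta (Pa s), > 0.
#' @param R_p Hydrodynamic radius (m), > 0.
#' @param flow Fluid velocity: length-d vector or n x d matrix (m/s).
#' @return Velocity, same shape as `force` (m/s).
#' @export
drift_velocity <- function(force, viscosity, R_p, flow = 0) {
  stopifnot(viscosity > 0, R_p > 0)
  v <- force / (6 * pi * viscosity * R_p)
  if (is.matrix(v) && !is.matrix(flow) && length(flow) > 1) {
    flow <- matrix(flow, nrow(v), length(flow), byrow = TRUE)
  }
  v + flow
}
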