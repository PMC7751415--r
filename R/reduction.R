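#' Proper orthogonal decomposition of a snapshot matrix
#'
#' Computes the SVD `X = U S V^T` of the snapshot matrix (states in
#' columns) and retains the smallest rank `l` whose captured energy
#' `eps(l) = sum_{i<=l} sigma_i^2 / sum_i sigma_i^2` reaches
#' `energy_target`; alternatively a fixed `rank` bypasses the energy
#' criterion. Snapshots are used raw (no mean-centering). Each retained
#' mode is sign-normalized so its largest-magnitude entry is positive,
#' giving a deterministic basis.
#'
#' @param X Snapshot matrix (n_x x n_s, n_s >= 2) or an `mnp_trajectory`
#'   (its `states` are used).
#' @param energy_target Energy threshold eps* in (0, 1], default 0.98.
#' @param rank Optional fixed rank overriding `energy_target`.
#' @return Object of class `pod_basis`: `U` (n_x x l, orthonormal
#'   columns), `singular_values` (all d of them), `rank`, `energy`
#'   (eps at the retained rank), `energy_target`.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' compute_pod(X, energy_target = 0.95)
#' @export
compute_pod <- function(X, energy_target = 0.98, rank = NULL) {
  if (inherits(X, "mnp_trajectory")) X <- X$states
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 snapshots", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite snapshots", call. = FALSE)
  if (all(X == 0)) stop("zero snapshot matrix", call. = FALSE)
  if (is.null(rank) &&
      (energy_target <= 0 || energy_target > 1)) {
    stop("`energy_target` must be in (0, 1]", call. = FALSE)
  }
  sv <- svd(X)
  s2 <- sv$d^2
  # numerical rank: drop trailing zero singular values
  d <- max(which(sv$d > sv$d[1] * 1e-14))
  frac <- cumsum(s2[seq_len(d)]) / sum(s2[seq_len(d)])
  l <- if (!is.null(rank)) {
    stopifnot(rank >= 1, rank <= d)
    as.integer(rank)
  } else {
    as.integer(which(frac >= energy_target - 1e-12)[1])
  }
  U <- sv$u[, seq_len(l), drop = FALSE]
  # deterministic sign: largest-|entry| of each mode positive
  for (cidx in seq_len(l)) {
    piv <- which.max(abs(U[, cidx]))
    if (U[piv, cidx] < 0) U[, cidx] <- -U[, cidx]
  }
  structure(
    list(U = U, singular_values = sv$d[seq_len(d)], rank = l,
         energy = frac[l], energy_target = energy_target),
    class = "pod_basis"
  )
}

#' @export
print.pod_basis <- function(x, ...) {
  cat(sprintf("<pod_basis> rank %d of %d, energy %.6f\n",
              x$rank, length(x$singular_values), x$energy))
  invisible(x)
}

#' Captured-energy curve
#'
#' @param basis A [compute_pod()] result.
#' @return Numeric vector: eps(l) for l = 1..d (nondecreasing, ending
#'   at 1).
#' @export
pod_energy <- function(basis) {
  s2 <- basis$singular_values^2
  cumsum(s2) / sum(s2)
}

#' Project the transport dynamics onto a POD basis
#'
#' Builds the reduced model `d xt/dt = U^T A(u) U xt` with the reduced
#' cost matrix `Qt = U^T Q U` (Q diagonal). The full operator `A(u)` is
#' assembled on demand for each current vector, then compressed; the lift
#' map is `x ~ U xt` and the restriction `xt = U^T x`.
#'
#' @param basis A [compute_pod()] result (orthonormal `U`).
#' @param grid,coils,particle,fluid Model components as in
#'   [integrate_transport()].
#' @param q_diag Length-`grid$n` diagonal of the state-cost matrix Q.
#' @param D Diffusion coefficient (m^2/s).
#' @param cache Optional [make_field_cache()].
#' @param scheme Advective flux scheme.
#' @return Object of class `reduced_model` with fields `dim`, `U`, `Qt`,
#'   `operator(u)` (returns the l x l dense reduced operator),
#'   `rhs_builder(u)` (returns `function(x) At %*% x`), `lift(xt)`,
#'   `restrict(x)`, `dt_hint(u)` (stable RK4 sub-step of the underlying
#'   full model).
#' @export
project_model <- function(basis, grid, coils, particle, fluid,
                          q_diag = numeric(grid$n), D = fluid$diffusion,
                          cache = NULL, scheme = "central") {
  U <- basis$U
  if (nrow(U) != grid$n) stop("basis does not match the grid",
                              call. = FALSE)
  if (length(q_diag) != grid$n) stop("q_diag must have length grid$n",
                                     call. = FALSE)
  if (is.null(cache)) cache <- make_field_cache(grid, coils)
  operator <- function(u) {
    dr <- drift_field(grid, coils, u, particle, fluid, cache = cache)
    A <- assemble_operator(grid, dr, D, scheme = scheme)
    as.matrix(Matrix::crossprod(U, A %*% U))
  }
  dt_hint <- function(u, safety = 0.4) {
    dr <- drift_field(grid, coils, u, particle, fluid, cache = cache)
    rk4_substep(grid, D, dr$max_speed, safety)
  }
  structure(
    list(
      dim = basis$rank,
      U = U,
      Qt = crossprod(U, q_diag * U),
      operator = operator,
      rhs_builder = function(u) {
        At <- operator(u)
        function(x) as.numeric(At %*% x)
      },
      lift = function(xt) as.numeric(U %*% xt),
      restrict = function(x) as.numeric(crossprod(U, x)),
      dt_hint = dt_hint
    ),
    class = "reduced_model"
  )
}

# fixed-step RK4 for a generic (ZOH-constant-input) RHS
rk4_advance_fun <- function(rhs, x0, interval, n_steps) {
  h <- interval / n_steps
  x <- x0
  for (s in seq_len(n_steps)) {
    k1 <- rhs(x)
    k2 <- rhs(x + h / 2 * k1)
    k3 <- rhs(x + h / 2 * k2)
    k4 <- rhs(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

#' Integrate a reduced model over a current schedule
#'
#' Same contract as [integrate_transport()] but in the l-dimensional
#' reduced space: within each constant-current segment the reduced
#' operator is built once and advanced by RK4 with the full model's
#' stable sub-step.
#'
#' @param x0t Initial reduced state (length `model$dim`), e.g.
#'   `model$restrict(c0)`.
#' @param schedule A [current_schedule()].
#' @param model A [project_model()] result (or any list providing
#'   `rhs_builder`, `dim`, optionally `dt_hint`).
#' @param n_snapshots Uniform snapshot count including both endpoints.
#' @param safety RK4 sub-step safety factor.
#' @return List of class `reduced_trajectory`: `times`, `states`
#'   (`model$dim` x n_snapshots).
#' @export
reduced_integrate <- function(x0t, schedule, model, n_snapshots = 101,
                              safety = 0.4) {
  stopifnot(length(x0t) == model$dim, n_snapshots >= 2)
  t_f <- schedule$t_f
  snap_times <- seq(0, t_f, length.out = n_snapshots)
  seg_bounds <- seq(0, t_f, length.out = schedule$n_t + 1)
  knots <- sort(unique(signif(c(snap_times, seg_bounds), 12)))
  states <- matrix(0, model$dim, n_snapshots)
  states[, 1] <- x0t
  x <- x0t
  snap_idx <- 2L
  seg_cur <- -1L
  rhs <- NULL
  dt_seg <- Inf
  for (kn in seq_len(length(knots) - 1)) {
    t0 <- knots[kn]; t1 <- knots[kn + 1]
    seg <- schedule_segment(schedule, t0)
    if (seg != seg_cur) {
      u <- schedule$u[, seg]
      rhs <- model$rhs_builder(u)
      dt_seg <- if (is.null(model$dt_hint)) Inf else
        model$dt_hint(u, safety)
      seg_cur <- seg
    }
    len <- t1 - t0
    n_steps <- if (is.finite(dt_seg)) max(1L, ceiling(len / dt_seg)) else 1L
    x <- rk4_advance_fun(rhs, x, len, n_steps)
    if (!all(is.finite(x))) {
      stop("reduced integration diverged", call. = FALSE)
    }
    while (snap_idx <= n_snapshots &&
           abs(snap_times[snap_idx] - t1) <= 1e-9 * max(t_f, 1)) {
      states[, snap_idx] <- x
      snap_idx <- snap_idx + 1L
    }
  }
  structure(list(times = snap_times, states = states),
            class = "reduced_trajectory")
}
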