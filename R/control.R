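#' Diagonal state cost selecting target voxels
#'
#' Builds the diagonal of the state-cost matrix Q for the running cost
#' `x^T Q x`: `-weight` at target voxels (their concentration is
#' maximized), `+weight` at avoid voxels (minimized), zero elsewhere. In
#' the packaged scenarios a single target voxel carries -1.
#'
#' @param grid A [grid_2d()].
#' @param targets Integer vector of 1-based target voxel positions.
#' @param weights Target weights (recycled), > 0.
#' @param avoid Optional avoid voxels (1-based).
#' @param avoid_weights Avoid weights (recycled), > 0.
#' @return Numeric vector of length `grid$n`: the diagonal of Q.
#' @export
build_cost <- function(grid, targets, weights = 1,
                       avoid = integer(0), avoid_weights = 1) {
  idx <- c(targets, avoid)
  if (length(targets) == 0) stop("`targets` must be nonempty",
                                 call. = FALSE)
  if (any(idx < 1 | idx > grid$n)) stop("voxel index out of range",
                                        call. = FALSE)
  q <- numeric(grid$n)
  q[targets] <- -rep_len(abs(weights), length(targets))
  if (length(avoid)) {
    q[avoid] <- q[avoid] + rep_len(abs(avoid_weights), length(avoid))
  }
  q
}

# trapezoidal quadrature on a (possibly nonuniform) time grid
trapz <- function(t, f) {
  n <- length(t)
  sum(diff(t) * (f[-1] + f[-n]) / 2)
}

#' Evaluate the optimal-control cost J
#'
#' `J = int_0^tf (x^T Q x + u^T R u) dt + gamma t_f` by trapezoidal
#' quadrature over the trajectory's uniform snapshot grid (which includes
#' both endpoints).
#'
#' @param trajectory An `mnp_trajectory`, `reduced_trajectory`, or any
#'   list with `times` and `states` (states in columns).
#' @param q Either the diagonal of Q (length = state dimension) or a dense
#'   (reduced) cost matrix.
#' @param schedule Optional [current_schedule()] supplying u(t); required
#'   when `r_diag` is nonzero.
#' @param r_diag Diagonal of R (length n_u) or a scalar, >= 0.
#' @param gamma Final-time weight; contributes `gamma * t_f`.
#' @return Scalar cost J.
#' @export
evaluate_cost <- function(trajectory, q, schedule = NULL, r_diag = 0,
                          gamma = 0) {
  tt <- trajectory$times
  X <- trajectory$states
  if (is.matrix(q)) {
    if (nrow(q) != nrow(X)) stop("cost matrix does not match trajectory",
                                 call. = FALSE)
    fx <- colSums(X * (q %*% X))
  } else {
    if (length(q) != nrow(X)) stop("cost diagonal does not match trajectory",
                                   call. = FALSE)
    fx <- colSums(q * X^2)
  }
  fu <- 0
  if (any(r_diag != 0)) {
    if (is.null(schedule)) stop("`schedule` required when R is nonzero",
                                call. = FALSE)
    seg <- schedule_segment(schedule, tt)
    ru <- colSums(rep_len(r_diag, schedule$n_u) * schedule$u^2)
    fu <- ru[seg]
  }
  trapz(tt, fx + fu) + gamma * max(tt)
}

#' Heuristic initial current schedule
#'
#' Activates, at `fraction * u_max`, the coil(s) whose direction from the
#' initial centroid best aligns with the centroid-to-target direction
#' (particles are pulled toward an energized coil), constant over all
#' segments. For a holding problem (target at the centroid) the coil
#' nearest to the upstream direction of the flow is used; with zero flow
#' the guess is all zeros.
#'
#' @param grid A [grid_2d()].
#' @param coils A [coil_set()].
#' @param x0 Initial concentration vector (positive total mass).
#' @param targets Target voxel positions (1-based).
#' @param u_max Current bound (A).
#' @param n_t Number of zero-order-hold segments.
#' @param t_f Horizon (s).
#' @param flow Uniform flow vector `c(vx, vy)` (m/s) for holding problems.
#' @param fraction Activation level as a fraction of `u_max`, default 0.5.
#' @return A feasible [current_schedule()].
#' @export
initial_guess <- function(grid, coils, x0, targets, u_max, n_t, t_f,
                          flow = c(0, 0), fraction = 0.5) {
  stopifnot(sum(x0) > 0, length(targets) >= 1)
  sm <- summarize_concentration(x0, grid = grid, targets = targets)
  vc <- voxel_centers(grid)
  tx <- mean(vc$x[targets]); ty <- mean(vc$y[targets])
  dir <- c(tx - sm$centroid_x, ty - sm$centroid_y)
  if (sqrt(sum(dir^2)) < grid$dx / 2) {
    # holding problem: pull against the flow
    if (is.numeric(flow) && sqrt(sum(flow^2)) > 0) {
      dir <- -flow[1:2]
    } else {
      return(current_schedule(matrix(0, nrow(coils), n_t), t_f))
    }
  }
  dir <- dir / sqrt(sum(dir^2))
  cdir <- cbind(coils$x - sm$centroid_x, coils$y - sm$centroid_y)
  cdir <- cdir / sqrt(rowSums(cdir^2))
  align <- cdir %*% dir
  u <- matrix(0, nrow(coils), n_t)
  u[align >= max(align) - 1e-9, ] <- fraction * u_max
  current_schedule(u, t_f)
}

#' Direct-multiple-shooting solver options
#'
#' @param max_iter Inner L-BFGS-B iteration cap per augmented-Lagrangian
#'   subproblem; `max_iter = 0` makes [dms_solve()] return the guess
#'   unchanged.
#' @param max_outer Augmented-Lagrangian (multiplier) updates.
#' @param quad_per_seg Quadrature sub-intervals per shooting segment for
#'   the running cost.
#' @param fd_step_frac Forward finite-difference step for current
#'   variables, as a fraction of `u_max`.
#' @param constraint_tol Continuity (matching) tolerance, relative to the
#'   initial reduced state norm.
#' @param penalty_growth Penalty multiplier when the constraint violation
#'   stalls.
#' @return List of class `dms_control`.
#' @export
dms_control <- function(max_iter = 40, max_outer = 5, quad_per_seg = 25,
                        fd_step_frac = 1e-3, constraint_tol = 1e-5,
                        penalty_growth = 10) {
  structure(list(max_iter = max_iter, max_outer = max_outer,
                 quad_per_seg = quad_per_seg,
                 fd_step_frac = fd_step_frac,
                 constraint_tol = constraint_tol,
                 penalty_growth = penalty_growth),
            class = "dms_control")
}

# integrate one shooting segment with constant input; returns end state
# and the segment's running-cost integral
segment_run <- function(model, s0, u, seg_len, quad_n, safety = 0.4) {
  rhs <- model$rhs_builder(u)
  dt_seg <- if (is.null(model$dt_hint)) Inf else model$dt_hint(u, safety)
  tq <- seq(0, seg_len, length.out = quad_n + 1)
  states <- matrix(0, length(s0), quad_n + 1)
  states[, 1] <- s0
  x <- s0
  for (qi in seq_len(quad_n)) {
    len <- tq[qi + 1] - tq[qi]
    n_steps <- if (is.finite(dt_seg)) max(1L, ceiling(len / dt_seg)) else 1L
    x <- rk4_advance_fun(rhs, x, len, n_steps)
    states[, qi + 1] <- x
  }
  fx <- colSums(states * (model$Qt %*% states))
  list(end = x, cost = trapz(tq, fx))
}

#' Solve the reduced optimal control problem by direct multiple shooting
#'
#' Transcribes the problem over `n_t` zero-order-hold segments: the
#' decision variables are the `n_u x n_t` current levels and the reduced
#' states at the `n_t - 1` interior shooting nodes; each segment is
#' integrated by RK4 in the reduced space, equality constraints enforce
#' node continuity, and the currents obey the box bound `|u| <= u_max`.
#' The resulting NLP is solved with an augmented-Lagrangian outer loop
#' around box-constrained L-BFGS-B, with forward finite-difference
#' gradients (step `fd_step_frac * u_max` on currents). The reported
#' solution is the best feasible iterate: after every outer iteration the
#' candidate currents are re-simulated from the initial state (single
#' continuous shoot) and the best re-simulated cost is kept, so the
#' returned cost never exceeds the guess's.
#'
#' @param model A [project_model()] result (or any list with
#'   `rhs_builder`, `Qt`, `dim`, optional `dt_hint`).
#' @param x0t Initial reduced state, e.g. `model$restrict(c0)`.
#' @param t_f Horizon (s).
#' @param u_max Symmetric current bound (A).
#' @param guess Feasible [current_schedule()] (max |u| <= u_max).
#' @param r_diag Diagonal of R (input cost), scalar or length n_u.
#' @param gamma Final-time weight (adds `gamma t_f`).
#' @param node_init Optional `dim x (n_t - 1)` matrix of warm-start node
#'   states; defaults to the guess trajectory's node states.
#' @param control A [dms_control()].
#' @return Object of class `dms_solution`: `schedule` (best currents),
#'   `cost` (re-simulated reduced cost), `trajectory`
#'   (`reduced_trajectory` under the best currents), `guess_cost`,
#'   `history` tibble (outer iteration, cost, constraint violation),
#'   `status` (`"converged"` or `"max_outer"`), `feasible`.
#' @export
dms_solve <- function(model, x0t, t_f, u_max, guess, r_diag = 0,
                      gamma = 0, node_init = NULL,
                      control = dms_control()) {
  n_u <- guess$n_u
  n_t <- guess$n_t
  stopifnot(abs(guess$t_f - t_f) <= 1e-9 * t_f)
  if (max(abs(guess$u)) > u_max + 1e-8) {
    stop("infeasible guess: currents exceed u_max", call. = FALSE)
  }
  l <- model$dim
  seg_len <- t_f / n_t
  quad_n <- control$quad_per_seg
  rvec <- rep_len(r_diag, n_u)

  resim_cost <- function(u_mat) {
    sched <- current_schedule(u_mat, t_f)
    traj <- reduced_integrate(x0t, sched, model,
                              n_snapshots = n_t * quad_n + 1)
    evaluate_cost(traj, model$Qt, schedule = sched, r_diag = rvec,
                  gamma = gamma)
  }

  guess_cost <- resim_cost(guess$u)
  if (control$max_iter == 0) {
    traj <- reduced_integrate(x0t, guess, model,
                              n_snapshots = n_t * quad_n + 1)
    return(structure(
      list(schedule = guess, cost = guess_cost, trajectory = traj,
           guess_cost = guess_cost,
           history = tibble::tibble(outer = integer(0), cost = numeric(0),
                                    violation = numeric(0)),
           status = "guess", feasible = TRUE),
      class = "dms_solution"))
  }

  # default warm start: node states from simulating the guess
  if (is.null(node_init)) {
    gt <- reduced_integrate(x0t, guess, model, n_snapshots = n_t + 1)
    node_init <- gt$states[, seq_len(n_t - 1) + 1, drop = FALSE]
  }
  node_init <- matrix(node_init, nrow = l)

  n_uvar <- n_u * n_t
  n_svar <- l * (n_t - 1)
  z0 <- c(as.numeric(guess$u), as.numeric(node_init))
  lower <- c(rep(-u_max, n_uvar), rep(-Inf, n_svar))
  upper <- c(rep(u_max, n_uvar), rep(Inf, n_svar))

  unpack <- function(z) {
    list(u = matrix(z[seq_len(n_uvar)], n_u, n_t),
         S = if (n_svar > 0)
           matrix(z[n_uvar + seq_len(n_svar)], l, n_t - 1)
         else matrix(0, l, 0))
  }

  shoot <- function(z) {
    p <- unpack(z)
    J <- gamma * t_f
    defect <- numeric(n_svar)
    for (k in seq_len(n_t)) {
      s_k <- if (k == 1) x0t else p$S[, k - 1]
      run <- segment_run(model, s_k, p$u[, k], seg_len, quad_n)
      J <- J + run$cost + sum(rvec * p$u[, k]^2) * seg_len
      if (k < n_t) {
        defect[(k - 1) * l + seq_len(l)] <- run$end - p$S[, k]
      }
    }
    list(J = J, defect = defect)
  }

  state_scale <- max(sqrt(sum(x0t^2)), 1e-12)
  lambda <- numeric(n_svar)
  sh0 <- shoot(z0)
  # normalize the objective to O(1) so the inner solver's gradient and
  # descent tolerances are meaningful regardless of the physical cost scale
  obj_scale <- 1 / max(abs(sh0$J), state_scale^2 * t_f * 1e-6, 1e-300)
  # penalty sized so unit-relative defects outweigh the (scaled) cost
  mu <- 100 / state_scale^2

  aug <- function(z) {
    sh <- shoot(z)
    obj_scale * sh$J + sum(lambda * sh$defect) + mu / 2 * sum(sh$defect^2)
  }
  # forward finite differences; current vars use fd_step_frac * u_max
  fd_steps <- c(rep(control$fd_step_frac * u_max, n_uvar),
                rep(1e-6 * state_scale, n_svar))
  aug_grad <- function(z) {
    f0 <- aug(z)
    g <- numeric(length(z))
    for (i in seq_along(z)) {
      h <- fd_steps[i]
      # keep current perturbations inside the box
      if (i <= n_uvar && z[i] + h > upper[i]) h <- -h
      zp <- z; zp[i] <- zp[i] + h
      g[i] <- (aug(zp) - f0) / h
    }
    g
  }

  z <- z0
  best_u <- guess$u
  best_cost <- guess_cost
  hist <- vector("list", control$max_outer)
  status <- "max_outer"
  prev_viol <- Inf
  for (outer in seq_len(control$max_outer)) {
    opt <- stats::optim(z, fn = aug, gr = aug_grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = control$max_iter,
                                       factr = 1e7, pgtol = 1e-8))
    z <- opt$par
    sh <- shoot(z)
    viol <- if (n_svar > 0) max(abs(sh$defect)) else 0
    cand <- unpack(z)$u
    cand_cost <- resim_cost(cand)
    if (cand_cost < best_cost) {
      best_cost <- cand_cost
      best_u <- cand
    }
    hist[[outer]] <- tibble::tibble(outer = outer, cost = cand_cost,
                                    violation = viol)
    if (viol <= control$constraint_tol * state_scale) {
      status <- "converged"
      break
    }
    lambda <- lambda + mu * sh$defect
    if (viol > 0.25 * prev_viol) mu <- mu * control$penalty_growth
    prev_viol <- viol
  }

  best_sched <- current_schedule(best_u, t_f)
  traj <- reduced_integrate(x0t, best_sched, model,
                            n_snapshots = n_t * quad_n + 1)
  structure(
    list(schedule = best_sched, cost = best_cost, trajectory = traj,
         guess_cost = guess_cost, history = dplyr::bind_rows(hist),
         status = status, feasible = max(abs(best_u)) <= u_max + 1e-8),
    class = "dms_solution"
  )
}

#' @export
print.dms_solution <- function(x, ...) {
  cat(sprintf("<dms_solution> status %s, cost %.6g (guess %.6g)\n",
              x$status, x$cost, x$guess_cost))
  invisible(x)
}

#' Alternating POD / direct-multiple-shooting optimization
#'
#' The outer loop of the method: (0) simulate the full-order model under
#' the initial guess to collect snapshots; then repeat `n_opt` times --
#' compute a POD basis from the current snapshots, run DMS on the reduced
#' system (warm-started from the previous currents and the restriction of
#' the previous full-order node states under the new basis), apply the
#' resulting currents to the full-order model to obtain new snapshots.
#' The best-so-far currents by full-order cost are kept, so the reported
#' cost is monotone nonincreasing across iterations; the loop exits early
#' once the final-time target concentration reaches `stop_threshold`.
#'
#' @param x0 Initial full-order concentration vector.
#' @param grid,coils,particle,fluid Model components.
#' @param targets Target voxel positions (1-based).
#' @param q_diag Diagonal of Q; default `build_cost(grid, targets)`.
#' @param t_f Horizon (s).
#' @param n_t Zero-order-hold segments.
#' @param u_max Current bound (A).
#' @param guess Optional feasible [current_schedule()]; default
#'   [initial_guess()].
#' @param guess_fraction Activation level of the default guess, as a
#'   fraction of `u_max`.
#' @param n_opt Number of POD-DMS iterations, >= 1.
#' @param energy_target POD energy threshold eps* (used unless `rank`).
#' @param rank Optional fixed POD rank.
#' @param r_diag,gamma Input-cost diagonal and final-time weight.
#' @param stop_threshold Optional target-concentration level that ends
#'   the loop early.
#' @param n_snapshots Full-order snapshot count per simulation.
#' @param scheme Advective flux scheme.
#' @param D Diffusion coefficient (m^2/s).
#' @param control A [dms_control()].
#' @return Object of class `oc_solution`: `schedule` (best currents),
#'   `trajectory` (full-order, under the best currents), `cost`
#'   (full-order J), `guess`, `guess_cost`, `history` tibble (one row per
#'   outer iteration: full-order cost, reduced cost, POD rank, DMS
#'   status), `targets`, `pod` (last basis).
#' @export
alternating_pod_dms <- function(x0, grid, coils, particle, fluid, targets,
                                q_diag = build_cost(grid, targets),
                                t_f, n_t, u_max, guess = NULL,
                                guess_fraction = 0.5, n_opt = 2,
                                energy_target = 0.98, rank = NULL,
                                r_diag = 0, gamma = 0,
                                stop_threshold = NULL, n_snapshots = 101,
                                scheme = "central", D = fluid$diffusion,
                                control = dms_control()) {
  stopifnot(n_opt >= 1 || !is.null(stop_threshold))
  cache <- make_field_cache(grid, coils)
  if (is.null(guess)) {
    flow <- if (is.numeric(fluid$flow)) fluid$flow else c(0, 0)
    guess <- initial_guess(grid, coils, x0, targets, u_max = u_max,
                           n_t = n_t, t_f = t_f, flow = flow,
                           fraction = guess_fraction)
  }
  rvec <- rep_len(r_diag, nrow(coils))

  simulate_full <- function(sched) {
    integrate_transport(x0, sched, grid, coils, particle, fluid, D = D,
                        n_snapshots = n_snapshots, cache = cache,
                        scheme = scheme)
  }
  full_cost <- function(traj, sched) {
    evaluate_cost(traj, q_diag, schedule = sched, r_diag = rvec,
                  gamma = gamma)
  }
  node_times <- seq(0, t_f, length.out = n_t + 1)[-c(1, n_t + 1)]
  node_cols <- function(traj) {
    vapply(node_times, function(tt) which.min(abs(traj$times - tt)),
           integer(1))
  }

  traj <- simulate_full(guess)
  best_cost <- full_cost(traj, guess)
  best_sched <- guess
  best_traj <- traj
  guess_cost <- best_cost
  prev_u <- guess$u
  prev_traj <- traj
  hist <- vector("list", n_opt)
  basis <- NULL
  for (i in seq_len(n_opt)) {
    basis <- compute_pod(prev_traj, energy_target = energy_target,
                         rank = rank)
    model <- project_model(basis, grid, coils, particle, fluid,
                           q_diag = q_diag, D = D, cache = cache,
                           scheme = scheme)
    x0t <- model$restrict(x0)
    warm_nodes <- if (n_t > 1) {
      crossprod(basis$U, prev_traj$states[, node_cols(prev_traj),
                                          drop = FALSE])
    } else NULL
    sol <- dms_solve(model, x0t, t_f = t_f, u_max = u_max,
                     guess = current_schedule(prev_u, t_f),
                     r_diag = rvec, gamma = gamma,
                     node_init = warm_nodes, control = control)
    traj <- simulate_full(sol$schedule)
    jf <- full_cost(traj, sol$schedule)
    improved <- jf < best_cost
    if (improved) {
      best_cost <- jf
      best_sched <- sol$schedule
      best_traj <- traj
    }
    hist[[i]] <- tibble::tibble(
      iteration = i, cost_full = jf, best_cost = best_cost,
      cost_reduced = sol$cost, pod_rank = basis$rank,
      dms_status = sol$status, improved = improved
    )
    prev_u <- sol$schedule$u
    prev_traj <- traj
    if (!is.null(stop_threshold)) {
      final_target <- sum(best_traj$states[targets,
                                           ncol(best_traj$states)])
      if (final_target >= stop_threshold) break
    }
  }
  structure(
    list(schedule = best_sched, trajectory = best_traj, cost = best_cost,
         guess = guess, guess_cost = guess_cost,
         history = dplyr::bind_rows(hist), targets = targets,
         pod = basis, grid = grid, t_f = t_f, u_max = u_max),
    class = "oc_solution"
  )
}

#' @export
print.oc_solution <- function(x, ...) {
  cat(sprintf(
    "<oc_solution> cost %.6g (guess %.6g), %d outer iteration(s)\n",
    x$cost, x$guess_cost, nrow(x$history)))
  cat("best currents (A):\n")
  print(round(x$schedule$u, 3))
  invisible(x)
}
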