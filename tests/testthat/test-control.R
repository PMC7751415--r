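test_that("cost diagonal selects targets and avoid voxels", {
  g <- grid_2d(5, 5, side_x = 0.05)
  q <- build_cost(g, targets = 13)
  expect_equal(sum(q != 0), 1)
  expect_equal(q[13], -1)
  q2 <- build_cost(g, targets = c(3, 7), weights = c(1, 2), avoid = 20,
                   avoid_weights = 0.5)
  expect_equal(q2[c(3, 7, 20)], c(-1, -2, 0.5))
  # quadratic form expands as advertised
  x <- runif(g$n)
  expect_equal(sum(q2 * x^2),
               -x[3]^2 - 2 * x[7]^2 + 0.5 * x[20]^2)
  expect_error(build_cost(g, targets = 26), "out of range")
  expect_error(build_cost(g, targets = integer(0)), "nonempty")
})

test_that("cost quadrature is exact for the documented cases", {
  tt <- seq(0, 100, length.out = 101)
  # x == 0: J = gamma t_f
  zero_traj <- list(times = tt, states = matrix(0, 3, 101))
  expect_equal(evaluate_cost(zero_traj, rep(-1, 3), gamma = 0.25),
               0.25 * 100)
  # constant unit target concentration with Q_target = -1: J = -t_f
  one_traj <- list(times = tt, states = matrix(1, 1, 101))
  expect_equal(evaluate_cost(one_traj, -1), -100)
  # quadratic-in-time state: trapezoid vs exact polynomial integral
  # x(t) = t/100 so x^2 = t^2/1e4, integral over [0,100] = 100/3
  quad_traj <- list(times = tt, states = matrix(tt / 100, 1))
  expect_equal(evaluate_cost(quad_traj, 1), 100 / 3, tolerance = 1e-4)
  # the input term integrates u^T R u exactly for piecewise-constant u
  sched <- current_schedule(matrix(c(2, 1), 1, 2), 100)
  expect_equal(evaluate_cost(zero_traj, rep(0, 3), schedule = sched,
                             r_diag = 1),
               (4 + 1) * 50, tolerance = 1e-2)
})

test_that("initial guess activates the aligned coil within bounds", {
  cmp <- ci_steering()
  cfg <- cmp$config
  g <- initial_guess(cmp$grid, cmp$coils, cmp$x0, cmp$targets,
                     u_max = cfg$u_max, n_t = cfg$n_t, t_f = cfg$t_f)
  # target is +y of the blob: only the +y coil (row 3) is active
  expect_true(all(g$u[3, ] == 0.5 * cfg$u_max))
  expect_true(all(g$u[-3, ] == 0))
  expect_lte(max(abs(g$u)), cfg$u_max)
  # holding with a +y flow: pull with the -y-ward coil (row 4 sits at -y,
  # so the coil whose direction is -y from the centroid is row 4)
  centroid_vox <- voxel_at(cmp$grid, 0, -0.03)
  gh <- initial_guess(cmp$grid, cmp$coils, cmp$x0, centroid_vox,
                      u_max = cfg$u_max, n_t = cfg$n_t, t_f = cfg$t_f,
                      flow = c(0, 3e-6))
  expect_true(all(gh$u[4, ] > 0))
  expect_true(all(gh$u[-4, ] == 0))
  # holding without flow: all-zero guess
  g0 <- initial_guess(cmp$grid, cmp$coils, cmp$x0, centroid_vox,
                      u_max = cfg$u_max, n_t = cfg$n_t, t_f = cfg$t_f)
  expect_true(all(g0$u == 0))
})

test_that("toy shooting problem recovers the grid-search optimum", {
  toy <- toy_model()
  guess <- current_schedule(matrix(0, 1, 1), 2)
  sol <- dms_solve(toy, 0, t_f = 2, u_max = 1, guess = guess)
  # exhaustive search over constant u in {-1, -0.9, ..., 1}: the cost
  # -int x^2 dt with x = u (1 - e^-t) is minimized at |u| = 1
  us <- seq(-1, 1, by = 0.1)
  Js <- vapply(us, function(u) {
    tr <- reduced_integrate(0, current_schedule(matrix(u, 1, 1), 2),
                            toy, n_snapshots = 26)
    evaluate_cost(tr, matrix(-1, 1, 1))
  }, numeric(1))
  expect_equal(abs(sol$schedule$u[1, 1]), 1, tolerance = 1e-6)
  expect_equal(sol$cost, min(Js), tolerance = 1e-6)
  expect_true(sol$feasible)
})

test_that("max_iter = 0 returns the guess unchanged", {
  toy <- toy_model()
  guess <- current_schedule(matrix(0.3, 1, 2), 2)
  sol <- dms_solve(toy, 0.1, t_f = 2, u_max = 1, guess = guess,
                   control = dms_control(max_iter = 0))
  expect_identical(sol$schedule$u, guess$u)
  expect_identical(sol$status, "guess")
  expect_equal(sol$cost, sol$guess_cost)
})

test_that("infeasible guesses are rejected", {
  toy <- toy_model()
  bad <- current_schedule(matrix(2, 1, 1), 2)
  expect_error(dms_solve(toy, 0, t_f = 2, u_max = 1, guess = bad),
               "infeasible")
})

test_that("alternating POD-DMS improves the steering cost monotonically", {
  cmp <- ci_steering()
  cfg <- cmp$config
  sol <- alternating_pod_dms(cmp$x0, cmp$grid, cmp$coils, cmp$particle,
                             cmp$fluid, targets = cmp$targets,
                             t_f = cfg$t_f, n_t = cfg$n_t,
                             u_max = cfg$u_max, n_opt = 2)
  # feasibility and improvement over guess and over zero control
  expect_lte(max(abs(sol$schedule$u)), cfg$u_max + 1e-8)
  expect_lte(sol$cost, sol$guess_cost)
  zero <- current_schedule(matrix(0, 4, cfg$n_t), cfg$t_f)
  tz <- integrate_transport(cmp$x0, zero, cmp$grid, cmp$coils,
                            cmp$particle, cmp$fluid)
  Jz <- evaluate_cost(tz, cmp$q_diag)
  expect_lte(sol$guess_cost, Jz + 1e-12)
  expect_lt(sol$cost, Jz)
  # best-so-far cost is nonincreasing across outer iterations
  expect_true(all(diff(sol$history$best_cost) <= 1e-12))
  # the optimized currents collect more particles at the target
  final_opt <- sum(sol$trajectory$states[cmp$targets,
                                         ncol(sol$trajectory$states)])
  final_zero <- sum(tz$states[cmp$targets, ncol(tz$states)])
  expect_gt(final_opt, final_zero)
})

test_that("reduced and full costs agree on a holding run at 0.98 energy", {
  cfg <- holding_scenario("ci")
  cmp <- scenario_components(cfg)
  sol <- alternating_pod_dms(cmp$x0, cmp$grid, cmp$coils, cmp$particle,
                             cmp$fluid, targets = cmp$targets,
                             t_f = cfg$t_f, n_t = cfg$n_t,
                             u_max = cfg$u_max, n_opt = 1)
  # basis built from the solution's own trajectory must price that
  # trajectory consistently with the full-order model
  basis <- compute_pod(sol$trajectory, energy_target = 0.98)
  cache <- make_field_cache(cmp$grid, cmp$coils)
  mod <- project_model(basis, cmp$grid, cmp$coils, cmp$particle,
                       cmp$fluid, q_diag = cmp$q_diag, cache = cache)
  red <- reduced_integrate(mod$restrict(cmp$x0), sol$schedule, mod,
                           n_snapshots = length(sol$trajectory$times))
  Jr <- evaluate_cost(red, mod$Qt)
  expect_lt(abs(Jr - sol$cost) / abs(sol$cost), 0.10)
})

test_that("one outer iteration unrolls to pod + dms + resimulation", {
  cmp <- ci_steering()
  cfg <- cmp$config
  guess <- initial_guess(cmp$grid, cmp$coils, cmp$x0, cmp$targets,
                         u_max = cfg$u_max, n_t = cfg$n_t, t_f = cfg$t_f)
  ctrl <- dms_control(max_iter = 8, max_outer = 2)
  sol <- alternating_pod_dms(cmp$x0, cmp$grid, cmp$coils, cmp$particle,
                             cmp$fluid, targets = cmp$targets,
                             t_f = cfg$t_f, n_t = cfg$n_t,
                             u_max = cfg$u_max, guess = guess,
                             n_opt = 1, control = ctrl)
  # manual unroll of the same single iteration
  cache <- make_field_cache(cmp$grid, cmp$coils)
  traj <- integrate_transport(cmp$x0, guess, cmp$grid, cmp$coils,
                              cmp$particle, cmp$fluid, cache = cache)
  basis <- compute_pod(traj, energy_target = 0.98)
  mod <- project_model(basis, cmp$grid, cmp$coils, cmp$particle,
                       cmp$fluid, q_diag = cmp$q_diag, cache = cache)
  node_cols <- which.min(abs(traj$times - cfg$t_f / 2))
  warm <- crossprod(basis$U, traj$states[, node_cols, drop = FALSE])
  ds <- dms_solve(mod, mod$restrict(cmp$x0), t_f = cfg$t_f,
                  u_max = cfg$u_max, guess = guess, node_init = warm,
                  control = ctrl)
  expect_equal(sol$history$pod_rank[1], basis$rank)
  manual <- integrate_transport(cmp$x0, ds$schedule, cmp$grid,
                                cmp$coils, cmp$particle, cmp$fluid,
                                cache = cache)
  Jmanual <- evaluate_cost(manual, cmp$q_diag)
  expect_equal(sol$history$cost_full[1], Jmanual, tolerance = 1e-10)
})
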