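test_that("coil field matches the on-axis closed form", {
  co <- test_coil()
  a <- 0.05; N <- 100; I <- 1.3
  z <- seq(-0.15, 0.15, length.out = 20)
  fs <- coil_field(co, I, cbind(0, 0, z))
  exact <- N * I * a^2 / (2 * (a^2 + z^2)^1.5)
  expect_lt(max(abs(fs$H[, 3] - exact) / abs(exact)), 1e-8)
  # transverse components vanish on the axis
  expect_equal(max(abs(fs$H[, 1:2])), 0)
  # center value N I / (2 a)
  fs0 <- coil_field(co, 1, c(0, 0, 0))
  expect_equal(fs0$H[1, 3], N / (2 * a), tolerance = 1e-12)
})

test_that("field is linear in the current and zero at zero current", {
  co <- test_coil()
  p <- c(0.013, -0.021, 0.037)
  f1 <- coil_field(co, 1, p)
  f3 <- coil_field(co, -3.7, p)
  expect_equal(f3$H, -3.7 * f1$H, tolerance = 1e-14)
  expect_equal(f3$jacobian, -3.7 * f1$jacobian, tolerance = 1e-14)
  f0 <- coil_field(co, 0, p)
  expect_equal(max(abs(f0$H)), 0)
  expect_equal(max(abs(f0$jacobian)), 0)
  expect_equal(f1$B, (4e-7 * pi) * f1$H)
})

test_that("analytic jacobian matches central finite differences", {
  co <- test_coil()
  set.seed(42)
  h <- 1e-7
  for (rep in 1:10) {
    p <- runif(3, -0.04, 0.04)
    J <- matrix(coil_field(co, 1, p)$jacobian, 3, 3)
    Jfd <- matrix(0, 3, 3)
    for (j in 1:3) {
      e <- replace(numeric(3), j, h)
      Jfd[, j] <- (coil_field(co, 1, p + e)$H -
                     coil_field(co, 1, p - e)$H) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }
  # near-axis branch agrees with the generic branch just outside it
  p_in <- c(1e-10, 0, 0.03)
  p_out <- c(1e-8, 0, 0.03)
  expect_equal(coil_field(co, 1, p_in)$H, coil_field(co, 1, p_out)$H,
               tolerance = 1e-6)
})

test_that("filament and bad inputs are rejected", {
  co <- test_coil()
  expect_error(coil_field(co, 1, c(0.05, 0, 0)), "filament")
  expect_error(coil_field(co, 1, c(NA, 0, 0)), "non-finite")
})

test_that("total_field superposes and checks shapes", {
  coils <- coil_set(x = c(-0.1, 0.1), y = 0, axis_x = c(1, -1),
                    axis_y = 0, radius = 0.05, turns = 100)
  p <- c(0.01, 0.02, 0)
  ft <- total_field(coils, c(2.5, 0), p)
  f1 <- coil_field(coils[1, ], 2.5, p)
  expect_equal(ft$H, f1$H)
  expect_equal(ft$jacobian, f1$jacobian)
  # zero currents
  f0 <- total_field(coils, c(0, 0), p)
  expect_equal(max(abs(f0$H)), 0)
  # coaxial pair with aligned axes and equal currents: the transverse
  # components cancel at the midpoint and grad(H^2) = 0 by symmetry
  pair <- coil_set(x = c(-0.1, 0.1), y = 0, axis_x = 1, axis_y = 0,
                   radius = 0.05, turns = 100)
  fm <- total_field(pair, c(1, 1), c(0, 0, 0))
  expect_lt(abs(fm$H[1, 2]), 1e-9 * max(abs(fm$H)))
  gH2 <- 2 * c(sum(fm$H * fm$jacobian[, 1:3]),
               sum(fm$H * fm$jacobian[, 4:6]),
               sum(fm$H * fm$jacobian[, 7:9]))
  expect_lte(max(abs(gH2)), 1e-9 * max(abs(fm$H))^2 / 0.05)
  expect_error(total_field(coils, 1, p), "currents")
})

test_that("langevin is accurate, odd, bounded, and smooth at the branch", {
  expect_identical(langevin(0), 0)
  expect_equal(langevin(1), 1 / tanh(1) - 1, tolerance = 1e-15)
  expect_lt(abs(langevin(1e4) - 1), 1e-3)
  x <- 10^seq(-6, 3, length.out = 40)
  expect_equal(langevin(-x), -langevin(x))
  expect_true(all(abs(langevin(x)) < 1))
  # Taylor and direct branches agree across the switch at 1e-4 (the
  # direct branch carries ~1e-12 absolute cancellation noise there)
  expect_equal(langevin(0.99e-4), 0.99e-4 / 3, tolerance = 1e-9)
  expect_equal(langevin(1.01e-4), 1.01e-4 / 3, tolerance = 1e-6)
})

test_that("magnetization saturates, is monotone, and has the right slope", {
  part <- particle_spec()
  Ms <- part$saturation_magnetization
  expect_identical(magnetization(0, part), 0)
  expect_equal(magnetization(1e9, part), Ms, tolerance = 1e-6)
  H <- 10^seq(-3, 7, length.out = 60)
  M <- magnetization(H, part)
  expect_true(all(diff(M) >= 0))
  expect_true(all(M >= 0 & M <= Ms))
  # initial susceptibility mu0 Ms^2 V / (3 kB T) against a finite
  # difference at H = 1 A/m
  mu0 <- 4e-7 * pi; kB <- 1.380649e-23
  slope <- mu0 * Ms^2 * part$core_volume / (3 * kB * part$temperature)
  fd <- (magnetization(1 + 1e-4, part) - magnetization(1 - 1e-4, part)) /
    2e-4
  # the curve is already nonlinear at H = 1 for this large particle, so
  # compare the analytic Langevin derivative instead of the linear limit
  beta <- mu0 * Ms * part$core_volume / (kB * part$temperature)
  dLdx <- function(x) 1 / x^2 - 1 / sinh(x)^2
  expect_equal(fd, Ms * beta * dLdx(beta), tolerance = 1e-4)
  # the linear limit is recovered for a particle small enough to stay in
  # the Langevin small-argument regime at H = 1
  small <- particle_spec(core_diameter = 10e-9)
  slope_s <- mu0 * small$saturation_magnetization^2 * small$core_volume /
    (3 * kB * small$temperature)
  fd_s <- (magnetization(1.0001, small) - magnetization(0.9999, small)) /
    2e-4
  expect_equal(fd_s, slope_s, tolerance = 1e-4)
})

test_that("moment coefficient is continuous at 0, nonnegative, saturating", {
  part <- particle_spec()
  g0 <- moment_coefficient(0, part)
  mu0 <- 4e-7 * pi; kB <- 1.380649e-23
  expect_equal(g0, mu0 * part$saturation_magnetization^2 *
                 part$core_volume^2 /
                 (3 * kB * part$temperature), tolerance = 1e-12)
  # analytic limit equals V M(H)/H at a tiny field
  H <- 1e-3
  expect_equal(g0, part$core_volume * magnetization(H, part) / H,
               tolerance = 1e-6)
  Hs <- 10^seq(-3, 7, length.out = 50)
  g <- moment_coefficient(Hs, part)
  expect_true(all(g >= 0))
  # saturated moment g(H) H -> V Ms
  expect_equal(g[length(g)] * Hs[length(Hs)],
               part$core_volume * part$saturation_magnetization,
               tolerance = 1e-3)
})

test_that("magnetic force: both analytic forms agree and point up-field", {
  co <- test_coil()
  part <- particle_spec()
  mu0 <- 4e-7 * pi
  set.seed(7)
  pts <- cbind(runif(10, -0.03, 0.03), runif(10, -0.03, 0.03),
               runif(10, 0.02, 0.06))
  fs <- coil_field(co, 2, pts)
  Fm <- magnetic_force(fs, part)
  # (m . grad)B = mu0 g (H . grad) H uses J H; the implementation uses
  # J^T H = (mu0/2) g grad(H^2). They agree because the coil field is
  # curl-free (J symmetric).
  for (i in 1:10) {
    J <- matrix(fs$jacobian[i, ], 3, 3)
    H <- fs$H[i, ]
    g <- moment_coefficient(sqrt(sum(H^2)), part)
    f_conv <- mu0 * g * as.numeric(J %*% H)
    expect_equal(Fm[i, ], f_conv, tolerance = 1e-10)
  }
  # finite-difference grad(H^2) oracle
  h <- 1e-7
  for (i in 1:10) {
    p <- pts[i, ]
    gH2 <- vapply(1:3, function(j) {
      e <- replace(numeric(3), j, h)
      (sum(coil_field(co, 2, p + e)$H^2) -
         sum(coil_field(co, 2, p - e)$H^2)) / (2 * h)
    }, numeric(1))
    g <- moment_coefficient(sqrt(sum(fs$H[i, ]^2)), part)
    expect_equal(Fm[i, ], mu0 / 2 * g * gH2, tolerance = 1e-4)
  }
  # on the axis below the coil plane the force points toward the coil
  fax <- coil_field(co, 1, c(0, 0, -0.04))
  Fax <- magnetic_force(fax, part)
  expect_gt(Fax[1, 3], 0)
  # zero field -> zero force
  f0 <- coil_field(co, 0, c(0.01, 0, 0.02))
  expect_equal(max(abs(magnetic_force(f0, part))), 0)
})

test_that("drift velocity is Stokes mobility times force plus flow", {
  eta <- 3e-3; Rp <- 2e-7
  expect_equal(drift_velocity(c(0, 0), eta, Rp), c(0, 0))
  expect_equal(drift_velocity(c(6 * pi * eta * Rp, 0), eta, Rp),
               c(1, 0))
  expect_equal(drift_velocity(c(0, 0), eta, Rp,
                              flow = c(-3e-6, 3e-6)),
               c(-3e-6, 3e-6))
  # matrix force with vector flow broadcasts row-wise
  Fm <- matrix(0, 3, 2)
  v <- drift_velocity(Fm, eta, Rp, flow = c(1e-6, 2e-6))
  expect_equal(v, matrix(c(1e-6, 2e-6), 3, 2, byrow = TRUE))
})
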