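# shared fixtures, all built in code

# single test coil: 100 turns, 5 cm radius, axis along z
test_coil <- function() {
  coil_set(0, 0, 0, axis_x = 0, axis_y = 0, axis_z = 1,
           radius = 0.05, turns = 100)
}

# scalar toy dynamics xdot = -x + u with cost -x^2 (not of the A(u) x
# form, exercising the generic rhs_builder contract of the DMS solver)
toy_model <- function() {
  list(dim = 1L, Qt = matrix(-1, 1, 1),
       rhs_builder = function(u) function(x) -x + u,
       dt_hint = NULL)
}

# small drift_field stub for operator-assembly tests
stub_drift <- function(vx, vy, max_speed = max(abs(c(vx, vy, 0)))) {
  structure(list(vx = vx, vy = vy, max_speed = max_speed),
            class = "drift_field")
}

# CI-scale steering components, shared across control/acceptance tests
ci_steering <- function() {
  cfg <- steering_scenario("ci")
  c(list(config = cfg), scenario_components(cfg))
}
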