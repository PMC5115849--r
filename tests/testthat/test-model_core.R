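# Core model: battery waveform, coupling assembly, accelerations,
# closed-form equilibria and the single-circuit analytic solution.

test_that("battery voltage combines steady, fluctuating and step terms", {
  drv <- drive_spec()                       # V = 1, G = sin(1.5 t) e^-t
  expect_identical(battery_voltage(0, drv), 1)
  expect_equal(battery_voltage(20, drv), 1, tolerance = 1e-8)
  expect_equal(battery_voltage(pi / 3, drv), 1 + exp(-pi / 3),
               tolerance = 1e-12)           # sin(1.5 * pi/3) = 1
  stepped <- drive_spec(step_offset = 0.5, step_time = 10)
  expect_equal(battery_voltage(c(9.99, 10, 30), stepped),
               c(battery_voltage(9.99, drv), battery_voltage(10, drv) + 0.5,
                 1.5), tolerance = 1e-8)
})

test_that("constructors reject invalid parameters by name", {
  expect_error(task_circuit("WF", 5, -1, 5), "capacitance")
  expect_error(task_circuit("WF", -1, 0.5, 5), "resistance")
  expect_error(task_circuit("CS", 5, 10, c(10, -5)), "inductance")
  expect_error(task_circuit("CS", 5, 10, 10), "length 2")  # CS has two coils
  expect_error(coupling_params(-0.1, 0.2, 0.1), "mutual inductance")
  expect_error(drive_spec(g_decay_rate = -1), "g_decay_rate")
  expect_error(model_config(cs_drain = -0.1), "cs_drain")
  two_wf <- list(task_circuit("WF", 5, 0.5, 5), task_circuit("WF", 5, 0.5, 5),
                 task_circuit("PF", 5, 3, c(5, 5)), task_circuit("B", 10, 10, 5))
  expect_error(model_config(circuits = two_wf), "one circuit per label")
})

test_that("coupling matrix follows the printed signs and the directional M1 rule", {
  uncoupled <- model_config(coupling = coupling_params(0, 0, 0))
  expect_equal(unname(coupling_matrix(uncoupled)), diag(4))
  A <- coupling_matrix(baseline_config("second_derivative"))
  # m1_b acts on the WF row (induction originating in CS), m1_a on the CS row
  expect_equal(unname(A["WF", ]), c(1, -0.2 / 5, 0, 0))
  expect_equal(unname(A["CS", ]), c(-0.1 / 15, 1, 0.1 / 15, 0))
  expect_equal(unname(A["PF", ]), c(0, -0.1 / 10, 1, 0.1 / 10))
  expect_equal(unname(A["B", ]), c(0, 0, -0.1 / 5, 1))
  # m1_a * m1_b = L1 * (L2 + L3) makes the WF/CS block singular
  expect_error(model_config(coupling = coupling_params(5, 15, 0),
                            coupling_mode = "second_derivative"), "singular")
})

test_that("accelerations evaluate the loop equations in both modes", {
  at_rest <- system_state()
  quiet <- model_config(drive = drive_spec(v_const = 0, g_amplitude = 0))
  expect_equal(unname(accelerations(at_rest, quiet)), rep(0, 4))
  quiet_sd <- model_config(drive = drive_spec(v_const = 0, g_amplitude = 0),
                           coupling_mode = "second_derivative")
  expect_equal(unname(accelerations(at_rest, quiet_sd)), rep(0, 4))

  # charge-equivalence from rest: only V_battery(0)/L1 = 1/5 is nonzero
  expect_equal(unname(accelerations(at_rest, baseline_config())),
               c(0.2, 0, 0, 0))

  # second-derivative from rest: solve A q'' = (0.2, 0, 0, 0) independently
  sd <- baseline_config("second_derivative")
  A <- rbind(c(1, -0.04, 0, 0), c(-1 / 150, 1, 1 / 150, 0),
             c(0, -0.01, 1, 0.01), c(0, 0, -0.02, 1))
  expected <- solve(A, c(0.2, 0, 0, 0))
  got <- accelerations(at_rest, sd)
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_equal(unname(got), c(0.20005, 1.333e-3, 1.33e-5, 2.7e-7),
               tolerance = 5e-3)
})

test_that("second-derivative accelerations re-multiply to the forcing vector", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- random_config("second_derivative")
    st <- system_state(t = runif(1, 0, 10), charges = rnorm(4),
                       currents = rnorm(4))
    acc <- accelerations(st, cfg)
    # independent re-derivation of A and f from the loop equations
    cc <- cfg$circuits; cp <- cfg$coupling
    Leff <- vapply(cc, function(x) sum(x$inductances), numeric(1))
    A <- diag(4)
    A[1, 2] <- -cp$m1_b / Leff[1]
    A[2, 1] <- -cp$m1_a / Leff[2]; A[2, 3] <- cp$m2 / Leff[2]
    A[3, 2] <- -cp$m2 / Leff[3];   A[3, 4] <- cp$m2 / Leff[3]
    A[4, 3] <- -cp$m2 / Leff[4]
    vb <- battery_voltage(st$t, cfg$drive)
    Rs <- vapply(cc, function(x) x$resistance, numeric(1))
    Cs <- vapply(cc, function(x) x$capacitance, numeric(1))
    f <- (-Rs * st$currents - st$charges / Cs +
            c(vb, -cfg$cs_drain, 0, 0)) / Leff
    expect_equal(unname(drop(A %*% acc)), unname(f), tolerance = 1e-12)
  }
})

test_that("system matrices reproduce accelerations for random states", {
  set.seed(7)
  for (mode in c("charge_equivalence", "second_derivative")) {
    for (rep in 1:4) {
      cfg <- random_config(mode)
      st <- system_state(t = runif(1, 0, 5), charges = rnorm(4),
                         currents = rnorm(4))
      m <- system_matrices(cfg)
      x <- c(st$charges, st$currents)
      rhs <- drop(m$A %*% x) + m$b + m$u * battery_voltage(st$t, cfg$drive)
      expect_equal(unname(rhs), unname(c(st$currents, accelerations(st, cfg))),
                   tolerance = 1e-12)
    }
  }
})

test_that("closed-form equilibria match an independent linear solve", {
  # second-derivative mode: all coupled terms vanish with the derivatives
  expect_equal(unname(equilibrium_charges(baseline_config("second_derivative"))),
               c(0.5, 0, 0, 0))
  # uncoupled: only the driven WF circuit holds charge, in either mode
  for (mode in c("charge_equivalence", "second_derivative")) {
    cfg0 <- model_config(coupling = coupling_params(0, 0, 0),
                         coupling_mode = mode)
    expect_equal(unname(equilibrium_charges(cfg0)), c(0.5, 0, 0, 0))
  }
  # charge-equivalence: solve W = C1(V + m1b C), C = C2(m1a W - m2 P),
  # P = C3 m2 (C - B), B = C4 m2 P with an independent solver
  K <- rbind(c(1, -0.5 * 0.2, 0, 0), c(-10 * 0.1, 1, 10 * 0.1, 0),
             c(0, -3 * 0.1, 1, 3 * 0.1), c(0, 0, -10 * 0.1, 1))
  expected <- solve(K, c(0.5, 0, 0, 0))
  eq <- equilibrium_charges(baseline_config())
  expect_equal(unname(eq), expected, tolerance = 1e-12)
  expect_equal(unname(eq), c(0.5442, 0.4422, 0.1020, 0.1020), tolerance = 1e-3)
  # the equilibrium is a fixed point of the long-run dynamics
  cfg <- baseline_config()
  st <- system_state(t = 60, charges = eq, currents = rep(0, 4))
  expect_equal(unname(accelerations(st, cfg)), rep(0, 4), tolerance = 1e-12)
  # a 0.05 V drain empties the common stomach at Table-1 values
  leaky <- model_config(cs_drain = 0.05)
  expect_equal(unname(equilibrium_charges(leaky)), c(0.5, 0, 0, 0),
               tolerance = 1e-10)
})

test_that("analytic RLC solution satisfies the circuit ODE in all branches", {
  grid <- seq(0.5, 30, by = 1e-3)
  h <- 1e-3
  for (R in c(5, 2 * sqrt(5 * 2), 25)) {   # under-, critically, overdamped
    q <- analytic_rlc_charge(R, L = 5, Cap = 0.5, V = 1, q0 = 0.3, i0 = -0.1,
                             t = grid)
    expect_identical(q[1], analytic_rlc_charge(R, 5, 0.5, 1, 0.3, -0.1, 0.5))
    inner <- 2:(length(grid) - 1)
    d1 <- (q[inner + 1] - q[inner - 1]) / (2 * h)
    d2 <- (q[inner + 1] - 2 * q[inner] + q[inner - 1]) / h^2
    resid <- 5 * d2 + R * d1 + q[inner] / 0.5 - 1
    expect_lt(max(abs(resid)), 1e-4)
    # long-run charge is Cap * V regardless of initial conditions
    expect_equal(analytic_rlc_charge(R, 5, 0.5, 1, 0.3, -0.1, 500), 0.5,
                 tolerance = 1e-8)
  }
  expect_identical(analytic_rlc_charge(3, 2, 1, 0, q0 = 0.7, i0 = 0, t = 0),
                   0.7)
})

test_that("the homogeneous coupled system is stable in both modes", {
  for (mode in c("charge_equivalence", "second_derivative")) {
    A <- system_matrices(baseline_config(mode))$A
    expect_true(all(Re(eigen(A, only.values = TRUE)$values) < 0))
  }
})
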