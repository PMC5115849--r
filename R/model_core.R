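# Core model: four task-group RLC circuits coupled by mutual inductance.
# State is the charge (coulombs, interpreted as water units) and current on
# each circuit, in the fixed order WF (water foragers), CS (common stomach),
# PF (pulp foragers), B (builders).

#' Circuit labels of the four task groups
#'
#' Fixed ordering used throughout the package for charge/current vectors:
#' water foragers (WF), common stomach (CS), pulp foragers (PF), builders (B).
#'
#' @export
circuit_labels <- function() c("WF", "CS", "PF", "B")

.n_inductors <- c(WF = 1L, CS = 2L, PF = 2L, B = 1L)

.check_num <- function(x, name, len = 1L, finite = TRUE) {
  if (!is.numeric(x) || length(x) != len)
    stop(sprintf("%s must be a numeric vector of length %d", name, len), call. = FALSE)
  if (finite && !all(is.finite(x)))
    stop(sprintf("%s must be finite", name), call. = FALSE)
  as.numeric(x)
}

#' Define one task-group circuit
#'
#' Each task group (water foragers, common stomach, pulp foragers, builders)
#' is a series RLC loop: the capacitance represents the group's water-holding
#' capacity (group size), the resistance its water losses (drinking, cooling,
#' evaporation), and the inductors the coils through which it exchanges
#' water with its neighbours. The CS and PF circuits carry two coils each
#' (they face two neighbours); WF and B carry one.
#'
#' @param label one of `"WF"`, `"CS"`, `"PF"`, `"B"`.
#' @param resistance ohms, must be >= 0.
#' @param capacitance farads, must be > 0.
#' @param inductances henries; one value for WF/B, two for CS/PF, all > 0.
#' @return an object of class `task_circuit`.
#' @examples
#' task_circuit("WF", resistance = 5, capacitance = 0.5, inductances = 5)
#' @export
task_circuit <- function(label, resistance, capacitance, inductances) {
  label <- match.arg(label, circuit_labels())
  resistance <- .check_num(resistance, "resistance")
  capacitance <- .check_num(capacitance, "capacitance")
  n <- .n_inductors[[label]]
  inductances <- .check_num(inductances, "inductances", len = n)
  if (resistance < 0)
    stop(sprintf("resistance must be >= 0 for circuit %s (got %g)", label, resistance),
         call. = FALSE)
  if (capacitance <= 0)
    stop(sprintf("capacitance must be > 0 for circuit %s (got %g)", label, capacitance),
         call. = FALSE)
  if (any(inductances <= 0))
    stop(sprintf("every inductance must be > 0 for circuit %s", label), call. = FALSE)
  structure(list(label = label, resistance = resistance,
                 capacitance = capacitance, inductances = inductances),
            class = "task_circuit")
}

#' Effective inductance of a circuit (sum of its coils)
#' @param circuit a [task_circuit()].
#' @return henries.
#' @export
effective_inductance <- function(circuit) sum(circuit$inductances)

#' Mutual-inductance couplings between the circuits
#'
#' The WF--CS link is directional: `m1_a` applies when the inducing current
#' change originates in the water foragers, `m1_b` when it originates in the
#' common stomach (step-up asymmetry so that perturbations back-propagate
#' visibly into the WF circuit). `m2` couples CS--PF and PF--B symmetrically.
#'
#' @param m1_a henries, WF -> CS direction (default 0.1).
#' @param m1_b henries, CS -> WF direction (default 0.2).
#' @param m2 henries, CS <-> PF and PF <-> B (default 0.1).
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(m1_a = 0.1, m1_b = 0.2, m2 = 0.1) {
  m1_a <- .check_num(m1_a, "m1_a"); m1_b <- .check_num(m1_b, "m1_b")
  m2 <- .check_num(m2, "m2")
  if (m1_a < 0 || m1_b < 0 || m2 < 0)
    stop("all mutual inductances must be >= 0", call. = FALSE)
  structure(list(m1_a = m1_a, m1_b = m1_b, m2 = m2), class = "coupling_params")
}

#' Water-influx battery of the water-forager circuit
#'
#' The environmental water supply driving the WF loop: a steady DC term
#' `v_const` plus a transient fluctuating term
#' `g_amplitude * sin(g_angular_freq * t) * exp(-g_decay_rate * t)`, with an
#' optional step offset switched on at `step_time` (used to model a sudden
#' change in water availability; the sign of `step_offset` sets the polarity
#' with which the step enters the WF loop).
#'
#' @param v_const volts, steady supply (default 1).
#' @param g_amplitude volts, amplitude of the decaying sinusoid (default 1).
#' @param g_angular_freq radians/second (default 1.5).
#' @param g_decay_rate 1/second, must be >= 0 (default 1).
#' @param step_offset volts added from `step_time` onward (default 0).
#' @param step_time seconds, or `NULL` for no step (default).
#' @return an object of class `drive_spec`.
#' @export
drive_spec <- function(v_const = 1, g_amplitude = 1, g_angular_freq = 1.5,
                       g_decay_rate = 1, step_offset = 0, step_time = NULL) {
  v_const <- .check_num(v_const, "v_const")
  g_amplitude <- .check_num(g_amplitude, "g_amplitude")
  g_angular_freq <- .check_num(g_angular_freq, "g_angular_freq")
  g_decay_rate <- .check_num(g_decay_rate, "g_decay_rate")
  step_offset <- .check_num(step_offset, "step_offset")
  if (!is.null(step_time)) step_time <- .check_num(step_time, "step_time")
  if (g_angular_freq < 0) stop("g_angular_freq must be >= 0", call. = FALSE)
  if (g_decay_rate < 0) stop("g_decay_rate must be >= 0", call. = FALSE)
  structure(list(v_const = v_const, g_amplitude = g_amplitude,
                 g_angular_freq = g_angular_freq, g_decay_rate = g_decay_rate,
                 step_offset = step_offset, step_time = step_time),
            class = "drive_spec")
}

#' Total battery voltage at time t
#'
#' Sum of the steady and fluctuating supply terms (plus the step offset once
#' `step_time` has passed). Vectorized over `t`.
#'
#' @param t seconds, `t >= 0`.
#' @param drive a [drive_spec()].
#' @return volts, same length as `t`.
#' @examples
#' battery_voltage(0, drive_spec())     # 1: sin(0) = 0
#' battery_voltage(pi / 3, drive_spec()) # 1 + exp(-pi/3)
#' @export
battery_voltage <- function(t, drive) {
  stopifnot(inherits(drive, "drive_spec"))
  v <- drive$v_const +
    drive$g_amplitude * sin(drive$g_angular_freq * t) * exp(-drive$g_decay_rate * t)
  if (!is.null(drive$step_time))
    v <- v + drive$step_offset * (t >= drive$step_time)
  v
}

.baseline_circuits <- function() {
  list(WF = task_circuit("WF", resistance = 5, capacitance = 0.5, inductances = 5),
       CS = task_circuit("CS", resistance = 5, capacitance = 10, inductances = c(10, 5)),
       PF = task_circuit("PF", resistance = 5, capacitance = 3, inductances = c(5, 5)),
       B  = task_circuit("B",  resistance = 10, capacitance = 10, inductances = 5))
}

#' Assemble a full model configuration
#'
#' @param circuits named list with exactly one [task_circuit()] per label
#'   `WF`, `CS`, `PF`, `B` (default: the published baseline parameter set,
#'   see [baseline_config()]).
#' @param coupling a [coupling_params()].
#' @param drive a [drive_spec()].
#' @param coupling_mode `"charge_equivalence"` (default) or
#'   `"second_derivative"`; see Details.
#' @param cs_drain volts, constant drain term in the common-stomach equation
#'   modelling a leak (default 0, must be >= 0).
#'
#' @details The induced-voltage coupling between neighbouring circuits can be
#' read two ways. In `second_derivative` mode the induced term in each loop
#' equation is `M` times the neighbour's current change (second derivative of
#' its charge), which makes the accelerations implicitly coupled and requires
#' a 4x4 linear solve per evaluation. In `charge_equivalence` mode the induced
#' term is `M` times the neighbour's *charge*, which yields sustained nonzero
#' steady-state charges on the downstream circuits and is the package default.
#'
#' @return an object of class `model_config`.
#' @export
model_config <- function(circuits = .baseline_circuits(),
                         coupling = coupling_params(),
                         drive = drive_spec(),
                         coupling_mode = c("charge_equivalence", "second_derivative"),
                         cs_drain = 0) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(inherits(coupling, "coupling_params"), inherits(drive, "drive_spec"))
  if (!is.list(circuits) || length(circuits) != 4L)
    stop("circuits must be a list of four task_circuit objects", call. = FALSE)
  labs <- vapply(circuits, function(ci) {
    if (!inherits(ci, "task_circuit")) stop("each circuit must be a task_circuit", call. = FALSE)
    ci$label
  }, character(1))
  if (!setequal(labs, circuit_labels()) || anyDuplicated(labs))
    stop("exactly one circuit per label WF, CS, PF, B is required", call. = FALSE)
  circuits <- circuits[order(match(labs, circuit_labels()))]
  names(circuits) <- circuit_labels()
  cs_drain <- .check_num(cs_drain, "cs_drain")
  if (cs_drain < 0) stop("cs_drain must be >= 0", call. = FALSE)
  cfg <- structure(list(circuits = circuits, coupling = coupling, drive = drive,
                        coupling_mode = coupling_mode, cs_drain = cs_drain),
                   class = "model_config")
  if (coupling_mode == "second_derivative") {
    A <- coupling_matrix(cfg)
    if (abs(det(A)) < 1e-12)
      stop(sprintf(paste0("singular acceleration matrix: couplings m1_a=%g, ",
                          "m1_b=%g, m2=%g make the system unsolvable"),
                   coupling$m1_a, coupling$m1_b, coupling$m2), call. = FALSE)
  }
  cfg
}

#' Baseline model configuration
#'
#' The published parameter set for a medium-sized *Metapolybia* colony:
#' C = (0.5, 10, 3, 10) F, R = (5, 5, 5, 10) ohm, L1..L6 = (5, 10, 5, 5, 5, 5) H,
#' M1a = 0.1, M1b = 0.2, M2 = 0.1 H, battery V = 1 V plus
#' G(t) = sin(1.5 t) e^(-t) V.
#'
#' @param coupling_mode passed to [model_config()].
#' @param ... further arguments passed to [model_config()].
#' @return a `model_config`.
#' @export
baseline_config <- function(coupling_mode = "charge_equivalence", ...) {
  model_config(coupling_mode = coupling_mode, ...)
}

#' Instantaneous system state
#'
#' @param t seconds.
#' @param charges coulombs, length-4 vector in order (WF, CS, PF, B).
#' @param currents amperes, length-4 vector in the same order.
#' @return an object of class `system_state`.
#' @export
system_state <- function(t = 0, charges = rep(0, 4), currents = rep(0, 4)) {
  t <- .check_num(t, "t")
  charges <- .check_num(charges, "charges", len = 4L)
  currents <- .check_num(currents, "currents", len = 4L)
  names(charges) <- names(currents) <- circuit_labels()
  structure(list(t = t, charges = charges, currents = currents),
            class = "system_state")
}

#' Acceleration coupling matrix (second-derivative mode)
#'
#' When the mutually-induced second-derivative terms of the four loop
#' equations are moved to the left-hand side, the system reads `A q'' = f`.
#' This returns the dimensionless 4x4 matrix `A`. The directional WF--CS
#' rule places `m1_b` in the WF row (induction originating in CS) and `m1_a`
#' in the CS row (originating in WF).
#'
#' @param config a [model_config()].
#' @return 4x4 numeric matrix with dimnames (WF, CS, PF, B).
#' @export
coupling_matrix <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cc <- config$circuits; cp <- config$coupling
  L1 <- effective_inductance(cc$WF); Lc <- effective_inductance(cc$CS)
  Lp <- effective_inductance(cc$PF); Lb <- effective_inductance(cc$B)
  A <- rbind(
    c(1,               -cp$m1_b / L1,  0,             0),
    c(-cp$m1_a / Lc,    1,             cp$m2 / Lc,    0),
    c(0,               -cp$m2 / Lp,    1,             cp$m2 / Lp),
    c(0,                0,            -cp$m2 / Lb,    1))
  dimnames(A) <- list(circuit_labels(), circuit_labels())
  A
}

# Forcing vector f of A q'' = f: the non-second-derivative terms of the four
# loop equations, each divided by the loop's effective inductance.
.forcing_vector <- function(state, config) {
  cc <- config$circuits
  q <- state$charges; i <- state$currents
  vb <- battery_voltage(state$t, config$drive)
  Leff <- vapply(cc, effective_inductance, numeric(1))
  f <- c(
    (-cc$WF$resistance * i[1] - q[1] / cc$WF$capacitance + vb),
    (-cc$CS$resistance * i[2] - q[2] / cc$CS$capacitance - config$cs_drain),
    (-cc$PF$resistance * i[3] - q[3] / cc$PF$capacitance),
    (-cc$B$resistance  * i[4] - q[4] / cc$B$capacitance)) / Leff
  names(f) <- circuit_labels()
  f
}

#' Charge accelerations of the four circuits
#'
#' Right-hand side of the coupled second-order system. In
#' `second_derivative` mode the implicit system `A q'' = f` is solved for
#' `q''`; in `charge_equivalence` mode each induced term `M * q''_neighbour`
#' is replaced by `M * q_neighbour` and the four loop equations are evaluated
#' directly.
#'
#' @param state a [system_state()].
#' @param config a [model_config()].
#' @return length-4 numeric vector of charge accelerations (C/s^2).
#' @export
accelerations <- function(state, config) {
  stopifnot(inherits(state, "system_state"), inherits(config, "model_config"))
  if (!all(is.finite(state$charges)) || !all(is.finite(state$currents)))
    stop("non-finite entries in system state", call. = FALSE)
  if (config$coupling_mode == "second_derivative") {
    A <- coupling_matrix(config)
    f <- .forcing_vector(state, config)
    acc <- solve(A, f)
  } else {
    cc <- config$circuits; cp <- config$coupling
    q <- state$charges; i <- state$currents
    vb <- battery_voltage(state$t, config$drive)
    acc <- c(
      (cp$m1_b * q[2] - cc$WF$resistance * i[1] - q[1] / cc$WF$capacitance + vb) /
        effective_inductance(cc$WF),
      (cp$m1_a * q[1] - cp$m2 * q[3] - cc$CS$resistance * i[2] -
         q[2] / cc$CS$capacitance - config$cs_drain) / effective_inductance(cc$CS),
      (cp$m2 * q[2] - cp$m2 * q[4] - cc$PF$resistance * i[3] -
         q[3] / cc$PF$capacitance) / effective_inductance(cc$PF),
      (cp$m2 * q[3] - cc$B$resistance * i[4] - q[4] / cc$B$capacitance) /
        effective_inductance(cc$B))
  }
  names(acc) <- circuit_labels()
  acc
}

#' Closed-form steady-state charges
#'
#' Sets all first and second derivatives to zero with the drive at its
#' long-run value (`v_const`, plus `step_offset` if a step is configured;
#' the decaying sinusoid G vanishes). In `second_derivative` mode every
#' coupled term vanishes with the derivatives, so the equilibrium is
#' `(C1 * V, 0, 0, 0)`. In `charge_equivalence` mode the coupled 4-variable
#' linear algebraic system is solved.
#'
#' @param config a [model_config()].
#' @return named length-4 vector of coulombs.
#' @export
equilibrium_charges <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cc <- config$circuits; cp <- config$coupling
  v <- config$drive$v_const +
    if (!is.null(config$drive$step_time)) config$drive$step_offset else 0
  Cs <- vapply(cc, function(x) x$capacitance, numeric(1))
  if (config$coupling_mode == "second_derivative") {
    eq <- c(Cs[["WF"]] * v, 0, 0, 0)
  } else {
    # W = C1 (v + m1b C); C = C2 (m1a W - m2 P - drain); P = C3 m2 (C - B);
    # B = C4 m2 P   -> solve K q = r
    K <- rbind(
      c(1, -Cs[["WF"]] * cp$m1_b, 0, 0),
      c(-Cs[["CS"]] * cp$m1_a, 1, Cs[["CS"]] * cp$m2, 0),
      c(0, -Cs[["PF"]] * cp$m2, 1, Cs[["PF"]] * cp$m2),
      c(0, 0, -Cs[["B"]] * cp$m2, 1))
    r <- c(Cs[["WF"]] * v, -Cs[["CS"]] * config$cs_drain, 0, 0)
    if (abs(det(K)) < 1e-12)
      stop("singular equilibrium system for the given couplings", call. = FALSE)
    eq <- solve(K, r)
  }
  names(eq) <- circuit_labels()
  eq
}

#' Closed-form charge of a single driven RLC circuit
#'
#' Analytic solution of `L q'' + R q' + q/Cap = V` with initial charge `q0`
#' and current `i0`, choosing the underdamped, critically damped or
#' overdamped branch as appropriate. Used as an independent oracle for the
#' numerical integrator on an uncoupled circuit.
#'
#' @param R ohms (>= 0).
#' @param L henries (> 0).
#' @param Cap farads (> 0).
#' @param V volts (constant drive).
#' @param q0 initial charge, coulombs.
#' @param i0 initial current, amperes.
#' @param t seconds (vectorized).
#' @return coulombs, same length as `t`.
#' @export
analytic_rlc_charge <- function(R, L, Cap, V, q0, i0, t) {
  stopifnot(L > 0, Cap > 0, R >= 0)
  qp <- Cap * V                     # particular (steady-state) solution
  alpha <- R / (2 * L)
  w0sq <- 1 / (L * Cap)
  disc <- alpha^2 - w0sq
  a <- q0 - qp
  if (disc < -1e-14 * w0sq) {               # underdamped
    wd <- sqrt(-disc)
    b <- (i0 + alpha * a) / wd
    qp + exp(-alpha * t) * (a * cos(wd * t) + b * sin(wd * t))
  } else if (disc > 1e-14 * w0sq) {         # overdamped
    sq <- sqrt(disc)
    r1 <- -alpha + sq; r2 <- -alpha - sq
    c2 <- (i0 - r1 * a) / (r2 - r1)
    c1 <- a - c2
    qp + c1 * exp(r1 * t) + c2 * exp(r2 * t)
  } else {                                  # critically damped
    b <- i0 + alpha * a
    qp + (a + b * t) * exp(-alpha * t)
  }
}

#' First-order system matrices of the coupled model
#'
#' The model is linear and time-invariant apart from the known battery
#' waveform, so with state `x = (q_WF..q_B, i_WF..i_B)` the dynamics are
#' `x' = A x + b + u * V_battery(t)`. Returns the 8x8 matrix `A`, the
#' constant forcing `b` (carries the CS drain) and the drive coefficient `u`.
#' This is the representation the integrator advances; tests cross-check it
#' against [accelerations()].
#'
#' @param config a [model_config()].
#' @return list with elements `A` (8x8), `b` (length 8), `u` (length 8).
#' @export
system_matrices <- function(config) {
  stopifnot(inherits(config, "model_config"))
  cc <- config$circuits; cp <- config$coupling
  Leff <- vapply(cc, effective_inductance, numeric(1))
  Cs <- vapply(cc, function(x) x$capacitance, numeric(1))
  Rs <- vapply(cc, function(x) x$resistance, numeric(1))
  Kd <- diag(-Rs / Leff)                     # damping block (per-loop)
  if (config$coupling_mode == "second_derivative") {
    Ainv <- solve(coupling_matrix(config))
    Kq <- Ainv %*% diag(-1 / (Cs * Leff))
    Kd <- Ainv %*% Kd
    b_acc <- drop(Ainv %*% c(0, -config$cs_drain / Leff[["CS"]], 0, 0))
    u_acc <- drop(Ainv %*% c(1 / Leff[["WF"]], 0, 0, 0))
  } else {
    Kq <- diag(-1 / (Cs * Leff))
    Kq[1, 2] <- cp$m1_b / Leff[["WF"]]
    Kq[2, 1] <- cp$m1_a / Leff[["CS"]]
    Kq[2, 3] <- -cp$m2 / Leff[["CS"]]
    Kq[3, 2] <- cp$m2 / Leff[["PF"]]
    Kq[3, 4] <- -cp$m2 / Leff[["PF"]]
    Kq[4, 3] <- cp$m2 / Leff[["B"]]
    b_acc <- c(0, -config$cs_drain / Leff[["CS"]], 0, 0)
    u_acc <- c(1 / Leff[["WF"]], 0, 0, 0)
  }
  A <- rbind(cbind(matrix(0, 4, 4), diag(4)), cbind(Kq, Kd))
  nm <- c(paste0("q_", circuit_labels()), paste0("i_", circuit_labels()))
  dimnames(A) <- list(nm, nm)
  list(A = A, b = c(rep(0, 4), b_acc), u = c(rep(0, 4), u_acc))
}

#' @export
print.model_config <- function(x, ...) {
  cat("Coupled task-circuit model configuration\n")
  cat(sprintf("  coupling mode: %s   cs_drain: %g V\n", x$coupling_mode, x$cs_drain))
  for (ci in x$circuits)
    cat(sprintf("  %-2s  R = %g ohm, C = %g F, L = {%s} H\n", ci$label,
                ci$resistance, ci$capacitance,
                paste(ci$inductances, collapse = ", ")))
  cat(sprintf("  coupling: m1_a = %g, m1_b = %g, m2 = %g H\n",
              x$coupling$m1_a, x$coupling$m1_b, x$coupling$m2))
  cat(sprintf("  drive: V = %g V, G = %g sin(%g t) exp(-%g t) V\n",
              x$drive$v_const, x$drive$g_amplitude,
              x$drive$g_angular_freq, x$drive$g_decay_rate))
  if (!is.null(x$drive$step_time))
    cat(sprintf("  drive step: %+g V from t = %g s\n",
                x$drive$step_offset, x$drive$step_time))
  invisible(x)
}
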