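# Fixed-step time integration of the coupled circuit system, with event
# handling for sudden mid-run parameter changes.
#
# Within any span between events the system is linear time-invariant apart
# from the known battery waveform, so the classical RK4 step collapses to a
# precomputed one-step propagator:
#   x_{n+1} = T x_n + c_b + c1 V(t_n) + c2 V(t_n + dt/2) + c3 V(t_n + dt)
# with T = I + dtA + (dtA)^2/2 + (dtA)^3/6 + (dtA)^4/24 and forcing weights
# derived by expanding the four RK4 stages. This is algebraically identical
# to textbook RK4 on this system and is what makes long runs fast in pure R.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solver settings for the fixed-step integrator
#'
#' @param dt step size, seconds (> 0; default 0.01).
#' @param t_end end time, seconds (> 0; default 3000).
#' @param method `"rk4"` (default) or `"euler"`.
#' @param record_stride record every `record_stride`-th step (integer >= 1);
#'   `NULL` (default) picks the smallest stride that keeps at most 1e5 rows.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.01, t_end = 3000,
                            method = c("rk4", "euler"), record_stride = NULL) {
  method <- match.arg(method)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (!is.null(record_stride)) {
    record_stride <- as.integer(record_stride)
    if (record_stride < 1L) stop("record_stride must be >= 1", call. = FALSE)
  }
  structure(list(dt = dt, t_end = t_end, method = method,
                 record_stride = record_stride),
            class = "solver_settings")
}

# One-step propagator matrices for a span governed by a fixed config.
.make_propagator <- function(config, dt, method) {
  m <- system_matrices(config)
  A <- m$A
  I8 <- diag(8)
  dA <- dt * A
  dA2 <- dA %*% dA; dA3 <- dA2 %*% dA; dA4 <- dA3 %*% dA
  if (method == "rk4") {
    Tm <- I8 + dA + dA2 / 2 + dA3 / 6 + dA4 / 24
    Phi1 <- I8 + dA + dA2 / 2 + dA3 / 4
    Phi2 <- 4 * I8 + 2 * dA + dA2 / 2
    cb <- (dt / 6) * drop((Phi1 + Phi2 + I8) %*% m$b)
    c1 <- (dt / 6) * drop(Phi1 %*% m$u)
    c2 <- (dt / 6) * drop(Phi2 %*% m$u)
    c3 <- (dt / 6) * m$u
  } else {                                   # explicit Euler
    Tm <- I8 + dA
    cb <- dt * m$b
    c1 <- dt * m$u
    c2 <- rep(0, 8)
    c3 <- rep(0, 8)
  }
  list(Tm = Tm, cb = matrix(cb, 8, 1), c1 = matrix(c1, 8, 1),
       c2 = matrix(c2, 8, 1), c3 = matrix(c3, 8, 1))
}

# Advance x over global steps (n_from, n_to]; record states at global step
# indices that are multiples of `stride`. Returns final state and records.
.step_span <- function(config, x, t0, n_from, n_to, dt, stride, method) {
  n_steps <- n_to - n_from
  pr <- .make_propagator(config, dt, method)
  tn <- t0 + (n_from + 0:(n_steps - 1)) * dt
  drv <- config$drive
  V1 <- battery_voltage(tn, drv)
  if (method == "rk4") {
    V2 <- battery_voltage(tn + dt / 2, drv)
    V3 <- battery_voltage(tn + dt, drv)
  } else {
    V2 <- V3 <- numeric(n_steps)
  }
  rec_n <- seq.int(n_from + 1L, n_to)
  rec_n <- rec_n[rec_n %% stride == 0L]
  rec <- matrix(NA_real_, 8, length(rec_n))
  j <- 1L
  Tm <- pr$Tm; cb <- pr$cb; c1 <- pr$c1; c2 <- pr$c2; c3 <- pr$c3
  nxt <- if (length(rec_n)) rec_n[1L] else -1L
  for (k in seq_len(n_steps)) {
    x <- Tm %*% x + cb + c1 * V1[k] + c2 * V2[k] + c3 * V3[k]
    if (n_from + k == nxt) {
      rec[, j] <- x
      j <- j + 1L
      nxt <- if (j <= length(rec_n)) rec_n[j] else -1L
    }
  }
  if (!all(is.finite(x)))
    stop(sprintf("integration diverged (non-finite state) by t = %g s",
                 t0 + n_to * dt), call. = FALSE)
  list(x = x, rec_n = rec_n, rec = rec)
}

.new_trajectory <- function(times, states, config_history) {
  charges <- t(states[1:4, , drop = FALSE])
  currents <- t(states[5:8, , drop = FALSE])
  colnames(charges) <- colnames(currents) <- circuit_labels()
  structure(list(times = times, charges = charges, currents = currents,
                 config_history = config_history),
            class = "circuit_trajectory")
}

#' Integrate the coupled circuit model with mid-run perturbation events
#'
#' Advances the first-order system `(q, q')` span by span; each
#' [perturbation_event()] changes parameters instantaneously at its time
#' while charges and currents carry over unchanged (a removed quantity is
#' not replaced -- the state simply evolves under the new parameters).
#'
#' @param config a [model_config()].
#' @param initial a [system_state()]; its `t` is the start time.
#' @param events list of [perturbation_event()]s sorted by time; times must
#'   lie strictly inside `(0, t_end)` relative to the start and are snapped
#'   to the step grid.
#' @param settings a [solver_settings()].
#' @return an object of class `circuit_trajectory`: `times`,
#'   `charges` (rows = times, cols = WF/CS/PF/B), `currents`, and
#'   `config_history` (the config governing each span).
#' @export
integrate_with_events <- function(config, initial = system_state(),
                                  events = list(),
                                  settings = solver_settings()) {
  stopifnot(inherits(config, "model_config"),
            inherits(initial, "system_state"),
            inherits(settings, "solver_settings"))
  dt <- settings$dt
  nstep <- as.integer(round(settings$t_end / dt))
  if (nstep < 1L) stop("t_end must allow at least one step", call. = FALSE)
  stride <- settings$record_stride %||% max(1L, as.integer(ceiling(nstep / 1e5)))

  ev_times <- vapply(events, function(e) e$time, numeric(1))
  if (is.unsorted(ev_times)) stop("events must be sorted by time", call. = FALSE)
  ev_steps <- as.integer(round((ev_times - initial$t) / dt))
  if (length(ev_steps) && (any(ev_steps <= 0L) || any(ev_steps >= nstep)))
    stop("event times must lie strictly inside the integration window",
         call. = FALSE)
  # validate every event target before paying for the integration
  invisible(Reduce(apply_event, events, config))

  x <- matrix(c(initial$charges, initial$currents), 8, 1)
  t0 <- initial$t
  nrec <- as.integer(nstep %/% stride) + 1L
  times <- numeric(nrec); states <- matrix(NA_real_, 8, nrec)
  times[1] <- t0; states[, 1] <- x
  filled <- 1L

  bounds <- c(ev_steps, nstep)
  span_from <- 0L
  cfg <- config
  history <- list()
  for (si in seq_along(bounds)) {
    span_to <- bounds[si]
    if (span_to > span_from) {
      res <- .step_span(cfg, x, t0, span_from, span_to, dt, stride,
                        settings$method)
      x <- res$x
      k <- length(res$rec_n)
      if (k) {
        idx <- filled + seq_len(k)
        times[idx] <- t0 + res$rec_n * dt
        states[, idx] <- res$rec
        filled <- filled + k
      }
      history[[length(history) + 1L]] <-
        list(from = t0 + span_from * dt, to = t0 + span_to * dt, config = cfg)
      span_from <- span_to
    }
    if (si <= length(events)) cfg <- apply_event(cfg, events[[si]])
  }
  .new_trajectory(times[seq_len(filled)], states[, seq_len(filled), drop = FALSE],
                  history)
}

#' Integrate the coupled circuit model (no events)
#'
#' @inheritParams integrate_with_events
#' @return a `circuit_trajectory`; see [integrate_with_events()].
#' @examples
#' traj <- integrate_circuits(baseline_config(),
#'                            settings = solver_settings(t_end = 100))
#' tail_equilibrium(traj, window = 20)
#' @export
integrate_circuits <- function(config, initial = system_state(),
                               settings = solver_settings()) {
  integrate_with_events(config, initial, events = list(), settings = settings)
}

#' Brute-force explicit-Euler reference integrator
#'
#' A deliberately naive step-by-step explicit Euler loop over
#' `x' = A x + b + u V(t)`, independent of the propagator algebra used by
#' [integrate_circuits()]. Intended for verification at small step sizes.
#'
#' @param config a [model_config()].
#' @param initial a [system_state()].
#' @param t_end seconds.
#' @param dt_small step size, seconds (choose much smaller than the run
#'   being checked).
#' @param record_stride record every k-th step (default: about every 0.01 s).
#' @return a `circuit_trajectory`.
#' @export
euler_oracle <- function(config, initial = system_state(), t_end, dt_small,
                         record_stride = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(initial, "system_state"))
  if (dt_small <= 0) stop("dt_small must be > 0", call. = FALSE)
  nstep <- as.integer(round(t_end / dt_small))
  stride <- as.integer(record_stride %||% max(1L, round(0.01 / dt_small)))
  m <- system_matrices(config)
  A <- m$A; b <- matrix(m$b, 8, 1); u <- matrix(m$u, 8, 1)
  t0 <- initial$t
  V <- battery_voltage(t0 + (0:(nstep - 1)) * dt_small, config$drive)
  x <- matrix(c(initial$charges, initial$currents), 8, 1)
  rec_n <- seq.int(stride, nstep, by = stride)
  times <- c(t0, t0 + rec_n * dt_small)
  states <- matrix(NA_real_, 8, length(rec_n) + 1L)
  states[, 1] <- x
  j <- 2L
  nxt <- if (length(rec_n)) rec_n[1L] else -1L
  for (n in seq_len(nstep)) {
    x <- x + dt_small * (A %*% x + b + u * V[n])
    if (n == nxt) {
      states[, j] <- x
      j <- j + 1L
      nxt <- if (j <= length(rec_n) + 1L) rec_n[j - 1L] else -1L
    }
  }
  if (!all(is.finite(x)))
    stop(sprintf("Euler integration diverged by t = %g s", t0 + t_end),
         call. = FALSE)
  .new_trajectory(times, states,
                  list(list(from = t0, to = t0 + t_end, config = config)))
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Circuit trajectory: %d samples over t = [%g, %g] s, %d span(s)\n",
              n, x$times[1], x$times[n], length(x$config_history)))
  cat("final charges (C):",
      paste(sprintf("%s = %.6g", circuit_labels(), x$charges[n, ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.circuit_trajectory <- function(x, ...) {
  df <- data.frame(t = x$times, x$charges, x$currents)
  names(df) <- c("t", paste0("q_", circuit_labels()),
                 paste0("i_", circuit_labels()))
  df
}
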