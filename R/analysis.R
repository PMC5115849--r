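# Trajectory diagnostics: tail equilibria, settling times, rise ordering,
# and phase-plane contraction toward the point attractor.

.window_means <- function(traj, from, to) {
  sel <- traj$times >= from & traj$times <= to
  if (!any(sel)) stop("no samples inside the requested window", call. = FALSE)
  out <- colMeans(traj$charges[sel, , drop = FALSE])
  names(out) <- circuit_labels()
  out
}

#' Mean charge of each circuit over the trajectory's final window
#'
#' @param traj a `circuit_trajectory`.
#' @param window seconds (> 0 and at most the trajectory span).
#' @return named length-4 vector of coulombs.
#' @export
tail_equilibrium <- function(traj, window = 200) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  n <- length(traj$times)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  span <- traj$times[n] - traj$times[1]
  if (window <= 0 || (span > 0 && window > span))
    stop("window must be positive and no longer than the trajectory span",
         call. = FALSE)
  .window_means(traj, traj$times[n] - window, traj$times[n])
}

#' Settling time of a trajectory
#'
#' The earliest recorded time after which every circuit's charge stays
#' within `band_fraction * |final - initial|` of its final value, where the
#' final value is the [tail_equilibrium()] over `window`. Circuits whose net
#' transition is below `abs_floor` carry no information about settling and
#' are skipped (with a note). Returns `NA` if some circuit is still outside
#' its band at the end, and the start time if every circuit is always within
#' band.
#'
#' @param traj a `circuit_trajectory`.
#' @param band_fraction in (0, 1); default 0.02 (the 2 percent band).
#' @param window tail window for the final value, seconds.
#' @param abs_floor coulombs; minimum net transition for a circuit to count.
#' @return seconds (scalar), possibly `NA`.
#' @export
settling_time <- function(traj, band_fraction = 0.02, window = 200,
                          abs_floor = 1e-9) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  if (band_fraction <= 0 || band_fraction >= 1)
    stop("band_fraction must be in (0, 1)", call. = FALSE)
  final <- tail_equilibrium(traj, window)
  init <- traj$charges[1, ]
  trans <- abs(final - init)
  t_settle <- traj$times[1]
  any_used <- FALSE
  for (k in seq_len(4L)) {
    if (trans[k] < abs_floor) next
    any_used <- TRUE
    outside <- abs(traj$charges[, k] - final[k]) > band_fraction * trans[k]
    if (outside[length(outside)]) return(NA_real_)
    last_out <- max(which(outside), 0L)
    if (last_out > 0L)
      t_settle <- max(t_settle, traj$times[last_out + 1L])
  }
  if (!any_used)
    message("settling_time: all circuits below the transition floor; ",
            "returning the start time")
  t_settle
}

#' First half-rise time of each circuit
#'
#' Per circuit, the first time its charge crosses halfway between its
#' initial and final (tail-equilibrium) value, linearly interpolated between
#' samples. Circuits with a net transition below `abs_floor` get `NA`.
#' The delayed cascade of the baseline run (water foragers first, then the
#' common stomach, then pulp foragers and builders) shows up as increasing
#' half-rise times along the chain.
#'
#' @inheritParams settling_time
#' @return named length-4 vector of seconds (possibly `NA`).
#' @export
rise_half_times <- function(traj, window = 200, abs_floor = 1e-9) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  final <- tail_equilibrium(traj, window)
  init <- traj$charges[1, ]
  out <- rep(NA_real_, 4L)
  names(out) <- circuit_labels()
  for (k in seq_len(4L)) {
    if (abs(final[k] - init[k]) < abs_floor) next
    mid <- (init[k] + final[k]) / 2
    q <- traj$charges[, k]
    crossed <- if (final[k] > init[k]) q >= mid else q <= mid
    idx <- which(crossed)[1]
    if (is.na(idx)) next
    if (idx == 1L) {
      out[k] <- traj$times[1]
    } else {
      t1 <- traj$times[idx - 1L]; t2 <- traj$times[idx]
      q1 <- q[idx - 1L]; q2 <- q[idx]
      out[k] <- if (q2 == q1) t2 else t1 + (mid - q1) / (q2 - q1) * (t2 - t1)
    }
  }
  out
}

#' Phase-plane diagnostics for a pair of circuits
#'
#' Projects the trajectory onto the (x, y) charge plane, estimates the point
#' attractor from the trajectory tail, and reports the contraction fraction:
#' the share of consecutive steps whose Euclidean distance to the attractor
#' does not increase (1 for a trajectory that spirals monotonically inward,
#' and by convention 1 for a trajectory sitting at the attractor).
#'
#' @param traj a `circuit_trajectory`.
#' @param x,y circuit labels for the two axes (e.g. `"WF"`, `"CS"`).
#' @param window tail window used for the attractor estimate, seconds.
#' @return an object of class `phase_diagnostics`: `points` (data frame
#'   `t, q_x, q_y`), `attractor` (named length-2 vector), and
#'   `contraction_fraction` in `[0, 1]`.
#' @export
phase_diagnostics <- function(traj, x = "WF", y = "CS", window = 200) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  x <- match.arg(x, circuit_labels())
  y <- match.arg(y, circuit_labels())
  n <- length(traj$times)
  if (n == 0L) stop("empty trajectory", call. = FALSE)
  span <- traj$times[n] - traj$times[1]
  eq <- if (span <= 0) {
    stats::setNames(traj$charges[n, ], circuit_labels())
  } else {
    .window_means(traj, traj$times[n] - min(window, span), traj$times[n])
  }
  attractor <- c(x = unname(eq[x]), y = unname(eq[y]))
  px <- traj$charges[, x]; py <- traj$charges[, y]
  d <- sqrt((px - attractor[1])^2 + (py - attractor[2])^2)
  cf <- if (length(d) < 2L) 1 else mean(diff(d) <= 0)
  structure(list(points = data.frame(t = traj$times, q_x = px, q_y = py),
                 x = x, y = y, attractor = attractor,
                 contraction_fraction = cf),
            class = "phase_diagnostics")
}

#' Equilibrium summary of a trajectory
#'
#' Bundles the tail equilibrium, the settling time at the given band, and
#' the circuits ranked by decreasing equilibrium charge.
#'
#' @inheritParams settling_time
#' @return an object of class `equilibrium_summary` with fields `values`,
#'   `window`, `settling_time`, `ordering`.
#' @export
equilibrium_summary <- function(traj, window = 200, band_fraction = 0.02) {
  values <- tail_equilibrium(traj, window)
  structure(list(values = values, window = window,
                 settling_time = settling_time(traj, band_fraction, window),
                 ordering = circuit_labels()[order(-values)]),
            class = "equilibrium_summary")
}

#' @export
print.equilibrium_summary <- function(x, ...) {
  cat(sprintf("Equilibrium over final %g s window:\n", x$window))
  for (lab in circuit_labels())
    cat(sprintf("  %-2s  %.6g C\n", lab, x$values[[lab]]))
  cat("ordering (high to low):", paste(x$ordering, collapse = " > "), "\n")
  cat(sprintf("settling time (2%% band unless changed): %s s\n",
              format(x$settling_time)))
  invisible(x)
}

#' @export
print.phase_diagnostics <- function(x, ...) {
  cat(sprintf("Phase diagnostics %s vs %s: attractor (%.6g, %.6g) C, ",
              x$x, x$y, x$attractor[1], x$attractor[2]))
  cat(sprintf("contraction fraction %.4f over %d points\n",
              x$contraction_fraction, nrow(x$points)))
  invisible(x)
}
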