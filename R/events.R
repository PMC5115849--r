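# Timed perturbation events: sudden parameter changes applied mid-run.

#' Define a timed perturbation event
#'
#' @param time seconds (> 0), when the change is applied.
#' @param kind `"set_param"` (assign a new value to a parameter),
#'   `"add_drive_step"` (add a constant voltage step to the battery from
#'   `time` onward; `value` may be signed) or `"set_drain"` (set the
#'   constant common-stomach drain, volts).
#' @param target for `set_param`: a dotted parameter path resolved against
#'   the configuration, e.g. `"circuits.WF.resistance"`,
#'   `"circuits.CS.capacitance"`, `"coupling.m2"`, `"drive.v_const"`,
#'   `"cs_drain"`. Ignored for the other kinds.
#' @param value number, in the target's units.
#' @return an object of class `perturbation_event`.
#' @examples
#' perturbation_event(2000, "set_param", "circuits.CS.capacitance", 3)
#' @export
perturbation_event <- function(time, kind = c("set_param", "add_drive_step",
                                              "set_drain"),
                               target = NULL, value) {
  kind <- match.arg(kind)
  if (!is.numeric(time) || length(time) != 1L || time <= 0)
    stop("event time must be a single number > 0", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("event value must be a single finite number", call. = FALSE)
  if (kind == "set_param" && (!is.character(target) || length(target) != 1L))
    stop("set_param events need a character target path", call. = FALSE)
  structure(list(time = time, kind = kind, target = target, value = value),
            class = "perturbation_event")
}

#' Apply a perturbation event to a configuration
#'
#' Returns a new validated [model_config()] with the event's change applied;
#' the original is untouched. Used internally by [integrate_with_events()].
#'
#' @param config a [model_config()].
#' @param event a [perturbation_event()].
#' @return a `model_config`.
#' @export
apply_event <- function(config, event) {
  stopifnot(inherits(config, "model_config"), inherits(event, "perturbation_event"))
  circuits <- config$circuits
  coupling <- config$coupling
  drive <- config$drive
  cs_drain <- config$cs_drain

  if (event$kind == "add_drive_step") {
    drive$step_offset <- drive$step_offset + event$value
    drive$step_time <- if (is.null(drive$step_time)) event$time
                       else min(drive$step_time, event$time)
  } else if (event$kind == "set_drain") {
    cs_drain <- event$value
  } else {
    path <- strsplit(event$target, ".", fixed = TRUE)[[1]]
    bad <- function() stop(sprintf("unknown parameter path '%s'", event$target),
                           call. = FALSE)
    if (path[1] == "cs_drain" && length(path) == 1L) {
      cs_drain <- event$value
    } else if (path[1] == "circuits" && length(path) %in% c(3L, 4L)) {
      lab <- path[2]
      if (!lab %in% circuit_labels()) bad()
      field <- path[3]
      ci <- circuits[[lab]]
      if (field == "inductances" && length(path) == 4L) {
        idx <- suppressWarnings(as.integer(path[4]))
        if (is.na(idx) || idx < 1L || idx > length(ci$inductances)) bad()
        ci$inductances[idx] <- event$value
      } else if (field %in% c("resistance", "capacitance") && length(path) == 3L) {
        ci[[field]] <- event$value
      } else bad()
      circuits[[lab]] <- task_circuit(lab, ci$resistance, ci$capacitance,
                                      ci$inductances)
    } else if (path[1] == "coupling" && length(path) == 2L) {
      field <- path[2]
      if (!field %in% c("m1_a", "m1_b", "m2")) bad()
      coupling[[field]] <- event$value
      coupling <- coupling_params(coupling$m1_a, coupling$m1_b, coupling$m2)
    } else if (path[1] == "drive" && length(path) == 2L) {
      field <- path[2]
      if (!field %in% c("v_const", "g_amplitude", "g_angular_freq",
                        "g_decay_rate", "step_offset", "step_time")) bad()
      drive[[field]] <- event$value
      drive <- do.call(drive_spec, drive)
    } else bad()
  }
  model_config(circuits = circuits, coupling = coupling, drive = drive,
               coupling_mode = config$coupling_mode, cs_drain = cs_drain)
}

#' @export
print.perturbation_event <- function(x, ...) {
  cat(sprintf("Perturbation at t = %g s: %s %s-> %g\n", x$time, x$kind,
              if (!is.null(x$target)) paste0(x$target, " ") else "", x$value))
  invisible(x)
}
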