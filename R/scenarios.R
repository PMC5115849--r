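# Registry of in-silico perturbation experiments: each scenario is the
# baseline colony with one printed parameter change applied at t = 2000 s
# (or, for the phase-plane experiments, a modified configuration from t = 0).

.scenario_registry <- function(t_event = 2000) {
  sp <- function(target, value)
    perturbation_event(t_event, "set_param", target, value)
  list(
    remove_water_foragers = list(
      description = "Capture of water foragers: C1 0.5 -> 0.25 F, R1 5 -> 2 ohm",
      perturbed = "WF",
      events = list(sp("circuits.WF.capacitance", 0.25),
                    sp("circuits.WF.resistance", 2))),
    add_water = list(
      description = "Extra environmental water: +0.5 V step on the battery",
      perturbed = "WF",
      events = list(perturbation_event(t_event, "add_drive_step", value = 0.5))),
    remove_pulp_foragers = list(
      description = "Removal of pulp foragers: C3 3 -> 1 F, R3 5 -> 2 ohm",
      perturbed = "PF",
      events = list(sp("circuits.PF.capacitance", 1),
                    sp("circuits.PF.resistance", 2))),
    remove_builders = list(
      description = "Removal of builders: C4 10 -> 5 F, R4 10 -> 5 ohm",
      perturbed = "B",
      events = list(sp("circuits.B.capacitance", 5),
                    sp("circuits.B.resistance", 5))),
    leaky_common_stomach = list(
      description = "Leaky common stomach: constant 0.05 V drain",
      perturbed = "CS",
      events = list(perturbation_event(t_event, "set_drain", value = 0.05))),
    reduce_cs_capacity = list(
      description = "Reduced storage capacity: C2 10 -> 3 F",
      perturbed = "CS",
      events = list(sp("circuits.CS.capacitance", 3))),
    reduce_coupling_25 = list(
      description = "Couplings reduced 25%: m1_a, m2 -> 0.075 H (m1_b scaled)",
      perturbed = NA_character_,
      events = list(sp("coupling.m1_a", 0.075), sp("coupling.m1_b", 0.15),
                    sp("coupling.m2", 0.075))),
    reduce_coupling_50 = list(
      description = "Couplings reduced 50%: m1_a, m2 -> 0.05 H (m1_b scaled)",
      perturbed = NA_character_,
      events = list(sp("coupling.m1_a", 0.05), sp("coupling.m1_b", 0.10),
                    sp("coupling.m2", 0.05))),
    reduce_coupling_90 = list(
      description = "Couplings reduced 90%: m1_a, m2 -> 0.01 H (m1_b scaled)",
      perturbed = NA_character_,
      events = list(sp("coupling.m1_a", 0.01), sp("coupling.m1_b", 0.02),
                    sp("coupling.m2", 0.01))),
    reduce_m2_only = list(
      description = "CS--PF transfer hindered: m2 0.1 -> 0.05 H",
      perturbed = NA_character_,
      events = list(sp("coupling.m2", 0.05))),
    phase_low_resistance_a = list(
      description = "Phase-plane run a: R1 5 -> 1e-6 ohm from t = 0",
      perturbed = "WF",
      config_patch = function(cfg) {
        cfg$circuits$WF <- task_circuit("WF", 1e-6,
                                        cfg$circuits$WF$capacitance,
                                        cfg$circuits$WF$inductances)
        cfg
      },
      events = list()),
    phase_low_resistance_b = list(
      description = "Phase-plane run b: R2 5 -> 1e-6 ohm from t = 0",
      perturbed = "CS",
      config_patch = function(cfg) {
        cfg$circuits$CS <- task_circuit("CS", 1e-6,
                                        cfg$circuits$CS$capacitance,
                                        cfg$circuits$CS$inductances)
        cfg
      },
      events = list())
  )
}

#' List the available perturbation scenarios
#'
#' @return data frame with columns `name`, `n_events`, `description`.
#' @export
list_scenarios <- function() {
  reg <- .scenario_registry()
  data.frame(name = names(reg),
             n_events = vapply(reg, function(s) length(s$events), integer(1)),
             description = vapply(reg, function(s) s$description, character(1)),
             row.names = NULL)
}

#' Build a named perturbation scenario
#'
#' Returns the baseline configuration plus the timed events implementing the
#' scenario's parameter change (applied at `t_event`, default 2000 s). The
#' two phase-plane scenarios modify the configuration from the start and
#' carry no events.
#'
#' @param name scenario identifier; see [list_scenarios()].
#' @param t_event seconds at which perturbation events fire (default 2000).
#' @param coupling_mode passed to [baseline_config()].
#' @return list with elements `name`, `config` ([model_config()]), `events`
#'   (list of [perturbation_event()]), `perturbed` (label of the directly
#'   perturbed circuit, or `NA`), `description`.
#' @export
build_scenario <- function(name, t_event = 2000,
                           coupling_mode = "charge_equivalence") {
  reg <- .scenario_registry(t_event)
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop(sprintf("unknown scenario '%s'; valid names: %s",
                 as.character(name)[1],
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  sc <- reg[[name]]
  cfg <- baseline_config(coupling_mode = coupling_mode)
  if (!is.null(sc$config_patch)) cfg <- sc$config_patch(cfg)
  list(name = name, config = cfg, events = sc$events,
       perturbed = sc$perturbed, description = sc$description)
}

.classify_signs <- function(baseline, post, tol = 0.005, floor = 1e-9) {
  rel <- (post - baseline) / pmax(abs(baseline), floor)
  out <- ifelse(abs(rel) < tol, "unchanged",
                ifelse(rel > 0, "increase", "decrease"))
  names(out) <- circuit_labels()
  out
}

#' Run a perturbation scenario and report pre/post equilibria
#'
#' Integrates the scenario with its events, then averages each circuit's
#' charge over a window ending at the event time (pre-perturbation
#' equilibrium) and over the final window (post-perturbation equilibrium),
#' and classifies each circuit's response as increase / decrease / unchanged
#' (relative change below `sign_tol` counts as unchanged). Scenarios without
#' events use the final window for both, so all signs read "unchanged".
#'
#' @param name scenario identifier (see [list_scenarios()]).
#' @param settings a [solver_settings()]; default runs to 4000 s so the
#'   post-event span has 2000 s to re-settle.
#' @param coupling_mode coupling interpretation, default `"charge_equivalence"`.
#' @param t_event event time, seconds (default 2000).
#' @param window equilibrium averaging window, seconds (default 200).
#' @param sign_tol relative tolerance of the sign classifier (default 0.005).
#' @param keep_trajectory keep the full trajectory in the report (default
#'   TRUE; set FALSE to slim the report for serialization).
#' @return an object of class `scenario_report` with fields `name`, `mode`,
#'   `baseline_eq`, `post_eq`, `signs`, `perturbed`, `events`, `settings`,
#'   and optionally `trajectory`.
#' @export
run_scenario <- function(name, settings = solver_settings(t_end = 4000),
                         coupling_mode = "charge_equivalence",
                         t_event = 2000, window = 200, sign_tol = 0.005,
                         keep_trajectory = TRUE) {
  sc <- build_scenario(name, t_event = t_event, coupling_mode = coupling_mode)
  traj <- integrate_with_events(sc$config, system_state(), sc$events, settings)
  post_eq <- tail_equilibrium(traj, window)
  if (length(sc$events)) {
    pre <- .window_means(traj, t_event - window, t_event)
  } else {
    pre <- post_eq
  }
  rep <- structure(list(name = name, mode = coupling_mode,
                        baseline_eq = pre, post_eq = post_eq,
                        signs = .classify_signs(pre, post_eq, sign_tol),
                        perturbed = sc$perturbed,
                        description = sc$description,
                        events = sc$events, settings = settings),
                   class = "scenario_report")
  if (keep_trajectory) rep$trajectory <- traj
  rep
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s mode): %s\n", x$name, x$mode, x$description))
  for (lab in circuit_labels())
    cat(sprintf("  %-2s  %.6g -> %.6g C  (%s)\n", lab,
                x$baseline_eq[[lab]], x$post_eq[[lab]], x$signs[[lab]]))
  invisible(x)
}
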