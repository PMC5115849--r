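# Shared fixtures. Long runs are computed once per test session and cached;
# everything is built in code (the model is deterministic, no stored data).

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Baseline charge-equivalence run, long enough that the slowest mode
# (-0.0118 1/s) has fully decayed inside the final 200 s window.
baseline_traj <- function() {
  with_cache("baseline_traj",
             integrate_circuits(baseline_config(),
                                settings = solver_settings(t_end = 1500,
                                                           record_stride = 10)))
}

# Perturbation-scenario runs used by several files (dt = 0.02 keeps each run
# to a few seconds while staying far inside the RK4 accuracy budget).
scenario_run <- function(name) {
  with_cache(paste0("scenario_", name),
             run_scenario(name,
                          settings = solver_settings(dt = 0.02, t_end = 4000),
                          keep_trajectory = FALSE))
}

# Build a trajectory object directly from arrays (for the analysis tests,
# which exercise diagnostics on series with known closed forms).
synthetic_traj <- function(times, charges, currents = NULL) {
  if (is.vector(charges)) charges <- matrix(charges, length(times), 4)
  if (is.null(currents)) currents <- matrix(0, nrow(charges), 4)
  colnames(charges) <- colnames(currents) <- circuit_labels()
  structure(list(times = times, charges = charges, currents = currents,
                 config_history = list()),
            class = "circuit_trajectory")
}

# Random valid configuration for property-style checks.
random_config <- function(mode = "charge_equivalence") {
  circuits <- list(
    WF = task_circuit("WF", runif(1, 0, 10), runif(1, 0.1, 10), runif(1, 1, 10)),
    CS = task_circuit("CS", runif(1, 0, 10), runif(1, 0.1, 10), runif(2, 1, 10)),
    PF = task_circuit("PF", runif(1, 0, 10), runif(1, 0.1, 10), runif(2, 1, 10)),
    B  = task_circuit("B",  runif(1, 0, 10), runif(1, 0.1, 10), runif(1, 1, 10)))
  model_config(circuits = circuits,
               coupling = coupling_params(runif(1, 0, 0.3), runif(1, 0, 0.3),
                                          runif(1, 0, 0.3)),
               drive = drive_spec(runif(1, 0, 2), runif(1, 0, 2),
                                  runif(1, 0.5, 3), runif(1, 0.1, 2)),
               coupling_mode = mode,
               cs_drain = runif(1, 0, 0.1))
}
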