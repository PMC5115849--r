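# Configuration files (YAML), trajectory CSV serialization, JSON reports
# and run manifests.

.config_defaults <- function() {
  list(
    mode = "charge_equivalence",
    cs_drain = 0,
    circuits = list(
      WF = list(resistance = 5, capacitance = 0.5, inductances = list(5)),
      CS = list(resistance = 5, capacitance = 10, inductances = list(10, 5)),
      PF = list(resistance = 5, capacitance = 3, inductances = list(5, 5)),
      B  = list(resistance = 10, capacitance = 10, inductances = list(5))),
    coupling = list(m1_a = 0.1, m1_b = 0.2, m2 = 0.1),
    drive = list(v_const = 1, g_amplitude = 1, g_angular_freq = 1.5,
                 g_decay_rate = 1, step_offset = 0, step_time = NULL),
    solver = list(dt = 0.01, t_end = 3000, method = "rk4",
                  record_stride = NULL))
}

.deep_merge <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .deep_merge(defaults[[nm]], user[[nm]])
    else
      defaults[[nm]] <- user[[nm]]
  }
  defaults
}

.config_from_list <- function(lst) {
  circuits <- lapply(circuit_labels(), function(lab) {
    ci <- lst$circuits[[lab]]
    task_circuit(lab, ci$resistance, ci$capacitance, unlist(ci$inductances))
  })
  names(circuits) <- circuit_labels()
  model_config(
    circuits = circuits,
    coupling = coupling_params(lst$coupling$m1_a, lst$coupling$m1_b,
                               lst$coupling$m2),
    drive = drive_spec(lst$drive$v_const, lst$drive$g_amplitude,
                       lst$drive$g_angular_freq, lst$drive$g_decay_rate,
                       lst$drive$step_offset, lst$drive$step_time),
    coupling_mode = lst$mode,
    cs_drain = lst$cs_drain)
}

#' Load a model configuration from a YAML file
#'
#' Any omitted field falls back to the baseline (published) parameter set,
#' so an empty file yields [baseline_config()] exactly. Top-level sections:
#' `circuits` (per-label `resistance`, `capacitance`, `inductances`),
#' `coupling` (`m1_a`, `m1_b`, `m2`), `drive`, `mode`, `cs_drain`, and an
#' optional `solver` section read by [load_settings()].
#'
#' @param path path to a YAML config file.
#' @return a validated [model_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  .config_from_list(.deep_merge(.config_defaults(), user))
}

#' Load solver settings from the `solver` section of a YAML config
#'
#' @param path path to a YAML config file (may be the same file passed to
#'   [load_config()]).
#' @return a [solver_settings()].
#' @export
load_settings <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else NULL
  s <- .deep_merge(.config_defaults(), user)$solver
  solver_settings(dt = s$dt, t_end = s$t_end, method = s$method,
                  record_stride = s$record_stride)
}

#' Write a trajectory to CSV
#'
#' Columns `t, q_WF, q_CS, q_PF, q_B, i_WF, i_CS, i_PF, i_B`, numbers
#' written with 17 significant digits so that [read_trajectory()]
#' round-trips the arrays losslessly. Locale-independent (`.` decimal
#' separator, `,` field separator).
#'
#' @param traj a `circuit_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  header <- "t,q_WF,q_CS,q_PF,q_B,i_WF,i_CS,i_PF,i_B"
  m <- cbind(traj$times, traj$charges, traj$currents)
  lines <- if (nrow(m)) {
    apply(matrix(sprintf("%.17g", m), nrow = nrow(m)), 1L, paste,
          collapse = ",")
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return a `circuit_trajectory` (the `config_history`, which is not
#'   serialized, is empty).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  expected <- c("t", paste0("q_", circuit_labels()),
                paste0("i_", circuit_labels()))
  if (!identical(names(df), expected))
    stop("unexpected trajectory CSV header", call. = FALSE)
  .new_trajectory(df$t, t(as.matrix(df[, -1, drop = FALSE])), list())
}

.config_as_list <- function(config) {
  list(mode = config$coupling_mode,
       cs_drain = config$cs_drain,
       circuits = lapply(config$circuits, function(ci)
         list(resistance = ci$resistance, capacitance = ci$capacitance,
              inductances = as.list(ci$inductances))),
       coupling = config$coupling[c("m1_a", "m1_b", "m2")],
       drive = config$drive[c("v_const", "g_amplitude", "g_angular_freq",
                              "g_decay_rate", "step_offset", "step_time")])
}

#' Serialize a scenario report (or any report list) to JSON
#'
#' @param report a `scenario_report` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "scenario_report")) {
    report <- list(
      name = report$name, mode = report$mode,
      description = report$description,
      perturbed = report$perturbed,
      baseline_eq = as.list(report$baseline_eq),
      post_eq = as.list(report$post_eq),
      signs = as.list(report$signs),
      events = lapply(report$events, function(e)
        list(time = e$time, kind = e$kind, target = e$target,
             value = e$value)),
      settings = unclass(report$settings))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a run bit-identically: the full
#' configuration snapshot, solver settings, optional scenario name, package
#' version, and output paths.
#'
#' @param config a [model_config()].
#' @param settings a [solver_settings()].
#' @param scenario scenario name or `NULL`.
#' @param outputs named list/character of output paths.
#' @return an object of class `run_manifest`.
#' @export
run_manifest <- function(config, settings, scenario = NULL, outputs = list()) {
  structure(list(
    tool = "taskcircuits",
    version = as.character(utils::packageVersion("taskcircuits")),
    scenario = scenario,
    config = .config_as_list(config),
    settings = unclass(settings),
    outputs = as.list(outputs)),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Re-run a manifest, reproducing its outputs
#'
#' Reads a manifest written by [write_manifest()], re-executes the run it
#' describes (scenario run if a scenario name is recorded, plain simulation
#' otherwise) and rewrites the recorded trajectory/report outputs.
#'
#' @param path manifest JSON path.
#' @return list with the recomputed `trajectory` (and `report` for scenario
#'   runs), invisibly.
#' @export
run_from_manifest <- function(path) {
  mf <- jsonlite::read_json(path, simplifyVector = FALSE)
  lst <- .deep_merge(.config_defaults(), mf$config)
  config <- .config_from_list(lst)
  st <- mf$settings
  settings <- solver_settings(dt = st$dt, t_end = st$t_end, method = st$method,
                              record_stride = st$record_stride)
  out <- list()
  if (!is.null(mf$scenario)) {
    rep <- run_scenario(mf$scenario, settings = settings,
                        coupling_mode = config$coupling_mode)
    out$report <- rep
    out$trajectory <- rep$trajectory
    if (!is.null(mf$outputs$report)) write_report(rep, mf$outputs$report)
  } else {
    out$trajectory <- integrate_circuits(config, settings = settings)
  }
  if (!is.null(mf$outputs$trajectory))
    write_trajectory(out$trajectory, mf$outputs$trajectory)
  invisible(out)
}
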