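## Scenario registry: runnable experiment definitions mirroring the study's
## figure protocols, plus structured-config I/O and trace/summary writers.

.scenario_list <- function() {
  pulse200 <- function() protocol_current_pulse(114.1, onset = 0.01, duration = 0.2)
  list(
    fig2_negative_pulses = list(
      figure = "Fig 2B", preset = "fig2",
      description = "passive responses to negative current pulses (steps of 8.14 pA)",
      protocols = lapply(-(1:4) * 8.14, protocol_current_pulse,
                         onset = 0.01, duration = 0.2),
      horizon = 0.6),
    fig2_positive_pulses = list(
      figure = "Fig 2D", preset = "fig2",
      description = "peak-and-sag responses to positive current pulses (9x and 14x 8.14 pA)",
      protocols = lapply(c(9, 14) * 8.14, protocol_current_pulse,
                         onset = 0.01, duration = 0.2),
      horizon = 0.6),
    fig4_highK = list(
      figure = "Fig 4B", preset = "fig2",
      description = "Ca2+ transient under a high-K+ bath swap (+130 mM K / -130 mM Na, 10 s)",
      protocols = list(protocol_high_k(130, -130, onset = 0.5, duration = 10)),
      horizon = 60),
    fig4_highK_ER_block = list(
      figure = "Fig 4D", preset = "fig2",
      description = "high-K+ swap with ER Ca2+ handling blocked (RyR, IP3R, ER leak and SERCA zeroed)",
      overrides = list(P_RYR = 0, P_leak_ER = 0, P_IP3 = 0, P_pump_ER = 0),
      protocols = list(protocol_high_k(130, -130, onset = 0.5, duration = 10)),
      horizon = 60),
    fig5_hypotonic = list(
      figure = "Fig 5B", preset = "fig2",
      description = "hypotonic shock: bath pre-equilibrated with 30 mM mannitol (Na lowered to 115 mM), mannitol removed",
      external = list(Na = 115, mannitol = 30),
      protocols = list(protocol_hypotonic(30, onset = 0.5)),
      horizon = 60),
    fig6a_gCav12_sweep = list(
      figure = "Fig 6A", preset = "fig2",
      description = "peak membrane potential vs Cav1.2 conductance (114.1 pA, 200 ms pulse)",
      sweep = list(param = "g_Cav12",
                   values = to_si(c(0, 2, 20, 200), "mS/cm^2"),
                   labels = c("0", "2", "20", "200 mS/cm2")),
      protocols = list(pulse200()),
      horizon = 1),
    fig7c_gBKCa_sweep = list(
      figure = "Fig 7C", preset = "fig2",
      description = "membrane potential vs BKCa conductance; at zero the depolarisation runs away beyond 100 mV",
      sweep = list(param = "g_BKCa",
                   values = to_si(c(0, 0.18, 1.8, 18), "mS/cm^2"),
                   labels = c("0", "0.18", "1.8", "18 mS/cm2")),
      protocols = list(pulse200()),
      horizon = 1),
    fig9b_gCav21_sweep = list(
      figure = "Fig 9B", preset = "fig2",
      description = "Ca2+ transient vs Cav2.1 conductance (114.1 pA, 60 s pulse); at 0.2e-2 mS/cm2 the Ca2+ load exceeds 50 uM",
      sweep = list(param = "g_Cav21",
                   values = to_si(c(0, 0.2e-4, 0.2e-3, 0.2e-2), "mS/cm^2"),
                   labels = c("0", "0.2e-4", "0.2e-3", "0.2e-2 mS/cm2")),
      protocols = list(protocol_current_pulse(114.1, onset = 0.01,
                                              duration = 60)),
      horizon = 70),
    fig12_compression = list(
      figure = "Fig 12", preset = "fig2",
      description = "indentation ramp-and-hold (1 um/ms), first 100 ms of the response",
      sweep = list(param = NULL, depths_um = 3:7),
      protocols = lapply(3:7, function(d)
        protocol_compression(d, 1, onset = 0.005, hold = Inf)),
      horizon = 0.105),
    fig13_compression = list(
      figure = "Fig 13", preset = "fig2",
      description = "indentation ramp-and-hold (1 um/ms), 20 s of the response; exocytosis duration grows with depth",
      protocols = lapply(3:7, function(d)
        protocol_compression(d, 1, onset = 0.005, hold = Inf)),
      horizon = 20),
    piezo2_knockout_compression = list(
      figure = "Fig G (supplementary claim)", preset = "fig2",
      description = "5 um indentation with g_Piezo2 = 0: no depolarisation, no exocytosis response",
      overrides = list(g_Piezo2 = 0),
      protocols = list(protocol_compression(5, 1, onset = 0.005, hold = Inf)),
      horizon = 5)
  )
}

#' Scenario registry
#'
#' Named registry of runnable experiment scenarios mirroring the study's
#' figure protocols; each entry records the figure it mirrors, the parameter
#' preset, overrides and protocol(s).
#'
#' @return Named list of scenario specs.
#' @export
list_scenarios <- function() .scenario_list()

#' Run a registered scenario
#'
#' Relaxes the model to rest for the scenario's preset and bath, applies any
#' parameter overrides or sweep values, runs the protocol(s), and optionally
#' writes one trace CSV per run plus a combined summary table. Reruns are
#' deterministic: identical configuration yields identical output.
#'
#' @param name Scenario name from [list_scenarios()].
#' @param out_dir Directory for CSV output, or `NULL` (no files).
#' @param model Optional pre-relaxed `"merkel_model"` matching the
#'   scenario's preset and bath (saves the rest relaxation).
#' @param dt_out,rtol Passed to [run_protocol()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `traces` (list of `"merkel_trace"`),
#'   `summary` (data.frame, one row per run) and `files` (paths written).
#' @export
run_scenario <- function(name, out_dir = NULL, model = NULL, dt_out = NULL,
                         rtol = 1e-6, quiet = FALSE) {
  reg <- .scenario_list()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; see list_scenarios()")
  }
  spec <- reg[[name]]
  ext <- do.call(external_solution, if (is.null(spec$external)) list() else spec$external)
  if (is.null(model)) {
    if (!quiet) message("relaxing to rest (preset ", spec$preset, ") ...")
    model <- merkel_model(params = merkel_params(spec$preset), external = ext)
  }
  base_model <- model
  if (!is.null(spec$overrides)) {
    base_model <- do.call(set_params, c(list(base_model), spec$overrides))
  }
  runs <- list()
  if (!is.null(spec$sweep) && !is.null(spec$sweep$param)) {
    for (i in seq_along(spec$sweep$values)) {
      m_i <- do.call(set_params,
                     stats::setNames(list(base_model, spec$sweep$values[i]),
                                     c("", spec$sweep$param)))
      runs[[length(runs) + 1L]] <- list(
        label = paste0(spec$sweep$param, "=", spec$sweep$labels[i]),
        model = m_i, protocol = spec$protocols[[1L]])
    }
  } else {
    for (i in seq_along(spec$protocols)) {
      pr <- spec$protocols[[i]]
      lab <- if (pr$kind == "compression") {
        paste0("d0=", pr$depth * 1e6, "um")
      } else if (pr$kind == "current_pulse") {
        paste0("I=", signif(pr$I_app * 1e12, 4), "pA")
      } else pr$kind
      runs[[length(runs) + 1L]] <- list(label = lab, model = base_model,
                                        protocol = pr)
    }
  }
  traces <- list()
  rows <- list()
  files <- character()
  for (r in runs) {
    if (!quiet) message("running ", name, " [", r$label, "] ...")
    tr <- run_protocol(r$model, r$protocol, spec$horizon, dt_out = dt_out,
                       rtol = rtol)
    sm <- summarize_trace(tr)
    traces[[r$label]] <- tr
    rows[[r$label]] <- data.frame(
      scenario = name, run = r$label,
      peak_Vm_mV = sm$peak_Vm_mV, steady_Vm_mV = sm$steady_Vm_mV,
      peak_C_Ca_uM = sm$peak_C_Ca_uM,
      ca_duration_ms = sm$ca_duration_ms,
      exo_duration_ms = sm$exo_duration_ms
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0(name, "_", gsub("[^A-Za-z0-9._-]", "_",
                                                     r$label), ".csv"))
      write_trace(tr, f)
      files <- c(files, f)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, paste0(name, "_summary.csv"))
    utils::write.csv(summary, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(list(traces = traces, summary = summary, files = files))
}

#' Write a trace as CSV
#'
#' Comma-separated with a header row; time in ms, concentrations in uM,
#' membrane potential in mV, cortex stress in Pa.
#'
#' @param trace A `"merkel_trace"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

## ---- structured config ---------------------------------------------------

#' Load a model configuration
#'
#' Reads a YAML configuration carrying model parameters (each with an
#' explicit unit string) and an optional bath composition. Unknown parameter
#' keys are rejected; a unit differing from the registry unit for that
#' symbol is an error; missing keys are filled from the preset defaults with
#' a notice.
#'
#' @param path YAML file. Top-level keys: `preset` (optional, `"fig2"` or
#'   `"fig3"`), `parameters` (map of symbol to `{value, unit}`), `external`
#'   (map with `Na`, `K`, `Cl`, `Ca`, `mannitol` in mM).
#' @param quiet Suppress the filled-defaults notice.
#' @return List with `params` (`"merkel_params"`) and `external`
#'   (`"external_solution"`).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("preset", "parameters", "external")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  preset <- if (is.null(cfg$preset)) "fig2" else cfg$preset
  reg <- param_registry()
  overrides <- list()
  if (!is.null(cfg$parameters)) {
    bad <- setdiff(names(cfg$parameters), reg$name)
    if (length(bad)) {
      stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "))
    }
    for (nm in names(cfg$parameters)) {
      entry <- cfg$parameters[[nm]]
      if (is.numeric(entry) && length(entry) == 1L) {
        entry <- list(value = entry, unit = reg$unit[reg$name == nm])
      }
      if (is.null(entry$value) || is.null(entry$unit)) {
        stop("parameter '", nm, "' needs {value, unit}")
      }
      expected <- reg$unit[reg$name == nm]
      if (!identical(entry$unit, expected)) {
        stop("unit mismatch for '", nm, "': got '", entry$unit,
             "', expected '", expected, "'")
      }
      overrides[[nm]] <- to_si(entry$value, entry$unit)
    }
  }
  filled <- setdiff(reg$name, names(overrides))
  if (!quiet && length(overrides)) {
    message(length(filled), " parameter(s) filled from preset '", preset, "' defaults")
  }
  params <- do.call(merkel_params, c(list(preset = preset), overrides))
  ext <- do.call(external_solution,
                 if (is.null(cfg$external)) list() else cfg$external)
  list(params = params, external = ext)
}

#' Write a model configuration
#'
#' Serialises a parameter set (and optionally a bath) back to YAML with the
#' registry unit strings; [load_config()] of the result reproduces the
#' parameters exactly.
#'
#' @param params A `"merkel_params"`.
#' @param path Output file.
#' @param external Optional `"external_solution"`.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, external = NULL) {
  reg <- param_registry()
  plist <- lapply(seq_len(nrow(reg)), function(i) {
    list(value = from_si(params[[reg$name[i]]], reg$unit[i]),
         unit = reg$unit[i])
  })
  names(plist) <- reg$name
  out <- list(preset = params$preset, parameters = plist)
  if (!is.null(external)) out$external <- unclass(external)
  yaml::write_yaml(out, path)
  invisible(path)
}
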