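## Parameter registry.
##
## One row per model constant: the symbol used throughout the package, the
## unit the value is quoted in (channel-table convention), and the two
## published presets. "fig2" is the passive/peak-forming electrophysiology
## column, "fig3" the oscillating-cell column; they differ only where the
## table differs. Internally everything is converted to SI via unit_factor().

.param_registry <- function() {
  # name, unit, fig2, fig3
  rows <- list(
    ## plasma-membrane conductances (mS/cm^2) and capacitance
    c("g_Kv14",   "mS/cm^2", 0.25,      4),
    c("g_Kv42",   "mS/cm^2", 0.2,       0.2),
    c("g_BKCa",   "mS/cm^2", 0.18,      0.3),
    c("g_KDR",    "mS/cm^2", 0.01,      0.01),
    c("g_Cav12",  "mS/cm^2", 2,         0.8),
    c("g_Cav21",  "mS/cm^2", 0.1e-2,    0.05e-2),
    c("g_Piezo2", "mS/cm^2", 3,         3),
    c("g_Na_leak","mS/cm^2", 0.043,     0.045),
    c("g_K_leak", "mS/cm^2", 0.09,      0.09),
    c("g_Cl_leak","mS/cm^2", 0.5e-2,    0.5e-2),
    c("g_Ca_leak","mS/cm^2", 0.2e-4,    0.2e-4),
    c("C_m",      "uF/um^2", 4e-8,      2e-8),
    ## pumps / cotransporters / exchangers
    c("P_NaKpump","mol/(cm^2.ms)",      0.37312e-12, 0.1696e-12),
    c("P_NKCC1",  "cm^10/(mol^3.ms)",   0.24e2,      0.24e2),
    c("P_KCC2",   "mol/(cm^2.ms.mM^2)", 0.25e-14,    0.25e-14),
    c("P_Capump", "mol/(cm^2.ms)",      0.3e-15,     150 * 0.3e-15),
    c("P_Cana",   "mol/(cm^2.ms)",      0.1e-12,     0.1e-12),
    c("K_Na_NaK", "mM", 10,   10),
    c("K_K_NaK",  "mM", 140,  140),
    c("K_Capump", "uM", 0.3,  0.3),
    c("K_mNa",    "mM", 87.5, 87.5),
    c("K_mCa",    "uM", 0.5,  0.5),
    c("eta",      "1",  0.1,  0.1),
    c("k_sat",    "1",  0.35, 0.35),
    c("K_BKCa",   "mM", 1,    1),
    c("K_hCa",    "uM", 1,    1),
    ## Piezo2 state machine
    c("sigma_s1", "Pa", 1450, 1450),
    c("sigma_f1", "Pa", 120,  120),
    c("sigma_s2", "Pa", 1450, 1450),
    c("sigma_f2", "Pa", 40,   40),
    c("sigma_s4", "Pa", 1450, 1450),
    c("sigma_f4", "Pa", 100,  100),
    c("sigma_s7", "Pa", 1450, 1450),
    c("sigma_f7", "Pa", 200,  200),
    c("sigma_s8", "Pa", 1450, 1450),
    c("sigma_f8", "Pa", 2000, 2000),
    c("E_Piezo2", "mV", 6,    6),
    ## ER / mitochondria
    c("P_pump_ER","mol/(cm^2.ms)", 0.7e-17, 0.7e-17),
    c("K_ERpump", "uM", 0.1, 0.1),
    c("P_RYR",    "cm/ms", 8.5, 8.5),
    c("K_s_RYR",  "uM", 0.3,  0.3),
    c("K_f_RYR",  "uM", 0.04, 0.04),
    c("P_leak_ER","cm/ms", 0.7e-3, 0.7e-3),
    c("P_IP3",    "cm/ms", 1.75, 1.75),
    c("K_IP3",    "uM", 3,    3),
    c("K_s1_IP3", "uM", 0.4,  0.4),
    c("K_f1_IP3", "uM", 0.04, 0.04),
    c("K_s2_IP3", "uM", 0.6,  0.6),
    c("K_f2_IP3", "uM", 0.04, 0.04),
    c("tau_m_IP3","ms", 10000, 10000),
    c("tau_h_IP3","ms", 20000, 20000),
    c("k_IP3",    "1/ms", 4e-5, 4e-5),
    c("k_dIP3",   "1/ms", 2e-5, 2e-5),
    c("K_IP3Ca",  "uM", 0.5, 0.5),
    c("k_preIP3", "mol/(cm^3.ms)", 1e-12, 1e-12),
    c("K_s_preIP3","uM", 5, 5),
    c("K_f_preIP3","uM", 1, 1),
    c("P_MCU",    "mol/(cm^2.ms)", 0.5e-15, 0.5e-15),
    c("K_MCU",    "uM", 0.6, 0.6),
    c("P_MNCX",   "mol/(cm^2.ms)", 0.1e-15, 0.1e-15),
    c("K_MNCX",   "uM", 1, 1),
    c("S_ER",     "um^2", 150, 150),
    c("V_ER",     "um^3", 100, 100),
    c("S_MT",     "um^2", 150, 150),
    c("V_MT",     "um^3", 10, 10),
    c("beta_MT",  "1", 0.3, 0.3),
    ## mechanics
    c("alpha_water", "cm/(ms.Pa)", 1e-9, 1e-9),
    c("K_cortex",    "Pa", 6000, 6000),
    c("sigma_a",     "Pa", -100, -100),
    c("h_c",         "um", 0.5, 0.5),
    c("r_ini",       "um", 7, 7),
    ## vesicle cycle
    c("k_ve",     "1/ms", 0.1, 0.1),
    c("n_ve_s",   "count", 500, 500),
    c("n_ve_f",   "count", 50, 50),
    c("k_exo",    "1/ms", 2e-4, 2e-4),
    c("c_Ca_s",   "uM", 0.2, 0.2),
    c("c_Ca_f",   "uM", 0.01, 0.01),
    c("r_ve",     "um", 0.05, 0.05),
    c("k_endo",   "1/ms", 1, 1),
    c("sigma_ve_s","Pa", 1000, 1000),
    c("sigma_ve_f","Pa", 15, 15),
    ## thermodynamics
    c("T", "K", 310, 310)
  )
  data.frame(
    name = vapply(rows, `[`, "", 1L),
    unit = vapply(rows, `[`, "", 2L),
    fig2 = as.numeric(vapply(rows, `[`, "", 3L)),
    fig3 = as.numeric(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Model parameter registry
#'
#' The full table of model constants: symbol, the unit its published value is
#' quoted in, and the two presets (`"fig2"`, `"fig3"`) corresponding to the
#' two columns of the ion-channel parameter table.
#'
#' @return A data.frame with columns `name`, `unit`, `fig2`, `fig3`.
#' @export
param_registry <- function() .param_registry()

.param_positive <- c(
  "K_Na_NaK", "K_K_NaK", "K_Capump", "K_mNa", "K_mCa", "K_BKCa", "K_hCa",
  "K_ERpump", "K_s_RYR", "K_f_RYR", "K_IP3", "K_s1_IP3", "K_f1_IP3",
  "K_s2_IP3", "K_f2_IP3", "tau_m_IP3", "tau_h_IP3", "K_IP3Ca",
  "K_s_preIP3", "K_f_preIP3", "K_MCU", "K_MNCX", "S_ER", "V_ER", "S_MT",
  "V_MT", "K_cortex", "h_c", "r_ini", "C_m", "T",
  "sigma_f1", "sigma_f2", "sigma_f4", "sigma_f7", "sigma_f8"
)
.param_nonnegative <- c(
  "g_Kv14", "g_Kv42", "g_BKCa", "g_KDR", "g_Cav12", "g_Cav21", "g_Piezo2",
  "g_Na_leak", "g_K_leak", "g_Cl_leak", "g_Ca_leak", "P_NaKpump", "P_NKCC1",
  "P_KCC2", "P_Capump", "P_Cana", "P_pump_ER", "P_RYR", "P_leak_ER", "P_IP3",
  "k_IP3", "k_dIP3", "k_preIP3", "P_MCU", "P_MNCX", "beta_MT", "k_ve",
  "n_ve_s", "n_ve_f", "k_exo", "c_Ca_s", "c_Ca_f", "r_ve", "k_endo",
  "sigma_ve_s", "sigma_ve_f", "eta", "k_sat", "alpha_water"
)

#' Model parameters
#'
#' Builds the complete constant set of the Merkel-cell model in internal SI
#' units, starting from one of the two published presets and applying any
#' overrides. Overrides are given in internal SI units (use [to_si()] to
#' convert from table units); use [load_config()] to supply values with
#' explicit unit strings instead.
#'
#' @param preset `"fig2"` (default) or `"fig3"`, the two columns of the
#'   ion-channel parameter table.
#' @param ... Named overrides in internal SI units, e.g. `g_BKCa = 0`.
#' @param literal_ip3ca Use the literally printed (unsquared) dissociation
#'   constant in the IP3 production term instead of the dimensionally
#'   consistent squared form. Default `FALSE`.
#' @param literal_vesicle_sign Use the literally printed orientation of the
#'   vesicle-synthesis sigmoid (increasing in the pool size) instead of the
#'   text's "inversely related" orientation. Default `FALSE`.
#' @param ryr_ramp_width Width (mol/m^3) of the C1 ramp that continuously
#'   switches the ryanodine-receptor flux on at its activation threshold
#'   inside the whole-cell integrator; the piecewise release law is
#'   discontinuous as written, which makes a stiff solver chatter at the
#'   threshold. Default 2e-6 (0.002 uM, under 1% of the threshold).
#' @return A named list of class `"merkel_params"`, all values in internal SI.
#' @examples
#' p <- merkel_params()
#' p$g_Kv14              # 2.5 S/m^2 (= 0.25 mS/cm^2)
#' p2 <- merkel_params(g_BKCa = 0)
#' @export
merkel_params <- function(preset = c("fig2", "fig3"), ...,
                          literal_ip3ca = FALSE,
                          literal_vesicle_sign = FALSE,
                          ryr_ramp_width = 2e-6) {
  preset <- match.arg(preset)
  reg <- .param_registry()
  vals <- reg[[preset]] * unit_factor(reg$unit)
  p <- as.list(vals)
  names(p) <- reg$name
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("parameter overrides must be named")
    }
    unknown <- setdiff(names(dots), reg$name)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  p$literal_ip3ca <- isTRUE(literal_ip3ca)
  p$literal_vesicle_sign <- isTRUE(literal_vesicle_sign)
  stopifnot(ryr_ramp_width > 0)
  p$ryr_ramp_width <- ryr_ramp_width
  p$preset <- preset
  class(p) <- "merkel_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks sign constraints: conductances and rate constants must be
#' non-negative, dissociation constants, geometry and time constants strictly
#' positive.
#'
#' @param p A `"merkel_params"` object (or plain named list).
#' @return `p`, invisibly; errors listing offending names otherwise.
#' @export
validate_params <- function(p) {
  num <- vapply(
    .param_registry()$name,
    function(nm) {
      v <- p[[nm]]
      if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) NA_real_ else v
    },
    numeric(1)
  )
  if (anyNA(num)) {
    stop("missing or non-finite parameter(s): ",
         paste(names(num)[is.na(num)], collapse = ", "))
  }
  bad_pos <- .param_positive[num[.param_positive] <= 0]
  bad_nn <- .param_nonnegative[num[.param_nonnegative] < 0]
  if (length(bad_pos) || length(bad_nn)) {
    stop("parameter constraint violations: ",
         paste(c(
           if (length(bad_pos)) paste0(bad_pos, " must be > 0"),
           if (length(bad_nn)) paste0(bad_nn, " must be >= 0")
         ), collapse = "; "))
  }
  invisible(p)
}

#' @export
print.merkel_params <- function(x, ...) {
  reg <- .param_registry()
  cat("Merkel-cell model parameters (preset '", x$preset, "')\n", sep = "")
  tab <- data.frame(
    name = reg$name,
    value = from_si(unlist(x[reg$name], use.names = FALSE), reg$unit),
    unit = reg$unit
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' External bathing solution
#'
#' Ionic composition of the extracellular solution, plus an impermeant
#' osmolyte (mannitol) used by the hypotonic-shock protocol. Concentrations
#' in mM (mol/m^3).
#'
#' @param Na,K,Cl,Ca Extracellular ion concentrations (mM).
#' @param mannitol Impermeant external osmolyte (mM); enters the osmotic
#'   balance only.
#' @return Named list of class `"external_solution"`.
#' @examples
#' external_solution()                     # standard bath
#' external_solution(Na = 115, mannitol = 30)  # hypotonic-shock baseline
#' @export
external_solution <- function(Na = 145, K = 5, Cl = 110, Ca = 2,
                              mannitol = 0) {
  v <- c(Na = Na, K = K, Cl = Cl, Ca = Ca, mannitol = mannitol)
  if (any(!is.finite(v)) || any(v[c("Na", "K", "Cl", "Ca")] <= 0) || mannitol < 0) {
    stop("external concentrations must be positive (mannitol >= 0)")
  }
  structure(as.list(v), class = "external_solution")
}
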