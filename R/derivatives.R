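## Whole-cell ODE right-hand side. The full dynamic state (28 variables):
## ion amounts, membrane potential, channel gating, Piezo2 states, store
## contents, IP3 turnover, volume, reference surface, vesicle pool.

.state_names <- c(
  "n_Na", "n_K", "n_Cl", "n_Ca",            # cytosolic amounts (mol)
  "Vm",                                     # membrane potential (V)
  "m_Kv14", "hf_Kv14", "hs_Kv14",           # Kv1.4 gating
  "m_Kv42", "h_Kv42",                       # Kv4.2
  "n_BKCa", "n_KDR",                        # BKCa, KDR
  "m_Cav12", "h_Cav12", "n_Cav21",          # Cav1.2, Cav2.1
  "pz_C", "pz_O", "pz_In", "pz_hslow",      # Piezo2 states
  "n_Ca_ER", "n_Ca_MT",                     # store contents (mol)
  "C_IP3", "C_preIP3",                      # IP3 turnover (mol/m^3)
  "m_IP3", "h_IP3",                         # IP3R gates
  "V", "S_ref",                             # volume (m^3), ref. surface (m^2)
  "n_ve"                                    # vesicle pool (count)
)

.flux_names <- c(
  "Kv1.4", "Kv4.2", "BKCa", "KDR", "Cav1.2", "Cav2.1", "Piezo2",
  "Na_leak", "K_leak", "Cl_leak", "Ca_leak",
  "NaK_pump", "NKCC1", "KCC2", "Ca_pump", "NCX",
  "SERCA", "RyR", "IP3R", "MCU", "MNCX", "water"
)

## charge carried into the cell per unit of each (positive-inward) flux,
## as booked by the membrane-potential balance; transporter entries are the
## net charge per cycle. Electro-neutral pathways carry 0.
.flux_charge <- c(
  "Kv1.4" = 1, "Kv4.2" = 1, "BKCa" = 1, "KDR" = 1,
  "Cav1.2" = 2, "Cav2.1" = 2, "Piezo2" = 2,
  "Na_leak" = 1, "K_leak" = 1, "Cl_leak" = -1, "Ca_leak" = 2,
  "NaK_pump" = -1, "NKCC1" = 0, "KCC2" = 0, "Ca_pump" = -2, "NCX" = -1,
  "SERCA" = 0, "RyR" = 0, "IP3R" = 0, "MCU" = 0, "MNCX" = 0, "water" = 0
)

## environment-based evaluation context: all model parameters plus the
## per-segment stimulus fields live in E (hashed lookup).
.make_ctx <- function(model, seg) {
  E <- list2env(unclass(model$params), hash = TRUE)
  E$n_A <- model$n_A
  E$z_A <- model$z_A
  E$I_app <- seg$I_app
  E$ext_Na <- seg$ext$Na
  E$ext_K <- seg$ext$K
  E$ext_Cl <- seg$ext$Cl
  E$ext_Ca <- seg$ext$Ca
  E$ext_man <- seg$ext$mannitol
  E$d0 <- seg$d0
  E$d_rate <- seg$d_rate
  E$t_seg0 <- seg$t0
  E$loading <- identical(seg$phase, "loading")
  E$depth_max <- 2 * model$params$r_ini * 0.999
  E
}

## core evaluation: derivatives + pathway fluxes + mechanical diagnostics
.cell_core <- function(t, y, E) {
  y <- unname(y)
  Vol <- y[26L]; S_ref <- y[27L]
  Vcyt <- Vol - E$V_ER - E$V_MT
  if (!is.finite(Vcyt) || Vcyt <= 0) stop("invalid state: cytosolic volume <= 0")
  cNa <- y[1L] / Vcyt; cK <- y[2L] / Vcyt; cCl <- y[3L] / Vcyt
  cCa <- y[4L] / Vcyt
  if (cNa <= 0 || cK <= 0 || cCl <= 0) stop("invalid state: non-positive ion concentration")
  cCap <- max(cCa, 1e-12)   # numerical floor for log/power rate laws
  Vm <- y[5L]
  Tt <- E$T
  rtf <- GAS_CONSTANT * Tt / FARADAY

  ## --- geometry / mechanics ---
  d <- E$d0 + E$d_rate * (t - E$t_seg0)
  if (d < 0) d <- 0
  if (d > E$depth_max) d <- E$depth_max
  if (d > 0) {
    H <- 2 * E$r_ini - d
    r_eff <- sqrt(Vol / (pi * H))
    S <- 2 * pi * r_eff * r_eff + 2 * pi * r_eff * H
  } else {
    r_eff <- (3 * Vol / (4 * pi))^(1 / 3)
    S <- 4 * pi * r_eff * r_eff
  }
  sigma <- E$K_cortex / 2 * (S / S_ref - 1) - E$sigma_a
  dP <- 2 * E$h_c * sigma / r_eff
  cA <- E$n_A / Vcyt
  dPi <- GAS_CONSTANT * Tt *
    ((cNa + cK + cCl + cCa + cA) -
       (E$ext_Na + E$ext_K + E$ext_Cl + E$ext_Ca + E$ext_man))
  Jw <- -E$alpha_water * (dP - dPi)

  ## --- reversal potentials ---
  E_Na <- -rtf * log(cNa / E$ext_Na)
  E_K <- -rtf * log(cK / E$ext_K)
  E_Cl <- rtf * log(cCl / E$ext_Cl)
  E_Ca <- -rtf / 2 * log(cCap / E$ext_Ca)

  ## --- gating kinetics (published fits in mV/ms) ---
  vmv <- Vm * 1e3
  r14 <- .kv14_rates(vmv)
  r42 <- .kv42_rates(vmv)
  rbk <- .bkca_rates(vmv, cCap, E$K_BKCa)
  rdr <- .kdr_rates(vmv)
  r12 <- .cav12_rates(vmv)
  r21 <- .cav21_rates(vmv)
  hCa <- 1 / (1 + (cCap / E$K_hCa)^4)

  ## --- channel fluxes (positive into the cytosol) ---
  po_Kv14 <- y[6L]^4 * (0.7 * y[7L] + 0.3 * y[8L])
  J_Kv14 <- -E$g_Kv14 * po_Kv14 * (Vm - E_K) / FARADAY
  J_Kv42 <- -E$g_Kv42 * y[9L] * y[10L] * (Vm - E_K) / FARADAY
  J_BK <- -E$g_BKCa * y[11L] * (Vm - E_K) / FARADAY
  J_KDR <- -E$g_KDR * y[12L] * (Vm - E_K) / FARADAY
  J_Cav12 <- -E$g_Cav12 * y[13L] * y[14L] * hCa * (Vm - E_Ca) / FARADAY
  J_Cav21 <- -E$g_Cav21 * y[15L] * (Vm - E_Ca) / FARADAY
  J_pz <- -E$g_Piezo2 * y[17L] * y[19L] * (Vm - E$E_Piezo2) / FARADAY
  J_Na_l <- -E$g_Na_leak * (Vm - E_Na) / FARADAY
  J_K_l <- -E$g_K_leak * (Vm - E_K) / FARADAY
  J_Cl_l <- E$g_Cl_leak * (Vm - E_Cl) / FARADAY
  J_Ca_l <- -E$g_Ca_leak * (Vm - E_Ca) / FARADAY

  ## --- pumps / cotransporters / exchangers ---
  J_pump <- E$P_NaKpump * (1 + E$K_Na_NaK / cNa)^-3 * (1 + cK / E$K_K_NaK)^-2
  J_nkcc <- E$P_NKCC1 * (E$ext_Na * E$ext_K * E$ext_Cl^2 - cNa * cK * cCl^2)
  J_kcc <- E$P_KCC2 * (cK * cCl - E$ext_K * E$ext_Cl)
  J_pmca <- E$P_Capump * cCa^2 / (cCa^2 + E$K_Capump^2)
  vf <- Vm / rtf
  e1 <- exp(E$eta * vf); e2 <- exp((E$eta - 1) * vf)
  J_ncx <- E$P_Cana *
    (e1 * cNa^3 * E$ext_Ca - e2 * E$ext_Na^3 * cCa) /
    ((E$K_mNa^3 + E$ext_Na^3) * (E$K_mCa + E$ext_Ca) * (1 + E$k_sat * e2))

  ## --- organelle stores ---
  cER <- y[20L] / E$V_ER
  cMT <- y[21L] / E$V_MT
  cIP3 <- y[22L]; cPre <- y[23L]
  J_serca <- E$P_pump_ER * cCa^2 / (cCa^2 + E$K_ERpump^2)
  ## the ryanodine threshold is discontinuous as written (the sigmoid is 1/2
  ## at threshold); a narrow C1 ramp keeps the flux continuous so the stiff
  ## solver can cross the threshold without chattering
  J_ryr <- if (cCa > E$K_s_RYR) {
    x <- (cCa - E$K_s_RYR) / E$ryr_ramp_width
    ramp <- if (x >= 1) 1 else x * x * (3 - 2 * x)
    E$P_RYR / (1 + exp(-(cCa - E$K_s_RYR) / E$K_f_RYR)) * ramp * (cER - cCa)
  } else 0
  hillIP3 <- cIP3^3 / (cIP3^3 + E$K_IP3^3)
  J_ip3r <- (E$P_leak_ER + E$P_IP3 * hillIP3 * y[24L] * y[25L]) * (cER - cCa)
  mcu_act <- cCap^2.3
  J_mcu <- E$P_MCU * mcu_act / (mcu_act + E$K_MCU^2.3)
  J_mncx <- E$P_MNCX * cMT / (cMT + E$K_MNCX)

  ## IP3 / precursor turnover
  kc <- if (E$literal_ip3ca) cCa^2 / (cCa^2 + E$K_IP3Ca) else cCa^2 / (cCa^2 + E$K_IP3Ca^2)
  ip3_prod <- E$k_IP3 * kc * cPre
  dIP3 <- ip3_prod - E$k_dIP3 * cIP3
  dPre <- E$k_preIP3 / (1 + exp((cPre - E$K_s_preIP3) / E$K_f_preIP3)) - ip3_prod

  ## IP3R slow gates
  m_inf <- 1 / (1 + exp(-(cCa - E$K_s1_IP3) / E$K_f1_IP3))
  h_inf <- 1 / (1 + exp((cCa - E$K_s2_IP3) / E$K_f2_IP3))

  ## --- Piezo2 state machine ---
  C_inf <- 1 / (1 + exp((sigma - E$sigma_s1) / E$sigma_f1))
  In_inf <- 1 - C_inf
  hs_inf <- 1 / (1 + exp(-(sigma - E$sigma_s7) / E$sigma_f7))
  tau_C <- (0.5 + 1.5 / (1 + exp(-(sigma - E$sigma_s2) / E$sigma_f2))) * 1e-3
  tau_O <- (2.5 + 5.5 / (1 + exp(-(sigma - E$sigma_s4) / E$sigma_f4))) * 1e-3
  tau_hs <- (150 / (1 + exp((sigma - E$sigma_s8) / E$sigma_f8))) * 1e-3
  pzC <- y[16L]; pzO <- y[17L]
  if (E$loading && C_inf <= pzC) {
    dpzC <- (C_inf - pzC) / tau_C
    dpzIn <- pzO / tau_O
    dpzO <- -dpzC - dpzIn
  } else if (E$loading) {
    C_t <- C_inf
    if (C_t > 1 - pzO) C_t <- 1 - pzO
    dpzC <- (C_t - pzC) / tau_C
    dpzO <- -pzO / tau_O
    dpzIn <- -dpzC - dpzO
  } else {
    # In recovers toward its steady value, limited to the pool not held open
    In_t <- In_inf
    if (In_t > 1 - pzO) In_t <- 1 - pzO
    dpzIn <- (In_t - y[18L]) / tau_C
    dpzC <- -dpzIn
    dpzO <- 0
  }
  dpzHs <- (hs_inf - y[19L]) / tau_hs

  ## --- vesicle cycle ---
  n_ve <- y[28L]
  exo_sig <- 1 / (1 + exp(-(cCa - E$c_Ca_s) / E$c_Ca_f))
  exo <- E$k_exo * exo_sig * n_ve
  syn_arg <- (n_ve - E$n_ve_s) / E$n_ve_f
  syn <- if (E$literal_vesicle_sign) E$k_ve / (1 + exp(-syn_arg)) else E$k_ve / (1 + exp(syn_arg))
  endo <- E$k_endo / (1 + exp((sigma - E$sigma_ve_s) / E$sigma_ve_f))

  ## --- balances ---
  dnNa <- S_ref * (-3 * J_pump + J_nkcc - 3 * J_ncx + J_Na_l)
  dnK <- S_ref * (J_Kv14 + J_Kv42 + J_KDR + J_BK + 2 * J_pump + J_nkcc -
                    J_kcc + J_K_l)
  dnCl <- S_ref * (2 * J_nkcc - J_kcc + J_Cl_l)
  dnCa <- S_ref * (J_Cav12 + J_Cav21 - J_pmca + J_ncx + J_pz + J_Ca_l) +
    E$S_ER * (J_ip3r + J_ryr - J_serca) +
    E$S_MT / (1 + E$beta_MT) * (J_mncx - J_mcu)
  dnER <- E$S_ER * (J_serca - J_ip3r - J_ryr)
  dnMT <- E$S_MT / (1 + E$beta_MT) * (J_mcu - J_mncx)
  dVm <- (FARADAY * (J_Kv14 + J_Kv42 + J_KDR + J_BK +
                       2 * (J_Cav12 + J_Cav21 + J_pz) -
                       J_pump - J_ncx - 2 * J_pmca +
                       J_K_l + J_Na_l - J_Cl_l + 2 * J_Ca_l) +
            E$I_app / S_ref) / E$C_m

  dy <- c(
    dnNa, dnK, dnCl, dnCa, dVm,
    (r14[["minf"]] - y[6L]) / r14[["taum"]],
    (r14[["hinf"]] - y[7L]) / r14[["tauhf"]],
    (r14[["hinf"]] - y[8L]) / r14[["tauhs"]],
    (r42[["minf"]] - y[9L]) / r42[["taum"]],
    (r42[["hinf"]] - y[10L]) / r42[["tauh"]],
    (rbk[["ninf"]] - y[11L]) / rbk[["taun"]],
    (rdr[["ninf"]] - y[12L]) / rdr[["taun"]],
    (r12[["minf"]] - y[13L]) / r12[["taum"]],
    (r12[["hinf"]] - y[14L]) / r12[["tauh"]],
    (r21[["ninf"]] - y[15L]) / r21[["taun"]],
    dpzC, dpzO, dpzIn, dpzHs,
    dnER, dnMT,
    dIP3, dPre,
    (m_inf - y[24L]) / E$tau_m_IP3,
    (h_inf - y[25L]) / E$tau_h_IP3,
    S * Jw,
    4 * pi * E$r_ve^2 * (exo - endo),
    syn - exo
  )
  fluxes <- c(J_Kv14, J_Kv42, J_BK, J_KDR, J_Cav12, J_Cav21, J_pz,
              J_Na_l, J_K_l, J_Cl_l, J_Ca_l,
              J_pump, J_nkcc, J_kcc, J_pmca, J_ncx,
              J_serca, J_ryr, J_ip3r, J_mcu, J_mncx, Jw)
  if (!all(is.finite(fluxes))) {
    stop("non-finite flux in pathway(s): ",
         paste(.flux_names[!is.finite(fluxes)], collapse = ", "))
  }
  list(dy = dy, fluxes = fluxes,
       aux = c(sigma = sigma, S = S, dP = dP, dPi = dPi, d = d,
               Vcyt = Vcyt, exo = exo, endo = endo, I_app = E$I_app,
               E_Na = E_Na, E_K = E_K, E_Cl = E_Cl, E_Ca = E_Ca))
}

.segment_for <- function(segs, t) {
  for (s in segs) if (t >= s$t0 && t < s$t1) return(s)
  segs[[length(segs)]]
}

#' Full state derivative
#'
#' Assembles the complete time derivative of the whole-cell state at time
#' `t` under a stimulus protocol: all ion and store balances, the
#' charge/membrane-potential equation (with injected current when a current
#' protocol is active), gating, Piezo2, IP3, volume, reference-surface and
#' vesicle dynamics.
#'
#' @param state Named numeric state vector (see [cell_state_template()]).
#' @param protocol A `"merkel_protocol"`.
#' @param t Time (s).
#' @param model A `"merkel_model"`.
#' @return Named derivative vector (per second), with the pathway fluxes
#'   attached as attribute `"fluxes"` and mechanical diagnostics as `"aux"`.
#' @export
assemble_derivatives <- function(state, protocol, t, model) {
  y <- .as_state_vector(state)
  segs <- protocol_segments(protocol, max(t, 1) * 2 + 1, model$external)
  seg <- .segment_for(segs, t)
  out <- .cell_core(t, y, .make_ctx(model, seg))
  dy <- out$dy
  names(dy) <- .state_names
  if (!all(is.finite(dy))) {
    stop("non-finite derivative component(s): ",
         paste(.state_names[!is.finite(dy)], collapse = ", "))
  }
  attr(dy, "fluxes") <- stats::setNames(out$fluxes, .flux_names)
  attr(dy, "aux") <- out$aux
  dy
}

#' Pathway fluxes at one instant
#'
#' Named molar flux densities of every membrane and store pathway (positive
#' into the cytosol for membrane pathways; store/pump pathways in their
#' stated directions), plus mechanical diagnostics, evaluated from a state
#' under a protocol.
#'
#' @inheritParams assemble_derivatives
#' @return Named numeric vector of fluxes (mol m^-2 s^-1; `water` in m/s)
#'   with attribute `"aux"`.
#' @export
flux_vector <- function(state, protocol, t, model) {
  dy <- assemble_derivatives(state, protocol, t, model)
  fl <- attr(dy, "fluxes")
  attr(fl, "aux") <- attr(dy, "aux")
  fl
}

.as_state_vector <- function(state) {
  y <- unlist(state, use.names = TRUE)
  if (length(y) != length(.state_names)) {
    stop("state must have ", length(.state_names), " components")
  }
  if (!is.null(names(y)) && all(.state_names %in% names(y))) {
    y <- y[.state_names]
  }
  unname(y)
}

#' State-vector template
#'
#' Names and order of the whole-cell state vector used by the simulator.
#'
#' @return Character vector of the 28 state-variable names.
#' @export
cell_state_template <- function() .state_names
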