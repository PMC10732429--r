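## ER and mitochondrial Ca2+ stores: SERCA pump, ryanodine receptor (CICR),
## IP3 receptor with slow Ca2+ activation/inhibition gates, IP3/precursor
## turnover, mitochondrial uniporter (MCU) and Na+/Ca2+ exchanger (MNCX).
## Store fluxes are molar flux densities over the respective organelle
## surface, positive in the direction stated per pathway.

#' SERCA (ER Ca2+ ATPase) flux
#'
#' Hill-type uptake from cytosol into the ER:
#' `P * C_Ca^2 / (C_Ca^2 + K^2)`.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param P Maximal pump rate density (mol m^-2 s^-1).
#' @param K Half-activation constant (mol/m^3), 0.1 uM by default.
#' @return Flux density (mol m^-2 s^-1), cytosol to ER, non-negative.
#' @export
serca_flux <- function(C_Ca, P, K = 1e-4) {
  if (any(C_Ca < 0)) stop("serca_flux: C_Ca must be >= 0")
  P * C_Ca^2 / (C_Ca^2 + K^2)
}

#' Ryanodine-receptor (CICR) flux
#'
#' Ca2+-induced Ca2+ release: zero below the cytosolic threshold
#' `K_s`, otherwise a sigmoidal permeability times the ER-cytosol gradient:
#' `P / (1 + exp(-(C_Ca - K_s)/K_f)) * (C_Ca,ER - C_Ca)`.
#' The threshold itself (`C_Ca == K_s`) belongs to the zero branch.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param C_Ca_ER ER Ca2+ (mol/m^3).
#' @param P Permeability (m/s).
#' @param K_s Activation threshold (mol/m^3), 0.3 uM default.
#' @param K_f Activation steepness (mol/m^3), 0.04 uM default.
#' @return Flux density (mol m^-2 s^-1), ER to cytosol; sign follows the
#'   gradient.
#' @export
ryr_flux <- function(C_Ca, C_Ca_ER, P, K_s = 3e-4, K_f = 4e-5) {
  if (any(C_Ca < 0) || any(C_Ca_ER < 0)) stop("ryr_flux: concentrations must be >= 0")
  ifelse(C_Ca <= K_s, 0,
         P / (1 + exp(-(C_Ca - K_s) / K_f)) * (C_Ca_ER - C_Ca))
}

#' IP3-receptor gate steady states
#'
#' Steady values of the slow Ca2+ activation gate `m` (rising sigmoid at
#' `K_s1`) and inhibition gate `h` (falling sigmoid at `K_s2`); the gates
#' relax with fixed time constants `tau_m`, `tau_h`. The product
#' `m_inf * h_inf` is bell-shaped in `C_Ca`.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param params `"merkel_params"` (store block).
#' @return Named vector `c(m_steady =, h_steady =, tau_m =, tau_h =)`,
#'   taus in seconds.
#' @export
ip3r_rates <- function(C_Ca, params = merkel_params()) {
  if (any(C_Ca < 0)) stop("ip3r_rates: C_Ca must be >= 0")
  c(
    m_steady = 1 / (1 + exp(-(C_Ca - params$K_s1_IP3) / params$K_f1_IP3)),
    h_steady = 1 / (1 + exp((C_Ca - params$K_s2_IP3) / params$K_f2_IP3)),
    tau_m = params$tau_m_IP3,
    tau_h = params$tau_h_IP3
  )
}

#' IP3-receptor (plus ER leak) flux
#'
#' ER-to-cytosol release
#' `(P_leak + P_IP3 * C_IP3^3 / (C_IP3^3 + K_IP3^3) * m * h) * (C_Ca,ER - C_Ca)`.
#'
#' @param C_Ca,C_Ca_ER Cytosolic and ER Ca2+ (mol/m^3).
#' @param C_IP3 Cytosolic IP3 (mol/m^3).
#' @param m,h IP3R gates in `[0, 1]`.
#' @param P_leak ER leak permeability (m/s).
#' @param P_IP3 Maximal IP3R permeability (m/s).
#' @param K_IP3 IP3 half-activation (mol/m^3), 3 uM default.
#' @return Flux density (mol m^-2 s^-1), ER to cytosol.
#' @export
ip3r_flux <- function(C_Ca, C_Ca_ER, C_IP3, m, h, P_leak, P_IP3, K_IP3 = 3e-3) {
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1)) {
    stop("ip3r_flux: gates must lie in [0, 1]")
  }
  (P_leak + P_IP3 * C_IP3^3 / (C_IP3^3 + K_IP3^3) * m * h) * (C_Ca_ER - C_Ca)
}

#' IP3 and precursor turnover
#'
#' Coupled turnover of cytosolic IP3 and its precursor pool:
#' production `k_IP3 * C_Ca^2/(C_Ca^2 + K_IP3Ca^2) * C_preIP3` (consuming
#' precursor), first-order IP3 degradation `k_dIP3 * C_IP3`, and saturating
#' precursor replenishment
#' `k_preIP3 / (1 + exp((C_preIP3 - K_s)/K_f))`. A config switch reproduces
#' the literally printed (unsquared) dissociation constant in the production
#' term.
#'
#' @param C_Ca,C_IP3,C_preIP3 Concentrations (mol/m^3).
#' @param params `"merkel_params"`.
#' @return `c(dIP3 =, dpreIP3 =)` in mol m^-3 s^-1.
#' @export
ip3_turnover <- function(C_Ca, C_IP3, C_preIP3, params = merkel_params()) {
  if (any(c(C_Ca, C_IP3, C_preIP3) < 0)) {
    stop("ip3_turnover: concentrations must be >= 0")
  }
  kc <- if (isTRUE(params$literal_ip3ca)) {
    C_Ca^2 / (C_Ca^2 + params$K_IP3Ca)
  } else {
    C_Ca^2 / (C_Ca^2 + params$K_IP3Ca^2)
  }
  production <- params$k_IP3 * kc * C_preIP3
  replenish <- params$k_preIP3 /
    (1 + exp((C_preIP3 - params$K_s_preIP3) / params$K_f_preIP3))
  c(dIP3 = production - params$k_dIP3 * C_IP3,
    dpreIP3 = replenish - production)
}

#' Mitochondrial Ca2+ fluxes
#'
#' Uniporter uptake `P_MCU * C_Ca^2.3 / (C_Ca^2.3 + K_MCU^2.3)` and
#' mitochondrial Na+/Ca2+ exchanger release
#' `P_MNCX * C_Ca,MT / (C_Ca,MT + K_MNCX)`.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param C_Ca_MT Mitochondrial Ca2+ (mol/m^3).
#' @param P_MCU,P_MNCX Rate densities (mol m^-2 s^-1).
#' @param K_MCU,K_MNCX Half-activation constants (mol/m^3).
#' @return `c(uptake =, release =)` (mol m^-2 s^-1), both non-negative.
#' @export
mito_fluxes <- function(C_Ca, C_Ca_MT, P_MCU, P_MNCX,
                        K_MCU = 6e-4, K_MNCX = 1e-3) {
  if (any(c(C_Ca, C_Ca_MT) < 0)) stop("mito_fluxes: concentrations must be >= 0")
  c(uptake = P_MCU * C_Ca^2.3 / (C_Ca^2.3 + K_MCU^2.3),
    release = P_MNCX * C_Ca_MT / (C_Ca_MT + K_MNCX))
}

#' Store mole balances
#'
#' Time derivatives of the ER and mitochondrial Ca2+ amounts from the store
#' fluxes: `dn_ER/dt = S_ER (J_serca - J_ip3r - J_ryr)` and
#' `dn_MT/dt = S_MT/(1 + beta_MT) (J_mcu - J_mncx)`; the cytosolic balance
#' receives exactly the negatives of these terms, so with the plasma
#' membrane closed `n_Ca + n_Ca,ER + n_Ca,MT` is conserved.
#'
#' @param fluxes Named list/vector with `serca`, `ip3r`, `ryr`, `mcu`,
#'   `mncx` (mol m^-2 s^-1).
#' @param params `"merkel_params"` (surfaces and `beta_MT`).
#' @return `c(dn_ER =, dn_MT =)` in mol/s.
#' @export
store_balances <- function(fluxes, params = merkel_params()) {
  f <- as.list(fluxes)
  c(dn_ER = params$S_ER * (f$serca - f$ip3r - f$ryr),
    dn_MT = params$S_MT / (1 + params$beta_MT) * (f$mcu - f$mncx))
}
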