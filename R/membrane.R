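## Plasma-membrane channel kinetics and flux densities.
##
## Sign convention (used by every pathway in the package): a flux is the molar
## flux density of the named species, POSITIVE INTO THE CYTOSOL, in
## mol m^-2 s^-1. The published channel equations carry a leading minus sign
## and the molar conversion J = -g * p_open * (Vm - E) / F for cation
## channels; anion (Cl-) ohmic flux is +g * (Vm - E) / F. Ca2+-carrying
## channel fluxes keep the published I/F molar conversion (no division by the
## valence); the charge balance books them with weight 2, matching the
## published membrane-potential equation.

#' Nernst (equilibrium) potential
#'
#' Membrane potential at which the electrochemical driving force on an ion
#' vanishes: `E = -(RT / zF) * log(C_in / C_out)`.
#'
#' @param C_in,C_out Intracellular / extracellular concentration (mol/m^3;
#'   any common unit works, only the ratio enters).
#' @param z Ion valence (nonzero integer).
#' @param T Absolute temperature (K).
#' @return Potential in volts.
#' @examples
#' nernst_potential(140, 5, 1)    # K+-like, about -0.089 V
#' @export
nernst_potential <- function(C_in, C_out, z, T = 310) {
  if (any(C_in <= 0) || any(C_out <= 0)) {
    stop("nernst_potential: concentrations must be positive")
  }
  if (any(z == 0)) stop("nernst_potential: valence must be nonzero")
  -(GAS_CONSTANT * T) / (z * FARADAY) * log(C_in / C_out)
}

## ---- gating-rate kernels -------------------------------------------------
## vmv: membrane potential in mV (published fits are in mV/ms);
## each returns steady values (dimensionless) and time constants in seconds.

.sigm <- function(x) 1 / (1 + exp(-x))

.kv14_rates <- function(vmv) {
  minf <- .sigm((vmv + 23.12) / 11.46)
  taum <- (0.6 + exp(-(vmv + 12.02) / 25.87)) * 1e-3
  hinf <- 1 / (1 + exp((vmv + 44.36) / 2.73))
  tauhf <- (-0.1086 * vmv + 48.67) * 1e-3
  tauhs <- 17.28e-3
  c(minf = minf, taum = taum, hinf = hinf, tauhf = tauhf, tauhs = tauhs)
}

.kv42_rates <- function(vmv) {
  minf <- .sigm((vmv - 17.66) / 22.75)
  taum <- (3 + 2 * exp(-(vmv - 19.68) / 41.23)) * 1e-3
  hinf <- 1 / (1 + exp((vmv + 44.36) / 2.73))
  tauh <- (10 + exp(-(vmv - 488) / 165.84)) * 1e-3
  c(minf = minf, taum = taum, hinf = hinf, tauh = tauh)
}

.bkca_rates <- function(vmv, cCa, K_BKCa = 1) {
  # cCa, K_BKCa in mol/m^3 (mM); pCa = log10 of their ratio
  pCa <- log10(cCa / K_BKCa)
  vhalf <- -43.3 * pCa - 110
  sf <- 33.88 * exp(-((pCa + 5.42) / 2.2)^2)
  ninf <- .sigm((vmv - vhalf) / sf)
  taun <- (0.75 + 5.55 * exp(vmv / 42.91) - 0.12 * vmv) * 1e-3
  c(ninf = ninf, taun = taun, vhalf = vhalf, sf = sf)
}

.kdr_rates <- function(vmv) {
  ninf <- .sigm((vmv + 33.3) / 8.7)
  taun <- (2.2 + 20 * exp(-((vmv + 13.03) / 29.55)^2)) * 1e-3
  c(ninf = ninf, taun = taun)
}

.cav12_rates <- function(vmv) {
  minf <- .sigm((vmv - 8.46) / 4.26)
  taum <- (2.11 + 3.86 * exp(-2 * ((vmv + 10) / 16.02)^2)) * 1e-3
  hinf <- 1 / (1 + exp((vmv + 42.52) / 7.48))
  tauh <- (825.80 + 637.91 * exp(-2 * (vmv / 39.75)^2)) * 1e-3
  c(minf = minf, taum = taum, hinf = hinf, tauh = tauh)
}

.cav21_rates <- function(vmv) {
  ninf <- .sigm((vmv + 5.1) / 3.1)
  taun <- (0.35 + 5.51 * exp(-2 * ((vmv + 9.73) / 18.14)^2)) * 1e-3
  c(ninf = ninf, taun = taun)
}

.hca_cav12 <- function(cCa, K_hCa) 1 / (1 + (cCa / K_hCa)^4)

#' Voltage- and Ca2+-dependent gating rates
#'
#' Steady-state values and relaxation time constants for every dynamic gating
#' variable of the named plasma-membrane channel. The L-type Ca2+ channel
#' additionally reports its algebraic Ca2+-dependent inactivation factor
#' `hCa = 1 / (1 + (C_Ca / K_hCa)^4)`.
#'
#' @param channel_id One of `"Kv1.4"`, `"Kv4.2"`, `"BKCa"`, `"KDR"`,
#'   `"Cav1.2"`, `"Cav2.1"`.
#' @param Vm Membrane potential (V).
#' @param C_Ca Cytosolic Ca2+ concentration (mol/m^3); used by BKCa (shifts
#'   the activation midpoint) and by the Cav1.2 `hCa` factor.
#' @param params Optional `"merkel_params"` for the dissociation constants;
#'   defaults are the published `K_BKCa` = 1 mM, `K_hCa` = 1 uM.
#' @return A list, one element per gating variable, each
#'   `c(steady = x_inf, tau = tau_x)` with `tau` in seconds; for Cav1.2 also
#'   a scalar element `hCa`.
#' @examples
#' gating_rates("Kv1.4", Vm = -23.12e-3)$m["steady"]  # 0.5 at the midpoint
#' @export
gating_rates <- function(channel_id, Vm, C_Ca = 1e-4, params = NULL) {
  K_BKCa <- if (is.null(params)) 1 else params$K_BKCa
  K_hCa <- if (is.null(params)) 1e-3 else params$K_hCa
  vmv <- Vm * 1e3
  switch(channel_id,
    "Kv1.4" = {
      r <- .kv14_rates(vmv)
      list(m = c(steady = r[["minf"]], tau = r[["taum"]]),
           h_fast = c(steady = r[["hinf"]], tau = r[["tauhf"]]),
           h_slow = c(steady = r[["hinf"]], tau = r[["tauhs"]]))
    },
    "Kv4.2" = {
      r <- .kv42_rates(vmv)
      list(m = c(steady = r[["minf"]], tau = r[["taum"]]),
           h = c(steady = r[["hinf"]], tau = r[["tauh"]]))
    },
    "BKCa" = {
      if (C_Ca <= 0) stop("gating_rates: C_Ca must be positive for BKCa")
      r <- .bkca_rates(vmv, C_Ca, K_BKCa)
      list(n = c(steady = r[["ninf"]], tau = r[["taun"]]))
    },
    "KDR" = {
      r <- .kdr_rates(vmv)
      list(n = c(steady = r[["ninf"]], tau = r[["taun"]]))
    },
    "Cav1.2" = {
      if (C_Ca <= 0) stop("gating_rates: C_Ca must be positive for Cav1.2")
      r <- .cav12_rates(vmv)
      list(m = c(steady = r[["minf"]], tau = r[["taum"]]),
           h = c(steady = r[["hinf"]], tau = r[["tauh"]]),
           hCa = .hca_cav12(C_Ca, K_hCa))
    },
    "Cav2.1" = {
      r <- .cav21_rates(vmv)
      list(n = c(steady = r[["ninf"]], tau = r[["taun"]]))
    },
    stop("gating_rates: unknown channel_id '", channel_id, "'")
  )
}

## ---- channel fluxes ------------------------------------------------------

.open_probability <- function(channel_id, gating, C_Ca, K_hCa = 1e-3) {
  switch(channel_id,
    "Kv1.4" = gating$m^4 * (0.7 * gating$h_fast + 0.3 * gating$h_slow),
    "Kv4.2" = gating$m * gating$h,
    "BKCa" = gating$n,
    "KDR" = gating$n,
    "Cav1.2" = gating$m * gating$h * .hca_cav12(C_Ca, K_hCa),
    "Cav2.1" = gating$n,
    stop("unknown channel_id '", channel_id, "'")
  )
}

#' Molar flux through a voltage-gated channel
#'
#' Per-area molar flux carried by the named channel, positive into the
#' cytosol: `J = -g * p_open * (Vm - E) / F`, where `p_open` is the channel's
#' open-probability product (Kv1.4: `m^4 (0.7 h_fast + 0.3 h_slow)`; Kv4.2:
#' `m h`; BKCa, KDR, Cav2.1: `n`; Cav1.2: `m h hCa`).
#'
#' @param channel_id Channel name, as in [gating_rates()].
#' @param gating Named list of gating variables in `[0, 1]` (`m`, `h`,
#'   `h_fast`, `h_slow`, `n` as the channel requires).
#' @param C_Ca Cytosolic Ca2+ (mol/m^3), used only by Cav1.2's `hCa`.
#' @param Vm Membrane potential (V).
#' @param reversal Reversal potential of the channel (V).
#' @param g Specific conductance (S/m^2).
#' @param K_hCa Dissociation constant of Cav1.2 Ca2+ inactivation (mol/m^3).
#' @return Molar flux density (mol m^-2 s^-1), positive inward.
#' @export
voltage_gated_flux <- function(channel_id, gating, C_Ca, Vm, reversal, g,
                               K_hCa = 1e-3) {
  if (g < 0) stop("voltage_gated_flux: negative conductance")
  gv <- unlist(gating[setdiff(names(gating), "hCa")], use.names = FALSE)
  if (any(gv < 0 | gv > 1)) {
    stop("voltage_gated_flux: gating variables must lie in [0, 1]")
  }
  p <- .open_probability(channel_id, gating, C_Ca, K_hCa)
  -g * p * (Vm - reversal) / FARADAY
}

#' Ohmic leak flux
#'
#' Passive molar flux through the Na+, K+, Cl- or Ca2+ leak pathway,
#' positive into the cytosol: cations `-g (Vm - E) / F`, the anion Cl-
#' `+g (Vm - E) / F`.
#'
#' @param ion_id `"Na"`, `"K"`, `"Cl"` or `"Ca"`.
#' @param Vm Membrane potential (V).
#' @param E_ion Equilibrium potential of the ion (V).
#' @param g_leak Specific leak conductance (S/m^2).
#' @return Molar flux density (mol m^-2 s^-1), positive inward.
#' @export
leak_flux <- function(ion_id, Vm, E_ion, g_leak) {
  if (g_leak < 0) stop("leak_flux: negative conductance")
  s <- switch(ion_id, Na = -1, K = -1, Ca = -1, Cl = 1,
              stop("leak_flux: unknown ion_id '", ion_id, "'"))
  s * g_leak * (Vm - E_ion) / FARADAY
}

## ---- pumps, cotransporters, exchangers -----------------------------------

#' Na+/K+ pump cycle rate
#'
#' Saturating pump rate
#' `P * (1 + K_Na/C_Na)^-3 * (1 + C_K/K_K)^-2`. Each cycle moves 3 Na+ out
#' and 2 K+ in (net one positive charge out); consumers apply that
#' stoichiometry.
#'
#' @param C_Na,C_K Intracellular Na+ and K+ (mol/m^3).
#' @param P Maximal pump rate density (mol m^-2 s^-1).
#' @param K_Na,K_K Half-activation constants (mol/m^3).
#' @return Cycle rate density (mol m^-2 s^-1), non-negative.
#' @export
nak_pump_flux <- function(C_Na, C_K, P, K_Na = 10, K_K = 140) {
  if (any(C_Na <= 0) || any(C_K <= 0)) {
    stop("nak_pump_flux: concentrations must be positive")
  }
  P * (1 + K_Na / C_Na)^-3 * (1 + C_K / K_K)^-2
}

#' Na+/K+/2Cl- cotransporter flux
#'
#' Electro-neutral cotransport, driven by the product difference
#' `P * (C_Na,o C_K,o C_Cl,o^2 - C_Na C_K C_Cl^2)`. Positive = 1 Na+, 1 K+
#' and 2 Cl- into the cell.
#'
#' @param env List with intracellular `C_Na, C_K, C_Cl` and extracellular
#'   `C_Na_out, C_K_out, C_Cl_out` (mol/m^3).
#' @param P Rate constant (m^10 mol^-3 s^-1).
#' @return Cycle rate density (mol m^-2 s^-1), positive = inward loading.
#' @export
nkcc1_flux <- function(env, P) {
  P * (env$C_Na_out * env$C_K_out * env$C_Cl_out^2 -
         env$C_Na * env$C_K * env$C_Cl^2)
}

#' K+/Cl- cotransporter flux
#'
#' Electro-neutral cotransport driven by the trans-membrane product
#' difference `P * (C_K C_Cl - C_K,o C_Cl,o)`. Positive = 1 K+ and 1 Cl-
#' extruded; zero at the product equilibrium.
#'
#' @param env As in [nkcc1_flux()].
#' @param P Rate constant (mol m^-2 s^-1 per (mol/m^3)^2).
#' @return Cycle rate density (mol m^-2 s^-1), positive = efflux.
#' @export
kcc2_flux <- function(env, P) {
  P * (env$C_K * env$C_Cl - env$C_K_out * env$C_Cl_out)
}

#' Plasma-membrane Ca2+ pump (PMCA) flux
#'
#' Hill-type pump `P * C_Ca^2 / (C_Ca^2 + K^2)`; the pumped Ca2+ leaves the
#' cell (2 positive charges out per ion).
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param P Maximal pump rate density (mol m^-2 s^-1).
#' @param K Half-activation constant (mol/m^3).
#' @return Pump rate density (mol m^-2 s^-1), non-negative (efflux).
#' @export
pmca_flux <- function(C_Ca, P, K = 3e-4) {
  if (any(C_Ca < 0)) stop("pmca_flux: C_Ca must be >= 0")
  P * C_Ca^2 / (C_Ca^2 + K^2)
}

#' Na+/Ca2+ exchanger (NCX) flux
#'
#' Electrogenic 3 Na+ : 1 Ca2+ exchange with the standard voltage-dependent
#' driving bracket
#' `exp(eta V F/RT) C_Na^3 C_Ca,o - exp((eta-1) V F/RT) C_Na,o^3 C_Ca`,
#' normalised by `(K_mNa^3 + C_Na,o^3)(K_mCa + C_Ca,o)(1 + k_sat exp((eta-1)VF/RT))`.
#'
#' Positive flux is the reverse mode: 1 Ca2+ enters and 3 Na+ leave per
#' cycle (net one positive charge out); at the resting state the bracket is
#' negative and the exchanger extrudes Ca2+. This orientation is the one
#' consistent with the model's ion and charge balances.
#'
#' @param Vm Membrane potential (V).
#' @param env List with `C_Na`, `C_Ca`, `C_Na_out`, `C_Ca_out` (mol/m^3).
#' @param P Rate scale (mol m^-2 s^-1).
#' @param K_mNa,K_mCa,eta,k_sat Exchanger constants (mol/m^3 and
#'   dimensionless).
#' @param T Temperature (K).
#' @return Cycle rate density (mol m^-2 s^-1); positive = Ca2+ influx with
#'   3 Na+ efflux.
#' @export
ncx_flux <- function(Vm, env, P, K_mNa = 87.5, K_mCa = 5e-4, eta = 0.1,
                     k_sat = 0.35, T = 310) {
  vf <- Vm * FARADAY / (GAS_CONSTANT * T)
  e1 <- exp(eta * vf)
  e2 <- exp((eta - 1) * vf)
  bracket <- e1 * env$C_Na^3 * env$C_Ca_out - e2 * env$C_Na_out^3 * env$C_Ca
  P * bracket /
    ((K_mNa^3 + env$C_Na_out^3) * (K_mCa + env$C_Ca_out) * (1 + k_sat * e2))
}
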