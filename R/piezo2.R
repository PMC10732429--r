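## Piezo2 mechanosensitive channel: four-state kinetics gated by cortex
## stress sigma. States: C (closed), O (open), In (short-time inactivated),
## plus a slow availability factor h_slow; C + O + In == 1 always.
##
## Two phase-dependent equation sets are used, switched by a protocol-driven
## flag: "loading" while a mechanical stimulus is applied or held (C drains
## through O into In), "unloading" after release and at rest (In recovers
## directly to C; O frozen). When the loading set is active but the stress is
## falling (C_inf above C), the literal equations would push O below zero, so
## the kernel switches to the recovery direction (In -> C, O decays); under
## monotone loading the published equations are reproduced exactly.

#' Piezo2 steady values and time constants
#'
#' Stress-dependent steady states and relaxation times of the Piezo2 state
#' machine: `C_inf`, `In_inf = 1 - C_inf`, the slow availability
#' `h_slow_inf`, and the time constants `tau_C`, `tau_O`, `tau_In`,
#' `tau_hslow` (seconds).
#'
#' @param sigma Cortex stress (Pa).
#' @param params `"merkel_params"` (only the Piezo2 block is used).
#' @return Named numeric vector.
#' @examples
#' piezo2_rates(1450)[c("C_inf", "h_slow_inf")]  # both 0.5 at the midpoint
#' @export
piezo2_rates <- function(sigma, params = merkel_params()) {
  p <- params
  c(
    C_inf = 1 / (1 + exp((sigma - p$sigma_s1) / p$sigma_f1)),
    In_inf = 1 / (1 + exp(-(sigma - p$sigma_s1) / p$sigma_f1)),
    h_slow_inf = 1 / (1 + exp(-(sigma - p$sigma_s7) / p$sigma_f7)),
    tau_C = (0.5 + 1.5 / (1 + exp(-(sigma - p$sigma_s2) / p$sigma_f2))) * 1e-3,
    tau_O = (2.5 + 5.5 / (1 + exp(-(sigma - p$sigma_s4) / p$sigma_f4))) * 1e-3,
    tau_In = (0.5 + 1.5 / (1 + exp(-(sigma - p$sigma_s2) / p$sigma_f2))) * 1e-3,
    tau_hslow = (150 / (1 + exp((sigma - p$sigma_s8) / p$sigma_f8))) * 1e-3
  )
}

#' Piezo2 state derivatives
#'
#' Time derivatives of `(C, O, In, h_slow)` at stress `sigma` under the given
#' phase. Their sum over `(C, O, In)` is identically zero.
#'
#' @param state Named vector or list with `C`, `O`, `In`, `h_slow`.
#' @param sigma Cortex stress (Pa).
#' @param phase `"loading"` or `"unloading"`.
#' @param params `"merkel_params"`.
#' @return Named numeric vector `c(C =, O =, In =, h_slow =)` in 1/s.
#' @export
piezo2_derivatives <- function(state, sigma, phase = c("loading", "unloading"),
                               params = merkel_params()) {
  phase <- match.arg(phase)
  r <- piezo2_rates(sigma, params)
  C <- state$C; O <- state$O; In <- state$In; hs <- state$h_slow
  dhs <- (r[["h_slow_inf"]] - hs) / r[["tau_hslow"]]
  if (phase == "loading" && r[["C_inf"]] <= C) {
    dC <- (r[["C_inf"]] - C) / r[["tau_C"]]
    dIn <- O / r[["tau_O"]]
    dO <- -dC - dIn
  } else if (phase == "loading") {
    # recovery direction while the loading flag is still set: closed states
    # replenish from In (up to the pool not held open), the open pool decays
    C_t <- min(r[["C_inf"]], 1 - O)
    dC <- (C_t - C) / r[["tau_C"]]
    dO <- -O / r[["tau_O"]]
    dIn <- -dC - dO
  } else {
    # In recovers toward its steady value, limited to the pool not held open
    In_t <- min(r[["In_inf"]], 1 - O)
    dIn <- (In_t - In) / r[["tau_In"]]
    dC <- -dIn
    dO <- 0
  }
  c(C = dC, O = dO, In = dIn, h_slow = unname(dhs))
}

#' Advance the Piezo2 state at constant stress
#'
#' Exact exponential-relaxation update of the four-state Piezo2 machine over
#' a step `dt` at fixed stress, under either phase. Used as a unit-testable
#' kernel; inside whole-cell simulations the same equations are integrated as
#' part of the global state vector.
#'
#' @param state List with `C`, `O`, `In`, `h_slow` (each in `[0, 1]`,
#'   `C + O + In = 1`) and optionally `phase`.
#' @param sigma Cortex stress (Pa), held constant over the step.
#' @param dt Step duration (s), positive.
#' @param phase `"loading"` or `"unloading"`; defaults to `state$phase` or
#'   `"loading"`.
#' @param params `"merkel_params"`.
#' @return Updated state list (same shape), satisfying `C + O + In = 1`.
#' @examples
#' s <- list(C = 1, O = 0, In = 0, h_slow = 0)
#' piezo2_advance(s, sigma = 3000, dt = 0.05)  # strong load: O spikes, then In
#' @export
piezo2_advance <- function(state, sigma, dt, phase = NULL,
                           params = merkel_params()) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("piezo2_advance: dt must be a positive scalar")
  }
  sv <- unlist(state[c("C", "O", "In", "h_slow")])
  if (any(sv < -1e-12) || any(sv > 1 + 1e-12) ||
      abs(sum(sv[1:3]) - 1) > 1e-6) {
    stop("piezo2_advance: state violates its invariants")
  }
  if (is.null(phase)) phase <- if (!is.null(state$phase)) state$phase else "loading"
  phase <- match.arg(phase, c("loading", "unloading"))
  r <- piezo2_rates(sigma, params)
  C0 <- state$C; O0 <- state$O; In0 <- state$In
  hs <- r[["h_slow_inf"]] + (state$h_slow - r[["h_slow_inf"]]) *
    exp(-dt / r[["tau_hslow"]])
  if (phase == "loading" && r[["C_inf"]] <= C0) {
    a <- 1 / r[["tau_O"]]; b <- 1 / r[["tau_C"]]
    C1 <- r[["C_inf"]] + (C0 - r[["C_inf"]]) * exp(-b * dt)
    # O' = -aO - C'; C' = -(C0 - C_inf) b e^{-bt}
    amp <- (C0 - r[["C_inf"]]) * b
    O1 <- if (abs(a - b) > 1e-12 * a) {
      O0 * exp(-a * dt) + amp * (exp(-b * dt) - exp(-a * dt)) / (a - b)
    } else {
      (O0 + amp * dt) * exp(-a * dt)
    }
    In1 <- 1 - C1 - O1
  } else if (phase == "loading") {
    C_t <- min(r[["C_inf"]], 1 - O0)
    C1 <- C_t + (C0 - C_t) * exp(-dt / r[["tau_C"]])
    O1 <- O0 * exp(-dt / r[["tau_O"]])
    In1 <- 1 - C1 - O1
  } else {
    In_t <- min(r[["In_inf"]], 1 - O0)
    In1 <- In_t + (In0 - In_t) * exp(-dt / r[["tau_In"]])
    O1 <- O0
    C1 <- 1 - In1 - O1
  }
  list(C = C1, O = O1, In = In1, h_slow = hs, phase = phase)
}

#' Piezo2 Ca2+ flux
#'
#' Molar Ca2+ flux through Piezo2, positive into the cytosol:
#' `J = -g * O * h_slow * (Vm - E) / F`. Only channels that are open and not
#' long-time inactivated conduct; the whole flux is booked as Ca2+ in the
#' ion and charge balances (divalent weight 2).
#'
#' @param state List with `O` and `h_slow`.
#' @param Vm Membrane potential (V).
#' @param g_Piezo2 Specific conductance (S/m^2).
#' @param E_Piezo2 Reversal potential (V), 6 mV by default.
#' @return Molar flux density (mol m^-2 s^-1), positive inward.
#' @export
piezo2_flux <- function(state, Vm, g_Piezo2, E_Piezo2 = 6e-3) {
  if (g_Piezo2 < 0) stop("piezo2_flux: negative conductance")
  -g_Piezo2 * state$O * state$h_slow * (Vm - E_Piezo2) / FARADAY
}
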