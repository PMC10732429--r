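## Cell mechanics: osmotic water flow across the membrane, elastic cortex
## stress, Laplace relation between stress and hydrostatic pressure, and the
## volume-conserving sphere-to-cylinder geometry used under indentation.

#' Osmotic pressure difference
#'
#' `RT * (sum C_in - sum C_out)` across the membrane. The intracellular sum
#' includes the impermeant anion species A-; the extracellular sum includes
#' any impermeant osmolyte (mannitol).
#'
#' @param internal Named list/vector of intracellular concentrations
#'   (mol/m^3), all species that contribute osmotically.
#' @param external Named list/vector of extracellular concentrations
#'   (mol/m^3), including `mannitol` if present.
#' @param T Temperature (K).
#' @return Pressure (Pa), positive when the inside is hypertonic.
#' @examples
#' osmotic_pressure_difference(c(Na = 10, K = 140, Cl = 10, A = 102),
#'                             c(Na = 145, K = 5, Cl = 110, Ca = 2))
#' @export
osmotic_pressure_difference <- function(internal, external, T = 310) {
  ci <- unlist(internal, use.names = FALSE)
  co <- unlist(external, use.names = FALSE)
  if (any(ci < 0) || any(co < 0)) {
    stop("osmotic_pressure_difference: concentrations must be >= 0")
  }
  GAS_CONSTANT * T * (sum(ci) - sum(co))
}

#' Trans-membrane water flux
#'
#' Linear filtration law `J_w = -alpha * (dP - dPi)`; the cell volume changes
#' as `dV/dt = S * J_w`.
#'
#' @param dP Hydrostatic pressure difference (Pa).
#' @param dPi Osmotic pressure difference (Pa).
#' @param alpha Membrane water permeability (m s^-1 Pa^-1).
#' @return Linear water velocity (m/s), positive = influx (swelling).
#' @export
water_flux <- function(dP, dPi, alpha = 1e-8) {
  -alpha * (dP - dPi)
}

#' Elastic cortex stress
#'
#' The cortex (membrane plus actin shell) is an elastic layer in the area
#' strain: `sigma = K/2 * (S/S_ref - 1) - sigma_a`, with active contraction
#' stress `sigma_a` (negative by convention, so it adds tension at rest).
#'
#' @param S Current surface area (m^2).
#' @param S_ref Unstressed reference surface area (m^2), positive.
#' @param K Cortex elastic modulus (Pa).
#' @param sigma_a Active stress (Pa), default -100.
#' @return Cortex stress (Pa).
#' @examples
#' cortex_stress(1, 1)  # 100 Pa: the active term alone
#' @export
cortex_stress <- function(S, S_ref, K = 6000, sigma_a = -100) {
  if (any(S_ref <= 0)) stop("cortex_stress: S_ref must be positive")
  K / 2 * (S / S_ref - 1) - sigma_a
}

#' Hydrostatic pressure from cortex stress
#'
#' Laplace relation for a thin shell: `dP = 2 h_c sigma / r`.
#'
#' @param sigma Cortex stress (Pa).
#' @param r Cell radius (m), positive; under compression the instantaneous
#'   cylinder radius.
#' @param h_c Cortex thickness (m).
#' @return Pressure difference (Pa).
#' @examples
#' hydrostatic_pressure(100, 5e-6, 0.5e-6)  # 20 Pa
#' @export
hydrostatic_pressure <- function(sigma, r, h_c = 0.5e-6) {
  if (any(r <= 0)) stop("hydrostatic_pressure: r must be positive")
  2 * h_c * sigma / r
}

#' Compressed-cell geometry
#'
#' Volume-conserving shape map for indentation between parallel plates: at
#' depth `d` the cell is a cylinder of height `H = 2 r_ini - d` whose radius
#' follows from the instantaneous volume, `r_cyl = sqrt(V / (pi H))`, with
#' surface `S = 2 pi r_cyl^2 + 2 pi r_cyl H`. At `d = 0` the spherical
#' formulas are used. For fixed volume the surface grows strictly with
#' depth, which is what loads the cortex.
#'
#' @param V Cell volume (m^3), positive.
#' @param r_ini Initial (uncompressed) radius (m).
#' @param d Indentation depth (m), `0 <= d < 2 r_ini`.
#' @return `c(H =, r_cyl =, S =)` height, radius and surface (m, m, m^2);
#'   at `d = 0`, `r_cyl` is the sphere radius of volume `V`.
#' @export
compressed_geometry <- function(V, r_ini, d = 0) {
  if (any(V <= 0)) stop("compressed_geometry: V must be positive")
  if (any(d < 0) || any(d >= 2 * r_ini)) {
    stop("compressed_geometry: need 0 <= d < 2 * r_ini")
  }
  if (d == 0) {
    r <- (3 * V / (4 * pi))^(1 / 3)
    return(c(H = 2 * r, r_cyl = r, S = 4 * pi * r^2))
  }
  H <- 2 * r_ini - d
  r_cyl <- sqrt(V / (pi * H))
  c(H = H, r_cyl = r_cyl, S = 2 * pi * r_cyl^2 + 2 * pi * r_cyl * H)
}
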