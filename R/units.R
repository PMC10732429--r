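#' @keywords internal
"_PACKAGE"

## Internal unit system (coherent SI):
##   time s, potential V, length m, area m^2, volume m^3, amount mol,
##   concentration mol/m^3 (numerically equal to mM), pressure Pa,
##   specific conductance S/m^2, molar flux density mol/(m^2 s),
##   specific capacitance F/m^2, current A.
## Published channel tables use mV/ms/mS cm^-2/uM etc.; everything is
## converted once at the parameter boundary through `unit_factor()`.

#' Physical constants
#'
#' Faraday constant (C/mol) and molar gas constant (J mol^-1 K^-1) used
#' throughout the model.
#' @name constants
#' @keywords internal
NULL

FARADAY <- 96485.33212
GAS_CONSTANT <- 8.314462618

## conversion factors: value_in_unit * unit_factor(unit) -> internal SI
.unit_table <- c(
  "1"              = 1,            # dimensionless
  "mV"             = 1e-3,
  "V"              = 1,
  "ms"             = 1e-3,
  "s"              = 1,
  "mM"             = 1,            # mol/m^3
  "uM"             = 1e-3,
  "mol/m^3"        = 1,
  "mS/cm^2"        = 10,           # -> S/m^2
  "S/m^2"          = 1,
  "uF/um^2"        = 1e6,          # 1e-6 F / 1e-12 m^2
  "F/m^2"          = 1,
  "mol/(cm^2.ms)"  = 1e7,          # -> mol/(m^2 s)
  "mol/(m^2.s)"    = 1,
  "cm^10/(mol^3.ms)" = 1e-17,      # -> m^10 mol^-3 s^-1
  "mol/(cm^2.ms.mM^2)" = 1e7,      # KCC2 driving form, see vignette
  "cm/ms"          = 10,           # -> m/s
  "m/s"            = 1,
  "mol/(cm^3.ms)"  = 1e9,          # -> mol/(m^3 s)
  "1/ms"           = 1e3,          # -> 1/s
  "1/s"            = 1,
  "Pa"             = 1,
  "um"             = 1e-6,
  "m"              = 1,
  "um^2"           = 1e-12,
  "um^3"           = 1e-18,
  "K"              = 1,
  "pA"             = 1e-12,
  "A"              = 1,
  "cm/(ms.Pa)"     = 10,           # -> m/(s Pa)
  "count"          = 1
)

#' Unit conversion factor
#'
#' Multiplicative factor taking a quantity expressed in `unit` to the
#' package's internal SI system (s, V, m, mol, mol/m^3, Pa).
#'
#' @param unit Unit string, e.g. `"mS/cm^2"`, `"uM"`, `"mol/(cm^2.ms)"`.
#' @return A numeric scalar factor.
#' @examples
#' unit_factor("mS/cm^2")  # 10: 1 mS/cm^2 == 10 S/m^2
#' @export
unit_factor <- function(unit) {
  f <- .unit_table[unit]
  if (anyNA(f)) {
    stop("unknown unit string(s): ", paste(unit[is.na(f)], collapse = ", "))
  }
  unname(f)
}

#' Convert a quantity between a published unit and internal SI
#'
#' @param x Numeric value(s).
#' @param from Unit `x` is expressed in.
#' @param to Target unit (default internal SI base of `from`).
#' @return `x` expressed in `to`.
#' @examples
#' to_si(0.25, "mS/cm^2")      # 2.5 S/m^2
#' from_si(2.5, "mS/cm^2")     # 0.25
#' @export
to_si <- function(x, from) x * unit_factor(from)

#' @rdname to_si
#' @export
from_si <- function(x, from) x / unit_factor(from)

## thermal voltage RT/F in volts
.rt_over_f <- function(T) GAS_CONSTANT * T / FARADAY
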