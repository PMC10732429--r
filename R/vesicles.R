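## Vesicle cycle: Ca2+-dependent exocytosis drains a vesicle pool that is
## replenished by synthesis (inversely related to the pool size);
## tension-dependent endocytosis and exocytosis move membrane area in and
## out of the reference surface S_ref.

#' Exocytosis rate
#'
#' Vesicle fusion rate `k_exo / (1 + exp(-(C_Ca - c_s)/c_f)) * n_ve`:
#' sigmoidal in cytosolic Ca2+ (half-maximal at `c_s` = 0.2 uM) and
#' proportional to the pool size. This is the model's neurotransmitter
#' release proxy.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param n_ve Vesicle count (>= 0).
#' @param params `"merkel_params"` (vesicle block).
#' @return Vesicles per second.
#' @export
exocytosis_rate <- function(C_Ca, n_ve, params = merkel_params()) {
  if (any(n_ve < 0)) stop("exocytosis_rate: n_ve must be >= 0")
  params$k_exo / (1 + exp(-(C_Ca - params$c_Ca_s) / params$c_Ca_f)) * n_ve
}

#' Vesicle-synthesis rate
#'
#' Pool replenishment `k_ve / (1 + exp((n_ve - n_s)/n_f))`: bounded, and
#' decreasing in the pool size so that the pool self-stabilises. The switch
#' `literal_vesicle_sign` restores the literally printed (increasing)
#' orientation.
#'
#' @inheritParams exocytosis_rate
#' @return Vesicles per second.
#' @export
vesicle_synthesis_rate <- function(n_ve, params = merkel_params()) {
  s <- if (isTRUE(params$literal_vesicle_sign)) -1 else 1
  params$k_ve / (1 + exp(s * (n_ve - params$n_ve_s) / params$n_ve_f))
}

#' Vesicle-pool derivative
#'
#' `dn_ve/dt = synthesis - exocytosis`; the pool stays non-negative because
#' synthesis is bounded and consumption is proportional to `n_ve`.
#'
#' @inheritParams exocytosis_rate
#' @return d n_ve / dt (vesicles per second).
#' @export
vesicle_derivative <- function(C_Ca, n_ve, params = merkel_params()) {
  vesicle_synthesis_rate(n_ve, params) - exocytosis_rate(C_Ca, n_ve, params)
}

#' Endocytosis rate
#'
#' Membrane retrieval `k_endo / (1 + exp((sigma - sigma_s)/sigma_f))`:
#' suppressed at high cortex tension (forming a vesicle against tension
#' costs energy), half-maximal at `sigma_s` = 1000 Pa.
#'
#' @param sigma Cortex stress (Pa).
#' @param params `"merkel_params"`.
#' @return Vesicles per second.
#' @export
endocytosis_rate <- function(sigma, params = merkel_params()) {
  params$k_endo / (1 + exp((sigma - params$sigma_ve_s) / params$sigma_ve_f))
}

#' Reference-surface turnover
#'
#' Each fused vesicle adds its membrane area `4 pi r_ve^2` to the reference
#' surface, each retrieved vesicle removes it:
#' `dS_ref/dt = 4 pi r_ve^2 * (exocytosis - endocytosis)`.
#'
#' @param C_Ca Cytosolic Ca2+ (mol/m^3).
#' @param n_ve Vesicle count.
#' @param sigma Cortex stress (Pa).
#' @param params `"merkel_params"`.
#' @return dS_ref/dt (m^2/s).
#' @export
surface_turnover <- function(C_Ca, n_ve, sigma, params = merkel_params()) {
  4 * pi * params$r_ve^2 *
    (exocytosis_rate(C_Ca, n_ve, params) - endocytosis_rate(sigma, params))
}
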