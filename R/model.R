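## The merkel_model S3 object: parameters + bath + the impermeant-species
## bookkeeping + (after initialisation) the relaxed resting state.

#' Construct a Merkel-cell model
#'
#' Bundles a parameter set and a bathing solution into a model object,
#' solves the impermeant intracellular species (amount `n_A` and mean
#' valence `z_A`) for simultaneous resting electro-neutrality and osmotic
#' balance at the target resting volume, and (by default) relaxes the full
#' system to its resting fixed point.
#'
#' @param params A `"merkel_params"` set, see [merkel_params()].
#' @param external An `"external_solution"` bath.
#' @param C_init Named initial intracellular concentrations (mM) for
#'   `Na`, `K`, `Cl`, `Ca` used to seed the impermeant-species solve and the
#'   relaxation.
#' @param Vm_init Initial membrane potential (V).
#' @param relax Relax to rest on construction (default `TRUE`); with
#'   `FALSE`, call [initialize_rest()] later.
#' @param ... Passed to [initialize_rest()].
#' @return An object of class `"merkel_model"` with elements `params`,
#'   `external`, `n_A`, `z_A`, `state0` (seed state) and, once relaxed,
#'   `rest` (the resting state vector) and `rest_info`.
#' @examples
#' \donttest{
#' m <- merkel_model()       # relaxes to rest (takes a little while)
#' summary(m)
#' }
#' @export
merkel_model <- function(params = merkel_params(),
                         external = external_solution(),
                         C_init = c(Na = 10, K = 140, Cl = 10, Ca = 1e-4),
                         Vm_init = -0.05,
                         relax = TRUE, ...) {
  validate_params(params)
  V0 <- 4 / 3 * pi * params$r_ini^3
  Vcyt0 <- V0 - params$V_ER - params$V_MT
  if (Vcyt0 <= 0) stop("V_ER + V_MT exceed the cell volume")
  ext_osm <- external$Na + external$K + external$Cl + external$Ca +
    external$mannitol
  C_A <- ext_osm - sum(C_init)
  if (C_A <= 0) {
    stop("no room for the impermeant species: internal ions already ",
         "exceed the external osmolarity")
  }
  z_A <- -(C_init[["Na"]] + C_init[["K"]] - C_init[["Cl"]] +
             2 * C_init[["Ca"]]) / C_A
  model <- structure(
    list(params = params, external = external,
         n_A = C_A * Vcyt0, z_A = z_A, V0 = V0),
    class = "merkel_model"
  )
  model$state0 <- .seed_state(model, C_init, Vm_init)
  if (relax) model <- initialize_rest(model, ...)
  model
}

## starting state for the rest relaxation: gating at steady state, stores in
## quasi-equilibrium, slow mechanics (S_ref) and the vesicle pool anchored at
## their algebraic balance for the seed Ca2+ level.
.seed_state <- function(model, C_init, Vm_init) {
  p <- model$params
  V0 <- model$V0
  Vcyt0 <- V0 - p$V_ER - p$V_MT
  cCa <- C_init[["Ca"]]
  vmv <- Vm_init * 1e3
  r14 <- .kv14_rates(vmv); r42 <- .kv42_rates(vmv)
  rbk <- .bkca_rates(vmv, cCa, p$K_BKCa); rdr <- .kdr_rates(vmv)
  r12 <- .cav12_rates(vmv); r21 <- .cav21_rates(vmv)

  anchors <- .slow_anchors(cCa, 4 * pi * p$r_ini^2, p)
  sig0 <- anchors$sigma
  In0 <- 1 / (1 + exp(-(sig0 - p$sigma_s1) / p$sigma_f1))
  hs0 <- 1 / (1 + exp(-(sig0 - p$sigma_s7) / p$sigma_f7))

  pre0 <- .preip3_anchor(cCa, p)
  kc <- cCa^2 / (cCa^2 + p$K_IP3Ca^2)
  ip30 <- p$k_IP3 * kc * pre0 / p$k_dIP3

  y <- c(
    C_init[["Na"]] * Vcyt0, C_init[["K"]] * Vcyt0,
    C_init[["Cl"]] * Vcyt0, cCa * Vcyt0,
    Vm_init,
    r14[["minf"]], r14[["hinf"]], r14[["hinf"]],
    r42[["minf"]], r42[["hinf"]],
    rbk[["ninf"]], rdr[["ninf"]],
    r12[["minf"]], r12[["hinf"]], r21[["ninf"]],
    1 - In0, 0, In0, hs0,
    cCa * p$V_ER, cCa * p$V_MT,
    ip30, pre0,
    1 / (1 + exp(-(cCa - p$K_s1_IP3) / p$K_f1_IP3)),
    1 / (1 + exp((cCa - p$K_s2_IP3) / p$K_f2_IP3)),
    V0, anchors$S_ref, anchors$n_ve
  )
  stats::setNames(y, .state_names)
}

## quasi-static balance of the slow membrane-turnover coordinates:
## vesicle pool where synthesis equals exocytosis, cortex stress where
## endocytosis equals exocytosis, and the S_ref realising that stress.
.slow_anchors <- function(cCa, S, p) {
  exo_sig <- 1 / (1 + exp(-(cCa - p$c_Ca_s) / p$c_Ca_f))
  syn <- function(n) {
    s <- if (isTRUE(p$literal_vesicle_sign)) -1 else 1
    p$k_ve / (1 + exp(s * (n - p$n_ve_s) / p$n_ve_f))
  }
  bal <- function(n) syn(n) - p$k_exo * exo_sig * n
  upper <- p$n_ve_s + 60 * p$n_ve_f
  n_ve <- if (bal(upper) > 0) upper else {
    stats::uniroot(bal, c(0, upper), tol = 1e-10)$root
  }
  rate <- p$k_exo * exo_sig * n_ve
  sigma <- if (rate >= p$k_endo || rate <= 0) {
    p$sigma_ve_s
  } else {
    p$sigma_ve_s + p$sigma_ve_f * log(p$k_endo / rate - 1)
  }
  S_ref <- S / (1 + 2 * (sigma + p$sigma_a) / p$K_cortex)
  list(n_ve = n_ve, sigma = sigma, S_ref = S_ref)
}

.preip3_anchor <- function(cCa, p) {
  kc <- cCa^2 / (cCa^2 + p$K_IP3Ca^2)
  f <- function(x) {
    p$k_preIP3 / (1 + exp((x - p$K_s_preIP3) / p$K_f_preIP3)) - p$k_IP3 * kc * x
  }
  upper <- p$K_s_preIP3 + 40 * p$K_f_preIP3
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

## variable scales for tolerance and residual normalisation
.state_scales <- function(y) {
  s <- abs(y)
  floors <- c(
    n_Na = 1e-18, n_K = 1e-18, n_Cl = 1e-18, n_Ca = 1e-21,
    Vm = 0.1,
    m_Kv14 = 1, hf_Kv14 = 1, hs_Kv14 = 1, m_Kv42 = 1, h_Kv42 = 1,
    n_BKCa = 1, n_KDR = 1, m_Cav12 = 1, h_Cav12 = 1, n_Cav21 = 1,
    pz_C = 1, pz_O = 1, pz_In = 1, pz_hslow = 1,
    n_Ca_ER = 1e-21, n_Ca_MT = 1e-22,
    C_IP3 = 1e-4, C_preIP3 = 1e-3, m_IP3 = 1, h_IP3 = 1,
    V = 1e-17, S_ref = 1e-11, n_ve = 10
  )
  pmax(s, floors[.state_names])
}

.rest_residual <- function(y, model) {
  dy <- assemble_derivatives(y, protocol_none(), 0, model)
  r <- abs(dy) / .state_scales(y)
  list(max = max(r), which = .state_names[which.max(r)], dy = dy)
}

#' Relax the model to its resting state
#'
#' Finds the stimulus-free fixed point of the full system: staged stiff
#' relaxation (with algebraic re-anchoring of the slow membrane-turnover
#' coordinates between stages), followed by a damped Newton polish on the
#' scaled derivative. Fails with the largest residual component if no fixed
#' point is reached.
#'
#' @param model A `"merkel_model"` (from [merkel_model()] with
#'   `relax = FALSE`, or to re-relax after changing the bath).
#' @param tol Convergence tolerance on the max-norm of the scaled state
#'   derivative (1/s). Default `1e-8`.
#' @param stage_time Length of one relaxation stage (s).
#' @param max_stages Maximum number of relaxation stages before giving up.
#' @param verbose Print stage residuals.
#' @return The model with `rest` (named resting state) and `rest_info`
#'   (residual, stages used) filled in.
#' @export
initialize_rest <- function(model, tol = 1e-8, stage_time = 150,
                            max_stages = 40, verbose = FALSE) {
  y <- .as_state_vector(model$state0)
  names(y) <- .state_names
  segs <- protocol_segments(protocol_none(), stage_time, model$external)
  E <- .make_ctx(model, segs[[1L]])
  rhs <- function(t, y, p) list(.cell_core(t, y, E)$dy)
  stages <- 0L
  res <- .rest_residual(y, model)
  while (res$max > 1e-4 && stages < max_stages) {
    sol <- deSolve::lsoda(y = y, times = c(0, stage_time), func = rhs,
                          parms = NULL, rtol = 1e-8,
                          atol = .state_scales(y) * 1e-10)
    y <- sol[nrow(sol), -1L]
    ## re-anchor the slow coordinates at their algebraic balance
    p <- model$params
    Vcyt <- y[["V"]] - p$V_ER - p$V_MT
    anchors <- .slow_anchors(y[["n_Ca"]] / Vcyt,
                             4 * pi * (3 * y[["V"]] / (4 * pi))^(2 / 3), p)
    y[["S_ref"]] <- anchors$S_ref
    y[["n_ve"]] <- anchors$n_ve
    stages <- stages + 1L
    res <- .rest_residual(y, model)
    if (verbose) {
      message(sprintf("rest stage %d: residual %.3e (%s)", stages, res$max,
                      res$which))
    }
  }
  newt <- .newton_rest(y, model, tol = tol, verbose = verbose)
  y <- newt$y
  res <- .rest_residual(y, model)
  if (res$max > tol) {
    ## fall back to further plain relaxation before failing
    for (k in seq_len(max_stages)) {
      sol <- deSolve::lsoda(y = y, times = c(0, stage_time), func = rhs,
                            parms = NULL, rtol = 1e-8,
                            atol = .state_scales(y) * 1e-10)
      y <- sol[nrow(sol), -1L]
      res <- .rest_residual(y, model)
      if (res$max <= tol) break
    }
  }
  if (res$max > tol) {
    stop(sprintf(
      "initialize_rest: no fixed point reached (residual %.3e in '%s')",
      res$max, res$which))
  }
  model$rest <- y
  model$rest_info <- list(residual = res$max, worst = res$which,
                          stages = stages, newton_iters = newt$iters)
  model
}

## damped Newton on the scaled derivative with numerical Jacobian
.newton_rest <- function(y, model, tol = 1e-8, max_iter = 25L,
                         verbose = FALSE) {
  n <- length(y)
  f <- function(yy) {
    sc <- .state_scales(yy)
    as.numeric(assemble_derivatives(yy, protocol_none(), 0, model)) / sc
  }
  iters <- 0L
  for (it in seq_len(max_iter)) {
    sc <- .state_scales(y)
    f0 <- f(y)
    r0 <- max(abs(f0))
    if (r0 <= tol) break
    J <- matrix(0, n, n)
    h <- pmax(abs(y), sc) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (f(yp) - f0) / (h[j] / sc[j])   # d f / d (y_j / sc_j)
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:8) {
      y_try <- y + lambda * step * sc
      ok <- tryCatch(max(abs(f(y_try))) , error = function(e) Inf)
      if (is.finite(ok) && ok < r0) {
        y <- y_try
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    iters <- it
    if (!improved) break
    if (verbose) message(sprintf("newton %d: residual %.3e", it,
                                 max(abs(f(y)))))
  }
  list(y = y, iters = iters)
}

#' Override model parameters without re-relaxing
#'
#' Returns a copy of the model with the given parameter overrides (internal
#' SI units) applied, keeping the already-relaxed resting state. This is the
#' standard setup of the knockout/over-expression experiments: the cell is
#' relaxed under the baseline parameter set, the conductance is changed, and
#' the stimulus is applied.
#'
#' @param model A relaxed `"merkel_model"`.
#' @param ... Named parameter overrides (see [merkel_params()]).
#' @return The modified model.
#' @export
set_params <- function(model, ...) {
  dots <- list(...)
  reg <- param_registry()$name
  unknown <- setdiff(names(dots), reg)
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  model$params[names(dots)] <- dots
  validate_params(model$params)
  model
}

#' @export
print.merkel_model <- function(x, ...) {
  cat("Merkel-cell whole-cell model (preset '", x$params$preset, "')\n", sep = "")
  cat(sprintf("  bath: Na %.4g, K %.4g, Cl %.4g, Ca %.4g mM (mannitol %.4g mM)\n",
              x$external$Na, x$external$K, x$external$Cl, x$external$Ca,
              x$external$mannitol))
  cat(sprintf("  impermeant species: n_A = %.4g mol, mean valence %.3f\n",
              x$n_A, x$z_A))
  if (!is.null(x$rest)) {
    cat(sprintf("  resting state: Vm = %.2f mV (residual %.2e)\n",
                x$rest[["Vm"]] * 1e3, x$rest_info$residual))
  } else {
    cat("  resting state: not yet relaxed (call initialize_rest)\n")
  }
  invisible(x)
}

#' @export
summary.merkel_model <- function(object, ...) {
  if (is.null(object$rest)) {
    print(object)
    return(invisible(object))
  }
  y <- object$rest
  p <- object$params
  Vcyt <- y[["V"]] - p$V_ER - p$V_MT
  print(object)
  cat("  resting composition:\n")
  cat(sprintf("    C_Na %.3g mM, C_K %.3g mM, C_Cl %.3g mM, C_Ca %.4g uM\n",
              y[["n_Na"]] / Vcyt, y[["n_K"]] / Vcyt, y[["n_Cl"]] / Vcyt,
              y[["n_Ca"]] / Vcyt * 1e3))
  cat(sprintf("    C_Ca_ER %.4g uM, C_Ca_MT %.4g uM, IP3 %.3g uM\n",
              y[["n_Ca_ER"]] / p$V_ER * 1e3, y[["n_Ca_MT"]] / p$V_MT * 1e3,
              y[["C_IP3"]] * 1e3))
  geo <- compressed_geometry(y[["V"]], p$r_ini, 0)
  sig <- cortex_stress(geo[["S"]], y[["S_ref"]], p$K_cortex, p$sigma_a)
  cat(sprintf("    volume %.1f um^3, S/S_ref %.3f, cortex stress %.0f Pa, vesicles %.0f\n",
              y[["V"]] * 1e18, geo[["S"]] / y[["S_ref"]], sig, y[["n_ve"]]))
  invisible(object)
}
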