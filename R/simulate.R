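## Protocol integration and trace extraction.

#' Run a stimulus protocol
#'
#' Integrates the whole-cell system from the model's resting state under a
#' stimulus protocol with a stiff adaptive solver (deSolve `lsoda` by
#' default). Protocol onsets/offsets are solver restart points, so
#' discontinuous drives never cross an integration step. Compression
#' protocols switch the Piezo2 phase flag to `loading` at ramp onset and to
#' `unloading` at release.
#'
#' @param model A relaxed `"merkel_model"`.
#' @param protocol A `"merkel_protocol"`.
#' @param horizon Simulated duration (s).
#' @param dt_out Output sampling interval (s). Default `horizon / 2000`.
#' @param rtol Relative solver tolerance (default `1e-6`).
#' @param atol_scale Absolute tolerances are `atol_scale` times each state
#'   variable's resting magnitude (default `1e-8`).
#' @param method deSolve integrator name (default `"lsoda"`).
#' @param initial Optional state vector to start from instead of
#'   `model$rest`.
#' @param maxsteps Maximum internal solver steps per output interval; the
#'   open ryanodine receptor couples ER and cytosol extremely stiffly, so
#'   the default is generous.
#' @return A `"merkel_trace"`: a data.frame with time in ms, `Vm_mV`,
#'   cytosolic/store Ca2+ and IP3 in uM, cortex stress in Pa, volume in
#'   um^3, vesicle count, exocytosis rate (vesicles/s) and indentation depth
#'   in um. The full state matrix is attached as attribute `"state"` (one
#'   row per sample, SI units).
#' @export
run_protocol <- function(model, protocol, horizon,
                         dt_out = NULL, rtol = 1e-6, atol_scale = 1e-8,
                         method = "lsoda", initial = NULL, maxsteps = 2e5) {
  if (is.null(model$rest) && is.null(initial)) {
    stop("run_protocol: model has no resting state; call initialize_rest()")
  }
  stopifnot(horizon > 0)
  y <- if (is.null(initial)) model$rest else .as_state_vector(initial)
  names(y) <- .state_names
  if (is.null(dt_out)) dt_out <- horizon / 2000
  segs <- protocol_segments(protocol, horizon, model$external)
  atol <- .state_scales(y) * atol_scale
  t_all <- NULL
  y_all <- NULL
  nfev <- 0L
  for (seg in segs) {
    E <- .make_ctx(model, seg)
    rhs <- function(t, y, p) list(.cell_core(t, y, E)$dy)
    times <- seq(seg$t0, seg$t1, by = dt_out)
    if (times[length(times)] < seg$t1) times <- c(times, seg$t1)
    if (length(times) < 2L) times <- c(seg$t0, seg$t1)
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("solver failure in segment [%g, %g] s; last valid time %g s",
                   seg$t0, seg$t1, sol[nrow(sol), 1L]))
    }
    nfev <- nfev + attr(sol, "istate")[3L]
    y <- sol[nrow(sol), -1L]
    keep <- if (is.null(t_all)) seq_len(nrow(sol)) else 2:nrow(sol)
    t_all <- c(t_all, sol[keep, 1L])
    y_all <- rbind(y_all, sol[keep, -1L, drop = FALSE])
  }
  colnames(y_all) <- .state_names
  trace <- .build_trace(t_all, y_all, model, protocol)
  attr(trace, "state") <- y_all
  attr(trace, "protocol") <- protocol
  attr(trace, "horizon") <- horizon
  attr(trace, "n_rhs_evaluations") <- nfev
  class(trace) <- c("merkel_trace", "data.frame")
  trace
}

## derived columns, vectorised over samples
.build_trace <- function(t, ymat, model, protocol) {
  p <- model$params
  Vcyt <- ymat[, "V"] - p$V_ER - p$V_MT
  cCa <- ymat[, "n_Ca"] / Vcyt
  d <- .depth_at(protocol, t, p)
  H <- 2 * p$r_ini - d
  r_sph <- (3 * ymat[, "V"] / (4 * pi))^(1 / 3)
  r_cyl <- sqrt(ymat[, "V"] / (pi * H))
  S <- ifelse(d > 0, 2 * pi * r_cyl^2 + 2 * pi * r_cyl * H, 4 * pi * r_sph^2)
  sigma <- p$K_cortex / 2 * (S / ymat[, "S_ref"] - 1) - p$sigma_a
  exo <- p$k_exo / (1 + exp(-(cCa - p$c_Ca_s) / p$c_Ca_f)) * ymat[, "n_ve"]
  data.frame(
    time_ms = t * 1e3,
    Vm_mV = ymat[, "Vm"] * 1e3,
    C_Ca_uM = cCa * 1e3,
    C_Ca_ER_uM = ymat[, "n_Ca_ER"] / p$V_ER * 1e3,
    C_Ca_MT_uM = ymat[, "n_Ca_MT"] / p$V_MT * 1e3,
    C_IP3_uM = ymat[, "C_IP3"] * 1e3,
    sigma_Pa = sigma,
    V_um3 = ymat[, "V"] * 1e18,
    n_ve = ymat[, "n_ve"],
    exo_rate_per_s = exo,
    d_um = d * 1e6
  )
}

.depth_at <- function(protocol, t, p) {
  if (protocol$kind != "compression") return(rep(0, length(t)))
  ramp <- protocol$depth / protocol$speed
  on <- protocol$onset
  t_top <- on + ramp
  t_rel <- if (is.finite(protocol$hold)) t_top + protocol$hold else Inf
  d <- pmin(pmax((t - on) * protocol$speed, 0), protocol$depth)
  if (is.finite(t_rel) && protocol$release) {
    after <- t >= t_rel
    d[after] <- pmax(protocol$depth - (t[after] - t_rel) * protocol$speed, 0)
  }
  pmin(d, 2 * p$r_ini * 0.999)
}

#' Simulate a Merkel-cell experiment
#'
#' `simulate()` method for `"merkel_model"`: runs a stimulus protocol from
#' the resting state. The model is deterministic, so `nsim` and `seed` are
#' accepted for interface compatibility but do not alter the result.
#'
#' @param object A relaxed `"merkel_model"`.
#' @param nsim Number of traces (deterministic; copies of the same trace if
#'   `> 1`).
#' @param seed Ignored (deterministic model); kept for the generic's
#'   signature.
#' @param protocol A `"merkel_protocol"` (default: none).
#' @param horizon Simulated duration (s).
#' @param ... Passed to [run_protocol()].
#' @return A `"merkel_trace"` (or a list of them if `nsim > 1`).
#' @export
simulate.merkel_model <- function(object, nsim = 1, seed = NULL,
                                  protocol = protocol_none(), horizon = 1,
                                  ...) {
  tr <- run_protocol(object, protocol, horizon, ...)
  if (nsim == 1) tr else rep(list(tr), nsim)
}

#' @export
print.merkel_trace <- function(x, ...) {
  cat(sprintf("Merkel-cell trace: %d samples over %.4g s (%s protocol)\n",
              nrow(x), utils::tail(x$time_ms, 1) / 1e3,
              attr(x, "protocol")$kind))
  print(utils::head(as.data.frame(x), 4))
  cat("...\n")
  invisible(x)
}

#' Time for a signal to complete a fraction of its return to baseline
#'
#' Starting at the signal's extremal excursion after `from`, the first time
#' at which the signal has covered `frac` of the distance back to
#' `baseline`; `NA` with a lower bound attribute if it never does within the
#' trace.
#'
#' @param time,x Numeric vectors (same length), time in any unit.
#' @param from Measure from the first time `>= from` (same unit as `time`).
#' @param baseline Baseline value; default the value at the start of the
#'   trace.
#' @param frac Fraction of the return to complete (default 0.9).
#' @return Elapsed time from the extremum to the crossing (units of `time`),
#'   or `NA` with attribute `lower_bound` if not reached.
#' @export
signal_return_time <- function(time, x, from = time[1], baseline = x[1],
                               frac = 0.9) {
  sel <- time >= from
  tt <- time[sel]; xx <- x[sel]
  dev <- abs(xx - baseline)
  ipk <- which.max(dev)
  if (dev[ipk] == 0) return(0)
  target <- (1 - frac) * dev[ipk]
  after <- seq(ipk, length(xx))
  hit <- after[dev[after] <= target]
  if (!length(hit)) {
    out <- NA_real_
    attr(out, "lower_bound") <- tt[length(tt)] - tt[ipk]
    return(out)
  }
  tt[hit[1]] - tt[ipk]
}

#' Time a signal spends above a threshold
#'
#' Total time (trapezoidal occupancy of samples) with `x > threshold`.
#'
#' @param time,x Numeric vectors.
#' @param threshold Threshold value.
#' @return Duration in the units of `time`.
#' @export
time_above <- function(time, x, threshold) {
  if (length(time) < 2L) return(0)
  dt <- diff(time)
  above <- x > threshold
  mid <- (above[-1] + above[-length(above)]) / 2
  sum(dt * mid)
}

#' Summarise a trace
#'
#' Quantifies the standard descriptors of a simulated experiment: peak and
#' steady membrane potential, peak cytosolic Ca2+, the Ca2+-transient
#' duration (time above a threshold interpolating between baseline and
#' peak), the exocytosis duration (time the exocytosis rate exceeds a
#' multiple of its pre-stimulus baseline), and 90%-return times of Vm and
#' Ca2+. Thresholds and windows are recorded alongside the numbers.
#'
#' @param trace A `"merkel_trace"`.
#' @param steady_frac Fraction of the trace tail averaged for the steady
#'   values (default 0.1).
#' @param ca_thresh_frac Ca2+ duration threshold as a fraction of the rise
#'   above baseline (default 0.5: full width above half-rise).
#' @param exo_factor Exocytosis duration threshold as a multiple of the
#'   pre-stimulus rate (default 2).
#' @param baseline_window Time (ms) at the start of the trace averaged for
#'   baselines; defaults to the span before the protocol onset, or the
#'   first sample if the stimulus starts at 0.
#' @return A list of named scalars plus a `settings` element.
#' @export
summarize_trace <- function(trace, steady_frac = 0.1, ca_thresh_frac = 0.5,
                            exo_factor = 2, baseline_window = NULL) {
  if (!nrow(trace)) stop("summarize_trace: empty trace")
  t_ms <- trace$time_ms
  prot <- attr(trace, "protocol")
  if (is.null(baseline_window)) {
    onset_ms <- if (!is.null(prot) && !is.null(prot$onset)) prot$onset * 1e3 else 0
    baseline_window <- max(onset_ms, 0)
  }
  base_idx <- if (baseline_window > 0) which(t_ms <= baseline_window) else 1L
  tail_idx <- which(t_ms >= (1 - steady_frac) * t_ms[length(t_ms)])
  base <- function(x) mean(x[base_idx])
  vm0 <- base(trace$Vm_mV); ca0 <- base(trace$C_Ca_uM)
  exo0 <- base(trace$exo_rate_per_s)
  vm_peak <- max(trace$Vm_mV); ca_peak <- max(trace$C_Ca_uM)
  ca_thr <- ca0 + ca_thresh_frac * (ca_peak - ca0)
  exo_thr <- exo_factor * max(exo0, .Machine$double.eps)
  list(
    peak_Vm_mV = vm_peak,
    steady_Vm_mV = mean(trace$Vm_mV[tail_idx]),
    baseline_Vm_mV = vm0,
    peak_C_Ca_uM = ca_peak,
    baseline_C_Ca_uM = ca0,
    ca_duration_ms = time_above(t_ms, trace$C_Ca_uM, ca_thr),
    exo_duration_ms = time_above(t_ms, trace$exo_rate_per_s, exo_thr),
    vm_return90_ms = signal_return_time(t_ms, trace$Vm_mV,
                                        baseline = vm0, frac = 0.9),
    ca_return90_ms = signal_return_time(t_ms, trace$C_Ca_uM,
                                        baseline = ca0, frac = 0.9),
    settings = list(steady_frac = steady_frac,
                    ca_thresh_frac = ca_thresh_frac,
                    ca_threshold_uM = ca_thr,
                    exo_factor = exo_factor,
                    exo_threshold_per_s = exo_thr,
                    baseline_window_ms = baseline_window)
  )
}

#' Plot a trace
#'
#' Four-panel base-graphics view of a simulated experiment: membrane
#' potential, cytosolic Ca2+, cortex stress and exocytosis rate against
#' time.
#'
#' @param x A `"merkel_trace"`.
#' @param ... Unused.
#' @export
plot.merkel_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  t_s <- x$time_ms / 1e3
  graphics::plot(t_s, x$Vm_mV, type = "l", xlab = "time (s)",
                 ylab = "Vm (mV)")
  graphics::plot(t_s, x$C_Ca_uM, type = "l", xlab = "time (s)",
                 ylab = expression(C[Ca] ~ (mu * M)))
  graphics::plot(t_s, x$sigma_Pa, type = "l", xlab = "time (s)",
                 ylab = expression(sigma ~ (Pa)))
  graphics::plot(t_s, x$exo_rate_per_s, type = "l", xlab = "time (s)",
                 ylab = "exocytosis (ves/s)")
  invisible(x)
}
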