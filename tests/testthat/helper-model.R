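# Shared fixtures: rest relaxation is deterministic but takes a few seconds,
# so relaxed models are built lazily and cached for the whole test run.

.model_cache <- new.env(parent = emptyenv())

cached_model <- function(key = "fig2", builder = function() merkel_model()) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

rest_fig2 <- function() cached_model("fig2")

# independent transcription of the exchanger law used as a numeric oracle
ncx_oracle <- function(Vm, cNa, cNa_out, cCa, cCa_out, P, T = 310) {
  RT <- 8.314462618 * T
  Fc <- 96485.33212
  vf <- Vm * Fc / RT
  num <- exp(0.1 * vf) * cNa^3 * cCa_out - exp(-0.9 * vf) * cNa_out^3 * cCa
  den <- (87.5^3 + cNa_out^3) * (5e-4 + cCa_out) * (1 + 0.35 * exp(-0.9 * vf))
  P * num / den
}

# classical fixed-step fourth-order Runge-Kutta on the package's derivative
rk4_integrate <- function(model, protocol, t_end, dt, y0, sample_every) {
  y <- unname(y0)
  n_steps <- round(t_end / dt)
  out_t <- numeric(0)
  out_y <- NULL
  f <- function(t, y) {
    unname(as.numeric(assemble_derivatives(y, protocol, t, model)))
  }
  # segment lookups per step would dominate; precompute contexts like the
  # solver does
  segs <- merkelcell:::protocol_segments(protocol, t_end, model$external)
  ctxs <- lapply(segs, function(s) merkelcell:::.make_ctx(model, s))
  core <- merkelcell:::.cell_core
  seg_i <- 1L
  t <- 0
  for (k in seq_len(n_steps)) {
    while (seg_i < length(segs) && t >= segs[[seg_i]]$t1 - 1e-12) {
      seg_i <- seg_i + 1L
    }
    E <- ctxs[[seg_i]]
    k1 <- core(t, y, E)$dy
    k2 <- core(t + dt / 2, y + dt / 2 * k1, E)$dy
    k3 <- core(t + dt / 2, y + dt / 2 * k2, E)$dy
    k4 <- core(t + dt, y + dt * k3, E)$dy
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (k %% sample_every == 0) {
      out_t <- c(out_t, t)
      out_y <- rbind(out_y, y)
    }
  }
  list(t = out_t, y = out_y)
}
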