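test_that("the relaxed resting state is a fixed point of the assembled system", {
  m <- rest_fig2()
  dy <- assemble_derivatives(m$rest, protocol_none(), 0, m)
  scales <- merkelcell:::.state_scales(m$rest)
  expect_lt(max(abs(dy) / scales), 1e-8)
  # resting water balance: hydrostatic and osmotic pressures agree
  aux <- attr(dy, "aux")
  expect_lt(abs(aux[["dP"]] - aux[["dPi"]]) / aux[["dP"]], 1e-6)
  # resting potential in the physiological band
  expect_gt(m$rest[["Vm"]], -0.08)
  expect_lt(m$rest[["Vm"]], -0.04)
})

test_that("zeroing every membrane pathway freezes the ion, charge and volume state", {
  m <- rest_fig2()
  zeroed <- set_params(m,
    g_Kv14 = 0, g_Kv42 = 0, g_BKCa = 0, g_KDR = 0, g_Cav12 = 0, g_Cav21 = 0,
    g_Piezo2 = 0, g_Na_leak = 0, g_K_leak = 0, g_Cl_leak = 0, g_Ca_leak = 0,
    P_NaKpump = 0, P_NKCC1 = 0, P_KCC2 = 0, P_Capump = 0, P_Cana = 0,
    P_pump_ER = 0, P_RYR = 0, P_leak_ER = 0, P_IP3 = 0, P_MCU = 0,
    P_MNCX = 0, alpha_water = 0)
  dy <- assemble_derivatives(m$rest, protocol_none(), 0, zeroed)
  frozen <- c("n_Na", "n_K", "n_Cl", "n_Ca", "Vm", "n_Ca_ER", "n_Ca_MT", "V")
  expect_equal(unname(dy[frozen]), rep(0, length(frozen)))
})

test_that("the membrane-potential equation equals an independent charge re-summation", {
  m <- rest_fig2()
  # charge moved into the cell per unit flux, transcribed independently:
  # K+ channels and K/Na leaks +1, Ca2+-carrying channel fluxes +2 (the
  # model's molar convention), Cl- leak -1, pump and exchanger net +1 out,
  # PMCA 2 charges out, cotransporters neutral
  w <- c("Kv1.4" = 1, "Kv4.2" = 1, "BKCa" = 1, "KDR" = 1,
         "Cav1.2" = 2, "Cav2.1" = 2, "Piezo2" = 2,
         "Na_leak" = 1, "K_leak" = 1, "Cl_leak" = -1, "Ca_leak" = 2,
         "NaK_pump" = -1, "NKCC1" = 0, "KCC2" = 0, "Ca_pump" = -2,
         "NCX" = -1, "SERCA" = 0, "RyR" = 0, "IP3R" = 0, "MCU" = 0,
         "MNCX" = 0, "water" = 0)
  Fc <- 96485.33212
  set.seed(7)
  prot <- protocol_current_pulse(50, onset = 0, duration = 1)
  for (k in 1:20) {
    y <- m$rest
    jitter <- stats::rnorm(length(y), 0, 0.02)
    y <- y * (1 + jitter)
    y[["Vm"]] <- stats::runif(1, -0.09, 0.05)
    gate_idx <- 6:19
    y[gate_idx] <- pmin(pmax(y[gate_idx], 0), 1)
    dy <- assemble_derivatives(y, prot, 0.5, m)
    fl <- attr(dy, "fluxes")
    aux <- attr(dy, "aux")
    dvm_oracle <- (Fc * sum(w[names(fl)] * fl) +
                     aux[["I_app"]] / y[["S_ref"]]) / m$params$C_m
    expect_equal(dy[["Vm"]], dvm_oracle, tolerance = 1e-9)
  }
})

test_that("non-finite fluxes are reported by pathway name", {
  m <- rest_fig2()
  y <- m$rest
  y[["Vm"]] <- 1e5   # exchange exponentials overflow
  expect_error(assemble_derivatives(y, protocol_none(), 0, m), "NCX")
})

test_that("the null protocol holds the resting state for a minute", {
  m <- rest_fig2()
  tr <- run_protocol(m, protocol_none(), horizon = 60, dt_out = 0.5)
  expect_lt(max(abs(tr$Vm_mV - tr$Vm_mV[1])), 0.1)
  # a further relaxation check at higher resolution: Vm moves < 0.01 mV
  expect_lt(max(abs(tr$Vm_mV - m$rest[["Vm"]] * 1e3)), 0.01)
  expect_lt(max(abs(tr$C_Ca_uM / tr$C_Ca_uM[1] - 1)), 0.01)
})

test_that("ion bookkeeping: amount changes equal time-integrated fluxes", {
  m <- rest_fig2()
  prot <- protocol_current_pulse(40, onset = 0.01, duration = 0.1)
  tr <- run_protocol(m, prot, horizon = 0.15, dt_out = 2.5e-4, rtol = 1e-8)
  st <- attr(tr, "state")
  t <- tr$time_ms / 1e3
  fl <- t(vapply(seq_along(t), function(i) {
    f <- flux_vector(st[i, ], prot, t[i], m)
    sref <- st[i, "S_ref"]
    c(K = sref * (f[["Kv1.4"]] + f[["Kv4.2"]] + f[["KDR"]] + f[["BKCa"]] +
                    2 * f[["NaK_pump"]] + f[["NKCC1"]] - f[["KCC2"]] +
                    f[["K_leak"]]),
      Cl = sref * (2 * f[["NKCC1"]] - f[["KCC2"]] + f[["Cl_leak"]]))
  }, c(K = 0, Cl = 0)))
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  dK <- unname(st[nrow(st), "n_K"] - st[1, "n_K"])
  dCl <- unname(st[nrow(st), "n_Cl"] - st[1, "n_Cl"])
  expect_lt(abs(trapz(t, fl[, "K"]) - dK), 0.01 * abs(dK))
  expect_lt(abs(trapz(t, fl[, "Cl"]) - dCl), 0.02 * abs(dCl))
})

test_that("trace summaries recover constructed pulse shapes", {
  t_ms <- seq(0, 1000, by = 1)
  tri <- pmax(0, 1 - abs(t_ms - 500) / 100)      # width 200 ms at base
  tr <- data.frame(time_ms = t_ms, Vm_mV = -55 + 0 * t_ms,
                   C_Ca_uM = 0.1 + tri, exo_rate_per_s = 0.01 + 0 * t_ms)
  class(tr) <- c("merkel_trace", "data.frame")
  s <- summarize_trace(tr, baseline_window = 100)
  expect_equal(s$peak_C_Ca_uM, 1.1)
  # full width above half the rise of a triangle of half-width 100 ms
  expect_equal(s$ca_duration_ms, 100, tolerance = 2)
  expect_equal(s$peak_Vm_mV, s$steady_Vm_mV)
  expect_equal(s$exo_duration_ms, 0)
  # constant trace: zero durations, peak equals steady
  tc <- data.frame(time_ms = t_ms, Vm_mV = -55, C_Ca_uM = 0.1,
                   exo_rate_per_s = 0.01)
  class(tc) <- c("merkel_trace", "data.frame")
  sc <- summarize_trace(tc, baseline_window = 100)
  expect_equal(sc$ca_duration_ms, 0)
  expect_error(summarize_trace(tc[0, ]), "empty")
})

test_that("time_above and signal_return_time measure what they say", {
  t <- 0:100
  x <- ifelse(t >= 20 & t < 60, 1, 0)
  expect_equal(time_above(t, x, 0.5), 40, tolerance = 1)
  y <- exp(-(t - 10) / 5) * (t >= 10)
  rt <- signal_return_time(t, y, baseline = 0, frac = 0.9)
  expect_equal(rt, 5 * log(10), tolerance = 1.1)
})
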