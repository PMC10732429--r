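test_that("Nernst potential: closed form, symmetry, domain errors", {
  expect_equal(nernst_potential(5, 5, 1), 0)
  expect_equal(nernst_potential(5, 5, -2), 0)
  expect_equal(nernst_potential(10, 2, 2, T = 300),
               -nernst_potential(2, 10, 2, T = 300))
  # K+-like gradient at body temperature, direct closed-form evaluation
  expected <- -(8.314462618 * 310 / 96485.33212) * log(140 / 5)
  expect_equal(nernst_potential(140, 5, 1, T = 310), expected,
               tolerance = 1e-12)
  expect_error(nernst_potential(-1, 5, 1), "positive")
  expect_error(nernst_potential(1, 0, 1), "positive")
  expect_error(nernst_potential(1, 5, 0), "valence")
})

test_that("gating steady states hit their published midpoints exactly", {
  tol <- 1e-12
  expect_equal(gating_rates("Kv1.4", -23.12e-3)$m[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Kv1.4", -44.36e-3)$h_fast[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Kv4.2", 17.66e-3)$m[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Kv4.2", -44.36e-3)$h[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("KDR", -33.3e-3)$n[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Cav1.2", 8.46e-3)$m[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Cav1.2", -42.52e-3)$h[["steady"]], 0.5, tolerance = tol)
  expect_equal(gating_rates("Cav2.1", -5.1e-3)$n[["steady"]], 0.5, tolerance = tol)
  # Ca2+-dependent midpoints
  expect_equal(gating_rates("Cav1.2", 0, C_Ca = 1e-3)$hCa, 0.5, tolerance = tol)
  # at 1 mM Ca2+ the BKCa shift vanishes and V_half sits at -110 mV
  expect_equal(gating_rates("BKCa", -110e-3, C_Ca = 1)$n[["steady"]], 0.5,
               tolerance = tol)
})

test_that("the two A-type inactivation curves are the same expression", {
  for (vm in seq(-100e-3, 60e-3, by = 20e-3)) {
    expect_identical(gating_rates("Kv1.4", vm)$h_fast[["steady"]],
                     gating_rates("Kv4.2", vm)$h[["steady"]])
  }
})

test_that("steady values are in (0,1), monotone, and time constants positive", {
  vms <- seq(-120e-3, 80e-3, length.out = 81)
  pull <- function(ch, elem, what) {
    vapply(vms, function(v) gating_rates(ch, v, C_Ca = 1e-4)[[elem]][[what]],
           numeric(1))
  }
  acts <- list(c("Kv1.4", "m"), c("Kv4.2", "m"), c("BKCa", "n"),
               c("KDR", "n"), c("Cav1.2", "m"), c("Cav2.1", "n"))
  inacts <- list(c("Kv1.4", "h_fast"), c("Kv1.4", "h_slow"),
                 c("Kv4.2", "h"), c("Cav1.2", "h"))
  for (a in acts) {
    x <- pull(a[1], a[2], "steady")
    expect_true(all(x > 0 & x < 1), label = paste(a, collapse = " "))
    expect_true(all(diff(x) > 0), label = paste("increasing", a[1], a[2]))
  }
  for (a in inacts) {
    x <- pull(a[1], a[2], "steady")
    expect_true(all(x > 0 & x < 1), label = paste(a, collapse = " "))
    expect_true(all(diff(x) < 0), label = paste("decreasing", a[1], a[2]))
  }
  for (a in c(acts, inacts)) {
    tau <- pull(a[1], a[2], "tau")
    expect_true(all(tau > 0), label = paste("tau", a[1], a[2]))
  }
  expect_error(gating_rates("Kv9.9", 0), "unknown channel")
})

test_that("BKCa activation right-shifts as Ca2+ falls", {
  # the empirical half-activation voltage (where n_inf crosses 0.5) moves to
  # more positive potentials as Ca2+ decreases
  vhalf <- vapply(c(1e-1, 1e-3, 1e-5), function(cca) {
    stats::uniroot(function(v) {
      gating_rates("BKCa", v, C_Ca = cca)$n[["steady"]] - 0.5
    }, c(-0.3, 0.3), tol = 1e-10)$root
  }, numeric(1))
  expect_true(all(diff(vhalf) > 0))
  # closed form of the shift: V_half = -43.3 * log10(C_Ca / 1 mM) - 110 mV
  expect_equal(vhalf * 1e3, -43.3 * log10(c(1e-1, 1e-3, 1e-5)) - 110,
               tolerance = 1e-6)
})

test_that("channel fluxes vanish at reversal and follow the open-probability laws", {
  gat <- list(m = 0.6, h = 0.4, h_fast = 0.3, h_slow = 0.8, n = 0.5)
  for (ch in c("Kv1.4", "Kv4.2", "BKCa", "KDR", "Cav1.2", "Cav2.1")) {
    expect_equal(voltage_gated_flux(ch, gat, 1e-4, -0.03, -0.03, 5), 0,
                 label = ch)
    zero_gat <- lapply(gat, function(x) 0)
    expect_equal(voltage_gated_flux(ch, zero_gat, 1e-4, 0.05, -0.09, 5), 0,
                 label = paste("closed", ch))
  }
  # direct evaluation: fully open Kv1.4 at 0.25 mS/cm2, 100 mV driving force
  J <- voltage_gated_flux("Kv1.4", list(m = 1, h_fast = 1, h_slow = 1),
                          1e-4, Vm = 0.1, reversal = 0,
                          g = to_si(0.25, "mS/cm^2"))
  expected_cgs <- 0.25e-3 * 0.1 / 96485.33212    # mol s^-1 cm^-2
  expect_equal(abs(J), expected_cgs * 1e4, tolerance = 1e-12)
  expect_lt(J, 0)  # outward K+ flux above the reversal
  expect_error(voltage_gated_flux("KDR", list(n = 0.5), 1e-4, 0, -0.09, -1),
               "negative")
  expect_error(voltage_gated_flux("KDR", list(n = 1.5), 1e-4, 0, -0.09, 1),
               "0, 1")
})

test_that("leak fluxes are ohmic with physiological directions", {
  expect_equal(leak_flux("Na", -0.06, -0.06, 2), 0)
  # Ca2+ leak is inward at rest (E_Ca far above Vm)
  expect_gt(leak_flux("Ca", -0.06, 0.13, 2e-4), 0)
  # K+ leak is outward above E_K
  expect_lt(leak_flux("K", -0.05, -0.089, 0.9), 0)
  # Cl- influx when Vm above E_Cl (anion convention)
  expect_gt(leak_flux("Cl", -0.05, -0.089, 0.05), 0)
  expect_equal(leak_flux("K", -0.05, -0.089, 1.8),
               2 * leak_flux("K", -0.05, -0.089, 0.9))
  expect_error(leak_flux("Mg", 0, 0, 1), "unknown ion")
})

test_that("Na/K pump saturates and halves at its half-activation point", {
  P <- 3.7312e-6
  expect_equal(nak_pump_flux(10, 140, P), P / 32, tolerance = 1e-12)
  expect_equal(nak_pump_flux(1e6, 1e-6, P), P, tolerance = 1e-4)
  expect_lt(nak_pump_flux(1e-3, 140, P), P * 1e-6)
})

test_that("cotransporters are zero at their product equilibria", {
  env <- list(C_Na = 10, C_K = 140, C_Cl = 11, C_Na_out = 140, C_K_out = 10,
              C_Cl_out = sqrt(10 * 140 * 11^2 / (140 * 10)))
  expect_equal(nkcc1_flux(env, 2.4e-16), 0, tolerance = 1e-25)
  env2 <- list(C_K = 70, C_Cl = 10, C_K_out = 7, C_Cl_out = 100)
  expect_equal(kcc2_flux(env2, 2.5e-8), 0)
  # directions
  env_in <- list(C_Na = 10, C_K = 5, C_Cl = 5, C_Na_out = 145, C_K_out = 5,
                 C_Cl_out = 110)
  expect_gt(nkcc1_flux(env_in, 2.4e-16), 0)
  env_out <- list(C_K = 140, C_Cl = 10, C_K_out = 5, C_Cl_out = 110)
  expect_gt(kcc2_flux(env_out, 2.5e-8), 0)
  expect_equal(nkcc1_flux(env_in, 4.8e-16), 2 * nkcc1_flux(env_in, 2.4e-16))
})

test_that("PMCA follows its Hill law", {
  P <- 3e-9
  expect_equal(pmca_flux(3e-4, P), P / 2, tolerance = 1e-12)
  expect_equal(pmca_flux(0, P), 0)
  expect_equal(pmca_flux(10, P), P, tolerance = 1e-6)
})

test_that("NCX reverses at its electrochemical equilibrium and matches a direct transcription", {
  P <- 1e-6
  env <- list(C_Na = 10, C_Ca = 1e-4, C_Na_out = 145, C_Ca_out = 2)
  # reversal: choose C_Ca making the bracket vanish at Vm = -40 mV
  Vm <- -0.04
  RT <- 8.314462618 * 310
  vf <- Vm * 96485.33212 / RT
  env_rev <- env
  env_rev$C_Ca <- exp(0.1 * vf) * env$C_Na^3 * env$C_Ca_out /
    (exp(-0.9 * vf) * env$C_Na_out^3)
  expect_equal(ncx_flux(Vm, env_rev, P), 0, tolerance = 1e-20)
  # at Vm = 0 the sign follows the concentration bracket
  expect_equal(sign(ncx_flux(0, env, P)),
               sign(env$C_Na^3 * env$C_Ca_out - env$C_Na_out^3 * env$C_Ca))
  # full numeric value against an independent transcription
  expect_equal(ncx_flux(0, env, P),
               ncx_oracle(0, 10, 145, 1e-4, 2, P), tolerance = 1e-12)
  expect_equal(ncx_flux(-0.055, env, P),
               ncx_oracle(-0.055, 10, 145, 1e-4, 2, P), tolerance = 1e-12)
})
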