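p_store <- merkel_params()

test_that("SERCA Hill law: midpoint, zero, saturation", {
  P <- 7e-11
  expect_equal(serca_flux(1e-4, P), P / 2, tolerance = 1e-12)
  expect_equal(serca_flux(0, P), 0)
  expect_equal(serca_flux(1, P), P, tolerance = 1e-7)
})

test_that("ryanodine release is gated by a cytosolic threshold", {
  P <- 85
  # below and at the threshold: zero branch
  expect_identical(ryr_flux(2e-4, 0.5, P), 0)
  expect_identical(ryr_flux(3e-4, 0.5, P), 0)
  # far above threshold the sigmoid saturates to the bare gradient law
  expect_equal(ryr_flux(5e-3, 0.5, P), P * (0.5 - 5e-3), tolerance = 1e-6)
  # no gradient, no flux; reversed gradient, reversed flux
  expect_equal(ryr_flux(5e-4, 5e-4, P), 0)
  expect_lt(ryr_flux(5e-3, 1e-3, P), 0)
})

test_that("IP3R gates: midpoints, fixed taus, bell-shaped open product", {
  r1 <- ip3r_rates(4e-4, p_store)
  expect_equal(r1[["m_steady"]], 0.5, tolerance = 1e-12)
  r2 <- ip3r_rates(6e-4, p_store)
  expect_equal(r2[["h_steady"]], 0.5, tolerance = 1e-12)
  expect_equal(r1[["tau_m"]], 10)
  expect_equal(r1[["tau_h"]], 20)
  cca <- 10^seq(log10(1e-5), log10(1e-2), length.out = 200)  # 0.01..10 uM
  prod <- vapply(cca, function(c) {
    r <- ip3r_rates(c, p_store); r[["m_steady"]] * r[["h_steady"]]
  }, numeric(1))
  imax <- which.max(prod)
  expect_gt(imax, 1)
  expect_lt(imax, length(prod))
  expect_gt(max(prod), 10 * prod[1])
  expect_gt(max(prod), 10 * prod[length(prod)])
})

test_that("IP3R flux separates leak and IP3-gated parts", {
  expect_equal(ip3r_flux(1e-4, 5e-4, 1e-3, 0.5, 0.5, P_leak = 7e-3, P_IP3 = 0),
               7e-3 * 4e-4, tolerance = 1e-12)
  # Hill midpoint at K_IP3: gated permeability is P_IP3 * m * h / 2
  J <- ip3r_flux(1e-4, 5e-4, 3e-3, 0.8, 0.5, P_leak = 0, P_IP3 = 17.5)
  expect_equal(J, 17.5 / 2 * 0.8 * 0.5 * 4e-4, tolerance = 1e-12)
  expect_equal(ip3r_flux(2e-4, 2e-4, 3e-3, 1, 1, 7e-3, 17.5), 0)
  expect_error(ip3r_flux(1e-4, 5e-4, 1e-3, 1.2, 0.5, 1, 1), "0, 1")
})

test_that("IP3 turnover: pure decay without Ca2+, midpoint replenishment, quasi-steady level", {
  d0 <- ip3_turnover(0, 2e-3, 5e-3, p_store)
  expect_equal(d0[["dIP3"]], -p_store$k_dIP3 * 2e-3, tolerance = 1e-15)
  # precursor at its sigmoid midpoint: replenishment at half rate
  d1 <- ip3_turnover(0, 0, p_store$K_s_preIP3, p_store)
  expect_equal(d1[["dpreIP3"]], p_store$k_preIP3 / 2, tolerance = 1e-12)
  # at fixed high Ca2+ the subsystem relaxes to the root-found fixed point
  cca <- 2e-3  # 2 uM
  sat <- cca^2 / (cca^2 + p_store$K_IP3Ca^2)
  pre_star <- stats::uniroot(function(x) {
    p_store$k_preIP3 / (1 + exp((x - p_store$K_s_preIP3) / p_store$K_f_preIP3)) -
      p_store$k_IP3 * sat * x
  }, c(0, 1), tol = 1e-14)$root
  ip3_star <- p_store$k_IP3 * sat * pre_star / p_store$k_dIP3
  rhs <- function(t, y, parms) {
    d <- ip3_turnover(cca, y[1], y[2], p_store)
    list(c(d[["dIP3"]], d[["dpreIP3"]]))
  }
  sol <- deSolve::lsoda(c(1e-4, 9e-3), c(0, 2000), rhs, NULL,
                        rtol = 1e-10, atol = 1e-14)
  expect_equal(unname(sol[2, 2]), ip3_star, tolerance = 1e-5)
  expect_equal(unname(sol[2, 3]), pre_star, tolerance = 1e-5)
})

test_that("mitochondrial uptake and release hit their half-activation points", {
  f <- mito_fluxes(6e-4, 1e-3, P_MCU = 5e-9, P_MNCX = 1e-9)
  expect_equal(f[["uptake"]], 5e-9 / 2, tolerance = 1e-12)
  expect_equal(f[["release"]], 1e-9 / 2, tolerance = 1e-12)
  f0 <- mito_fluxes(0, 0, 5e-9, 1e-9)
  expect_equal(unname(f0), c(0, 0))
})

test_that("store balances book the organelle surfaces and the buffer factor", {
  fl <- list(serca = 2e-10, ip3r = 5e-11, ryr = 3e-11, mcu = 4e-10,
             mncx = 1e-10)
  b <- store_balances(fl, p_store)
  expect_equal(b[["dn_ER"]], p_store$S_ER * (2e-10 - 5e-11 - 3e-11))
  expect_equal(b[["dn_MT"]],
               p_store$S_MT / 1.3 * (4e-10 - 1e-10))
  # the mitochondrial buffer scales the derivative by 1/(1+beta)
  p0 <- merkel_params(beta_MT = 0)
  expect_equal(store_balances(fl, p0)[["dn_MT"]] / b[["dn_MT"]], 1.3,
               tolerance = 1e-12)
  z <- store_balances(list(serca = 0, ip3r = 0, ryr = 0, mcu = 0, mncx = 0),
                      p_store)
  expect_equal(unname(z), c(0, 0))
})

test_that("IP3R gates converge monotonically to their steady values", {
  cca <- 5e-4
  r <- ip3r_rates(cca, p_store)
  m <- 0.05; h <- 0.95
  dt <- 0.5
  ms <- hs <- numeric(60)
  for (k in 1:60) {
    m <- m + dt * (r[["m_steady"]] - m) / r[["tau_m"]]
    h <- h + dt * (r[["h_steady"]] - h) / r[["tau_h"]]
    ms[k] <- m; hs[k] <- h
  }
  expect_true(all(diff(ms) > 0) || all(diff(ms) < 0))
  expect_true(all(diff(hs) > 0) || all(diff(hs) < 0))
  expect_equal(ms[60], r[["m_steady"]], tolerance = 0.05)
})
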