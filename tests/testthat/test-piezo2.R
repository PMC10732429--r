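test_that("stress midpoints and time constants match the state-machine table", {
  r <- piezo2_rates(1450)
  expect_equal(r[["C_inf"]], 0.5, tolerance = 1e-12)
  expect_equal(r[["In_inf"]], 0.5, tolerance = 1e-12)
  expect_equal(r[["h_slow_inf"]], 0.5, tolerance = 1e-12)
  expect_equal(r[["tau_hslow"]], 150 / 2 * 1e-3, tolerance = 1e-12)
  # taus strictly positive over the working stress range
  for (s in seq(0, 5000, by = 250)) {
    r <- piezo2_rates(s)
    expect_true(all(r[c("tau_C", "tau_O", "tau_In", "tau_hslow")] > 0))
  }
})

test_that("state derivatives conserve the C+O+In simplex exactly", {
  st <- list(C = 0.55, O = 0.15, In = 0.30, h_slow = 0.4)
  for (ph in c("loading", "unloading")) {
    for (s in c(100, 1200, 1450, 3000)) {
      d <- piezo2_derivatives(st, s, ph)
      scale <- max(1, abs(d[["C"]]), abs(d[["In"]]))
      expect_lt(abs(d[["C"]] + d[["O"]] + d[["In"]]) / scale, 1e-12)
    }
  }
})

test_that("exact-relaxation updates stay on the simplex and in [0,1]", {
  set.seed(42)
  st <- list(C = 1, O = 0, In = 0, h_slow = 0.1)
  for (k in 1:200) {
    sigma <- runif(1, 0, 4000)
    dt <- 10^runif(1, -4, -0.5)
    phase <- sample(c("loading", "unloading"), 1)
    st <- piezo2_advance(st, sigma, dt, phase = phase)
    v <- unlist(st[c("C", "O", "In", "h_slow")])
    expect_lt(abs(sum(v[1:3]) - 1), 1e-9)
    expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
  }
})

test_that("a long hold at high stress inactivates the open state", {
  st <- list(C = 1, O = 0, In = 0, h_slow = 0)
  # strong load: open fraction spikes, then drains into inactivation
  st1 <- piezo2_advance(st, sigma = 3000, dt = 0.004)
  expect_gt(st1$O, 0.2)
  st2 <- piezo2_advance(st1, sigma = 3000, dt = 2)
  expect_lt(st2$O, 1e-6)
  expect_gt(st2$In, 0.99)
  # unloading recovers the closed state
  st3 <- piezo2_advance(st2, sigma = 100, dt = 2, phase = "unloading")
  expect_gt(st3$C, 0.99)
})

test_that("the exact kernel agrees with small-step Euler integration", {
  st <- list(C = 1, O = 0, In = 0, h_slow = 0.05)
  sigma <- 2000
  big <- piezo2_advance(st, sigma, dt = 0.01)
  small <- st
  h <- 1e-6
  for (k in seq_len(10000)) {
    d <- piezo2_derivatives(small, sigma, "loading")
    small <- list(C = small$C + h * d[["C"]], O = small$O + h * d[["O"]],
                  In = small$In + h * d[["In"]],
                  h_slow = small$h_slow + h * d[["h_slow"]])
  }
  expect_equal(big$C, small$C, tolerance = 1e-3)
  expect_equal(big$O, small$O, tolerance = 1e-3)
  expect_equal(big$In, small$In, tolerance = 1e-3)
  expect_equal(big$h_slow, small$h_slow, tolerance = 1e-3)
})

test_that("Piezo2 flux follows O * h_slow and its reversal potential", {
  expect_equal(piezo2_flux(list(O = 0, h_slow = 1), -0.06, 30), 0)
  expect_equal(piezo2_flux(list(O = 0.5, h_slow = 0.5), 6e-3, 30), 0)
  # direct evaluation: fully available channel at 3 mS/cm2, Vm = -60 mV
  J <- piezo2_flux(list(O = 1, h_slow = 1), -0.06, to_si(3, "mS/cm^2"))
  expect_equal(J, 3e-3 * 0.066 / 96485.33212 * 1e4, tolerance = 1e-12)
  expect_gt(J, 0)  # inward Ca2+ below the reversal
  expect_error(piezo2_advance(list(C = 1, O = 0, In = 0, h_slow = 0), 100, -1),
               "dt")
  expect_error(piezo2_advance(list(C = 0.5, O = 0.5, In = 0.5, h_slow = 0),
                              100, 0.1), "invariant")
})
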