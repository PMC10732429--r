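p_ves <- merkel_params()

test_that("exocytosis is sigmoidal in Ca2+ and proportional to the pool", {
  # Ca2+ at the sigmoid midpoint (0.2 uM): half the maximal specific rate
  expect_equal(exocytosis_rate(2e-4, 600, p_ves), p_ves$k_exo * 600 / 2,
               tolerance = 1e-12)
  expect_equal(exocytosis_rate(1e-3, 0, p_ves), 0)
  cas <- seq(1e-5, 1e-3, length.out = 40)
  r <- vapply(cas, exocytosis_rate, numeric(1), n_ve = 500, params = p_ves)
  expect_true(all(diff(r) >= 0))         # saturates at high Ca2+
  expect_gt(r[25] - r[1], 0)             # strictly rising through midrange
})

test_that("the vesicle pool has a synthesis/consumption fixed point", {
  c_rest <- 1.2e-4
  bal <- function(n) vesicle_derivative(c_rest, n, p_ves)
  n_star <- stats::uniroot(bal, c(1, 5000), tol = 1e-10)$root
  expect_equal(vesicle_derivative(c_rest, n_star, p_ves), 0, tolerance = 1e-12)
  # stepping Ca2+ up from rest drains the pool
  expect_lt(vesicle_derivative(1e-3, n_star, p_ves), 0)
  # overloaded pool at low Ca2+: synthesis shut, derivative ~ -exocytosis
  n_big <- p_ves$n_ve_s + 45 * p_ves$n_ve_f
  expect_equal(vesicle_derivative(1e-5, n_big, p_ves),
               -exocytosis_rate(1e-5, n_big, p_ves), tolerance = 1e-9)
  expect_lte(vesicle_derivative(1e-5, n_big, p_ves), 0)
})

test_that("the pool stays non-negative under a bounded Ca2+ trajectory", {
  rhs <- function(t, y, parms) {
    cca <- 5e-4 + 4.9e-4 * sin(2 * pi * t / 5)   # 0.01..0.99 uM swings
    list(vesicle_derivative(cca, max(y[1], 0), p_ves))
  }
  for (n0 in c(0, 5, 2000)) {
    sol <- deSolve::lsoda(n0, seq(0, 60, by = 1), rhs, NULL,
                          rtol = 1e-8, atol = 1e-8)
    expect_true(all(sol[, 2] >= -1e-6), label = paste("n0 =", n0))
  }
})

test_that("membrane turnover books one vesicle area per fusion event", {
  # cortex stress at the endocytosis midpoint: retrieval at half rate
  expect_equal(endocytosis_rate(1000, p_ves), p_ves$k_endo / 2,
               tolerance = 1e-12)
  # balance: pick n_ve so exocytosis equals endocytosis
  cca <- 3e-4
  sig <- 1100
  n_bal <- endocytosis_rate(sig, p_ves) /
    (p_ves$k_exo / (1 + exp(-(cca - p_ves$c_Ca_s) / p_ves$c_Ca_f)))
  expect_equal(surface_turnover(cca, n_bal, sig, p_ves), 0, tolerance = 1e-20)
  # area quantum is 4 pi r_ve^2 per unit rate difference
  d <- surface_turnover(cca, 2 * n_bal, sig, p_ves)
  expect_equal(d, 4 * pi * p_ves$r_ve^2 * exocytosis_rate(cca, n_bal, p_ves),
               tolerance = 1e-12)
})

test_that("the literal printed synthesis orientation is available as a switch", {
  p_lit <- merkel_params(literal_vesicle_sign = TRUE)
  # text orientation: synthesis falls with the pool; literal: it rises
  expect_lt(vesicle_synthesis_rate(600, p_ves),
            vesicle_synthesis_rate(400, p_ves))
  expect_gt(vesicle_synthesis_rate(600, p_lit),
            vesicle_synthesis_rate(400, p_lit))
})
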