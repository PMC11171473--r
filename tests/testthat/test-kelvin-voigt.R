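test_that("transmissibility matches its closed-form limits and values", {
  # rigid-body limit and direct hand evaluation at resonance
  expect_identical(kv_transmissibility(0, 0.3), 1)
  expect_equal(kv_transmissibility(1, 0.5), sqrt(2), tolerance = 1e-12)
  # high-frequency isolation: monotone decay beyond the peak towards zero,
  # approaching the damped asymptote 2 zeta / r
  r <- seq(2, 50, by = 0.5)
  Tz <- kv_transmissibility(r, 0.1)
  expect_true(all(diff(Tz) < 0))
  expect_equal(tail(Tz, 1), 2 * 0.1 / 50, tolerance = 0.01)
  # domain errors
  expect_error(kv_transmissibility(-0.1, 0.1), "non-negative")
  expect_error(kv_transmissibility(1, 1), "zeta")
  expect_error(kv_transmissibility(1, -0.01), "zeta")
})

test_that("kv_params validates its physics and derives zeta and c", {
  p <- kv_params(k = 20, m_osc = 5e-3, zeta = 0.05)
  expect_equal(p$c, 2 * 0.05 * sqrt(20 * 5e-3), tolerance = 1e-12)
  expect_equal(p$f0, sqrt(20 / 5e-3) / (2 * pi), tolerance = 1e-12)
  p2 <- kv_params(k = 20, m_osc = 5e-3, c = p$c)
  expect_equal(p2$zeta, 0.05, tolerance = 1e-12)
  expect_error(kv_params(k = -1, m_osc = 1, zeta = 0.1), "positive")
  expect_error(kv_params(k = 1, m_osc = 1, zeta = 1), "zeta")
  expect_error(kv_params(k = 1, m_osc = 1), "supply one")
})

test_that("static elongation follows the statics and is linear in mass", {
  p <- kv_params(k = 100, m_osc = 5e-3, zeta = 0.1)
  expect_identical(static_elongation(0, p), 0)
  expect_equal(static_elongation(0.005, p), 0.005 * 9.80665 / 100,
               tolerance = 1e-12)
  expect_equal(static_elongation(0.010, p), 2 * static_elongation(0.005, p),
               tolerance = 1e-12)
  expect_error(static_elongation(-0.001, p), "non-negative")
})

test_that("sweep_spec enforces its invariants", {
  expect_error(sweep_spec(10, 5, 0.1, sampling_rate = 200), "f_start < f_end")
  expect_error(sweep_spec(5, 10, 0.1, sampling_rate = 90), "sampling_rate")
  expect_error(sweep_spec(5, 10, -1, sampling_rate = 200), "sweep_rate")
  sw <- sweep_spec(5, 10, 0.1, sampling_rate = 200, settle_time = 1)
  expect_equal(sweep_frequency(sw, c(0, 1, 11)), c(5, 5, 6))
})

test_that("simulation is reproducible from the seed", {
  r1 <- sim_linear_record(0.1, rate_factor = 0.2, noise_sigma = 0.02,
                          seed = 99)
  r2 <- sim_linear_record(0.1, rate_factor = 0.2, noise_sigma = 0.02,
                          seed = 99)
  expect_identical(r1$response, r2$response)
  # a different seed changes only the noise, not the underlying dynamics
  r3 <- sim_linear_record(0.1, rate_factor = 0.2, noise_sigma = 0.02,
                          seed = 100)
  r0 <- sim_linear_record(0.1, rate_factor = 0.2, noise_sigma = 0)
  expect_false(identical(r1$response, r3$response))
  expect_equal(sd(r1$response - r0$response), 0.02 * 1e-3, tolerance = 0.1)
  expect_equal(sd(r3$response - r0$response), 0.02 * 1e-3, tolerance = 0.1)
})

test_that("a quasi-steady linear sweep reproduces the closed form", {
  zeta <- 0.05
  rec <- sim_linear_record(zeta)
  f0 <- (1 / (2 * pi)) * sqrt(20 / 5e-3) # not used: helper fixes f0 = 10
  cv <- extract_resonance_curve(rec)
  r <- cv$frequency / 10
  keep <- r > 0.65 & r < 1.45
  rel <- cv$amplitude[keep] / oracle_transmissibility(r[keep], zeta) - 1
  expect_lt(max(abs(rel)), 0.02)
  # peak height close to the analytic maximum (about 10 at zeta = 0.05)
  expect_equal(max(cv$amplitude), oracle_peak(zeta)$T, tolerance = 0.02)
})

test_that("violating the quasi-steady criterion raises a warning", {
  p <- kv_params(k = 20, m_osc = 5e-3, zeta = 0.02)
  bw <- 2 * p$zeta * p$f0
  sw <- sweep_spec(0.8 * p$f0, 1.2 * p$f0, sweep_rate = 2 * bw^2,
                   sampling_rate = 15 * p$f0, settle_time = 0.5)
  expect_warning(simulate_strip_response(p, sw), "quasi-steady")
})

test_that("quadrupling the stiffness doubles the resonance frequency", {
  m <- 5e-3
  f_of_k <- function(k) {
    p <- kv_params(k = k, m_osc = m, zeta = 0.08)
    bw <- 2 * p$zeta * p$f0
    sw <- sweep_spec(0.6 * p$f0, 1.5 * p$f0, sweep_rate = 0.05 * bw^2,
                     sampling_rate = 18 * p$f0, settle_time = 2)
    natural_frequency(extract_resonance_curve(simulate_strip_response(p, sw)))
  }
  f1 <- f_of_k(20); f2 <- f_of_k(80)
  expect_equal(f2 / f1, 2, tolerance = 0.01)
})
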