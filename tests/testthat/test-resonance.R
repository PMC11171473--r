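test_that("features read from an analytic curve match the numeric oracle", {
  for (zeta in c(0.02, 0.05, 0.1, 0.2)) {
    cv <- analytic_curve(zeta, f0 = 10)
    pk <- oracle_peak(zeta)
    hp <- oracle_halfpower(zeta)
    f0_hat <- as.numeric(natural_frequency(cv))
    expect_equal(f0_hat, pk$r * 10, tolerance = 0.005)
    bw <- bandwidth_3db(cv)
    expect_equal(bw$delta_f, hp$width * 10, tolerance = 0.05)
    expect_equal(bw$f_lo, hp$r_lo * 10, tolerance = 0.01)
    expect_equal(bw$f_hi, hp$r_hi * 10, tolerance = 0.01)
  }
})

test_that("toy curves give exact or failing answers as appropriate", {
  # symmetric triangle peaking at 12 Hz
  f <- seq(8, 16, by = 0.25)
  tri <- resonance_curve(f, 1 - abs(f - 12) / 8)
  expect_equal(as.numeric(natural_frequency(tri)), 12, tolerance = 1e-6)
  # monotone curve: no interior maximum
  mono <- resonance_curve(f, seq(0.1, 1, length.out = length(f)))
  expect_error(natural_frequency(mono), "not bracketed")
  # shallow peak whose shoulders never fall below peak/sqrt(2)
  shallow <- resonance_curve(f, 0.85 + 0.05 * (1 - abs(f - 12) / 4))
  expect_error(bandwidth_3db(shallow), "bandwidth not resolved")
})

test_that("octave length and damping ratio follow their definitions", {
  expect_equal(octave_length(10, 20), 1, tolerance = 1e-12)
  expect_equal(octave_length(10, 10 * 2^0.3), 0.3, tolerance = 1e-12)
  expect_error(octave_length(10, 10), "f_lo < f_hi")
  expect_error(octave_length(-1, 5), "f_lo")
  expect_equal(damping_ratio(10, 1), 0.05, tolerance = 1e-12)
  expect_equal(damping_ratio(10, 1e-9), 5e-11, tolerance = 1e-6)
  expect_error(damping_ratio(0, 1), "f0")
  expect_error(damping_ratio(10, 0), "delta_f")
})

test_that("features are invariant to the response amplitude scale", {
  set.seed(42)
  for (i in 1:5) {
    zeta <- runif(1, 0.03, 0.2)
    f0 <- runif(1, 5, 20)
    cv <- analytic_curve(zeta, f0 = f0)
    sc <- runif(1, 0.1, 50)
    cv2 <- resonance_curve(cv$frequency, cv$amplitude * sc)
    expect_equal(as.numeric(natural_frequency(cv2)),
                 as.numeric(natural_frequency(cv)), tolerance = 1e-12)
    b1 <- bandwidth_3db(cv); b2 <- bandwidth_3db(cv2)
    expect_equal(b2$f_lo, b1$f_lo, tolerance = 1e-10)
    expect_equal(b2$f_hi, b1$f_hi, tolerance = 1e-10)
  }
})

test_that("resonance_curve validates its invariants", {
  f <- seq(1, 10, length.out = 30)
  expect_error(resonance_curve(f[1:10], rep(1, 10)), "at least 20")
  expect_error(resonance_curve(rev(f), rep(1, 30)), "strictly increasing")
  expect_error(resonance_curve(f, rep(-1, 30)), "non-negative")
  expect_error(resonance_curve(f, c(NA, rep(1, 29))), "non-finite")
})

test_that("extraction fails cleanly on degenerate records", {
  rec <- sim_linear_record(0.1, rate_factor = 0.2)
  rec$sweep$f_end <- rec$sweep$f_start # constant-frequency record
  expect_error(extract_resonance_curve(rec), "sweep interval empty")
  rec2 <- sim_linear_record(0.1, rate_factor = 0.2)
  rec2$response[5] <- NaN
  expect_error(extract_resonance_curve(rec2), "non-finite")
})

test_that("mild measurement noise leaves the curve within 5%", {
  rec_clean <- sim_linear_record(0.1, rate_factor = 0.05)
  rec_noisy <- sim_linear_record(0.1, rate_factor = 0.05, noise_sigma = 0.01,
                                 seed = 7)
  cv0 <- extract_resonance_curve(rec_clean)
  cv1 <- extract_resonance_curve(rec_noisy)
  keep <- cv0$amplitude > 0.5 # relative comparison where the signal lives
  rel <- cv1$amplitude[keep] / cv0$amplitude[keep] - 1
  expect_lt(max(abs(rel)), 0.05)
  f0_0 <- as.numeric(natural_frequency(cv0))
  f0_1 <- as.numeric(natural_frequency(cv1))
  expect_equal(f0_1, f0_0, tolerance = 0.01)
})

test_that("merge_sweeps is an upper envelope and idempotent on one input", {
  cv <- analytic_curve(0.08)
  m_raw <- merge_sweeps(cv, cv, smooth = FALSE)
  expect_equal(m_raw$amplitude, cv$amplitude, tolerance = 1e-12)
  expect_identical(m_raw$direction, "merged")
  # smoothing is idempotent on already-smoothed input up to its own window
  m1 <- merge_sweeps(cv, cv)
  m2 <- merge_sweeps(m1, m1, smooth = FALSE)
  expect_equal(m2$amplitude, m1$amplitude, tolerance = 1e-12)
  # one curve everywhere below the other: envelope equals the upper one
  lo_curve <- resonance_curve(cv$frequency, cv$amplitude * 0.5)
  m3 <- merge_sweeps(cv, lo_curve, smooth = FALSE)
  expect_equal(m3$amplitude, cv$amplitude, tolerance = 1e-12)
  # disjoint ranges fail
  shifted <- resonance_curve(cv$frequency + 100, cv$amplitude)
  expect_error(merge_sweeps(cv, shifted), "disjoint")
})

test_that("a linear element has near-zero skew between sweep directions", {
  up <- extract_resonance_curve(sim_linear_record(0.08, direction = "up"))
  dn <- extract_resonance_curve(sim_linear_record(0.08, direction = "down"))
  expect_lt(abs(skew_index(up, dn)), 0.01)
})

test_that("a softening element yields a negative skew index", {
  up <- extract_resonance_curve(sim_linear_record(
    0.05, duffing_beta = -4000, r_lo = 0.5, r_hi = 1.7, direction = "up"))
  dn <- extract_resonance_curve(sim_linear_record(
    0.05, duffing_beta = -4000, r_lo = 0.5, r_hi = 1.7, direction = "down"))
  expect_lt(skew_index(up, dn), -0.01)
})
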