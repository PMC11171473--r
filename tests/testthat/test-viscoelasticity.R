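test_that("dynamic modulus reproduces hand arithmetic and its scalings", {
  # (2 pi 10)^2 * 0.001 * 0.025 / 3e-7 = 3.28987e5 Pa
  expect_equal(dynamic_modulus(10, 0.001, 0.02, 0.005, 3e-7), 3.28987e5,
               tolerance = 1e-5)
  # quadratic dependence on f0, exact
  expect_identical(dynamic_modulus(20, 0.001, 0.02, 0.005, 3e-7),
                   4 * dynamic_modulus(10, 0.001, 0.02, 0.005, 3e-7))
  # unloaded limit
  expect_equal(dynamic_modulus(10, 0.001, 0.02, 0, 3e-7),
               (2 * pi * 10)^2 * 0.001 * 0.02 / 3e-7, tolerance = 1e-12)
  expect_error(dynamic_modulus(0, 1, 1, 0, 1), "f0")
  expect_error(dynamic_modulus(1, 1, 1, -0.1, 1), "dL")
  expect_error(dynamic_modulus(1, 1, 1, 0, 0), "S")
})

test_that("dynamic modulus matches an independent stepwise oracle", {
  # oracle coded as explicit sequential arithmetic, not the one-line formula
  oracle <- function(f0, m, L0, dL, S) {
    omega <- 2 * pi * f0
    accel_factor <- omega * omega
    force_scale <- accel_factor * m
    length_stretched <- L0 + dL
    force_scale * length_stretched / S
  }
  set.seed(2024)
  for (i in 1:1000) {
    f0 <- runif(1, 1, 50); m <- runif(1, 1e-4, 1e-2)
    L0 <- runif(1, 0.01, 0.05); dL <- runif(1, 0, 0.01)
    S <- runif(1, 1e-8, 1e-6)
    expect_equal(dynamic_modulus(f0, m, L0, dL, S), oracle(f0, m, L0, dL, S),
                 tolerance = 1e-13)
  }
})

test_that("mass maps to equivalent pressure by the Laplace equivalence", {
  g <- strip_geometry(width = 0.003, vessel_radius = 0.0013)
  expect_equal(mass_to_equivalent_pressure(0.004, g),
               0.004 * 9.80665 / (0.003 * 0.0013) / 133.322,
               tolerance = 1e-12)
  expect_equal(mass_to_equivalent_pressure(0.004, g), 75.44, tolerance = 1e-4)
  # p -> 0 with the mass, strictly increasing
  m <- c(1e-6, 1e-3, 5e-3, 1e-2)
  p <- mass_to_equivalent_pressure(m, g)
  expect_true(all(diff(p) > 0))
  expect_lt(p[1], 0.02)
  expect_error(mass_to_equivalent_pressure(0, g), "positive")
})

test_that("the default calibrated rings span the standard operating range", {
  steps <- load_steps()
  expect_identical(nrow(steps), 4L)
  expect_true(all(diff(steps$p_mmHg) > 0))
  expect_equal(steps$p_mmHg[1], 77.2, tolerance = 1e-4)
  expect_equal(steps$p_mmHg[4], 157.4, tolerance = 1e-4)
  # elongation column fills from the static relation when k is given
  steps_k <- load_steps(stiffness = 50)
  expect_equal(steps_k$dL_m, steps_k$ring_mass * 9.80665 / 50,
               tolerance = 1e-12)
  expect_error(load_steps(ring_masses = c(2, 1, 3, 4) * 1e-3), "increasing")
})

test_that("strip geometry validates and derives the cross-section", {
  g <- strip_geometry(L0 = 0.02, width = 0.004, thickness = 2e-4)
  expect_identical(g$S, 0.004 * 2e-4)
  expect_error(strip_geometry(L0 = -1), "positive")
})

test_that("assembled points agree with the generating ground truth", {
  cfg <- tiny_config(n_sham = 2, n_pin = 0, stages = "control",
                     noise_sigma = 0, subject_sd = 0.05, seed = 5)
  study <- generate_study(cfg, signals = TRUE)
  features <- do.call(rbind, lapply(study$records, function(rec) {
    cv <- extract_resonance_curve(rec)
    cbind(data.frame(subject = rec$metadata$subject,
                     stage = rec$metadata$stage,
                     mass_index = rec$metadata$mass_index),
          as.data.frame(resonance_features(cv)))
  }))
  pts <- assemble_points(features, cfg$geometry, study$manifest)
  gt <- study$ground_truth
  i <- match(paste(pts$subject, pts$stage, pts$mass_index),
             paste(gt$subject, gt$stage, gt$mass_index))
  expect_false(anyNA(i))
  expect_equal(pts$Eprime_MPa * 1e6, gt$Eprime_true_Pa[i], tolerance = 0.02)
  expect_equal(pts$f0_Hz, gt$f0_true[i], tolerance = 0.01)
})

test_that("assembly enforces join integrity", {
  cfg <- tiny_config(n_sham = 1, n_pin = 0, stages = "control",
                     f0_noise_sd = 0)
  study <- generate_study(cfg)
  feat <- data.frame(subject = study$points$subject,
                     stage = study$points$stage,
                     mass_index = study$points$mass_index,
                     f0_Hz = study$points$f0_Hz)
  ok <- assemble_points(feat, cfg$geometry, study$manifest)
  expect_identical(nrow(ok), 4L)
  expect_equal(ok$Eprime_MPa, study$points$Eprime_MPa, tolerance = 1e-12)
  # duplicated measurement id
  expect_error(assemble_points(rbind(feat, feat[1, ]), cfg$geometry,
                               study$manifest), "duplicated")
  # orphan row without manifest entry
  feat2 <- feat; feat2$mass_index[1] <- 9L
  expect_error(assemble_points(feat2, cfg$geometry, study$manifest),
               "without manifest entry")
  # empty features: empty result with a warning
  expect_warning(out <- assemble_points(feat[0, ], cfg$geometry,
                                        study$manifest), "empty")
  expect_identical(nrow(out), 0L)
})

test_that("f0 and the modulus increase with pressure under the default model", {
  cfg <- study_config(n_sham = 1, n_pin = 1, subject_sd = 0, f0_noise_sd = 0,
                      seed = 3)
  study <- generate_study(cfg)
  pts <- study$points
  for (cell in split(pts, paste(pts$subject, pts$stage))) {
    cell <- cell[order(cell$p_mmHg), ]
    expect_true(all(diff(cell$f0_Hz) > 0))
    expect_true(all(diff(cell$Eprime_MPa) > 0))
  }
})
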