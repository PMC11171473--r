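# Independent closed-form oracle for the base-excited Kelvin-Voigt element,
# kept separate from the package implementation on purpose.
oracle_transmissibility <- function(r, zeta) {
  sqrt((1 + (2 * zeta * r)^2) / ((1 - r^2)^2 + (2 * zeta * r)^2))
}

# analytic peak location/height and half-power crossings by numerical
# maximisation / root finding on the oracle
oracle_peak <- function(zeta) {
  op <- optimize(function(r) -oracle_transmissibility(r, zeta), c(0.3, 1.5),
                 tol = 1e-12)
  list(r = op$minimum, T = -op$objective)
}

oracle_halfpower <- function(zeta) {
  pk <- oracle_peak(zeta)
  lvl <- pk$T / sqrt(2)
  f <- function(r) oracle_transmissibility(r, zeta) - lvl
  lo <- uniroot(f, c(1e-6, pk$r), tol = 1e-12)$root
  hi <- uniroot(f, c(pk$r, 10), tol = 1e-12)$root
  list(r_lo = lo, r_hi = hi, width = hi - lo)
}

# resonance curve sampled from the closed form (no simulation involved)
analytic_curve <- function(zeta, f0 = 10, n = 401, r_lo = 0.5, r_hi = 1.6) {
  f <- seq(r_lo * f0, r_hi * f0, length.out = n)
  resonance_curve(f, oracle_transmissibility(f / f0, zeta))
}

# short helper for a linear simulated record around its resonance;
# rate_factor 0.02 keeps the sweep quasi-steady
sim_linear_record <- function(zeta, f0_target = 10, rate_factor = 0.02,
                              r_lo = 0.6, r_hi = 1.5, noise_sigma = 0,
                              seed = NULL, direction = "up",
                              duffing_beta = 0, A = 1e-3) {
  m <- 5e-3
  k <- (2 * pi * f0_target)^2 * m
  p <- kv_params(k = k, m_osc = m, zeta = zeta, duffing_beta = duffing_beta,
                 excitation_amplitude = A, noise_sigma = noise_sigma,
                 seed = seed)
  bw <- 2 * zeta * p$f0
  sw <- sweep_spec(r_lo * p$f0, r_hi * p$f0,
                   sweep_rate = rate_factor * bw^2, direction = direction,
                   sampling_rate = 12 * r_hi * p$f0, settle_time = 3 / bw)
  simulate_strip_response(p, sw)
}

# tiny synthetic study configuration for fast end-to-end tests
tiny_config <- function(..., stages = c("control", "Fe-9"), n_sham = 1,
                        n_pin = 1, seed = 11) {
  study_config(n_sham = n_sham, n_pin = n_pin, stages = stages, seed = seed,
               ...)
}
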