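#' Kelvin-Voigt element parameters
#'
#' Bundles the physical parameters of the suspended strip-mass system: the
#' strip is idealised as an elastic spring and a viscous damper in parallel
#' (Kelvin-Voigt), optionally with a cubic (Duffing) stiffness correction for
#' softening (`duffing_beta < 0`) or hardening (`duffing_beta > 0`) behaviour.
#'
#' Exactly one of `c` and `zeta` must be supplied; the other is derived via
#' `zeta = c / (2 * sqrt(k * m_osc))`.
#'
#' @param k spring stiffness, N/m. Must be positive.
#' @param m_osc oscillating mass, kg (opaque mask plus any suspended lead
#'   ring). Must be positive.
#' @param c damping coefficient, N s/m (non-negative).
#' @param zeta damping ratio in `[0, 1)`; alternative to `c`.
#' @param duffing_beta cubic stiffness coefficient, 1/m^2; 0 for a linear
#'   element, negative for softening, positive for hardening.
#' @param excitation_amplitude amplitude of the base (excitation) sine, m.
#' @param noise_sigma additive Gaussian measurement noise on the response,
#'   expressed as a fraction of `excitation_amplitude`.
#' @param seed optional integer seed making simulated noise reproducible.
#' @return An object of class `kv_params`.
#' @examples
#' p <- kv_params(k = 20, m_osc = 5e-3, zeta = 0.05)
#' p$f0 # undamped natural frequency, Hz
#' @export
kv_params <- function(k, m_osc, c = NULL, zeta = NULL, duffing_beta = 0,
                      excitation_amplitude = 1e-3, noise_sigma = 0,
                      seed = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(m_osc), length(m_osc) == 1L, is.finite(m_osc))
  if (k <= 0) stop("stiffness k must be positive")
  if (m_osc <= 0) stop("oscillating mass m_osc must be positive")
  if (is.null(c) && is.null(zeta)) stop("supply one of c or zeta")
  if (!is.null(c) && !is.null(zeta)) stop("supply only one of c and zeta")
  if (is.null(c)) {
    if (zeta < 0 || zeta >= 1) stop("zeta must lie in [0, 1)")
    c <- 2 * zeta * sqrt(k * m_osc)
  } else {
    if (c < 0) stop("damping c must be non-negative")
    zeta <- c / (2 * sqrt(k * m_osc))
    if (zeta >= 1) stop("overdamped element: zeta = ", signif(zeta, 4),
                        " must be < 1")
  }
  if (excitation_amplitude <= 0) stop("excitation_amplitude must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(k = k, c = c, m_osc = m_osc, zeta = zeta,
                 duffing_beta = duffing_beta,
                 excitation_amplitude = excitation_amplitude,
                 noise_sigma = noise_sigma, seed = seed,
                 f0 = sqrt(k / m_osc) / (2 * pi)),
            class = "kv_params")
}

#' @export
print.kv_params <- function(x, ...) {
  cat("Kelvin-Voigt element:\n")
  cat(sprintf("  k = %.4g N/m, c = %.4g N s/m, m_osc = %.4g kg\n",
              x$k, x$c, x$m_osc))
  cat(sprintf("  zeta = %.4g, f0 = %.4g Hz, beta = %.4g 1/m^2\n",
              x$zeta, x$f0, x$duffing_beta))
  cat(sprintf("  A = %.4g m, noise = %.3g * A\n",
              x$excitation_amplitude, x$noise_sigma))
  invisible(x)
}

#' Swept-sine excitation descriptor
#'
#' Describes a constant-amplitude sine whose frequency is held at the starting
#' frequency for `settle_time` seconds (to shed the start-up transient) and
#' then swept linearly between `f_start` and `f_end`.
#'
#' @param f_start,f_end sweep interval bounds, Hz (`0 < f_start < f_end`).
#' @param sweep_rate magnitude of the frequency ramp, Hz/s (positive).
#' @param direction `"up"` (from `f_start`) or `"down"` (from `f_end`).
#' @param sampling_rate ADC sampling rate, Hz; must exceed `10 * f_end`.
#' @param settle_time dwell at the starting frequency before the ramp, s.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(f_start, f_end, sweep_rate, direction = c("up", "down"),
                       sampling_rate, settle_time = 2) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(f_start), is.numeric(f_end), is.numeric(sweep_rate),
            is.numeric(sampling_rate), is.numeric(settle_time))
  if (!(f_start > 0 && f_end > f_start))
    stop("need 0 < f_start < f_end (got ", f_start, ", ", f_end, ")")
  if (sweep_rate <= 0) stop("sweep_rate must be positive")
  if (sampling_rate <= 10 * f_end)
    stop("sampling_rate must exceed 10 * f_end")
  if (settle_time < 0) stop("settle_time must be non-negative")
  structure(list(f_start = f_start, f_end = f_end, sweep_rate = sweep_rate,
                 direction = direction, sampling_rate = sampling_rate,
                 settle_time = settle_time),
            class = "sweep_spec")
}

# total record duration implied by a sweep, s
sweep_duration <- function(sweep) {
  sweep$settle_time + (sweep$f_end - sweep$f_start) / sweep$sweep_rate
}

# starting frequency and signed ramp rate of the chirp
sweep_law <- function(sweep) {
  if (sweep$direction == "up") {
    list(f_from = sweep$f_start, rate = sweep$sweep_rate)
  } else {
    list(f_from = sweep$f_end, rate = -sweep$sweep_rate)
  }
}

#' Instantaneous frequency of the sweep at given times
#'
#' The drive frequency is known exactly because the apparatus commands it;
#' features are therefore read against this law rather than an estimate from
#' the recorded signal.
#'
#' @param sweep a [sweep_spec()].
#' @param t numeric vector of times, s.
#' @return Instantaneous frequency, Hz.
#' @export
sweep_frequency <- function(sweep, t) {
  law <- sweep_law(sweep)
  ifelse(t <= sweep$settle_time, law$f_from,
         law$f_from + law$rate * (t - sweep$settle_time))
}

# phase of the chirp (rad); must match chirp_phase() in src/duffing.cpp
sweep_phase <- function(sweep, t) {
  law <- sweep_law(sweep)
  tau <- pmax(t - sweep$settle_time, 0)
  2 * pi * (law$f_from * pmin(t, sweep$settle_time) +
              law$f_from * tau + 0.5 * law$rate * tau^2)
}

#' Transmissibility of the base-excited Kelvin-Voigt element
#'
#' Steady-state amplitude ratio |response| / |excitation| of a linear spring-
#' damper element driven through its base:
#' `T(r, zeta) = sqrt((1 + (2 zeta r)^2) / ((1 - r^2)^2 + (2 zeta r)^2))`
#' with `r` the ratio of drive frequency to undamped natural frequency.
#'
#' @param r frequency ratio `f / f0`, non-negative (vectorised).
#' @param zeta damping ratio in `[0, 1)`.
#' @return Amplitude ratio, same length as `r`.
#' @examples
#' kv_transmissibility(1, 0.5) # sqrt(2)
#' @export
kv_transmissibility <- function(r, zeta) {
  stopifnot(is.numeric(r), is.numeric(zeta), length(zeta) == 1L)
  if (any(r < 0)) stop("frequency ratio r must be non-negative")
  if (zeta < 0 || zeta >= 1) stop("zeta must lie in [0, 1)")
  num <- 1 + (2 * zeta * r)^2
  den <- (1 - r^2)^2 + (2 * zeta * r)^2
  sqrt(num / den)
}

#' Static elongation under a suspended mass
#'
#' Elongation of the preparation produced by hanging a concentrated mass from
#' its lower end: `dL = m_ring * g / k`, the static operating-point consequence
#' of the element's stiffness.
#'
#' @param m_ring suspended mass, kg (non-negative, vectorised).
#' @param params a [kv_params()] object (its `k` is used).
#' @return Elongation, m.
#' @export
static_elongation <- function(m_ring, params) {
  stopifnot(inherits(params, "kv_params"), is.numeric(m_ring))
  if (any(m_ring < 0)) stop("m_ring must be non-negative")
  m_ring * .g0 / params$k
}

#' Quasi-steady-state criterion for a sweep
#'
#' A swept-sine record approximates the steady-state resonance curve only when
#' the sweep traverses the resonance slowly compared with the oscillator's own
#' settling time, i.e. when `sweep_rate` is small against the square of the
#' half-power bandwidth `(2 zeta f0)^2`. Returns the ratio
#' `sweep_rate / (2 zeta f0)^2`; values well below 1 (0.1 or less in practice)
#' indicate a quasi-steady sweep.
#'
#' @param params a [kv_params()].
#' @param sweep a [sweep_spec()].
#' @return The dimensionless sweep-rate ratio.
#' @export
quasi_steady_ratio <- function(params, sweep) {
  bw <- 2 * params$zeta * params$f0
  if (bw <= 0) return(Inf)
  sweep$sweep_rate / bw^2
}

#' Simulate a swept-sine forced-oscillation record
#'
#' Integrates the base-excited (optionally Duffing) Kelvin-Voigt element
#' `m_osc x'' = k (u - x) (1 + beta (u - x)^2) + c (u' - x')` with
#' `u(t)` a constant-amplitude linear chirp, using a compiled fixed-step RK4
#' scheme, and adds Gaussian measurement noise of standard deviation
#' `noise_sigma * excitation_amplitude` to the response channel.
#'
#' With `duffing_beta = 0` and a quasi-steady sweep (see
#' [quasi_steady_ratio()]), the measured amplitude ratio reproduces
#' [kv_transmissibility()] to within about 2%.
#'
#' @param params a [kv_params()].
#' @param sweep a [sweep_spec()].
#' @param metadata optional named list carried along with the record (subject,
#'   group, stage, mass index, ...).
#' @param oversample minimum number of integrator sub-steps per period of the
#'   fastest relevant frequency (drive end or natural frequency).
#' @return An object of class `oscillation_record`: list with `time`,
#'   `excitation`, `response`, `sweep`, `metadata`.
#' @examples
#' p <- kv_params(k = 20, m_osc = 5e-3, zeta = 0.1)
#' sw <- sweep_spec(0.6 * p$f0, 1.5 * p$f0, sweep_rate = 0.1 * (2 * p$zeta * p$f0)^2,
#'                  sampling_rate = 12 * 1.5 * p$f0, settle_time = 1)
#' rec <- simulate_strip_response(p, sw)
#' @export
simulate_strip_response <- function(params, sweep, metadata = list(),
                                    oversample = 40) {
  stopifnot(inherits(params, "kv_params"), inherits(sweep, "sweep_spec"))
  qss <- quasi_steady_ratio(params, sweep)
  if (is.finite(qss) && qss > 1)
    warning("sweep_rate exceeds the quasi-steady criterion (ratio ",
            signif(qss, 3), "); resonance features will be biased")

  fs <- sweep$sampling_rate
  n <- floor(sweep_duration(sweep) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  law <- sweep_law(sweep)
  f_ref <- max(sweep$f_end, params$f0)
  n_sub <- max(1L, as.integer(ceiling(oversample * f_ref / fs)))

  x <- .duffing_response(n, fs, params$m_osc, params$k, params$c,
                         params$duffing_beta, params$excitation_amplitude,
                         law$f_from, law$rate, sweep$settle_time, n_sub)
  u <- params$excitation_amplitude * sin(sweep_phase(sweep, t))

  if (params$noise_sigma > 0) {
    sd_noise <- params$noise_sigma * params$excitation_amplitude
    if (!is.null(params$seed)) {
      x <- x + with_local_seed(params$seed, rnorm(n, sd = sd_noise))
    } else {
      x <- x + rnorm(n, sd = sd_noise)
    }
  }
  if (any(!is.finite(x)) || any(!is.finite(u)))
    stop("non-finite samples in simulated record")

  structure(list(time = t, excitation = u, response = x, sweep = sweep,
                 metadata = metadata),
            class = "oscillation_record")
}

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.oscillation_record <- function(x, ...) {
  cat(sprintf(
    "oscillation_record: %d samples @ %g Hz, sweep %s %.3g-%.3g Hz (%.3g Hz/s)\n",
    length(x$time), x$sweep$sampling_rate, x$sweep$direction,
    x$sweep$f_start, x$sweep$f_end, x$sweep$sweep_rate))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.oscillation_record <- function(x, ...) {
  graphics::plot(x$time, x$response, type = "l", xlab = "time (s)",
                 ylab = "displacement (m)", ...)
  graphics::lines(x$time, x$excitation, col = "grey60")
  invisible(x)
}
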