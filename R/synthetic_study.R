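#' Canonical treatment-stage labels
#'
#' The ordered stage vocabulary of the staged fentanyl/naloxone protocol:
#' untreated control, cumulative fentanyl 10^-9..10^-6 M, 30-min wash-out,
#' 10-min naloxone 10^-6 M, then the cumulative fentanyl series repeated in
#' the presence of naloxone. Labels are stable across all file outputs.
#'
#' @return Character vector of the 11 stage labels in protocol order.
#' @export
treatment_stages <- function() {
  c("control", "Fe-9", "Fe-8", "Fe-7", "Fe-6", "washout30", "nal10",
    "Fe-9+Nal", "Fe-8+Nal", "Fe-7+Nal", "Fe-6+Nal")
}

#' Default phenomenological effect model
#'
#' Per (group, stage) intercept and slope of the generating linear relation
#' `f0(p) = f0_intercept + f0_slope * p` (Hz, Hz/mmHg). The pattern encodes
#' the study's qualitative findings as treatment-stage shifts: fentanyl
#' lowers the modulus (via f0) relative to control at every concentration in
#' the sham group; the pinealectomized group sits above the sham group only
#' at the lowest fentanyl concentration (with a slope component so the group
#' difference grows with pressure); wash-out largely restores control in the
#' sham group; naloxone alone lowers the modulus; the naloxone + fentanyl
#' series mirrors the fentanyl series except at Fe-8.
#'
#' @return Data frame with columns `group`, `stage`, `f0_intercept`,
#'   `f0_slope`.
#' @export
default_effect_model <- function() {
  st <- treatment_stages()
  sham_int <- c(control = 5.00, `Fe-9` = 4.50, `Fe-8` = 4.50, `Fe-7` = 4.50,
                `Fe-6` = 4.20, washout30 = 4.95, nal10 = 4.40,
                `Fe-9+Nal` = 4.40, `Fe-8+Nal` = 4.80, `Fe-7+Nal` = 4.40,
                `Fe-6+Nal` = 4.40)
  pin_int <- c(control = 5.00, `Fe-9` = 5.20, `Fe-8` = 4.50, `Fe-7` = 4.50,
               `Fe-6` = 4.20, washout30 = 4.50, nal10 = 4.40,
               `Fe-9+Nal` = 5.10, `Fe-8+Nal` = 4.50, `Fe-7+Nal` = 4.50,
               `Fe-6+Nal` = 4.30)
  pin_slope <- c(control = 0.050, `Fe-9` = 0.055, `Fe-8` = 0.050,
                 `Fe-7` = 0.050, `Fe-6` = 0.050, washout30 = 0.050,
                 nal10 = 0.050, `Fe-9+Nal` = 0.055, `Fe-8+Nal` = 0.050,
                 `Fe-7+Nal` = 0.050, `Fe-6+Nal` = 0.050)
  rbind(
    data.frame(group = "sham", stage = st, f0_intercept = unname(sham_int[st]),
               f0_slope = 0.050, stringsAsFactors = FALSE),
    data.frame(group = "pin", stage = st, f0_intercept = unname(pin_int[st]),
               f0_slope = unname(pin_slope[st]), stringsAsFactors = FALSE))
}

#' Synthetic study configuration
#'
#' Full description of a synthetic forced-oscillation study: group sizes,
#' protocol stages, loading, geometry, the phenomenological effect model
#' (linear f0-pressure relation per group and stage, from which the per-cell
#' stiffness is derived), variance components and signal settings.
#'
#' @param n_sham,n_pin animals per group (non-negative; at least one animal
#'   in total).
#' @param stages ordered subset of [treatment_stages()].
#' @param ring_masses strictly increasing vector of 4 ring masses, kg.
#' @param mask_mass mass of the opaque mask, kg.
#' @param geometry a [strip_geometry()].
#' @param effect_model data frame as [default_effect_model()]; must cover
#'   every group x stage cell in use.
#' @param zeta damping ratio of the simulated element.
#' @param subject_sd between-animal SD of the f0 intercept, Hz.
#' @param f0_noise_sd residual measurement SD of f0, Hz (feature-level
#'   generation).
#' @param noise_sigma ADC noise on the response channel as a fraction of the
#'   excitation amplitude (signal-level generation).
#' @param sweep list of signal-generation settings: `r_lo`/`r_hi` sweep bounds
#'   as multiples of the cell's f0, `rate_factor` as a multiple of the squared
#'   half-power bandwidth (quasi-steady when well below 1), `settle_time` (s),
#'   `oversample` (sampling rate as a multiple of the sweep's top frequency).
#' @param seed integer seed making the whole study reproducible.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_sham = 3, n_pin = 4, stages = treatment_stages(),
                         ring_masses = default_ring_masses(),
                         mask_mass = 0.0015, geometry = strip_geometry(),
                         effect_model = default_effect_model(), zeta = 0.08,
                         subject_sd = 0.10, f0_noise_sd = 0.12,
                         noise_sigma = 0.01,
                         sweep = list(r_lo = 0.6, r_hi = 1.5,
                                      rate_factor = 0.05, settle_time = 2,
                                      oversample = 12),
                         seed = 1L) {
  if (n_sham < 0 || n_pin < 0 || n_sham + n_pin < 1)
    stop("need at least one animal across the two groups")
  if (!all(stages %in% treatment_stages()))
    stop("unknown stage label(s): ",
         paste(setdiff(stages, treatment_stages()), collapse = ", "))
  if (is.unsorted(match(stages, treatment_stages()), strictly = TRUE))
    stop("stages must follow the protocol order of treatment_stages()")
  if (length(ring_masses) != 4L || any(diff(ring_masses) <= 0))
    stop("ring_masses must be 4 strictly increasing masses")
  stopifnot(inherits(geometry, "strip_geometry"))
  need <- c("group", "stage", "f0_intercept", "f0_slope")
  if (!all(need %in% names(effect_model)))
    stop("effect_model needs columns: ", paste(need, collapse = ", "))
  if (zeta <= 0 || zeta >= 1) stop("zeta must lie in (0, 1)")
  if (subject_sd < 0 || f0_noise_sd < 0 || noise_sigma < 0)
    stop("variance components must be non-negative")
  groups <- c(if (n_sham > 0) "sham", if (n_pin > 0) "pin")
  have <- paste(effect_model$group, effect_model$stage)
  want <- as.vector(outer(groups, stages, paste))
  if (length(miss <- setdiff(want, have)))
    stop("effect_model lacks cells: ", paste(miss, collapse = ", "))
  structure(list(n_sham = n_sham, n_pin = n_pin, stages = stages,
                 ring_masses = ring_masses, mask_mass = mask_mass,
                 geometry = geometry, effect_model = effect_model,
                 zeta = zeta, subject_sd = subject_sd,
                 f0_noise_sd = f0_noise_sd, noise_sigma = noise_sigma,
                 sweep = sweep, seed = as.integer(seed)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "study_config: %d sham + %d pin animals, %d stages x 4 loads, seed %d\n",
    x$n_sham, x$n_pin, length(x$stages), x$seed))
  p <- mass_to_equivalent_pressure(x$ring_masses, x$geometry)
  cat(sprintf("  equivalent pressures: %s mmHg\n",
              paste(sprintf("%.1f", p), collapse = ", ")))
  cat(sprintf("  zeta = %.3g, subject_sd = %.3g Hz, f0_noise_sd = %.3g Hz, noise_sigma = %.3g\n",
              x$zeta, x$subject_sd, x$f0_noise_sd, x$noise_sigma))
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' Draws a multi-animal study under the configured effect model. For every
#' (subject, stage, load step) the generating truth is built as: equivalent
#' pressure from the ring mass, cell-level `f0` from the group x stage linear
#' relation plus the animal's random intercept, stiffness
#' `k = (2 pi f0)^2 m_osc`, damping from the configured damping ratio, static
#' elongation `m_ring g / k`, and the true modulus by the dynamic-modulus
#' relation - so the stored ground truth is internally consistent by
#' construction.
#'
#' With `signals = FALSE` (the default) observed features are drawn directly
#' at the feature level (`f0` plus Gaussian measurement noise, modulus
#' recomputed from the noisy `f0`), which is the appropriate scale for
#' statistical replication studies. With `signals = TRUE` every measurement is
#' simulated as a full swept-sine record via [simulate_strip_response()] for
#' end-to-end analysis of the signal-processing stage.
#'
#' @param config a [study_config()].
#' @param signals logical; simulate full oscillation records (see above).
#' @return An object of class `fo_study`: list with `config`, `subjects`
#'   (animal table), `manifest` (one row per measurement with load and sweep
#'   metadata), `ground_truth` (true k, c, m_osc, dL, p, f0, E'), `points`
#'   (observed viscoelastic points; feature-level mode) and `records` (named
#'   list of `oscillation_record`s; signal mode).
#' @export
generate_study <- function(config, signals = FALSE) {
  stopifnot(inherits(config, "study_config"))
  with_local_seed(config$seed, generate_study_impl(config, signals))
}

generate_study_impl <- function(config, signals) {
  geom <- config$geometry
  subjects <- data.frame(
    subject = c(sprintf("sham%d", seq_len(config$n_sham)),
                sprintf("pin%d", seq_len(config$n_pin))),
    group = rep(c("sham", "pin"), c(config$n_sham, config$n_pin)),
    stringsAsFactors = FALSE)
  subjects$f0_offset <- rnorm(nrow(subjects), sd = config$subject_sd)

  steps <- load_steps(config$ring_masses, config$mask_mass, geom)
  em_key <- paste(config$effect_model$group, config$effect_model$stage)

  grid <- expand.grid(mass_index = steps$mass_index, stage = config$stages,
                      subject = subjects$subject, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("subject", "stage", "mass_index")]
  si <- match(grid$subject, subjects$subject)
  grid$group <- subjects$group[si]
  li <- match(grid$mass_index, steps$mass_index)
  grid$ring_mass <- steps$ring_mass[li]
  grid$m_osc <- steps$m_osc[li]
  grid$p_mmHg <- steps$p_mmHg[li]

  ei <- match(paste(grid$group, grid$stage), em_key)
  f0_cell <- config$effect_model$f0_intercept[ei] +
    config$effect_model$f0_slope[ei] * grid$p_mmHg
  f0_true <- f0_cell + subjects$f0_offset[si]
  if (any(bad <- !is.finite(f0_true) | f0_true < 0.2)) {
    b <- which(bad)[1L]
    stop("effect model implies non-physical stiffness (f0 = ",
         signif(f0_true[b], 3), " Hz) in cell ", grid$group[b], "/",
         grid$stage[b], "/load ", grid$mass_index[b])
  }

  k <- (2 * pi * f0_true)^2 * grid$m_osc
  c_damp <- 2 * config$zeta * sqrt(k * grid$m_osc)
  dL <- grid$ring_mass * .g0 / k
  E_true <- (2 * pi * f0_true)^2 * grid$m_osc * (geom$L0 + dL) / geom$S

  ground_truth <- data.frame(grid[, c("subject", "group", "stage",
                                      "mass_index")],
                             ring_mass = grid$ring_mass, m_osc = grid$m_osc,
                             k = k, c = c_damp, dL_m = dL,
                             p_mmHg = grid$p_mmHg, f0_true = f0_true,
                             Eprime_true_Pa = E_true,
                             stringsAsFactors = FALSE)
  manifest <- data.frame(grid[, c("subject", "group", "stage", "mass_index")],
                         ring_mass = grid$ring_mass, m_osc = grid$m_osc,
                         dL_m = dL, p_mmHg = grid$p_mmHg,
                         stringsAsFactors = FALSE)

  out <- list(config = config, subjects = subjects, manifest = manifest,
              ground_truth = ground_truth)

  if (!signals) {
    f0_obs <- f0_true + rnorm(nrow(grid), sd = config$f0_noise_sd)
    f0_obs <- pmax(f0_obs, 0.05)
    E_obs <- dynamic_modulus(f0_obs, grid$m_osc, geom$L0, dL, geom$S)
    out$points <- data.frame(grid[, c("subject", "group", "stage",
                                      "mass_index")],
                             p_mmHg = grid$p_mmHg, f0_Hz = f0_obs,
                             Eprime_MPa = E_obs / 1e6, qc_flags = "",
                             stringsAsFactors = FALSE)
  } else {
    sw <- config$sweep
    rec_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
    records <- vector("list", nrow(grid))
    sweep_tab <- data.frame(f_start = numeric(nrow(grid)), f_end = NA_real_,
                            sweep_rate = NA_real_, direction = "up",
                            sampling_rate = NA_real_, settle_time = NA_real_,
                            stringsAsFactors = FALSE)
    for (j in seq_len(nrow(grid))) {
      bw <- 2 * config$zeta * f0_true[j]
      spec <- sweep_spec(f_start = sw$r_lo * f0_true[j],
                         f_end = sw$r_hi * f0_true[j],
                         sweep_rate = sw$rate_factor * bw^2,
                         direction = "up",
                         sampling_rate = sw$oversample * sw$r_hi * f0_true[j],
                         settle_time = sw$settle_time)
      par <- kv_params(k = k[j], m_osc = grid$m_osc[j], c = c_damp[j],
                       noise_sigma = config$noise_sigma,
                       seed = rec_seeds[j])
      md <- list(subject = grid$subject[j], group = grid$group[j],
                 stage = grid$stage[j], mass_index = grid$mass_index[j])
      records[[j]] <- simulate_strip_response(par, spec, metadata = md)
      sweep_tab[j, ] <- list(spec$f_start, spec$f_end, spec$sweep_rate,
                             spec$direction, spec$sampling_rate,
                             spec$settle_time)
    }
    names(records) <- measurement_id(grid$subject, grid$stage,
                                     grid$mass_index)
    out$manifest <- cbind(manifest, sweep_tab)
    out$records <- records
  }
  structure(out, class = "fo_study")
}

measurement_id <- function(subject, stage, mass_index) {
  sprintf("%s_%s_m%d", subject, gsub("[^A-Za-z0-9-]", "", stage),
          as.integer(mass_index))
}

#' @export
print.fo_study <- function(x, ...) {
  cat(sprintf("fo_study: %d measurements (%d animals x %d stages x 4 loads)\n",
              nrow(x$manifest), nrow(x$subjects), length(x$config$stages)))
  cat(sprintf("  mode: %s\n",
              if (!is.null(x$records)) "signal records" else "feature level"))
  invisible(x)
}
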