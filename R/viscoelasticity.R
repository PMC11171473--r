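#' Strip preparation geometry
#'
#' Dimensions of the helical tunica-media strip and the radius of the vessel
#' it was cut from (used for the equivalent-pressure mapping). The cross
#' section is `S = width * thickness` by construction.
#'
#' @param L0 initial (unloaded) length of the preparation, m.
#' @param width strip width, m (the preparation is cut about 3 mm wide).
#' @param thickness wall (media) thickness, m.
#' @param vessel_radius radius of the source vessel, m.
#' @return An object of class `strip_geometry` with derived `S` (m^2).
#' @export
strip_geometry <- function(L0 = 0.025, width = 0.003, thickness = 1.5e-4,
                           vessel_radius = 1.3e-3) {
  vals <- c(L0 = L0, width = width, thickness = thickness,
            vessel_radius = vessel_radius)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be positive and finite")
  structure(list(L0 = L0, width = width, thickness = thickness,
                 S = width * thickness, vessel_radius = vessel_radius),
            class = "strip_geometry")
}

#' @export
print.strip_geometry <- function(x, ...) {
  cat(sprintf(
    "strip_geometry: L0 = %.3g mm, %0.3g x %0.3g mm (S = %.3g mm^2), r_v = %.3g mm\n",
    x$L0 * 1e3, x$width * 1e3, x$thickness * 1e3, x$S * 1e6,
    x$vessel_radius * 1e3))
  invisible(x)
}

#' Dynamic modulus of elasticity
#'
#' Computes the dynamic elastic modulus of the strip from its resonance
#' frequency, the suspended oscillating mass and the stretched geometry:
#' `E' = (2 pi f0)^2 * m * (L0 + dL) / S` (Pa). Higher `E'` means a stiffer,
#' less distensible wall.
#'
#' @param f0 natural frequency, Hz (positive; vectorised).
#' @param m oscillating mass, kg (positive).
#' @param L0 initial preparation length, m (positive).
#' @param dL elongation under the suspended mass, m (non-negative).
#' @param S cross-section area, m^2 (positive).
#' @return Dynamic modulus, Pa.
#' @examples
#' dynamic_modulus(10, 0.001, 0.02, 0.005, 3e-7) # ~0.329 MPa
#' @export
dynamic_modulus <- function(f0, m, L0, dL, S) {
  args <- list(f0 = f0, m = m, L0 = L0, S = S)
  for (nm in names(args))
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0))
      stop(nm, " must be positive and finite")
  if (any(!is.finite(dL)) || any(dL < 0)) stop("dL must be non-negative")
  (2 * pi * f0)^2 * m * (L0 + dL) / S
}

#' Equivalent intraluminal blood pressure of a suspended mass
#'
#' Maps a suspended concentrated mass to the intraluminal pressure of a
#' thin-walled cylindrical vessel whose wall would carry the same tension
#' (Laplace equivalence): the mass loads the strip of width `b` with force
#' `m g`, i.e. a wall tension `m g / b` per unit axial length, which a
#' pressure `p = m g / (b r_v)` would produce in a vessel of radius `r_v`.
#' Reported in mmHg (1 mmHg = 133.322 Pa).
#'
#' @param m_ring suspended mass, kg (positive; vectorised).
#' @param geometry a [strip_geometry()] (its `width` and `vessel_radius` are
#'   used).
#' @return Equivalent blood pressure, mmHg.
#' @examples
#' mass_to_equivalent_pressure(0.004, strip_geometry()) # ~75.4 mmHg
#' @export
mass_to_equivalent_pressure <- function(m_ring, geometry) {
  stopifnot(inherits(geometry, "strip_geometry"))
  if (any(!is.finite(m_ring)) || any(m_ring <= 0))
    stop("m_ring must be positive")
  m_ring * .g0 / (geometry$width * geometry$vessel_radius) / .pa_per_mmHg
}

#' Default calibrated ring masses
#'
#' The four lead-ring masses shipped as the package default, kg. They are
#' calibrated (see `scripts/calibrate_ring_masses.R`) so that, with the
#' default [strip_geometry()], the four load steps map through
#' [mass_to_equivalent_pressure()] onto equally spaced equivalent pressures
#' spanning the instrument's standard operating range 77.2-157.4 mmHg.
#'
#' @return Numeric vector of 4 strictly increasing masses, kg.
#' @export
default_ring_masses <- function() {
  c(0.00409320, 0.00551062, 0.00692804, 0.00834546)
}

#' Load-step table
#'
#' Builds the table of the four incremental load steps: ring mass, total
#' oscillating mass (mask + ring), equivalent pressure and, when a stiffness
#' is supplied, the static elongation.
#'
#' @param ring_masses strictly increasing vector of suspended ring masses, kg.
#' @param mask_mass mass of the opaque mask, kg (always oscillating).
#' @param geometry a [strip_geometry()].
#' @param stiffness optional spring stiffness k (N/m) used to fill `dL_m` via
#'   the static relation `m g / k`; otherwise `dL_m` is `NA` (to be supplied
#'   from measurement).
#' @return A data frame with columns `mass_index`, `ring_mass`, `m_osc`,
#'   `p_mmHg`, `dL_m`.
#' @export
load_steps <- function(ring_masses = default_ring_masses(),
                       mask_mass = 0.0015, geometry = strip_geometry(),
                       stiffness = NULL) {
  if (any(!is.finite(ring_masses)) || any(ring_masses <= 0))
    stop("ring masses must be positive")
  if (any(diff(ring_masses) <= 0))
    stop("ring masses must be strictly increasing")
  if (mask_mass <= 0) stop("mask_mass must be positive")
  p <- mass_to_equivalent_pressure(ring_masses, geometry)
  dL <- if (is.null(stiffness)) NA_real_ else ring_masses * .g0 / stiffness
  data.frame(mass_index = seq_along(ring_masses), ring_mass = ring_masses,
             m_osc = ring_masses + mask_mass, p_mmHg = p, dL_m = dL)
}

#' Assemble the tidy viscoelastic observation table
#'
#' Joins per-measurement resonance features with the measurement manifest
#' (subject, group, stage, load metadata) and computes the dynamic modulus for
#' every measurement, producing the unit of analysis of the statistics stage:
#' one row per (subject, stage, load step) with equivalent pressure, natural
#' frequency and modulus.
#'
#' @param features data frame with columns `subject`, `stage`, `mass_index`,
#'   `f0_Hz` and optionally `qc_flags` (as written by the analysis stage).
#' @param geometry a [strip_geometry()].
#' @param manifest data frame with one row per measurement: `subject`,
#'   `group`, `stage`, `mass_index`, `m_osc`, `dL_m` and optionally `p_mmHg`
#'   and `ring_mass`. Missing `p_mmHg` is filled from `ring_mass` via
#'   [mass_to_equivalent_pressure()].
#' @return A data frame with columns `subject`, `group`, `stage`,
#'   `mass_index`, `p_mmHg`, `f0_Hz`, `Eprime_MPa`, `qc_flags`. Rows whose
#'   features failed QC keep their flags (and `NA` modulus if `f0_Hz` is
#'   `NA`); downstream statistics exclude flagged rows by default.
#' @export
assemble_points <- function(features, geometry, manifest) {
  stopifnot(is.data.frame(features), is.data.frame(manifest),
            inherits(geometry, "strip_geometry"))
  if (nrow(features) == 0L) {
    warning("empty features table: no viscoelastic points assembled")
    return(data.frame(subject = character(), group = character(),
                      stage = character(), mass_index = integer(),
                      p_mmHg = numeric(), f0_Hz = numeric(),
                      Eprime_MPa = numeric(), qc_flags = character(),
                      stringsAsFactors = FALSE))
  }
  need_f <- c("subject", "stage", "mass_index", "f0_Hz")
  need_m <- c("subject", "group", "stage", "mass_index", "m_osc", "dL_m")
  if (length(miss <- setdiff(need_f, names(features))))
    stop("features table lacks columns: ", paste(miss, collapse = ", "))
  if (length(miss <- setdiff(need_m, names(manifest))))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))

  key <- function(d) paste(d$subject, d$stage, d$mass_index, sep = "\r")
  kf <- key(features); km <- key(manifest)
  if (anyDuplicated(kf))
    stop("duplicated measurement id(s) in features: ",
         paste(unique(gsub("\r", "/", kf[duplicated(kf)])), collapse = ", "))
  if (anyDuplicated(km)) stop("duplicated measurement id(s) in manifest")
  orphans <- setdiff(kf, km)
  if (length(orphans))
    stop("features rows without manifest entry: ",
         paste(gsub("\r", "/", orphans), collapse = ", "))

  i <- match(kf, km)
  man <- manifest[i, , drop = FALSE]
  p <- if ("p_mmHg" %in% names(man) && all(is.finite(man$p_mmHg))) {
    man$p_mmHg
  } else {
    mass_to_equivalent_pressure(man$ring_mass, geometry)
  }
  qc <- if ("qc_flags" %in% names(features)) as.character(features$qc_flags)
        else rep("", nrow(features))
  qc[is.na(qc)] <- ""

  E <- rep(NA_real_, nrow(features))
  ok <- is.finite(features$f0_Hz) & features$f0_Hz > 0
  E[ok] <- dynamic_modulus(features$f0_Hz[ok], man$m_osc[ok], geometry$L0,
                           man$dL_m[ok], geometry$S)
  data.frame(subject = as.character(features$subject),
             group = as.character(man$group),
             stage = as.character(features$stage),
             mass_index = as.integer(features$mass_index),
             p_mmHg = p, f0_Hz = features$f0_Hz,
             Eprime_MPa = E / 1e6, qc_flags = qc,
             stringsAsFactors = FALSE)
}
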