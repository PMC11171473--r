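#!/usr/bin/env Rscript
# Calibration of the default lead-ring masses.
#
# The instrument's standard operating range of equivalent intraluminal
# pressure is 77.2-157.4 mmHg. With the default strip geometry (width 3 mm,
# source-vessel radius 1.3 mm) the Laplace equivalence
#   p = m g / (b r_v)
# fixes the lightest and heaviest masses; the two intermediate rings are
# placed so the four pressures are equally spaced. The rounded results are
# frozen in forcedosc::default_ring_masses().

library(forcedosc)

geom <- strip_geometry()
g <- 9.80665
pa_per_mmHg <- 133.322
p_target <- c(77.2, 157.4) # mmHg

m_bounds <- p_target * pa_per_mmHg * geom$width * geom$vessel_radius / g
masses <- signif(seq(m_bounds[1], m_bounds[2], length.out = 4), 6)
p_check <- mass_to_equivalent_pressure(masses, geom)

cat("calibrated masses (kg):", sprintf("%.6g", masses), "\n")
cat("equivalent pressures (mmHg):", sprintf("%.4f", p_check), "\n")
stopifnot(max(abs(range(p_check) - p_target)) < 0.01)
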