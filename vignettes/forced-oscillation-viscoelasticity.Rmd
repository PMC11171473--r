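---
title: "Estimating arterial strip viscoelasticity from forced oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating arterial strip viscoelasticity from forced oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcedosc)
```

## The measurement and its model

An arterial strip (the tunica media of a rat thoracic aorta, cut as a helical
strip about 3 mm wide) hangs between a sinusoidal drive at its upper end and a
small oscillating mass (an opaque mask, optionally loaded with one of four
lead rings) at its lower end. The drive frequency is swept slowly through the
strip-mass system's resonance while both the excitation and the response
displacement are digitised. `forcedosc` models the strip as a Kelvin-Voigt
element - a spring of stiffness $k$ and a viscous damper $c$ in parallel - so
the oscillating mass $m$ obeys

$$ m\,\ddot{x} = k\,(u - x)\,\bigl(1 + \beta (u - x)^2\bigr) + c\,(\dot{u} - \dot{x}), $$

where $u(t)$ is the commanded base motion and $\beta$ an optional cubic
(Duffing) stiffness coefficient: $\beta < 0$ gives the softening behaviour
typical of arterial tissue (resonance curve leaning left), $\beta > 0$
hardening. For the linear element ($\beta = 0$) the steady-state amplitude
ratio is the classical base-excitation transmissibility

$$ T(r, \zeta) = \sqrt{\frac{1 + (2\zeta r)^2}{(1 - r^2)^2 + (2\zeta r)^2}},
\qquad r = f/f_0,\quad \zeta = \frac{c}{2\sqrt{k m}} , $$

implemented in `kv_transmissibility()` and used throughout as the analytic
oracle for the signal-processing stage.

Two scalar characteristics summarise the viscoelasticity:

* the **natural frequency** $f_0$, read from the peak of the resonance curve,
  and
* the **dynamic elastic modulus**
  $E' = (2\pi f_0)^2\, m\, (L_0 + \Delta L)/S$ (`dynamic_modulus()`), with
  $L_0$ the unloaded strip length, $\Delta L$ the static elongation under the
  suspended mass and $S$ the cross-section. $E'$ is reported in MPa.

Each ring mass also defines a point on the pressure axis: the wall tension it
imposes on a strip of width $b$ equals the tension a cylindrical vessel of
radius $r_v$ would carry under an intraluminal pressure
$p = m g / (b\, r_v)$ (`mass_to_equivalent_pressure()`; 1 mmHg = 133.322 Pa).
This thin-walled Laplace equivalence is a modelling choice - the equivalence
itself is standard, but no unique mapping is dictated by the experiment - so
it is isolated behind a single function and $r_v$ is configurable. The
default ring masses (4.093-8.345 g, `default_ring_masses()`) are calibrated
once (`scripts/calibrate_ring_masses.R`) so the four load steps fall on
equally spaced pressures spanning the instrument's standard operating range
of 77.2-157.4 mmHg.

## Reading the resonance curve

`extract_resonance_curve()` converts a swept-sine record into an amplitude
ratio-vs-frequency curve by synchronous (quadrature) demodulation: each
channel is mixed with the in-phase and quadrature carriers of the *commanded*
chirp phase and averaged over a window spanning exactly three whole cycles of
the local drive frequency. Taking the phase from the known sweep law rather
than estimating it from the signal mirrors the instrument, which records the
excitation it commands; snapping the window end to a whole-cycle phase
boundary (with a fractionally interpolated endpoint) cancels the
double-frequency mixing term that otherwise ripples through the curve. The
settle segment at the start of each record is discarded.

From the curve, `resonance_features()` reads:

* `natural_frequency()` - the maximum, refined by three-point quadratic
  interpolation; a boundary maximum is an error ("resonance not bracketed").
  Ties between equal discrete maxima resolve to the lower frequency and are
  flagged.
* `bandwidth_3db()` - the half-power crossings nearest the peak, linearly
  interpolated; `octave_length()` expresses the same interval as
  $\log_2(f_{hi}/f_{lo})$. The half-power interval is used because the
  underlying interval definition is not fixed by the protocol; this
  interpretation is documented rather than assumed silently.
* `damping_ratio()` - the standard light-damping estimator
  $\zeta = \Delta f / (2 f_0)$, whose bias against the exact base-excitation
  transmissibility is below 1% for $\zeta \le 0.1$ (about 2% at
  $\zeta = 0.15$).
* `skew_index()` - nonlinearity indicator from an up- and a down-sweep. Its
  magnitude is the relative peak-frequency shift between the two directional
  sweeps (the jump hysteresis). The *sign* cannot come from that shift: on
  either bend direction the down-sweep peak sits at or below the up-sweep
  peak, because each sweep rides the resonant branch to its fold tip. The
  sign is therefore taken from the bend of the merged curve - peak below the
  half-power midpoint means leaning left (softening, negative), above means
  hardening (positive).

`merge_sweeps()` combines the two directional curves into one steady-state
("theoretical") curve as their pointwise upper envelope on the common
interval, followed by a moving median (5 points) and moving mean (5 points);
with a nonlinear element each directional sweep drops off one side of the
bent resonance at its jump, and the upper envelope restores the full peak.
The construction of the merged curve is a documented choice; the upper
envelope is the natural one for jump truncation.

### Sweep-rate criterion

A swept sine only approximates steady state when the sweep is slow against
the oscillator's settling, i.e. when the rate is small compared with the
squared half-power bandwidth. `quasi_steady_ratio()` returns
$\eta = \text{rate}/(2\zeta f_0)^2$; simulation shows the curve error scales
about linearly with $\eta$ (about 2.3% at $\eta = 0.05$, about 0.9% at
$\eta = 0.02$ across $\zeta \in [0.02, 0.1]$). The package uses
$\eta = 0.02$ where sweeps are validated against the closed form and
$\eta = 0.05$ as the synthetic-study default (f0 bias $\le$ 0.6%, hence
modulus bias $\le$ 1.2%); `simulate_strip_response()` warns at $\eta > 1$ and
the feature stage flags `sweep_fast` when the rate exceeds
$0.2\,\Delta f^2$.

## The synthetic study generator

No raw oscillation recordings are publicly deposited for this protocol, so
`generate_study()` emulates the full staged experiment and is the package's
test bed. The protocol vocabulary (`treatment_stages()`) is: control, four
cumulative fentanyl concentrations ($10^{-9}$-$10^{-6}$ M), a 30-min
wash-out, 10-min naloxone $10^{-6}$ M, and the four fentanyl concentrations
repeated under naloxone - 11 stages, each measured at the four load steps.
(The protocol's materials list four fentanyl dilutions; the package follows
that list and keeps the stage list configurable.)

The generating truth is phenomenological: for every group $\times$ stage
cell a linear relation $f_0(p) = a + s\,p$ (defaults in
`default_effect_model()`), plus a per-animal random intercept
(`subject_sd`, default 0.10 Hz). For each measurement the stiffness follows
as $k = (2\pi f_0)^2 m_{osc}$, damping from the configured $\zeta$ (default
0.08), elongation from the statics $\Delta L = m_{ring} g / k$, and the true
modulus from the dynamic-modulus relation - so the stored ground truth is
internally consistent by construction. The modulus then grows convexly,
approximately exponentially, over the pressure range, which is exactly what
the nonlinear regression stage consumes. The linear $f_0$ relation was made
primary (rather than an exponential modulus law) because the two cannot both
hold exactly once Eq.-consistency ties $E'$ to $f_0$ and the masses; with
the linear choice a noise-free study returns the configured slopes exactly,
which gives the parameter-recovery tests a sharp target.

The default effect pattern encodes the study's qualitative findings as stage
shifts of the $f_0$ intercept (all in Hz, against a control intercept of
5.0 and slope 0.050 Hz/mmHg): fentanyl lowers the curve in the sham group at
every concentration; the pinealectomized group sits above the sham group
only at the lowest concentration (with a slope component, so the group
difference grows with pressure); wash-out restores the sham group almost to
control; naloxone alone lowers the curve; the fentanyl + naloxone series
mirrors the fentanyl series except at Fe-8. Magnitudes (0.3-0.8 Hz) are
chosen so that effects are large against the measurement noise at the
study's small group sizes (3 sham, 4 pin animals, matching the reported
usable preparations), i.e. clearly detectable but not trivial.

Two generation modes exist. Feature-level (`signals = FALSE`, default) draws
observed $f_0$ directly with Gaussian measurement noise (`f0_noise_sd`,
default 0.12 Hz) and recomputes the observed modulus from the noisy $f_0$ -
the appropriate scale for statistical replication. Signal-level
(`signals = TRUE`) synthesises every measurement as a full swept-sine record
through the compiled integrator (fixed-step RK4 at $\ge 40$ steps per period)
with additive ADC noise (`noise_sigma`, default 0.01 of the excitation
amplitude), for end-to-end validation of the signal path. What the generator
does *not* emulate: drug pharmacodynamics (effects are static per-stage
shifts, not kinetics), superfusion hydrodynamics, slow drift or creep within
a record, non-Gaussian or correlated ADC noise, and any within-stage
time-order effects. Passing tests therefore validate the estimation
machinery under the stated statistical structure, not the biology of real
recordings.

## The statistics stage

Following the protocol's analysis plan, $f_0(p)$ is fitted by ordinary least
squares (`fit_linear()`) and $E'(p)$ by the two-parameter growth model
$a e^{b p}$ (`fit_exponential()`, Levenberg-Marquardt, initialised from the
log-linear regression; non-convergence is flagged and excluded from
comparisons). Points are pooled across the animals of a group $\times$ stage
cell; per-animal random effects are deliberately out of scope (see
limitations).

`compare_lines()` is the classic two-line ANCOVA: an extra-sum-of-squares
F test of equal slopes, and - only when slopes do not differ significantly -
an F test of equal elevations under the common slope. `compare_curves()` is
the extra-sum-of-squares F test of one shared $(a, b)$ pair against separate
pairs, $F$ on $(2, n_A + n_B - 4)$ degrees of freedom. `run_comparisons()`
applies both over a contrast plan (default: between groups at every stage,
and every stage against its group's control), at per-comparison
$\alpha = 0.05$ with no multiplicity correction, mirroring the original
analysis; a Holm option exists but defaults off. Cells with fewer than three
usable points, single-group designs and non-converged fits are skipped with
an explicit reason.

Null simulations (two groups of 16 points on the four default pressures,
Gaussian noise) show both tests holding their nominal size: across 2000
replicates the slope test rejected at 4.7% and the curve test at 4.9%,
within two Monte-Carlo standard errors of 5%.

## Numerical choices

* Integrator: fixed-step RK4 in compiled code, at least 40 sub-steps per
  period of the fastest relevant frequency; divergence or non-finite states
  raise an error rather than truncating. RK4's local error at 40 steps per
  cycle (about $10^{-3}$ relative per cycle in the worst term) is negligible
  against the 2% sweep-transient budget.
* Demodulation window: 3 cycles of the local frequency; shorter windows track
  the envelope faster, longer windows filter noise harder. The window end is
  placed at an exact whole-cycle phase boundary by interpolating the
  cumulative (trapezoidal) mixed-product integrals.
* Peak refinement: three-point quadratic interpolation; equal-maxima ties
  resolve to the lower frequency with a QC flag.
* Exponential fits run on MPa-scaled moduli for conditioning; the fitted
  parameters are scale-covariant, and comparisons are invariant to the unit.
* Degenerate inputs fail loudly and early: empty sweeps, boundary maxima,
  uncrossed half-power levels, duplicated or orphaned measurement ids, and
  rank-deficient regressions all carry named errors; QC-flagged measurements
  propagate as flags and are excluded from statistics by default.

## Problem sizes used by the test suite

The acceptance-style checks run at the following sizes, chosen as the points
where the Monte-Carlo error is comfortably below the tolerances being
verified: closed-form equivalence on three damping ratios over
$r \in [0.2, 3]$; feature recovery on 100 seeded random oscillators; modulus
exactness on 1000 random inputs; 2000-replicate null calibrations of both
comparison tests; and 40 seeded feature-level replicates of the default
study for the significance-pattern check.

## Known limitations

* **Exact pattern reproduction is capped by the per-comparison error rate.**
  The pattern check asks every planned contrast to land on its generated
  truth simultaneously. Three of the checked between-group contrasts are
  true nulls, so with per-comparison $\alpha = 0.05$ and no multiplicity
  correction the probability that all of them stay non-significant is at
  most $0.95^3 \approx 0.86$ even for perfectly calibrated tests - and
  pooling four points per animal with a realistic between-animal intercept
  SD inflates the between-group type-I error beyond $\alpha$ (a design
  effect of about 2 at four points per animal). A $\ge 95\%$ exact-pattern
  rate is therefore not attainable under the default (uncorrected) analysis;
  the Holm option restores it at the cost of departing from the original
  per-comparison convention. The package reports the honest rate.
* Pooling across animals ignores the repeated-measures structure; a
  mixed-effects treatment is deliberately not implemented because the
  original analysis fitted group-level curves.
* Exactly one resonance is assumed; there is no multi-mode fitting.
* The mass-to-pressure mapping is the thin-walled Laplace equivalence with a
  configurable vessel radius; other calibrations can be expressed through
  `strip_geometry()` but none is derivable from the protocol text.
* The loss modulus (complex-modulus decomposition) is not computed; the
  method reports $f_0$ and $E'$ only.

## A minimal session

```{r example, eval = FALSE}
cfg <- pipeline_config(study = study_config(n_sham = 3, n_pin = 4, seed = 1))
res <- run_pipeline(cfg, mode = "all", out_dir = "study_out")
res$report          # significant contrasts
head(res$points)    # tidy (subject, stage, pressure, f0, E') table
```
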