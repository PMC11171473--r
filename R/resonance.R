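#' Resonance curve
#'
#' Amplitude ratio (response envelope / excitation envelope) against drive
#' frequency, as read from one swept-sine record or merged from an up and a
#' down sweep.
#'
#' @param frequency strictly increasing frequency grid, Hz (>= 20 points).
#' @param amplitude non-negative amplitude ratios, same length.
#' @param direction `"up"`, `"down"` or `"merged"`.
#' @param qc_flags character vector of quality flags attached to the curve.
#' @return An object of class `resonance_curve` (a list with the fields above).
#' @export
resonance_curve <- function(frequency, amplitude,
                            direction = c("up", "down", "merged"),
                            qc_flags = character()) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(frequency), is.numeric(amplitude))
  if (length(frequency) != length(amplitude))
    stop("frequency and amplitude must have equal length")
  if (length(frequency) < 20L)
    stop("a resonance curve needs at least 20 points")
  if (any(!is.finite(frequency)) || any(!is.finite(amplitude)))
    stop("non-finite values in resonance curve")
  if (any(diff(frequency) <= 0))
    stop("frequency grid must be strictly increasing")
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  structure(list(frequency = frequency, amplitude = amplitude,
                 direction = direction, qc_flags = qc_flags),
            class = "resonance_curve")
}

#' @export
print.resonance_curve <- function(x, ...) {
  cat(sprintf("resonance_curve (%s): %d points, %.4g-%.4g Hz, peak ratio %.4g\n",
              x$direction, length(x$frequency), min(x$frequency),
              max(x$frequency), max(x$amplitude)))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.resonance_curve <- function(x, ...) {
  graphics::plot(x$frequency, x$amplitude, type = "l",
                 xlab = "frequency (Hz)", ylab = "amplitude ratio", ...)
  invisible(x)
}

#' Extract the resonance curve from a swept-sine record
#'
#' Estimates the local amplitude of both channels by synchronous (quadrature)
#' demodulation against the known sweep phase - the lock-in principle: each
#' channel is mixed with the in-phase and quadrature carriers of the commanded
#' chirp and averaged over a short window spanning `window_cycles` whole
#' cycles of the local drive frequency, so the double-frequency mixing term
#' cancels and the local amplitude follows as twice the magnitude of the
#' complex average, independent of the channel's phase lag. The curve is the
#' ratio of the two amplitudes on a frequency grid; the settle segment of the
#' record is discarded.
#'
#' @param record an `oscillation_record`.
#' @param n_points number of points of the output frequency grid.
#' @param window_cycles demodulation window length in periods of the local
#'   drive frequency.
#' @return A [resonance_curve()], direction inherited from the sweep.
#' @export
extract_resonance_curve <- function(record, n_points = 201, window_cycles = 3) {
  stopifnot(inherits(record, "oscillation_record"))
  sweep <- record$sweep
  if (!is.finite(sweep$f_end - sweep$f_start) ||
      sweep$f_end - sweep$f_start <= 0)
    stop("sweep interval empty")
  x <- record$response; u <- record$excitation; t <- record$time
  if (length(x) == 0L || any(!is.finite(x)) || any(!is.finite(u)))
    stop("empty or non-finite signal in record")

  fs <- sweep$sampling_rate
  law <- sweep_law(sweep)
  t_end <- t[length(t)]

  # output grid, uniform in frequency between the sweep bounds with margins so
  # every demodulation window fits inside the swept (post-settle) segment
  f_grid <- seq(sweep$f_start, sweep$f_end, length.out = n_points + 2L)
  f_grid <- f_grid[-c(1L, n_points + 2L)]
  # time at which the sweep passes frequency f
  t_of_f <- sweep$settle_time + (f_grid - law$f_from) / law$rate
  w <- window_cycles / f_grid                    # window duration, s
  ok <- (t_of_f - w / 2 >= sweep$settle_time) & (t_of_f + w / 2 <= t_end)
  if (sum(ok) < 20L)
    stop("sweep too short to place at least 20 envelope windows")
  f_grid <- f_grid[ok]; t_of_f <- t_of_f[ok]; w <- w[ok]

  ph <- sweep_phase(sweep, t)
  n <- length(t); dt <- 1 / fs
  cph <- cos(ph); sph <- sin(ph)

  # windows start on a sample near t_c - w/2 and end at the exact time where
  # the commanded phase has advanced by 2 pi window_cycles, so the
  # double-frequency mixing term integrates out without a partial-cycle
  # residual; the fractional end sample is handled by interpolation
  i1 <- pmax(1L, as.integer(round((t_of_f - w / 2) * fs)) + 1L)
  ph2 <- ph[i1] + 2 * pi * window_cycles
  j2 <- findInterval(ph2, ph)              # last sample with phase <= target
  keep <- j2 < n & (j2 - i1) >= 4L
  if (sum(keep) < 20L)
    stop("sweep too short to place at least 20 envelope windows")
  f_grid <- f_grid[keep]; t_of_f <- t_of_f[keep]
  i1 <- i1[keep]; ph2 <- ph2[keep]; j2 <- j2[keep]
  # invert the phase law within one sample via the local frequency
  t2 <- t[j2] + (ph2 - ph[j2]) / (2 * pi * sweep_frequency(sweep, t[j2]))
  frac <- (t2 - t[j2]) / dt

  ctrap <- function(v) c(0, cumsum((v[-n] + v[-1L]) / 2)) * dt
  wmean <- function(v) {
    cv <- ctrap(v)
    v2 <- v[j2] + (v[j2 + 1L] - v[j2]) * frac          # v at t2
    seg <- cv[j2] - cv[i1] + (v[j2] + v2) / 2 * (t2 - t[j2])
    seg / (t2 - t[i1])
  }
  amp_x <- 2 * sqrt(wmean(x * cph)^2 + wmean(x * sph)^2)
  amp_u <- 2 * sqrt(wmean(u * cph)^2 + wmean(u * sph)^2)
  if (any(amp_u <= 0)) stop("excitation envelope vanished inside the sweep")
  amp <- amp_x / amp_u

  o <- order(f_grid)  # down sweeps come out reversed in time, same grid
  resonance_curve(f_grid[o], amp[o], direction = sweep$direction)
}

# interior discrete maximum with 3-point quadratic refinement; returns
# list(f0, amplitude, tie_flag) or errors when the peak is not bracketed
curve_peak <- function(curve) {
  a <- curve$amplitude; f <- curve$frequency; n <- length(a)
  i_max <- which(a == max(a))
  tie <- length(i_max) > 1L
  i <- i_max[1L]  # tie-break: lower frequency, flagged
  if (i == 1L || i == n) stop("resonance not bracketed by the frequency grid")
  # parabola through the three points around the discrete peak
  x1 <- f[i - 1L]; x2 <- f[i]; x3 <- f[i + 1L]
  y1 <- a[i - 1L]; y2 <- a[i]; y3 <- a[i + 1L]
  d21 <- (y2 - y1) / (x2 - x1)
  d32 <- (y3 - y2) / (x3 - x2)
  curv <- (d32 - d21) / (x3 - x1)
  if (!is.finite(curv) || curv >= 0) {
    f0 <- x2; amp <- y2  # flat or degenerate: keep the grid point
  } else {
    # vertex of the Newton-form parabola y1 + d21 (x-x1) + curv (x-x1)(x-x2)
    f0 <- (x1 + x2) / 2 - d21 / (2 * curv)
    f0 <- min(max(f0, x1), x3)
    amp <- y1 + d21 * (f0 - x1) + curv * (f0 - x1) * (f0 - x2)
  }
  list(f0 = f0, amplitude = amp, tie_flag = tie)
}

#' Natural frequency from a resonance curve
#'
#' Frequency of the curve's maximum, refined by 3-point quadratic
#' interpolation around the discrete peak. Fails if the maximum sits on the
#' boundary of the grid (resonance not bracketed). If two discrete maxima tie,
#' the lower frequency is taken and the result carries a `"peak_tie"`
#' attribute.
#'
#' @param curve a [resonance_curve()].
#' @return Natural frequency, Hz.
#' @export
natural_frequency <- function(curve) {
  stopifnot(inherits(curve, "resonance_curve"))
  pk <- curve_peak(curve)
  out <- pk$f0
  if (pk$tie_flag) attr(out, "qc") <- "peak_tie"
  out
}

#' Half-power (3 dB) bandwidth
#'
#' Finds the two frequencies nearest the peak at which the curve crosses
#' `peak / sqrt(2)`, by linear interpolation between grid points, and returns
#' them with their difference.
#'
#' @param curve a [resonance_curve()].
#' @return A list with `f_lo`, `f_hi`, `delta_f` (Hz).
#' @export
bandwidth_3db <- function(curve) {
  stopifnot(inherits(curve, "resonance_curve"))
  pk <- curve_peak(curve)
  a <- curve$amplitude; f <- curve$frequency; n <- length(a)
  level <- pk$amplitude / sqrt(2)
  i_pk <- which.max(a)

  cross_down <- function(idx_seq) {
    # walk from the peak outward; first bracketing pair with a < level
    for (j in idx_seq) {
      if (a[j] < level) {
        j_in <- j + sign(i_pk - j)  # neighbour towards the peak
        return(f[j] + (level - a[j]) * (f[j_in] - f[j]) / (a[j_in] - a[j]))
      }
    }
    NA_real_
  }
  f_lo <- if (i_pk > 1L) cross_down(seq(i_pk - 1L, 1L)) else NA_real_
  f_hi <- if (i_pk < n) cross_down(seq(i_pk + 1L, n)) else NA_real_
  if (!is.finite(f_lo) || !is.finite(f_hi))
    stop("bandwidth not resolved: half-power level not crossed on ",
         if (!is.finite(f_lo)) "the low side" else "the high side")
  list(f_lo = f_lo, f_hi = f_hi, delta_f = f_hi - f_lo)
}

#' Octave length of a frequency interval
#'
#' The half-power interval expressed in octaves: `log2(f_hi / f_lo)`.
#'
#' @param f_lo,f_hi interval bounds, Hz, `0 < f_lo < f_hi`.
#' @return Interval length in octaves.
#' @examples
#' octave_length(10, 20) # 1
#' @export
octave_length <- function(f_lo, f_hi) {
  stopifnot(is.numeric(f_lo), is.numeric(f_hi))
  if (any(f_lo <= 0) || any(f_hi <= f_lo))
    stop("need 0 < f_lo < f_hi")
  log2(f_hi / f_lo)
}

#' Half-power damping ratio estimate
#'
#' Standard light-damping estimator `zeta = delta_f / (2 f0)` from the
#' half-power bandwidth; its bias against the base-excitation transmissibility
#' is below 1% for `zeta <= 0.1`.
#'
#' @param f0 natural frequency, Hz (positive).
#' @param delta_f half-power bandwidth, Hz (positive).
#' @return Damping ratio estimate.
#' @export
damping_ratio <- function(f0, delta_f) {
  stopifnot(is.numeric(f0), is.numeric(delta_f))
  if (any(f0 <= 0)) stop("f0 must be positive")
  if (any(delta_f <= 0)) stop("delta_f must be positive")
  delta_f / (2 * f0)
}

#' Merge up- and down-sweep resonance curves
#'
#' Builds the steady-state ("theoretical") resonance curve from the two
#' directional sweeps as their pointwise upper envelope on the overlapping
#' frequency interval, optionally followed by the module's standard smoothing
#' (moving median of 5 then moving mean of 5). With a nonlinear element each
#' directional sweep drops off one side of the bent resonance at the jump; the
#' upper envelope restores the full peak.
#'
#' @param up,down [resonance_curve()] objects spanning a common interval.
#' @param smooth logical; apply the standard smoothing (default `TRUE`).
#' @return A merged [resonance_curve()].
#' @export
merge_sweeps <- function(up, down, smooth = TRUE) {
  stopifnot(inherits(up, "resonance_curve"), inherits(down, "resonance_curve"))
  lo <- max(min(up$frequency), min(down$frequency))
  hi <- min(max(up$frequency), max(down$frequency))
  if (hi <= lo) stop("sweeps cover disjoint frequency ranges")
  keep <- up$frequency >= lo & up$frequency <= hi
  f <- up$frequency[keep]
  if (length(f) < 20L) stop("overlap of the two sweeps is too short")
  a_up <- up$amplitude[keep]
  a_dn <- approx(down$frequency, down$amplitude, xout = f, rule = 2)$y
  a <- pmax(a_up, a_dn)
  if (smooth) a <- smooth_curve(a)
  resonance_curve(f, pmax(a, 0), direction = "merged",
                  qc_flags = union(up$qc_flags, down$qc_flags))
}

# moving median (5) then centred moving mean (5), ends handled by shrinking
# windows; used by merge_sweeps
smooth_curve <- function(a, k = 5L) {
  a <- runmed(a, k, endrule = "median")
  n <- length(a); h <- k %/% 2L
  cs <- c(0, cumsum(a))
  i1 <- pmax(seq_len(n) - h, 1L); i2 <- pmin(seq_len(n) + h, n)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

#' Softening/hardening skew index from directional sweeps
#'
#' Quantifies amplitude-dependent (Duffing-type) bending of the resonance.
#' The magnitude is the relative peak-frequency shift between the two
#' directional sweeps, `2 |f_down - f_up| / (f_down + f_up)` - the jump
#' hysteresis, which vanishes for a linear element. Because the down-sweep
#' peak sits at or below the up-sweep peak for either bend direction (the
#' sweep rides the resonant branch to its fold tip in both cases), the sign
#' of the shift itself cannot tell softening from hardening; the index
#' therefore takes its sign from the bend direction of the merged curve: the
#' peak lying below the midpoint of the half-power interval means the curve
#' leans left (softening, negative index), above means hardening (positive).
#'
#' @param up,down [resonance_curve()] objects from an up and a down sweep
#'   over the same interval.
#' @return Signed skew index (dimensionless); near zero for a linear element.
#' @export
skew_index <- function(up, down) {
  f_up <- as.numeric(natural_frequency(up))
  f_dn <- as.numeric(natural_frequency(down))
  mag <- 2 * abs(f_dn - f_up) / (f_dn + f_up)
  merged <- merge_sweeps(up, down)
  pk <- curve_peak(merged)
  bw <- bandwidth_3db(merged)
  lean <- pk$f0 - (bw$f_lo + bw$f_hi) / 2
  if (lean == 0 || mag == 0) return(0)
  sign(lean) * mag
}

#' All scalar resonance features of a curve
#'
#' Convenience wrapper computing natural frequency, interpolated peak
#' amplitude, half-power bandwidth, octave length and damping ratio, plus QC
#' flags. When `sweep_rate` is supplied the quasi-steady criterion is checked
#' against the measured bandwidth (`sweep_rate > 0.2 * delta_f^2` flags
#' `"sweep_fast"`).
#'
#' @param curve a [resonance_curve()].
#' @param sweep_rate optional sweep rate (Hz/s) used for the QC check.
#' @return A list of class `resonance_features` with fields `f0`,
#'   `peak_amplitude`, `f_lo`, `f_hi`, `bandwidth_3db`, `octave_length`,
#'   `damping_ratio`, `qc_flags`.
#' @export
resonance_features <- function(curve, sweep_rate = NULL) {
  stopifnot(inherits(curve, "resonance_curve"))
  pk <- curve_peak(curve)
  bw <- bandwidth_3db(curve)
  qc <- curve$qc_flags
  if (pk$tie_flag) qc <- union(qc, "peak_tie")
  if (!is.null(sweep_rate) && sweep_rate > 0.2 * bw$delta_f^2)
    qc <- union(qc, "sweep_fast")
  structure(list(f0 = pk$f0, peak_amplitude = pk$amplitude,
                 f_lo = bw$f_lo, f_hi = bw$f_hi,
                 bandwidth_3db = bw$delta_f,
                 octave_length = octave_length(bw$f_lo, bw$f_hi),
                 damping_ratio = damping_ratio(pk$f0, bw$delta_f),
                 qc_flags = qc),
            class = "resonance_features")
}

#' @export
print.resonance_features <- function(x, ...) {
  cat(sprintf(
    "f0 = %.4g Hz, peak = %.4g, bw3dB = %.4g Hz, octaves = %.4g, zeta = %.4g\n",
    x$f0, x$peak_amplitude, x$bandwidth_3db, x$octave_length,
    x$damping_ratio))
  if (length(x$qc_flags)) cat("qc:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.resonance_features <- function(x, ...) {
  data.frame(f0_Hz = x$f0, peak_amp = x$peak_amplitude,
             bw3db_Hz = x$bandwidth_3db, octave_len = x$octave_length,
             zeta = x$damping_ratio,
             qc_flags = paste(x$qc_flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
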