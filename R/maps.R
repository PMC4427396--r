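# Auxiliary parameter-map computations: T2 from T2-prepared b-SSFP and
# multi-TE spin echo, flip-angle (B1+) maps from the Bloch-Siegert phase
# shift, and gold-standard inversion-recovery T1 fitting.

#' 2D parameter map with units and mask
#'
#' @param values Numeric matrix.
#' @param units One of `"ms"`, `"degrees"`, `"Hz"`, `"dimensionless"`, `"radians"`.
#' @param mask Logical matrix congruent with `values`; `NULL` means all pixels.
#' @param meta Named list of acquisition metadata.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, units = "dimensionless", mask = NULL,
                          meta = list()) {
  stopifnot(is.matrix(values))
  units <- match.arg(units, c("ms", "degrees", "Hz", "dimensionless", "radians"))
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  structure(list(values = values, units = units, mask = mask, meta = meta),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %dx%d [%s], %d masked-in pixels\n",
              nrow(x$values), ncol(x$values), x$units, sum(x$mask)))
  cat(sprintf("  mean = %.4g, sd = %.4g\n", pm_mean(x), pm_sd(x)))
  invisible(x)
}

#' Masked mean and standard deviation of a parameter map
#'
#' Statistics over in-mask, non-NA pixels only; masked-out values never
#' contribute.
#' @param map A [parameter_map()].
#' @return A single number.
#' @export
pm_mean <- function(map) mean(map$values[map$mask], na.rm = TRUE)

#' @rdname pm_mean
#' @export
pm_sd <- function(map) stats::sd(map$values[map$mask], na.rm = TRUE)

# Log-linear weighted least squares for S = s0 * exp(-t / t2). Weights
# proportional to S^2 make the log-domain fit equivalent (to first order in
# the noise) to the amplitude-domain fit; with 3 points this is exact enough
# and deterministic.
loglin_t2 <- function(signals, times, what = "T2") {
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop(what, " fit requires positive finite signals")
  y <- log(signals)
  w <- signals^2
  fit <- stats::lm.wfit(cbind(1, times), y, w)
  slope <- fit$coefficients[2]
  if (slope >= -1e-12)  # non-decaying signals: no finite T2
    return(list(t2 = Inf, s0 = exp(fit$coefficients[1]), ok = FALSE))
  list(t2 = as.numeric(-1 / slope),
       s0 = as.numeric(exp(fit$coefficients[1])), ok = TRUE)
}

#' Fit T2 from T2-prepared b-SSFP signals
#'
#' Mono-exponential `S = S0 * exp(-t_prep / T2)` by signal-squared-weighted
#' log-linear least squares over the preparation times.
#'
#' @param signals Positive signal amplitudes, one per preparation time.
#' @param prep_times Preparation durations in ms.
#' @return List with `t2` (ms), `s0` and `ok` (FALSE when the signals do not
#'   decay, in which case `t2 = Inf`).
#' @examples
#' fit_t2prep(exp(-c(0, 25, 75) / 45), c(0, 25, 75))$t2
#' @export
fit_t2prep <- function(signals, prep_times) {
  stopifnot(length(signals) == length(prep_times), length(signals) >= 2)
  loglin_t2(signals, prep_times, "T2-prep")
}

#' Fit T2 from multi-echo spin-echo signals
#'
#' Same mono-exponential model as [fit_t2prep()] over the echo-time
#' schedule (e.g. the 8-TE protocol 10/20/40/60/90/120/200/400 ms).
#'
#' @param signals Positive signal amplitudes, one per TE.
#' @param te Echo times in ms (>= 3 echoes).
#' @return As [fit_t2prep()].
#' @export
fit_t2_se <- function(signals, te) {
  stopifnot(length(signals) == length(te), length(signals) >= 3)
  loglin_t2(signals, te, "spin-echo T2")
}

#' Gold-standard inversion-recovery T1 fit
#'
#' 3-parameter fit `S = A - B * exp(-TI / T1)` with no Look-Locker
#' correction (long-TR IR acquisition assumed). Magnitude data undergo the
#' same polarity restoration as [fit_standard()].
#'
#' @param signals Signal amplitudes.
#' @param ti Inversion times in ms (>= 4 points).
#' @param magnitude Whether `signals` are magnitude data needing polarity
#'   restoration.
#' @return A list with `t1` (ms), `a`, `b`, `rss`, `converged`,
#'   `polarity_index`.
#' @export
fit_ir <- function(signals, ti, magnitude = FALSE) {
  stopifnot(length(signals) == length(ti), length(signals) >= 4)
  curve <- recovery_curve(ti, signals, is_magnitude = magnitude)
  f <- fit_exp_recovery(curve)
  if (!f$converged) return(f)
  list(t1 = f$t1_star, a = f$a, b = f$b, rss = f$rss, converged = TRUE,
       polarity_index = f$polarity_index)
}

# --- Bloch-Siegert B1+ mapping -------------------------------------------

#' Bloch-Siegert encoding-pulse parameters
#'
#' Off-resonance Fermi pulse played at `+/- delta_omega` inside a GRE
#' sequence; the phase difference between the two acquisitions encodes
#' B1peak^2. The Fermi envelope is
#' `f(t) = 1 / (1 + exp((|t - T/2| - t0) / a))` with `t0 = 0.6 * T / 2` and
#' `a = T / 70` by default, normalized to unit peak and scaled so the
#' on-resonance flip of the pulse equals `pulse_flip`.
#'
#' @param delta_omega Off-resonance of the encoding pulse in kHz.
#' @param pulse_duration Pulse duration in ms.
#' @param pulse_flip Equivalent on-resonance flip angle in degrees.
#' @param t0,a Fermi width and transition constants in ms (defaults derived
#'   from `pulse_duration` as above).
#' @return An object of class `bloch_siegert_params`.
#' @export
bloch_siegert_params <- function(delta_omega = 8, pulse_duration = 8,
                                 pulse_flip = 600,
                                 t0 = 0.6 * pulse_duration / 2,
                                 a = pulse_duration / 70) {
  stopifnot(delta_omega != 0, pulse_duration > 0, pulse_flip > 0)
  structure(list(delta_omega = delta_omega, pulse_duration = pulse_duration,
                 pulse_flip = pulse_flip, t0 = t0, a = a, shape = "fermi"),
            class = "bloch_siegert_params")
}

fermi_envelope <- function(t, params) {
  1 / (1 + exp((abs(t - params$pulse_duration / 2) - params$t0) / params$a))
}

# Peak B1 (uT) realizing the stated on-resonance flip, and the
# Bloch-Siegert constant K_BS (rad / uT^2) of the normalized envelope,
# both by numerical integration at dt = 1 us. Far-off-resonance
# approximation: phase = K_BS * B1peak^2 per pulse.
bs_constants <- function(params) {
  dt <- 1e-3  # ms
  t <- seq(dt / 2, params$pulse_duration - dt / 2, by = dt)
  f <- fermi_envelope(t, params)
  flip_rad <- params$pulse_flip * pi / 180
  b1_peak <- flip_rad / (GAMMA_RAD_MS_UT * sum(f) * dt)
  dw_rad_ms <- 2 * pi * params$delta_omega  # kHz -> rad/ms
  k_bs <- sum((GAMMA_RAD_MS_UT * f)^2 / (2 * dw_rad_ms)) * dt
  list(b1_peak = b1_peak, k_bs = k_bs)
}

#' Forward Bloch-Siegert phase model
#'
#' Phase difference (radians) between the `+delta_omega` and `-delta_omega`
#' acquisitions for a pixel whose transmit scale is `b1_scale`:
#' `2 * K_BS * (b1_scale * B1_nominal_peak)^2`.
#'
#' @param b1_scale Transmit scale(s), actual/nominal.
#' @param params A [bloch_siegert_params()].
#' @return Phase difference(s) in radians.
#' @export
bloch_siegert_phase <- function(b1_scale, params = bloch_siegert_params()) {
  k <- bs_constants(params)
  2 * k$k_bs * (b1_scale * k$b1_peak)^2
}

#' Convert a Bloch-Siegert phase-difference map to a flip-angle map
#'
#' Inverts the quadratic phase law: per-pixel peak B1 is
#' `sqrt(phase / (2 * K_BS))` and the achieved excitation flip angle is
#' `nominal_alpha * B1 / B1_nominal`. Pixels with negative phase (after
#' unwrapping) are masked out.
#'
#' @param phase_diff Matrix of phase differences in radians.
#' @param params A [bloch_siegert_params()].
#' @param nominal_alpha Nominal excitation flip angle in degrees.
#' @param mask Optional logical matrix.
#' @return A [parameter_map()] of achieved flip angles in degrees.
#' @examples
#' ph <- matrix(bloch_siegert_phase(1.01), 2, 2)
#' bloch_siegert_to_alpha(ph, nominal_alpha = 35)
#' @export
bloch_siegert_to_alpha <- function(phase_diff, params = bloch_siegert_params(),
                                   nominal_alpha = 35, mask = NULL) {
  stopifnot(is.matrix(phase_diff))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase_diff), ncol(phase_diff))
  k <- bs_constants(params)
  ok <- mask & is.finite(phase_diff) & phase_diff >= 0
  vals <- matrix(NA_real_, nrow(phase_diff), ncol(phase_diff))
  vals[ok] <- nominal_alpha * sqrt(phase_diff[ok] / (2 * k$k_bs)) / k$b1_peak
  parameter_map(vals, units = "degrees", mask = ok,
                meta = list(bloch_siegert = unclass(params),
                            nominal_alpha = nominal_alpha))
}
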