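# Forward simulation of the ECG-gated MOLLI acquisition and of the
# T2-prepared b-SSFP acquisition.
#
# The readout train is propagated with composed affine operators: each TR is
# [pulse -> TE evolution (echo sampled) -> (TR - TE) evolution]. Composing
# the 5 ramp pulses and the +/-alpha train once per (tissue, alpha) yields
# two affine maps -- readout start to centre-line echo, and readout start to
# readout end -- reused for every image of the acquisition.

readout_affine_maps <- function(tissue, alpha, p) {
  # The +/-alpha train continues the sign alternation of the ramp (the ramp
  # ends at +5/6 alpha, so the train starts at -alpha); breaking the
  # alternation would destroy the catalyzed pseudo-steady state.
  last_prep <- if (p$n_prep_pulses > 0) p$prep_scale_factors[p$n_prep_pulses] else -1
  s0 <- if (last_prep >= 0) -1 else 1
  angles <- c(p$prep_scale_factors * alpha,
              alpha * s0 * rep_len(c(1, -1), p$n_readout_pulses))
  if (any(abs(angles) > 360))
    stop("pulse angle exceeds 360 degrees; check alpha and prep_scale_factors")
  center <- p$n_prep_pulses + p$center_line_index
  if (tissue$delta_f == 0)
    return(readout_affine_maps_2d(angles, center, tissue, p))
  e_te <- op_evolve(p$te, tissue)
  e_rem <- op_evolve(p$tr - p$te, tissue)
  A <- diag(3); b <- c(0, 0, 0)
  A_sig <- NULL; b_sig <- NULL
  for (j in seq_along(angles)) {
    R <- op_rotate(angles[j])
    A <- R$A %*% A; b <- as.numeric(R$A %*% b)
    A <- e_te$A %*% A; b <- as.numeric(e_te$A %*% b) + e_te$b
    if (j == center) { A_sig <- A; b_sig <- b }
    A <- e_rem$A %*% A; b <- as.numeric(e_rem$A %*% b) + e_rem$b
  }
  list(A_sig = A_sig, b_sig = b_sig, A_end = A, b_end = b,
       duration = readout_duration(p), center_offset = readout_center_offset(p))
}

# On-resonance fast path: x-rotations never mix mx into (my, mz) and with
# delta_f = 0 the evolution matrices are diagonal, so starting from any
# state the (my, mz) dynamics is a closed 2x2 affine recursion and mx only
# decays by exp(-t/T2). Composed in scalar arithmetic, then embedded back
# into the 3x3 representation.
readout_affine_maps_2d <- function(angles, center, tissue, p) {
  rad <- angles * pi / 180
  ca <- cos(rad); sa <- sin(rad)
  e2a <- exp(-p$te / tissue$t2); e1a <- exp(-p$te / tissue$t1)
  e2b <- exp(-(p$tr - p$te) / tissue$t2); e1b <- exp(-(p$tr - p$te) / tissue$t1)
  ra <- (1 - e1a) * tissue$m0; rb <- (1 - e1b) * tissue$m0
  # affine (my, mz): M' = [[a11 a12],[a21 a22]] M + (b1, b2)
  a11 <- 1; a12 <- 0; a21 <- 0; a22 <- 1; b1 <- 0; b2 <- 0
  sig <- NULL
  for (j in seq_along(ca)) {
    c_ <- ca[j]; s_ <- sa[j]
    # rotation: my' = c my + s mz ; mz' = -s my + c mz
    t11 <- c_ * a11 + s_ * a21; t12 <- c_ * a12 + s_ * a22
    t21 <- -s_ * a11 + c_ * a21; t22 <- -s_ * a12 + c_ * a22
    tb1 <- c_ * b1 + s_ * b2; tb2 <- -s_ * b1 + c_ * b2
    # TE evolution
    a11 <- e2a * t11; a12 <- e2a * t12; b1 <- e2a * tb1
    a21 <- e1a * t21; a22 <- e1a * t22; b2 <- e1a * tb2 + ra
    if (j == center)
      sig <- c(a11, a12, a21, a22, b1, b2)
    # remainder of TR
    a11 <- e2b * a11; a12 <- e2b * a12; b1 <- e2b * b1
    a21 <- e1b * a21; a22 <- e1b * a22; b2 <- e1b * b2 + rb
  }
  co <- readout_center_offset(p)
  dur <- readout_duration(p)
  embed <- function(v, x_decay) {
    A <- matrix(c(x_decay, 0, 0,
                  0, v[1], v[2],
                  0, v[3], v[4]), 3, 3, byrow = TRUE)
    list(A = A, b = c(0, v[5], v[6]))
  }
  S <- embed(sig, exp(-co / tissue$t2))
  E <- embed(c(a11, a12, a21, a22, b1, b2), exp(-dur / tissue$t2))
  list(A_sig = S$A, b_sig = S$b, A_end = E$A, b_end = E$b,
       duration = dur, center_offset = co)
}

#' Simulate one single-shot b-SSFP readout
#'
#' Applies the flip-angle ramp (prep_scale_factors x alpha, separated by TR)
#' followed by the +/-alpha pulse train to a caller-supplied starting state,
#' sampling the echo TE after the centre-line pulse.
#'
#' @param state Magnetization state at readout start (length-3 vector).
#' @param tissue A [tissue_params()].
#' @param alpha Achieved excitation flip angle in degrees.
#' @param protocol A [molli_protocol()] or [t2prep_protocol()] supplying the
#'   train structure (tr, te, pulse counts, ramp factors, centre line).
#' @param magnitude If `TRUE` return `|signal|`; otherwise the transverse
#'   magnitude at the echo signed by the polarity of `mz` at readout start
#'   (phase-sensitive convention).
#' @return List with `signal`, `state` (at readout end) and `duration` (ms).
#' @export
simulate_bssfp_readout <- function(state, tissue, alpha, protocol,
                                   magnitude = FALSE) {
  maps <- readout_affine_maps(tissue, alpha, protocol)
  sgn <- if (state[3] < 0) -1 else 1
  echo <- as.numeric(maps$A_sig %*% state) + maps$b_sig
  sig <- sqrt(echo[1]^2 + echo[2]^2) * (if (magnitude) 1 else sgn)
  out <- as.numeric(maps$A_end %*% state) + maps$b_end
  list(signal = sig, state = out, duration = maps$duration)
}

#' Recovery curve container
#'
#' The sampled (TI, signal) pairs produced by one MOLLI run for one pixel,
#' in acquisition order, with block/beat metadata enabling TI-sorted
#' reordering.
#'
#' @param ti Inversion times in ms (acquisition order).
#' @param signal Signed (or magnitude) signal amplitudes.
#' @param is_magnitude Whether `signal` holds magnitude data.
#' @param block Optional block index per sample.
#' @return An object of class `recovery_curve`.
#' @export
recovery_curve <- function(ti, signal, is_magnitude = FALSE, block = NULL) {
  stopifnot(length(ti) == length(signal), all(ti > 0))
  structure(list(ti = as.numeric(ti), signal = as.numeric(signal),
                 is_magnitude = isTRUE(is_magnitude), block = block),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve> %d samples (%s)\n", length(x$ti),
              if (x$is_magnitude) "magnitude" else "signed"))
  print(data.frame(ti = x$ti, signal = signif(x$signal, 5)))
  invisible(x)
}

#' Sort a recovery curve by inversion time
#' @param curve A [recovery_curve()].
#' @return The curve with samples reordered by increasing TI.
#' @export
sort_by_ti <- function(curve) {
  o <- order(curve$ti)
  recovery_curve(curve$ti[o], curve$signal[o], curve$is_magnitude,
                 if (!is.null(curve$block)) curve$block[o])
}

#' Simulate a full MOLLI acquisition
#'
#' Starting from equilibrium, simulates each inversion (instantaneous, with
#' efficacy `eta` applied to mz and transverse magnetization spoiled), the
#' free recovery to the readout, every b-SSFP readout on its R-R beat, and
#' the rest periods between blocks (free precession and relaxation only).
#' Returns the signal sampled at the centre-line echo of each of the images,
#' i.e. the sequence response f(T1, T2, eta, alpha, TI) at the 11 inversion
#' times of the standard 3-3-5 protocol.
#'
#' @param tissue A [tissue_params()].
#' @param protocol A [molli_protocol()].
#' @param eta Inversion efficacy in (0, 1]: the inversion maps mz to
#'   `-eta * mz`.
#' @param alpha_actual Achieved flip angle in degrees (defaults to the
#'   protocol's nominal angle; supply the B1+-scaled value to model transmit
#'   inhomogeneity).
#' @param magnitude If `TRUE` return magnitude signals (scanner-like);
#'   default is the signed phase-sensitive convention.
#' @param sched Precomputed [molli_ti_schedule()] of `protocol`; computed
#'   when `NULL`. Passing it avoids recomputation in tight fitting loops.
#' @return A [recovery_curve()] in acquisition order.
#' @examples
#' curve <- simulate_molli(tissue_params(1180, 45), molli_protocol(), eta = 0.92)
#' sort_by_ti(curve)
#' @export
simulate_molli <- function(tissue, protocol, eta = 1,
                           alpha_actual = protocol$alpha_nominal,
                           magnitude = FALSE, sched = NULL) {
  stopifnot(inherits(protocol, "molli_protocol"))
  if (!is.finite(eta) || eta <= 0 || eta > 1)
    stop("eta must lie in (0, 1]")
  p <- protocol
  if (is.null(sched)) sched <- molli_ti_schedule(p)
  maps <- readout_affine_maps(tissue, alpha_actual, p)
  co <- maps$center_offset
  onres <- tissue$delta_f == 0
  evolve <- function(state, t) {
    if (t == 0) return(state)
    if (onres) {
      e2 <- exp(-t / tissue$t2); e1 <- exp(-t / tissue$t1)
      c(state[1] * e2, state[2] * e2,
        state[3] * e1 + (1 - e1) * tissue$m0)
    } else apply_op(op_evolve(t, tissue), state)
  }
  blocks <- sched$block; t_centers <- sched$t_center
  t_invs <- sched$t_inversion; tis <- sched$ti
  state <- equilibrium_state(tissue)
  t_cur <- -Inf  # before the first inversion the state is at equilibrium
  signal <- numeric(length(tis))
  for (i in seq_along(tis)) {
    if (i == 1L || blocks[i] != blocks[i - 1L]) {
      # free recovery up to this block's inversion, then invert
      t_inv <- t_invs[i]
      if (is.finite(t_cur)) {
        if (t_inv < t_cur - 1e-9)
          stop(sprintf(
            "negative delay before inversion of block %d (TI = %g ms)",
            blocks[i], tis[i]))
        state <- evolve(state, t_inv - t_cur)
      }
      state <- c(0, 0, -eta * state[3])
      t_cur <- t_inv
    }
    rs <- t_centers[i] - co
    if (rs < t_cur - 1e-9)
      stop(sprintf("negative inversion-to-readout delay for TI = %g ms", tis[i]))
    state <- evolve(state, rs - t_cur)
    sgn <- if (state[3] < 0) -1 else 1
    echo <- as.numeric(maps$A_sig %*% state) + maps$b_sig
    s <- sqrt(echo[1]^2 + echo[2]^2)
    signal[i] <- if (magnitude) s else sgn * s
    state <- as.numeric(maps$A_end %*% state) + maps$b_end
    t_cur <- rs + maps$duration
  }
  recovery_curve(tis, signal, is_magnitude = magnitude, block = blocks)
}

#' Simulate a T2-prepared b-SSFP acquisition
#'
#' For each preparation time: an ideal T2 preparation (mz scaled by
#' `exp(-t_prep / T2)`, transverse magnetization spoiled), a b-SSFP readout,
#' then `rest_rr` R-R intervals of free recovery.
#'
#' @param tissue A [tissue_params()].
#' @param protocol A [t2prep_protocol()].
#' @return A data.frame with columns `prep_time` (ms) and `signal`.
#' @export
simulate_t2prep_bssfp <- function(tissue, protocol) {
  stopifnot(inherits(protocol, "t2prep_protocol"))
  p <- protocol
  maps <- readout_affine_maps(tissue, p$alpha, p)
  state <- equilibrium_state(tissue)
  sig <- numeric(length(p$prep_times))
  for (i in seq_along(p$prep_times)) {
    state <- c(0, 0, state[3] * exp(-p$prep_times[i] / tissue$t2))
    echo <- as.numeric(maps$A_sig %*% state) + maps$b_sig
    sig[i] <- sqrt(echo[1]^2 + echo[2]^2) * (if (state[3] < 0) -1 else 1)
    state <- as.numeric(maps$A_end %*% state) + maps$b_end
    rest <- p$rest_rr * p$rr_interval
    state <- apply_op(op_evolve(rest, tissue), state)
  }
  data.frame(prep_time = p$prep_times, signal = sig)
}
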