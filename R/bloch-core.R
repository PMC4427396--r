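# Elementary Bloch operators in affine form M' = A %*% M + b, from which
# every sequence block in the package is composed.

#' Tissue relaxation parameters for one pixel or tube
#'
#' Bundles the longitudinal and transverse relaxation times, off-resonance
#' frequency and equilibrium magnetization of a single isochromat.
#'
#' @param t1 Longitudinal relaxation time in ms (> 0; `Inf` allowed to
#'   disable T1 relaxation).
#' @param t2 Transverse relaxation time in ms (> 0; `Inf` allowed).
#' @param delta_f Off-resonance frequency in Hz.
#' @param m0 Equilibrium magnetization (dimensionless, > 0). The default of 1
#'   makes all simulated signals fractions of M0; absolute scale is a free
#'   amplitude in the fitting routines.
#' @return An object of class `tissue_params`.
#' @examples
#' myo <- tissue_params(t1 = 1180, t2 = 45)
#' @export
tissue_params <- function(t1, t2, delta_f = 0, m0 = 1) {
  stopifnot(is.numeric(t1), is.numeric(t2), is.numeric(delta_f), is.numeric(m0))
  if (is.na(t1) || t1 <= 0) stop("t1 must be positive")
  if (is.na(t2) || t2 <= 0) stop("t2 must be positive")
  if (!is.finite(delta_f)) stop("delta_f must be finite")
  if (!is.finite(m0) || m0 <= 0) stop("m0 must be positive and finite")
  if (is.finite(t2) && is.finite(t1) && t2 > t1)
    warning("t2 > t1 is unphysical for tissue; simulating anyway")
  structure(list(t1 = t1, t2 = t2, delta_f = delta_f, m0 = m0),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> T1 = %g ms, T2 = %g ms, df = %g Hz, M0 = %g\n",
              x$t1, x$t2, x$delta_f, x$m0))
  invisible(x)
}

#' Magnetization state vector
#'
#' @param mx,my,mz Components in units of M0.
#' @return Numeric length-3 vector `c(mx, my, mz)`.
#' @export
mag_state <- function(mx = 0, my = 0, mz = 1) {
  m <- c(mx, my, mz)
  if (!all(is.finite(m))) stop("magnetization components must be finite")
  m
}

#' Equilibrium magnetization state
#' @param tissue A [tissue_params()] object (only `m0` is used).
#' @return `c(0, 0, m0)`.
#' @export
equilibrium_state <- function(tissue) c(0, 0, tissue$m0)

#' Affine Bloch operator
#'
#' An operator acting on a magnetization state as `A %*% M + b`. Rotations
#' have `b = 0`; relaxation carries the recovery offset toward `c(0, 0, m0)`.
#'
#' @param A 3x3 numeric matrix.
#' @param b Numeric length-3 offset vector.
#' @return An object of class `bloch_op`.
#' @export
bloch_op <- function(A, b = c(0, 0, 0)) {
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)), length(b) == 3)
  structure(list(A = A, b = as.numeric(b)), class = "bloch_op")
}

#' Identity Bloch operator
#' @return A `bloch_op` leaving any state unchanged.
#' @export
op_identity <- function() bloch_op(diag(3))

#' RF nutation operator about the x-axis
#'
#' @param alpha Nutation angle in degrees (any sign, finite).
#' @return A `bloch_op` with matrix
#'   `[[1,0,0],[0,cos a,sin a],[0,-sin a,cos a]]`.
#' @export
op_rotate <- function(alpha) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  a <- alpha * pi / 180
  ca <- cos(a); sa <- sin(a)
  bloch_op(matrix(c(1, 0, 0,
                    0, ca, sa,
                    0, -sa, ca), 3, 3, byrow = TRUE))
}

#' Free-precession operator
#'
#' Rotates the transverse plane by `2 * pi * delta_f * t` (t in ms, delta_f
#' in Hz); the longitudinal component is untouched.
#'
#' @param t Duration in ms (>= 0).
#' @param delta_f Off-resonance frequency in Hz.
#' @export
op_precess <- function(t, delta_f) {
  if (!is.finite(t) || t < 0) stop("t must be non-negative")
  phi <- 2 * pi * delta_f * t / 1000  # Hz * ms -> cycles/1000
  cp <- cos(phi); sp <- sin(phi)
  bloch_op(matrix(c(cp, sp, 0,
                    -sp, cp, 0,
                    0, 0, 1), 3, 3, byrow = TRUE))
}

#' Relaxation operator
#'
#' Exponential T2 decay of the transverse components and T1 recovery of the
#' longitudinal component toward `m0`: `M' = C(t) M + (I - C(t)) c(0,0,m0)`.
#'
#' @param t Duration in ms (>= 0).
#' @param tissue A [tissue_params()] object.
#' @export
op_relax <- function(t, tissue) {
  if (!is.finite(t) && !is.infinite(t)) stop("t must be numeric")
  if (t < 0) stop("t must be non-negative")
  e2 <- exp(-t / tissue$t2)
  e1 <- exp(-t / tissue$t1)
  bloch_op(diag(c(e2, e2, e1)), c(0, 0, (1 - e1) * tissue$m0))
}

# Combined free evolution (precession + relaxation) over t; the two commute
# because precession is a transverse rotation and T2 decay is isotropic in
# the transverse plane.
op_evolve <- function(t, tissue) {
  if (tissue$delta_f == 0) return(op_relax(t, tissue))
  op_compose(op_precess(t, tissue$delta_f), op_relax(t, tissue))
}

#' Apply a Bloch operator to a state
#' @param op A `bloch_op`.
#' @param state Numeric length-3 magnetization vector.
#' @return The transformed state.
#' @export
apply_op <- function(op, state) as.numeric(op$A %*% state + op$b)

#' Compose Bloch operators in order of application
#'
#' `op_compose(op1, op2, ...)` returns the single affine operator equivalent
#' to applying `op1` first, then `op2`, and so on:
#' `(A2, b2) o (A1, b1) = (A2 A1, A2 b1 + b2)`. With no arguments the
#' identity operator is returned.
#'
#' @param ... `bloch_op` objects, or a single list of them.
#' @export
op_compose <- function(...) {
  ops <- list(...)
  if (length(ops) == 1L && !inherits(ops[[1]], "bloch_op")) ops <- ops[[1]]
  A <- diag(3); b <- c(0, 0, 0)
  for (op in ops) {
    stopifnot(inherits(op, "bloch_op"))
    A <- op$A %*% A
    b <- as.numeric(op$A %*% b) + op$b
  }
  bloch_op(A, b)
}

#' @export
print.bloch_op <- function(x, ...) {
  cat("<bloch_op> A =\n"); print(signif(x$A, 6))
  cat("b =", signif(x$b, 6), "\n")
  invisible(x)
}

# --- Convenience state-level wrappers -------------------------------------

#' Rotate a magnetization state about the x-axis
#' @inheritParams op_rotate
#' @param state Numeric length-3 magnetization vector.
#' @export
rotate <- function(alpha, state) apply_op(op_rotate(alpha), state)

#' Let a state precess freely
#' @inheritParams op_precess
#' @param state Numeric length-3 magnetization vector.
#' @export
precess <- function(t, delta_f, state) apply_op(op_precess(t, delta_f), state)

#' Relax a state toward equilibrium
#' @inheritParams op_relax
#' @param state Numeric length-3 magnetization vector.
#' @export
relax <- function(t, tissue, state) apply_op(op_relax(t, tissue), state)
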