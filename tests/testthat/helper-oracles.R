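# Independent fine-step integrators used as oracles against the composed
# affine-operator propagation. These step the state vector directly through
# every pulse and dt-sized free-evolution slice, never touching
# readout_affine_maps().

step_evolve <- function(state, t, tissue, dt = 0.001) {
  if (t <= 0) return(state)
  n <- ceiling(t / dt)
  h <- t / n
  e2 <- exp(-h / tissue$t2); e1 <- exp(-h / tissue$t1)
  phi <- 2 * pi * tissue$delta_f * h / 1000
  cp <- cos(phi); sp <- sin(phi)
  rec <- (1 - e1) * tissue$m0
  for (i in seq_len(n)) {
    mx <- cp * state[1] + sp * state[2]
    my <- -sp * state[1] + cp * state[2]
    state <- c(mx * e2, my * e2, state[3] * e1 + rec)
  }
  state
}

# Step-by-step readout: instantaneous pulses, echo recorded TE after the
# centre-line pulse, fine-step free evolution elsewhere.
step_readout <- function(state, tissue, alpha, p, dt = 0.001) {
  last_prep <- p$prep_scale_factors[p$n_prep_pulses]
  s0 <- if (last_prep >= 0) -1 else 1
  angles <- c(p$prep_scale_factors * alpha,
              alpha * s0 * rep_len(c(1, -1), p$n_readout_pulses))
  center <- p$n_prep_pulses + p$center_line_index
  echo <- NULL
  for (j in seq_along(angles)) {
    state <- rotate(angles[j], state)
    state <- step_evolve(state, p$te, tissue, dt)
    if (j == center) echo <- state
    state <- step_evolve(state, p$tr - p$te, tissue, dt)
  }
  list(echo = echo, state = state)
}

# Full MOLLI acquisition by sequential fine-step integration. Free
# evolution slices are exact at any dt (relaxation/precession form a
# semigroup), so dt controls only runtime; the independence from the
# composed-operator path lies in stepping the state through every pulse.
step_molli <- function(tissue, p, eta = 1, alpha = p$alpha_nominal,
                       dt = 0.2) {
  sched <- molli_ti_schedule(p)
  co <- (p$n_prep_pulses + p$center_line_index - 1) * p$tr + p$te
  dur <- (p$n_prep_pulses + p$n_readout_pulses) * p$tr
  state <- c(0, 0, tissue$m0)
  t_cur <- NA
  signal <- numeric(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    if (i == 1 || sched$block[i] != sched$block[i - 1]) {
      t_inv <- sched$t_inversion[i]
      if (!is.na(t_cur)) state <- step_evolve(state, t_inv - t_cur, tissue, dt)
      state <- c(0, 0, -eta * state[3])
      t_cur <- t_inv
    }
    rs <- sched$t_center[i] - co
    state <- step_evolve(state, rs - t_cur, tissue, dt)
    sgn <- if (state[3] < 0) -1 else 1
    out <- step_readout(state, tissue, alpha, p, dt)
    signal[i] <- sgn * sqrt(out$echo[1]^2 + out$echo[2]^2)
    state <- out$state
    t_cur <- rs + dur
  }
  recovery_curve(sched$ti, signal, block = sched$block)
}

# Dense grid search oracle for the 3-parameter recovery fit: profiles A and
# B in closed form (linear least squares) on a fine T1* grid.
grid_fit_exp <- function(ti, s, t1s_grid = seq(50, 4000, by = 0.5)) {
  best <- NULL
  for (t1s in t1s_grid) {
    x <- exp(-ti / t1s)
    fit <- stats::lm.fit(cbind(1, -x), s)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(a = fit$coefficients[1], b = fit$coefficients[2],
                   t1_star = t1s, rss = rss)
  }
  best
}

# Dense grid search oracle for the simulation-based fit.
grid_fit_sim <- function(curve, t2, eta, alpha, p, t1_grid) {
  y <- curve$signal
  sched <- molli_ti_schedule(p)
  perm <- match(round(curve$ti, 6), round(sched$ti, 6))
  rss <- vapply(t1_grid, function(t1) {
    f <- simulate_molli(tissue_params(t1, t2), p, eta = eta,
                        alpha_actual = alpha, sched = sched)$signal[perm]
    s <- sum(f * y) / sum(f * f)
    sum((y - s * f)^2)
  }, numeric(1))
  t1_grid[which.min(rss)]
}

expect_state_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
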