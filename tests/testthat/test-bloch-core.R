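test_that("rotation operator matches its closed trigonometric form", {
  expect_state_equal(rotate(90, c(0, 0, 1)), c(0, 1, 0))
  expect_state_equal(rotate(180, c(0, 0, 1)), c(0, 0, -1))
  expect_state_equal(rotate(35, c(0, 0, 1)),
                     c(0, sin(35 * pi / 180), cos(35 * pi / 180)))
  # norm preservation and orthogonality for arbitrary angles
  set.seed(4)
  for (a in stats::runif(10, -360, 360)) {
    R <- op_rotate(a)
    expect_lt(max(abs(t(R$A) %*% R$A - diag(3))), 1e-12)
    m <- stats::rnorm(3)
    expect_equal(sqrt(sum(rotate(a, m)^2)), sqrt(sum(m^2)), tolerance = 1e-12)
  }
  expect_error(op_rotate(NaN), "finite")
})

test_that("free precession rotates the transverse plane with mz untouched", {
  m <- c(0.3, -0.2, 0.7)
  expect_state_equal(precess(5, 0, m), m)
  # quarter period: 100 Hz for 2.5 ms
  expect_state_equal(precess(2.5, 100, c(1, 0, 0)), c(0, -1, 0), tol = 1e-12)
  # group property: composition in time
  p1 <- precess(1.3, 77, precess(2.2, 77, m))
  expect_state_equal(p1, precess(3.5, 77, m), tol = 1e-12)
  expect_error(op_precess(-1, 100), "non-negative")
})

test_that("relaxation follows the closed exponential forms", {
  tis <- tissue_params(800, 60)
  expect_state_equal(relax(100 * tis$t1, tis, c(0.5, -0.5, -1)), c(0, 0, 1),
                     tol = 1e-10)
  expect_equal(relax(800, tis, c(0, 0, 0))[3], 1 - exp(-1), tolerance = 1e-12)
  out <- relax(60, tis, c(1, 0, 1))
  expect_equal(out[1], exp(-1), tolerance = 1e-12)
  expect_equal(out[3], 1 - (1 - 1) * exp(-60 / 800), tolerance = 1e-12)
  expect_error(op_relax(-0.1, tis), "non-negative")
})

test_that("relaxation contracts every state toward equilibrium", {
  tis <- tissue_params(1000, 50)
  eq <- c(0, 0, 1)
  set.seed(7)
  for (i in 1:5) {
    m <- stats::runif(3, -1, 1)
    d <- vapply(c(0, 5, 20, 100, 500), function(t)
      sqrt(sum((relax(t, tis, m) - eq)^2)), numeric(1))
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("affine composition equals sequential application and associates", {
  tis <- tissue_params(1100, 45, delta_f = 30)
  ops <- list(op_rotate(35), op_precess(1.2, 30),
              op_relax(1.2, tis), op_rotate(-35), op_relax(3, tis))
  m <- c(0.2, -0.4, 0.6)
  seq_applied <- Reduce(function(s, op) apply_op(op, s), ops, m)
  expect_state_equal(apply_op(op_compose(ops), m), seq_applied, tol = 1e-12)
  ab_c <- op_compose(op_compose(ops[[1]], ops[[2]]), ops[[3]])
  a_bc <- op_compose(ops[[1]], op_compose(ops[[2]], ops[[3]]))
  expect_state_equal(apply_op(ab_c, m), apply_op(a_bc, m), tol = 1e-12)
  # identity / inverse rotations
  expect_state_equal(apply_op(op_compose(op_identity()), m), m)
  expect_state_equal(apply_op(op_compose(op_rotate(50), op_rotate(-50)), m),
                     m, tol = 1e-12)
  expect_state_equal(apply_op(op_compose(), m), m)
})

test_that("composed inversion recovery reproduces the closed form exactly", {
  # with T2 = T1 and no off-resonance, mz evolves as
  # 1 - (1 - mz0) exp(-t/T1) regardless of how the evolution is sliced
  tis <- tissue_params(900, 900)
  mz0 <- -0.85
  slices <- c(12, 40, 100, 333, 515)
  op <- op_compose(lapply(slices, function(t) op_relax(t, tis)))
  out <- apply_op(op, c(0, 0, mz0))
  expect_equal(out[3], 1 - (1 - mz0) * exp(-sum(slices) / 900),
               tolerance = 1e-12)
})

test_that("composed b-SSFP TR agrees with a fine-step integrator", {
  p <- molli_protocol()
  for (df in c(0, 40)) {
    tis <- tissue_params(1180, 45, delta_f = df)
    maps <- mollifit:::readout_affine_maps(tis, 35, p)
    m0 <- c(0, 0, -0.9)
    composed <- as.numeric(maps$A_end %*% m0) + maps$b_end
    stepped <- step_readout(m0, tis, 35, p, dt = 0.001)$state
    expect_state_equal(composed, stepped, tol = 1e-6)
  }
})

test_that("tissue parameter validation flags unphysical inputs", {
  expect_error(tissue_params(-5, 50), "positive")
  expect_error(tissue_params(1000, 0), "positive")
  expect_warning(tissue_params(40, 60), "t2 > t1")
  expect_silent(tissue_params(1180, 45))
})
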