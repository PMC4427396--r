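test_that("the standard 3-3-5 protocol yields the canonical TI schedule", {
  sched <- molli_ti_schedule(molli_protocol())
  expect_equal(sched$ti,
               c(100, 1100, 2100, 180, 1180, 2180, 260, 1260, 2260, 3260, 4260))
  expect_equal(sched$block, rep(1:3, c(3, 3, 5)))
  # readout duration of the in vitro protocol: 74 pulses x 2.5 ms
  expect_equal(mollifit:::readout_duration(molli_protocol()), 185)
})

test_that("zero flip angle gives zero signal and pure free relaxation", {
  tis <- tissue_params(1180, 45)
  p <- molli_protocol()
  st <- c(0, 0, -0.9)
  out <- simulate_bssfp_readout(st, tis, 0, p)
  expect_equal(out$signal, 0)
  expect_state_equal(out$state, relax(out$duration, tis, st), tol = 1e-10)
})

test_that("full MOLLI simulation matches fine-step sequential integration", {
  p <- molli_protocol()
  set.seed(21)
  for (i in 1:3) {
    t1 <- stats::runif(1, 500, 2000)
    t2 <- stats::runif(1, 30, 80)
    al <- stats::runif(1, 15, 40)
    eta <- stats::runif(1, 0.85, 1)
    tis <- tissue_params(t1, t2)
    fast <- simulate_molli(tis, p, eta = eta, alpha_actual = al)
    slow <- step_molli(tis, p, eta = eta, alpha = al, dt = 0.2)
    expect_lt(max(abs(fast$signal - slow$signal)), 1e-5)
  }
})

test_that("TI-sorted signed recovery is monotone and bounded", {
  p <- molli_protocol()
  for (t1 in c(535, 1180, 2085)) {
    cv <- sort_by_ti(simulate_molli(tissue_params(t1, 45), p, eta = 1))
    expect_true(all(diff(cv$signal) > 0))
    expect_true(all(cv$signal > -1))
    expect_true(all(cv$signal < sin(35 * pi / 180)))
  }
})

test_that("small flip angles recover the ideal inversion-recovery shape", {
  p <- molli_protocol(alpha_nominal = 0.001)
  t1 <- 1000
  cv <- sort_by_ti(simulate_molli(tissue_params(t1, 60), p, eta = 1))
  ideal <- 1 - 2 * exp(-cv$ti / t1)
  # compare shapes after common scaling
  s <- sum(cv$signal * ideal) / sum(ideal^2)
  expect_lt(max(abs(cv$signal - s * ideal)) / max(abs(s * ideal)), 0.005)
})

test_that("longer rest periods deepen the post-inversion signal of later blocks", {
  # more complete recovery before re-inversion means a larger |mz| is
  # inverted, so the signed first-image signal of blocks 2 and 3 becomes
  # more negative (its magnitude grows)
  tis <- tissue_params(1800, 50)
  first_of_block <- function(rest) {
    p <- molli_protocol(rest_periods = c(rest, rest))
    cv <- simulate_molli(tis, p, eta = 0.92)
    cv$signal[match(2:3, cv$block)]
  }
  s3 <- first_of_block(3)
  s6 <- first_of_block(6)
  expect_true(all(s6 <= s3 + 1e-12))
  expect_true(all(abs(s6) >= abs(s3) - 1e-12))
})

test_that("simulated signal is linear in m0", {
  p <- molli_protocol()
  a <- simulate_molli(tissue_params(1180, 45, m0 = 1), p, eta = 0.92)
  b <- simulate_molli(tissue_params(1180, 45, m0 = 2.5), p, eta = 0.92)
  expect_equal(b$signal, 2.5 * a$signal, tolerance = 1e-12)
})

test_that("invalid timing and parameters are rejected with clear errors", {
  expect_error(simulate_molli(tissue_params(1000, 50),
                              molli_protocol(ti1 = 40)),
               "negative inversion-to-readout delay")
  expect_error(simulate_molli(tissue_params(1000, 50), molli_protocol(),
                              eta = 1.2), "eta")
  expect_error(mollifit:::readout_affine_maps(
    tissue_params(1000, 50), 500, molli_protocol()), "360")
})

test_that("T2 preparation produces monotone decay and plain readout at zero prep", {
  tis <- tissue_params(1200, 45)
  tp <- t2prep_protocol()
  out <- simulate_t2prep_bssfp(tis, tp)
  expect_equal(out$prep_time, c(0, 25, 75))
  r <- out$signal / out$signal[1]
  expect_true(r[3] < r[2] && r[2] < 1)
  # prep_time 0 equals an unprepared readout from equilibrium
  plain <- simulate_bssfp_readout(c(0, 0, 1), tis, tp$alpha, tp)
  expect_equal(out$signal[1], plain$signal, tolerance = 1e-12)
})

test_that("protocols round-trip through JSON and YAML", {
  p <- molli_protocol(ti1 = 120, rest_periods = c(2, 4),
                      alpha_nominal = 24)
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_protocol(p, f)
    q <- read_protocol(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
    unlink(f)
  }
})
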