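test_that("T2-prep fitter inverts its forward model exactly", {
  tp <- c(0, 25, 75)
  expect_equal(fit_t2prep(exp(-tp / 45), tp)$t2, 45, tolerance = 1e-9)
  # two-point closed form
  f <- fit_t2prep(c(1, exp(-75 / 52)), c(0, 75))
  expect_equal(f$t2, 75 / log(1 / exp(-75 / 52)), tolerance = 1e-9)
  expect_error(fit_t2prep(c(1, -0.1, 0.5), tp), "positive")
  expect_false(fit_t2prep(c(1, 1.05, 1.1), tp)$ok)
})

test_that("multi-echo spin-echo T2 fit inverts the 8-TE schedule", {
  te <- c(10, 20, 40, 60, 90, 120, 200, 400)
  expect_equal(fit_t2_se(0.8 * exp(-te / 42.9), te)$t2, 42.9,
               tolerance = 1e-9)
  f <- fit_t2_se(rep(0.5, 8), te)
  expect_false(f$ok)
  expect_equal(f$t2, Inf)
})

test_that("spin-echo T2 is precise under modest noise", {
  te <- c(10, 20, 40, 60, 90, 120, 200, 400)
  set.seed(42)
  est <- replicate(400, {
    s <- exp(-te / 45) * (1 + stats::rnorm(8, 0, 0.01))
    fit_t2_se(abs(s), te)$t2
  })
  expect_lt(stats::sd(est) / mean(est), 0.03)
  expect_lt(abs(mean(est) - 45) / 45, 0.01)
})

test_that("T2-prepared b-SSFP readout biases T2 upward", {
  tis <- tissue_params(1422, 45)
  tp <- t2prep_protocol()
  sim <- simulate_t2prep_bssfp(tis, tp)
  f <- fit_t2prep(sim$signal, sim$prep_time)
  expect_gt(f$t2, 45)
})

test_that("inversion-recovery fit inverts exact data and matches a grid oracle", {
  ti <- round(exp(seq(log(30), log(8000), length.out = 24)))
  s <- 1 - 2 * exp(-ti / 2085)
  f <- fit_ir(s, ti)
  expect_equal(f$t1, 2085, tolerance = 1e-3)
  expect_equal(f$b / f$a, 2, tolerance = 1e-6)
  g <- grid_fit_exp(ti, s, seq(2000, 2200, by = 0.5))
  expect_lt(abs(f$t1 - g$t1_star) / g$t1_star, 0.001)
  # magnitude path
  fm <- fit_ir(abs(s), ti, magnitude = TRUE)
  expect_equal(fm$t1, 2085, tolerance = 1e-3)
})

test_that("Bloch-Siegert conversion obeys the quadratic phase law", {
  bs <- bloch_siegert_params()
  expect_equal(bloch_siegert_phase(0, bs), 0)
  a1 <- bloch_siegert_to_alpha(matrix(bloch_siegert_phase(0.6, bs), 1, 1),
                               bs, nominal_alpha = 35)
  a2 <- bloch_siegert_to_alpha(matrix(4 * bloch_siegert_phase(0.6, bs), 1, 1),
                               bs, nominal_alpha = 35)
  expect_equal(a2$values[1, 1], 2 * a1$values[1, 1], tolerance = 1e-9)
})

test_that("Bloch-Siegert round trip recovers the transmit scale", {
  bs <- bloch_siegert_params()
  for (scale in c(0.5, 0.8, 1.01, 1.3, 1.5)) {
    ph <- matrix(bloch_siegert_phase(scale, bs), 2, 2)
    am <- bloch_siegert_to_alpha(ph, bs, nominal_alpha = 35)
    expect_lt(abs(pm_mean(am) - 35 * scale) / (35 * scale), 0.005)
  }
  # negative phase is masked out
  ph <- matrix(c(-0.1, bloch_siegert_phase(1, bs)), 1, 2)
  am <- bloch_siegert_to_alpha(ph, bs, nominal_alpha = 35)
  expect_true(is.na(am$values[1, 1]) && !am$mask[1, 1])
})

test_that("masked statistics ignore masked-out pixel values", {
  v <- matrix(c(1, 2, 3, 1000), 2, 2)
  mk <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pm <- parameter_map(v, "ms", mk)
  expect_equal(pm_mean(pm), 2)
  v2 <- v; v2[2, 2] <- -99
  expect_equal(pm_mean(parameter_map(v2, "ms", mk)), 2)
})
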