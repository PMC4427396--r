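default_tis <- c(100, 1100, 2100, 180, 1180, 2180, 260, 1260, 2260, 3260, 4260)

test_that("the 3-parameter fit recovers exact exponential data and applies the
           Look-Locker correction", {
  # ideal IR: A = 1, B = 2, LL correction is the identity
  s <- 1 - 2 * exp(-default_tis / 800)
  f <- fit_standard(recovery_curve(default_tis, s))
  expect_true(f$converged)
  expect_equal(f$a, 1, tolerance = 1e-6)
  expect_equal(f$b, 2, tolerance = 1e-6)
  expect_equal(f$t1_star, 800, tolerance = 1e-4)
  expect_equal(f$t1, 800, tolerance = 1e-3)
  # readout-shortened curve: T1 = 1000 * (1.8 - 1) = 800
  s2 <- 1 - 1.8 * exp(-default_tis / 1000)
  f2 <- fit_standard(recovery_curve(default_tis, s2))
  expect_equal(f2$t1, 800, tolerance = 1e-3)
})

test_that("polarity restoration recovers the signed fit from magnitude data", {
  s <- 1 - 1.9 * exp(-default_tis / 1200)
  fmag <- fit_standard(recovery_curve(default_tis, abs(s), is_magnitude = TRUE))
  fsig <- fit_standard(recovery_curve(default_tis, s))
  expect_equal(fmag$t1, fsig$t1, tolerance = 1e-6)
  expect_equal(fmag$polarity_index, sum(sort(default_tis) < 1200 * log(1.9)))
})

test_that("standard fit on simulated MOLLI underestimates T1 and matches a
           grid-search oracle", {
  p <- molli_protocol()
  cv <- sort_by_ti(simulate_molli(tissue_params(1180, 60), p, eta = 1))
  f <- fit_standard(cv)
  expect_true(f$converged)
  expect_lt(f$t1, 1180)
  oracle <- grid_fit_exp(cv$ti, cv$signal)
  t1_oracle <- oracle$t1_star * (oracle$b / oracle$a - 1)
  expect_lt(abs(f$t1 - t1_oracle) / t1_oracle, 0.005)
})

test_that("simulation-based fit is exact on self-generated noiseless curves", {
  p <- molli_protocol()
  set.seed(31)
  for (i in 1:6) {
    t1 <- stats::runif(1, 450, 2300)
    t2 <- stats::runif(1, 30, 90)
    al <- stats::runif(1, 15, 40)
    eta <- stats::runif(1, 0.85, 1)
    cv <- simulate_molli(tissue_params(t1, t2), p, eta = eta,
                         alpha_actual = al)
    f <- fit_simulation(cv, t2 = t2, eta = eta, alpha_actual = al,
                        protocol = p)
    expect_true(f$converged)
    expect_lt(abs(f$t1 - t1) / t1, 0.001)
  }
})

test_that("simulation-based fit agrees with a dense grid search", {
  p <- molli_protocol()
  cv <- simulate_molli(tissue_params(1300, 45), p, eta = 0.92)
  # deliberately biased T2 so the optimum is away from the truth
  f <- fit_simulation(cv, t2 = 48.1, eta = 0.92, alpha_actual = 35,
                      protocol = p)
  g <- grid_fit_sim(cv, 48.1, 0.92, 35, p,
                    seq(f$t1 - 5, f$t1 + 5, by = 0.1))
  expect_lt(abs(f$t1 - g), 0.5)
})

test_that("imperfect inversion worsens the standard fit's underestimation", {
  p <- molli_protocol()
  dev <- vapply(c(1, 0.92, 0.85), function(eta) {
    cv <- simulate_molli(tissue_params(1180, 60), p, eta = eta)
    fit_standard(cv)$t1 / 1180 - 1
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_true(all(dev < 0))
})

test_that("simulation-fit error is continuous in the supplied T2 and alpha", {
  p <- molli_protocol()
  cv <- simulate_molli(tissue_params(1300, 45), p, eta = 0.92)
  t2_grid <- 45 * seq(0.9, 1.1, length.out = 9)
  t1_t2 <- vapply(t2_grid, function(t2)
    fit_simulation(cv, t2, 0.92, 35, p)$t1, numeric(1))
  expect_true(all(abs(diff(t1_t2)) < 15))
  al_grid <- 35 * seq(0.9, 1.1, length.out = 9)
  t1_al <- vapply(al_grid, function(al)
    fit_simulation(cv, 45, 0.92, al, p)$t1, numeric(1))
  expect_true(all(abs(diff(t1_al)) < 40))
})

test_that("deviation sweeps reproduce the qualitative bias structure", {
  p <- molli_protocol()
  # small flip angle with perfect inversion: vanishing readout perturbation
  d_small <- generate_deviation_curves(dataset = NULL, values = 0.5,
                                       varies = "alpha", protocol = p)
  expect_lt(abs(d_small$deviation), 0.02)
  # deviation magnitude grows monotonically with alpha
  d_alpha <- generate_deviation_curves(dataset = 3,
                                       values = seq(5, 75, by = 10),
                                       protocol = p)
  expect_true(all(diff(-d_alpha$deviation) > 0))
  expect_true(all(d_alpha$deviation < 0))
  # dataset 1 structure
  d1 <- generate_deviation_curves(dataset = 1, values = c(400, 1200, 2400),
                                  protocol = p)
  expect_equal(d1$varies, rep("t1", 3))
  expect_equal(d1$t1_true, c(400, 1200, 2400))
})
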