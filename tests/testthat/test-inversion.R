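test_that("lossless adiabatic passage inverts almost completely", {
  eta <- simulate_inversion(hs_pulse(), tissue_params(1e9, 1e9))
  expect_gte(as.numeric(eta), 0.99)
  expect_true(attr(eta, "inverted"))
})

test_that("relaxation during the pulse reduces the efficacy below one", {
  eta <- as.numeric(simulate_inversion(hs_pulse(), tissue_params(1180, 45)))
  expect_lt(eta, 0.98)
  expect_gt(eta, 0.85)
})

test_that("efficacy decreases with shorter T2 at fixed pulse", {
  etas <- vapply(c(200, 80, 45, 25, 12), function(t2)
    as.numeric(simulate_inversion(hs_pulse(), tissue_params(1180, t2))),
    numeric(1))
  expect_true(all(diff(etas) < 0))
})

test_that("halving the integration step changes eta by less than 1e-4", {
  tis <- tissue_params(1180, 45)
  e1 <- as.numeric(simulate_inversion(hs_pulse(dt = 0.005), tis))
  e2 <- as.numeric(simulate_inversion(hs_pulse(dt = 0.0025), tis))
  expect_lt(abs(e1 - e2), 1e-4)
})

test_that("eta is flat across the adiabatic plateau of B1 scales", {
  tis <- tissue_params(1180, 45)
  etas <- vapply(seq(0.8, 1.2, by = 0.1), function(s)
    as.numeric(simulate_inversion(hs_pulse(), tis, b1_scale = s)),
    numeric(1))
  expect_lt(max(etas) - min(etas), 0.02)
})

test_that("too coarse a step and invalid B1 scale are rejected", {
  expect_error(simulate_inversion(hs_pulse(dt = 0.05), tissue_params(1180, 45)),
               "too coarse")
  expect_error(simulate_inversion(hs_pulse(), tissue_params(1180, 45),
                                  b1_scale = 0), "positive")
})

test_that("eta maps reduce to the scalar case for uniform fields", {
  tis <- tissue_params(1180, 45)
  fm <- field_maps(b0 = matrix(0, 6, 6), b1_scale = matrix(1, 6, 6))
  em <- eta_map(hs_pulse(), tis, fm)
  scalar <- as.numeric(simulate_inversion(hs_pulse(), tis))
  expect_true(all(abs(em$values - scalar) < 1e-12))
})

test_that("eta map interpolation stays close to direct simulation", {
  tis <- tissue_params(1180, 45)
  set.seed(5)
  b0 <- matrix(stats::runif(16 * 16, -60, 60), 16)
  b1 <- matrix(stats::runif(16 * 16, 0.85, 1.15), 16)
  fm <- field_maps(b0, b1)
  em_grid <- eta_map(hs_pulse(), tis, fm, use_grid = TRUE)
  sub <- cbind(sample(16, 8), sample(16, 8))
  direct <- mapply(function(i, j)
    as.numeric(simulate_inversion(hs_pulse(), tis, b0[i, j], b1[i, j])),
    sub[, 1], sub[, 2])
  expect_lt(max(abs(em_grid$values[sub] - direct)), 0.002)
})

test_that("masked-out pixels carry no data and are excluded from statistics", {
  tis <- tissue_params(1180, 45)
  mask <- matrix(TRUE, 4, 4); mask[1, ] <- FALSE
  fm <- field_maps(matrix(0, 4, 4), matrix(1, 4, 4), mask)
  em <- eta_map(hs_pulse(), tis, fm)
  expect_true(all(is.na(em$values[1, ])))
  expect_false(anyNA(em$values[2:4, ]))
  m1 <- pm_mean(em)
  em$values[1, ] <- 99
  expect_equal(pm_mean(em), m1)
  expect_error(eta_map(hs_pulse(), tis,
                       field_maps(matrix(0, 2, 2), matrix(1, 2, 2),
                                  matrix(FALSE, 2, 2))),
               "empty mask")
})
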