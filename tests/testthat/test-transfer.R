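test_that("a noiseless off-grid parabola vertex is recovered within 1 mV", {
  v <- seq(-0.5, 1, by = 0.01)
  vertex <- 0.303
  cv <- transfer_curve(v, 5e-6 + 2e-5 * (v - vertex)^2)
  est <- extract_dirac_point(cv)
  expect_equal(est$v_dirac, vertex, tolerance = 1e-3)
  expect_equal(est$method, "parabola")
})

test_that("a symmetric on-grid V shape gives the exact vertex", {
  cv <- generate_transfer_curve(0.30, noise_sd = 0)
  expect_equal(extract_dirac_point(cv)$v_dirac, 0.30, tolerance = 1e-12)
})

test_that("noisy sweeps recover the Dirac point within 5 mV in >= 95/100 seeds", {
  errs <- vapply(1:100, function(s) {
    cv <- generate_transfer_curve(0.285, noise_sd = 0.01 * 5e-6, seed = s)
    extract_dirac_point(cv)$v_dirac - 0.285
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.005), 0.95)
})

test_that("extraction is translation-equivariant and scale-invariant", {
  cv <- generate_transfer_curve(0.27, noise_sd = 0.02 * 5e-6, seed = 5)
  base <- extract_dirac_point(cv)$v_dirac
  delta <- 0.123
  shifted <- transfer_curve(cv$v_gs + delta, cv$i_ds)
  expect_equal(extract_dirac_point(shifted)$v_dirac, base + delta, tolerance = 1e-12)
  scaled <- transfer_curve(cv$v_gs, cv$i_ds * 7.3)
  expect_equal(extract_dirac_point(scaled)$v_dirac, base, tolerance = 1e-12)
})

test_that("edge minima and ties are handled as specified", {
  v <- seq(0, 1, by = 0.05)
  rising <- transfer_curve(v, 1e-6 + 1e-5 * v)
  expect_error(extract_dirac_point(rising), "sweep edge")

  # two equal smoothed minima: smallest voltage wins, tie flagged
  i <- c(5, 4, 3, 2, 3, 4, 5, 4, 3, 2, 3, 4, 5) * 1e-6
  cv <- transfer_curve(seq_along(i) * 0.1, i)
  est <- extract_dirac_point(cv, smooth_window = 1, fit_halfwidth = 0)
  expect_true(est$tie)
  expect_equal(est$v_dirac, 0.4)
})

test_that("shift series reference the baseline and report mean +/- SD in mV", {
  curves <- list(
    generate_transfer_curve(0.30, label = "baseline"),
    generate_transfer_curve(0.30, label = "baseline"),
    generate_transfer_curve(0.28, label = "dosed"),
    generate_transfer_curve(0.28, label = "dosed")
  )
  ss <- shift_series(curves, baseline = "baseline")
  expect_equal(ss$shift_mv[ss$condition == "baseline"], 0)
  # added negative charge n-dopes: constructed -20 mV (leftward) shift
  expect_equal(ss$shift_mv[ss$condition == "dosed"], -20, tolerance = 5)
  expect_lt(ss$shift_mv[ss$condition == "dosed"], 0)
  expect_equal(ss$n, c(2L, 2L))
  expect_error(shift_series(curves, baseline = "missing"), "not present")
})

test_that("pH sensitivity recovers exact and noisy slopes", {
  ph <- c(3, 5, 7, 9, 11)
  exact <- tibble::tibble(condition = ph, shift_mv = 30 * (ph - 7))
  fit <- suppressWarnings(ph_sensitivity(exact))
  expect_equal(fit$slope_mv_per_ph, 30, tolerance = 1e-9)

  reversed <- tibble::tibble(condition = ph, shift_mv = -30 * (ph - 7))
  expect_equal(suppressWarnings(ph_sensitivity(reversed))$slope_mv_per_ph, -30,
    tolerance = 1e-9
  )

  set.seed(2)
  noisy <- tibble::tibble(condition = ph, shift_mv = 22 * (ph - 7) + rnorm(5, 0, 3))
  nf <- ph_sensitivity(noisy)
  expect_lt(abs(nf$slope_mv_per_ph - 22), 2 * nf$se)

  expect_error(ph_sensitivity(tibble::tibble(condition = c(3, 7), shift_mv = c(0, 1))), "3 pH levels")
})

test_that("transfer-curve validation enforces the sweep invariants", {
  expect_error(transfer_curve(1:4, rep(1e-6, 4)), ">= 5 points")
  expect_error(transfer_curve(c(1, 2, 2, 3, 4), rep(1e-6, 5)), "strictly increasing")
  expect_error(transfer_curve(1:5, c(1e-6, -1e-6, 1e-6, 1e-6, 1e-6)), "positive")
})
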