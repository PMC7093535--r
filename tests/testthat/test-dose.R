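test_that("noiseless Sips data are recovered to 1e-6 relative accuracy", {
  truth <- sips_params(
    dv_max = 180, affinity_K = 5e16, heterogeneity_a = 0.8,
    noise_sd = 0, n_replicates = 1
  )
  fit <- fit_sips(generate_dose_response(truth))
  expect_equal(fit$dv_max, 180, tolerance = 1e-6)
  expect_equal(fit$affinity_K, 5e16, tolerance = 1e-6)
  expect_equal(fit$heterogeneity_a, 0.8, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$a_at_bound)
})

test_that("Langmuir data (a = 1) fit with a within 2 SE of 1", {
  dr <- generate_dose_response(sips_params(heterogeneity_a = 1, noise_sd = 2, seed = 31))
  fit <- fit_sips(dr)
  expect_lt(abs(fit$heterogeneity_a - 1), 2 * fit$se_a)
})

test_that("fit_sips is scale-equivariant in concentration", {
  dr <- generate_dose_response(sips_params(noise_sd = 2, seed = 8))
  f1 <- fit_sips(dr)
  s <- 1e3
  scaled <- dose_response(
    dr$concentration * s, dr$shift_mv, dr$replicate_id,
    dr$is_negative_control
  )
  f2 <- fit_sips(scaled)
  expect_equal(f2$affinity_K * s, f1$affinity_K, tolerance = 1e-4)
  expect_equal(f2$dv_max, f1$dv_max, tolerance = 1e-6)
  expect_equal(f2$heterogeneity_a, f1$heterogeneity_a, tolerance = 1e-6)
})

test_that("fit_sips enforces its preconditions and tidies cleanly", {
  thin <- dose_response(c(0, 1e-15, 1e-14), c(0, 10, 20))
  expect_error(fit_sips(thin), ">= 3 distinct")
  fit <- fit_sips(generate_dose_response(sips_params(seed = 2)))
  td <- tidy(fit)
  expect_equal(td$term, c("dv_max", "log10_K", "heterogeneity_a"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_obs, 24)
})

test_that("the LOD rule picks the lowest persistently detected concentration", {
  # negative controls with zero spread: any positive signal at the lowest dose
  zero_nc <- dose_response(
    c(0, 0, 1e-18, 1e-17, 1e-16),
    c(0, 0, 3, 8, 20)
  )
  expect_equal(estimate_lod(zero_nc)$lod_concentration, 1e-18)

  # only >= 20 aM rows clear the 3-sigma control band (the 2 aM reading does not)
  conc <- rep(c(0, 2e-18, 2e-17, 2e-16, 2e-15), each = 3)
  shift <- c(
    rnorm2 <- c(1, -1, 0.5), # controls: mean |shift| ~0.83, sd ~0.29
    c(1.2, 0.8, 1.0), # 2 aM: inside the band
    c(12, 13, 11), # 20 aM on
    c(30, 32, 31),
    c(60, 61, 62)
  )
  lod <- estimate_lod(dose_response(conc, shift))
  expect_equal(lod$lod_concentration, 2e-17)
  expect_false(lod$trace$pass[lod$trace$concentration == 2e-18])
  expect_true(all(lod$trace$pass[lod$trace$concentration >= 2e-17]))

  # nothing clears the band -> absent LOD
  flat <- dose_response(rep(c(0, 1e-18, 1e-17), each = 3),
    c(1, -1, 0.5, 1.1, 0.2, -0.4, 0.9, 0.1, 0.6))
  expect_message(none <- estimate_lod(flat), "LOD absent")
  expect_true(is.na(none$lod_concentration))
})

test_that("a non-persistent spike does not set the LOD", {
  conc <- rep(c(0, 1e-18, 1e-17, 1e-16), each = 3)
  shift <- c(
    c(0.5, -0.5, 0), # controls
    c(40, 41, 39), # isolated spike at the lowest dose
    c(0.6, 0.2, 0.1), # next dose back inside the band
    c(50, 52, 51)
  )
  lod <- estimate_lod(dose_response(conc, shift))
  expect_equal(lod$lod_concentration, 1e-16)
})

test_that("estimate_lod is monotone in k_sigma and validates controls", {
  dr <- generate_dose_response(sips_params(noise_sd = 3, seed = 9))
  lods <- vapply(c(1, 3, 6, 12), function(k) {
    out <- suppressMessages(estimate_lod(dr, k_sigma = k))$lod_concentration
    if (is.na(out)) Inf else out
  }, numeric(1))
  expect_true(all(diff(lods) >= 0))
  no_nc <- dose_response(c(1e-15, 1e-14, 1e-13), c(10, 20, 30))
  expect_error(estimate_lod(no_nc), "negative-control")
})

test_that("molecule counts reproduce the headline conversions and linearity", {
  res <- molecules_from_concentration(c(600e-21, 20e-18), 50e-6)
  expect_equal(res$molecules, c(18, 602))
  expect_equal(res$molecules_approx[2], 600)
  expect_equal(molecules_from_concentration(0, 1e-3)$molecules, 0)
  # exact bilinearity before rounding
  a <- molecules_from_concentration(3e-18, 50e-6)$molecules_exact
  b <- molecules_from_concentration(6e-18, 50e-6)$molecules_exact
  cc <- molecules_from_concentration(3e-18, 100e-6)$molecules_exact
  expect_equal(b, 2 * a)
  expect_equal(cc, 2 * a)
  expect_error(molecules_from_concentration(-1, 1), "concentration")
})
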