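test_that("the 22-base probe sequence yields 22 backbone charge sites of -1 e", {
  dna <- dna_placement() # AACCACACAACCTACTACCTCA
  expect_equal(dna$n_bases, 22L)
  fr <- generate_ion_configuration(
    surface_model("flat", sigma = -0.01), ion_bath(),
    dna = dna_placement(geometry = "flat"), seed = 1
  )
  sites <- fr[fr$species == "DNA_charge", ]
  expect_equal(nrow(sites), 22L)
  expect_equal(unname(attr(fr, "charges")["DNA_charge"]), -1)
})

test_that("dna placements validate sequence and geometry compatibility", {
  expect_error(dna_placement(sequence = ""), "nonempty")
  expect_error(dna_placement(sequence = "ACGU"), "A, C, G, T")
  expect_error(
    generate_ion_configuration(surface_model("flat"), ion_bath(),
      dna = dna_placement(geometry = "concave"), seed = 1
    ),
    "incompatible"
  )
})

test_that("zero-field sampling is uniform in the distance coordinate", {
  s <- surface_model("flat", sigma = 0)
  fr <- generate_ion_configuration(s, ion_bath(),
    box = c(30, 30, 31),
    n_ions_target = 10000L, seed = 11
  )
  ions <- fr[fr$species %in% c("Na+", "Cl-"), ]
  d <- surface_distance(as.matrix(ions[, c("x", "y", "z")]), s)
  # chi-square of a 10-bin histogram over [ion radius, box top] vs uniform
  counts <- table(cut(d, seq(0.15, 31, length.out = 11)))
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.99, df = 9))
})

test_that("charged flat surface reproduces the Gouy-Chapman profile within 3 SE", {
  bath <- fixture_bath()
  s <- surface_model("flat", sigma = -0.05)
  fr <- generate_frames(s, bath, 10, seed = 21)
  prof <- bin_concentration(fr, "Na+", bin_width = 0.2, d_max = 3)
  lam <- debye_length(0.6, 300, 78.5)$debye_length
  psi0 <- -0.05 * lam * 1e-9 / (8.8541878128e-12 * 78.5)
  sel <- prof$d_mid >= 0.2
  expected <- 0.6 * exp(-1.602176634e-19 * psi0 * exp(-prof$d_mid[sel] / lam) /
    (1.380649e-23 * 300))
  expected_counts <- expected * 6.02214076e23 * prof$bin_volume[sel] * 1e-24 * 10
  obs_counts <- prof$count[sel] * 10
  z <- (obs_counts - expected_counts) / sqrt(pmax(expected_counts, 1))
  expect_lt(max(abs(z)), 3)
})

test_that("every generated frame is electroneutral to within 1 e", {
  bath <- ion_bath()
  cases <- list(
    generate_ion_configuration(surface_model("flat", sigma = -0.01), bath, seed = 1),
    generate_ion_configuration(surface_model("sinusoid", sigma = -0.01), bath, seed = 2),
    generate_ion_configuration(surface_model("flat", sigma = -0.01), bath,
      dna = dna_placement(geometry = "flat"), seed = 3
    ),
    generate_ion_configuration(surface_model("trench", sigma = -0.01), bath,
      dna = dna_placement(geometry = "trench_bottom"), seed = 4
    )
  )
  for (fr in cases) expect_lt(abs(frame_charge(fr)), 1)
})

test_that("identical spec and seed give bit-identical frames", {
  args <- list(surface_model("sinusoid", sigma = -0.01), ion_bath(),
    dna = dna_placement(geometry = "concave"), seed = 99
  )
  a <- do.call(generate_ion_configuration, args)
  b <- do.call(generate_ion_configuration, args)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the box capacity guard rejects impossible ion loads", {
  expect_error(
    generate_ion_configuration(surface_model("flat", sigma = 0), ion_bath(0.01),
      box = c(5, 5, 5), n_ions_target = 100000L, seed = 1
    ),
    "too small"
  )
})

test_that("concave valleys deplete near-surface counter-ions relative to crests", {
  s <- surface_model("sinusoid", sigma = -0.01)
  fr <- generate_frames(s, fixture_bath(), 60, seed = 5)
  m <- map_concentration_2d(fr, "Na+", x_width = 0.27, z_width = 0.1, z_max = 3)
  h <- surface_height(m$x_mid, s)
  near <- m$z_mid > h & m$z_mid < h + 0.35 & m$cell_volume > 0
  phase <- sin(2 * pi * m$x_mid / s$wavelength)
  valley <- mean(m$concentration[near & abs(phase + 1) < 0.25], na.rm = TRUE)
  crest <- mean(m$concentration[near & abs(phase - 1) < 0.25], na.rm = TRUE)
  expect_lt(valley, crest)
})

test_that("noiseless transfer curves have their minimum at the requested Dirac point", {
  cv <- generate_transfer_curve(0.30, noise_sd = 0)
  expect_equal(cv$v_gs[which.min(cv$i_ds)], 0.30)
  # Dirac points within the experimentally observed 0-0.5 V window
  cv2 <- generate_transfer_curve(0.25, noise_sd = 0)
  vmin <- cv2$v_gs[which.min(cv2$i_ds)]
  expect_gte(vmin, 0)
  expect_lte(vmin, 0.5)
  expect_error(generate_transfer_curve(0.3, k_h = 0), "slopes")
})

test_that("dose generator honours Sips saturation and half-saturation identities", {
  sp <- sips_params(dv_max = 180, affinity_K = 5e16, heterogeneity_a = 1, noise_sd = 0)
  sat <- sips_curve(1e6 / sp$affinity_K, sp$dv_max, sp$affinity_K, sp$heterogeneity_a)
  expect_equal(sat, 180, tolerance = 1e-3)
  half <- sips_curve(1 / sp$affinity_K, sp$dv_max, sp$affinity_K, sp$heterogeneity_a)
  expect_identical(half, 90)
  dr <- generate_dose_response(sp)
  expect_s3_class(dr, "dose_response")
  expect_equal(sum(dr$is_negative_control), sp$n_replicates)
  # seed determinism
  expect_identical(
    as.data.frame(generate_dose_response(sips_params(seed = 12))),
    as.data.frame(generate_dose_response(sips_params(seed = 12)))
  )
})

test_that("sips parameter validation enforces the stated bounds", {
  expect_error(sips_params(dv_max = 0), "dv_max")
  expect_error(sips_params(heterogeneity_a = 2.5), "heterogeneity_a")
  expect_error(sips_params(noise_sd = -1), "noise_sd")
  expect_error(ion_bath(0), "bulk_concentration")
})
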