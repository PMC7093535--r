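test_that("an empty frame bins to an all-zero profile", {
  fr <- particle_frame(
    tibble::tibble(species = character(), x = numeric(), y = numeric(), z = numeric()),
    box = c(10, 10, 10), surface = surface_model("flat")
  )
  prof <- bin_concentration(fr, "Na+", bin_width = 0.5, d_max = 5)
  expect_true(all(prof$concentration == 0))
  m <- map_concentration_2d(fr, "Na+", x_width = 1, z_width = 1, z_max = 5)
  expect_true(all(m$count == 0))
})

test_that("one ion in a known slab gives the hand-computed molarity", {
  fr <- particle_frame(
    tibble::tibble(species = "Na+", x = 5, y = 5, z = 0.5),
    box = c(10, 10, 10), surface = surface_model("flat")
  )
  prof <- bin_concentration(fr, "Na+", bin_width = 1, d_max = 5)
  # 1 / (N_A * 100 nm^3) = 1 / (6.022e23 * 1e-22 L) ~ 0.0166 mol/L
  expect_equal(prof$concentration[1], 1 / (6.02214076e23 * 1e-22), tolerance = 1e-9)
  expect_true(all(prof$concentration[-1] == 0))
})

test_that("uniform bulk sampling reads back the bulk molarity within 3 SE", {
  s <- surface_model("flat", sigma = 0)
  fr <- generate_ion_configuration(s, ion_bath(0.6),
    box = c(30, 30, 31),
    n_ions_target = 10000L, seed = 13
  )
  prof <- bin_concentration(fr, "Na+", bin_width = 1, d_max = 25)
  se <- sqrt(pmax(prof$count, 1)) / (6.02214076e23 * prof$bin_volume * 1e-24)
  # species split is ~half the ions; compare against half of 0.6 M twice
  expect_true(all(abs(prof$concentration - 0.3) <= 3 * se))
})

test_that("count conservation holds exactly per frame", {
  fr <- fixture_small_flat_frame(400)
  prof <- bin_concentration(fr, "Na+", bin_width = 0.25, d_max = 8)
  n_na <- sum(fr$species == "Na+" & fr$z <= 8)
  expect_equal(sum(prof$count), n_na)
  expect_equal(
    sum(prof$concentration * prof$bin_volume * 1e-24 * 6.02214076e23),
    n_na,
    tolerance = 1e-9
  )
})

test_that("a zero-amplitude sinusoid reproduces flat profiles bin-for-bin", {
  set.seed(31)
  parts <- tibble::tibble(
    species = "Na+", x = runif(300, 0, 10), y = runif(300, 0, 10),
    z = runif(300, 0, 5)
  )
  fr_flat <- particle_frame(parts, c(10, 10, 5), surface_model("flat"))
  fr_sin0 <- particle_frame(parts, c(10, 10, 5), surface_model("sinusoid", amplitude = 0))
  p1 <- bin_concentration(fr_flat, "Na+", bin_width = 0.25, d_max = 4)
  p2 <- bin_concentration(fr_sin0, "Na+", bin_width = 0.25, d_max = 4, n_mc = 1e6)
  expect_identical(p1$count, p2$count)
  # volumes agree to Monte-Carlo accuracy
  expect_equal(p2$bin_volume, p1$bin_volume, tolerance = 5e-3)
})

test_that("2-D maps conserve mass and reject trench geometry", {
  fr <- fixture_small_flat_frame(500)
  m <- map_concentration_2d(fr, "Cl-", x_width = 1, z_width = 1, z_max = 8)
  expect_equal(sum(m$count), sum(fr$species == "Cl-" & fr$z < 8))
  expect_error(
    map_concentration_2d(
      generate_ion_configuration(surface_model("trench", sigma = -0.01),
        ion_bath(),
        seed = 2
      ),
      "Na+"
    ),
    "trench"
  )
})

test_that("uniform ions give a uniform map within 3 SE of bulk", {
  s <- surface_model("flat", sigma = 0)
  fr <- generate_ion_configuration(s, ion_bath(0.6),
    box = c(30, 30, 31),
    n_ions_target = 10000L, seed = 17
  )
  m <- map_concentration_2d(fr, "Na+", x_width = 10, z_width = 8, z_max = 25)
  se <- sqrt(pmax(m$count, 1)) / (6.02214076e23 * m$cell_volume * 1e-24)
  expect_true(all(abs(m$concentration - 0.3) <= 3 * se))
})

test_that("curved-surface bin volumes integrate to the accessible volume", {
  s <- surface_model("sinusoid")
  box <- c(2 * s$wavelength, 12.5, 10)
  edges <- seq(0, 3, by = 0.1)
  vols <- crumplefet:::distance_bin_volumes(s, box, edges, n_mc = 4e5)
  expect_true(all(vols > 0))
  # total volume within 3 nm of the sheet is close to area * 3 for a
  # shallow corrugation (cancellation of crest/valley shell corrections)
  expect_equal(sum(vols), surface_area(s, box) * 1e18 * 3, tolerance = 0.05)
})
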