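test_that("Debye length reproduces closed-form values and scaling identities", {
  phys <- debye_length(0.150, 298.15, 78.5)
  expect_equal(phys$debye_length, 0.785, tolerance = 2e-3)
  expect_lt(phys$debye_length, 1) # sub-nm at physiological ionic strength

  # quadrupling the ionic strength exactly halves lambda_D
  expect_equal(
    debye_length(0.15)$debye_length / debye_length(0.6)$debye_length, 2,
    tolerance = 1e-12
  )
  # the two bath concentrations used in the simulations differ by sqrt(2)
  expect_equal(
    debye_length(0.6, 300)$debye_length / debye_length(1.2, 300)$debye_length,
    sqrt(2),
    tolerance = 1e-12
  )
})

test_that("screening factor is zero for balanced profiles and errors on sigma = 0", {
  conc <- rep(0.6, 40)
  na <- fixture_profile(conc)
  cl <- fixture_profile(conc, species = "Cl-")
  sfr <- screening_factor(na, cl, -0.01)
  expect_true(all(sfr$sf == 0))
  expect_error(screening_factor(na, cl, 0), "sigma = 0")
  bad <- fixture_profile(conc, bin_width = 0.1)
  expect_error(screening_factor(na, bad, -0.01), "identical bin grid")
})

test_that("a step net-charge profile integrates to SF = 1 at the step edge", {
  # [Na+] - [Cl-] = c0 on [0, L], zero after, with |sigma| = F * c0 * L (SI)
  c0 <- 0.5
  L <- 1 # nm
  nb_in <- 20
  conc_na <- c(rep(c0, nb_in), rep(0, 20))
  na <- fixture_profile(conc_na)
  cl <- fixture_profile(rep(0, 40), species = "Cl-")
  sigma <- 96485.33212 * c0 * 1e3 * L * 1e-9
  sfr <- screening_factor(na, cl, sigma)
  expect_equal(sfr$sf[sfr$d == L], 1, tolerance = 1e-12)
  expect_equal(sfr$sf[length(sfr$sf)], 1, tolerance = 1e-12)
})

test_that("linearized Gouy-Chapman profiles give SF(z) = 1 - exp(-z/lambda)", {
  pair <- fixture_gc_pair(sigma = -0.01, bin_width = 0.02, d_max = 6)
  lam <- debye_length(0.6, 300, 78.5)$debye_length
  sfr <- screening_factor(pair$na, pair$cl, -0.01)
  expect_lt(max(abs(sfr$sf - (1 - exp(-sfr$d / lam)))), 1e-3)
  # SF is nondecreasing when [Na+] >= [Cl-] pointwise
  expect_true(all(diff(sfr$sf) >= 0))
})

test_that("screening onset inverts the closed form and handles absence", {
  d <- seq(0, 10, by = 0.01)
  sfr <- fixture_screening(d, 1 - exp(-d / 1))
  expect_equal(screening_onset(sfr, 0.05), -log(0.95), tolerance = 1e-3)
  flatline <- fixture_screening(d, rep(0, length(d)))
  expect_message(onset <- screening_onset(flatline), "no onset")
  expect_true(is.na(onset))
})

test_that("unscreened DNA charge obeys its limiting cases and symbolic integral", {
  bw <- 0.01
  edges <- seq(0, 12, by = bw)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dna <- fixture_profile(exp(-mid / 0.4) * bw, bin_width = bw, species = "DNA_charge")
  total <- sum(dna$count)

  fully <- fixture_screening(edges, rep(1, length(edges)))
  expect_equal(unscreened_dna_charge(dna, fully, 1)$n_unscreened_e, 0)

  none <- fixture_screening(edges, rep(0, length(edges)))
  expect_equal(unscreened_dna_charge(dna, none, 1)$n_unscreened_e, total)

  # exponential DNA layer against SF = 1 - exp(-z/lam): fraction = lam/(lam+mu)
  sfr <- fixture_screening(edges, 1 - exp(-edges / 1))
  nu <- unscreened_dna_charge(dna, sfr, 1)
  expect_equal(nu$fraction, 1 / (1 + 0.4), tolerance = 5e-3)
})

test_that("potential profile obeys the trivial and parallel-plate oracles", {
  h <- 0.005
  zmid <- seq(-0.25 + h / 2, 6, by = h)
  A <- 1e-16

  zero <- tibble::tibble(z_mid = zmid, charge = rep(0, length(zmid)))
  expect_true(all(potential_profile(zero, A)$v == 0))

  # single sheet Q at a bin midpoint: V(z) = -Q (z - a) / (A eps0) beyond it
  q <- numeric(length(zmid))
  a_pos <- zmid[which.min(abs(zmid - 1))]
  q[which.min(abs(zmid - 1))] <- 2e-18
  pot <- suppressWarnings(potential_profile(tibble::tibble(z_mid = zmid, charge = q), A))
  zq <- 4
  v_num <- approx(pot$z, pot$v, zq)$y
  v_exact <- -2e-18 * (zq - a_pos) * 1e-9 / (A * 8.8541878128e-12)
  expect_equal(v_num, v_exact, tolerance = 1e-3)

  expect_error(
    potential_profile(tibble::tibble(z_mid = c(0, 1, 3), charge = c(0, 0, 0)), A),
    "uniform grid"
  )
})

test_that("a net-neutral double layer's potential plateaus beyond the layer", {
  h <- 0.005
  zmid <- seq(-0.25 + h / 2, 8, by = h)
  A <- 1e-16
  lam <- 0.4
  q <- numeric(length(zmid))
  q[which.min(abs(zmid))] <- -1e-18
  ion <- 1e-18 * (exp(-pmax(zmid - h / 2, 0) / lam) - exp(-pmax(zmid + h / 2, 0) / lam)) * (zmid > 0)
  pot <- potential_profile(tibble::tibble(z_mid = zmid, charge = q + ion), A)
  n <- nrow(pot)
  tail_v <- pot$v[seq(floor(0.8 * n), n)]
  expect_lt(max(tail_v) - min(tail_v), 1e-4 * abs(pot$v[1] - mean(tail_v)))
})

test_that("capacitance proxy matches the Gouy-Chapman closed form within 2%", {
  bath <- fixture_bath()
  lam <- debye_length(0.6, 300, 78.5)$debye_length
  sg <- -0.01
  h <- 0.005
  zmid <- seq(-0.25 + h / 2, 6, by = h)
  A <- 1e-16
  q <- numeric(length(zmid))
  q[which.min(abs(zmid))] <- sg * A
  ion <- -sg * A * (exp(-pmax(zmid - h / 2, 0) / lam) - exp(-pmax(zmid + h / 2, 0) / lam)) * (zmid > 0)
  qp <- tibble::tibble(z_mid = zmid, charge = q + ion)
  pot <- potential_profile(qp, A, relative_permittivity = 78.5)
  cap <- capacitance_from_profile(pot, sg)
  c_gc <- 8.8541878128e-12 * 78.5 / (lam * 1e-9)
  expect_equal(cap$c_eff, c_gc, tolerance = 0.02)
  expect_true(cap$plateau_ok)

  # doubling sigma in the linear regime leaves C_eff unchanged
  pot2 <- potential_profile(dplyr::mutate(qp, charge = 2 * charge), A,
    relative_permittivity = 78.5
  )
  cap2 <- capacitance_from_profile(pot2, 2 * sg)
  expect_equal(cap2$c_eff, cap$c_eff, tolerance = 1e-9)
})

test_that("SF at the far boundary equals (|sigma| A + |Q_DNA|) / (|sigma| A)", {
  s <- surface_model("flat", sigma = -0.01)
  bath <- fixture_bath()
  fr <- generate_frames(s, bath, 25, dna = dna_placement(geometry = "flat"), seed = 41)
  na <- bin_concentration(fr, "Na+", bin_width = 0.1, d_max = 10)
  cl <- bin_concentration(fr, "Cl-", bin_width = 0.1, d_max = 10)
  sfr <- screening_factor(na, cl, -0.01)
  area <- surface_area(s, attr(fr[[1]], "box"))
  expected <- (0.01 * area / 1.602176634e-19 + 22) / (0.01 * area / 1.602176634e-19)
  expect_equal(sfr$sf[length(sfr$sf)], expected, tolerance = 0.02)
})
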