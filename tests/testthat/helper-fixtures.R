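# Shared fixtures: everything is built in code at test time.

fixture_bath <- function() ion_bath(0.6, 300, 78.5)

# Analytic linearized Gouy-Chapman Na+/Cl- profile pair on a shared grid.
fixture_gc_pair <- function(sigma = -0.01, bin_width = 0.02, d_max = 6,
                            bath = fixture_bath()) {
  list(
    na = gouy_chapman_profile("Na+", bath, sigma, bin_width, d_max),
    cl = gouy_chapman_profile("Cl-", bath, sigma, bin_width, d_max)
  )
}

# Hand-built concentration profile from per-bin molarities (flat geometry).
fixture_profile <- function(conc, bin_width = 0.05, area_nm2 = 100,
                            species = "Na+") {
  edges <- seq(0, length(conc) * bin_width, by = bin_width)
  vols <- rep(area_nm2 * bin_width, length(conc))
  structure(
    tibble::tibble(
      d_lo = edges[-length(edges)], d_hi = edges[-1],
      d_mid = (edges[-1] + edges[-length(edges)]) / 2,
      count = conc * 6.02214076e23 * vols * 1e-24,
      bin_volume = vols, concentration = conc
    ),
    species = species, frame_count = 1L,
    surface = surface_model("flat"), box = c(10, 10, max(edges)),
    class = c("concentration_profile", class(tibble::tibble()))
  )
}

# Screening result with a prescribed SF(z) on a given edge grid.
fixture_screening <- function(d, sf) {
  structure(
    tibble::tibble(d = d, sf = sf),
    sigma = -0.01,
    class = c("screening_result", class(tibble::tibble()))
  )
}

fixture_small_flat_frame <- function(n = 500, seed = 7) {
  set.seed(seed)
  particle_frame(
    tibble::tibble(
      species = sample(c("Na+", "Cl-"), n, replace = TRUE),
      x = runif(n, 0, 10), y = runif(n, 0, 10), z = runif(n, 0, 8)
    ),
    box = c(10, 10, 8), surface = surface_model("flat")
  )
}
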