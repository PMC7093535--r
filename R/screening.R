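#' Debye screening length of a 1:1 electrolyte
#'
#' `lambda_D = sqrt(eps0 * eps_r * kB * T / (2 * N_A * e^2 * I * 1e3))` with
#' the ionic strength I in mol/L, returned in nm. At physiological ionic
#' strength (150 mM, 298 K, eps_r 78.5) this is about 0.78 nm — the sub-nm
#' screening horizon that limits FET biosensing of adsorbed charge.
#'
#' @param ionic_strength mol/L, > 0.
#' @param temperature K, > 0.
#' @param relative_permittivity Dimensionless, > 0.
#' @return An object of class `debye_params`: the inputs plus `debye_length`
#'   in nm.
#' @examples
#' debye_length(0.15)$debye_length # ~0.78 nm
#' @export
debye_length <- function(ionic_strength, temperature = 298.15,
                         relative_permittivity = 78.5) {
  stopifnot(ionic_strength > 0, temperature > 0, relative_permittivity > 0)
  lam_m <- sqrt(
    .const$eps0 * relative_permittivity * .const$kB * temperature /
      (2 * .const$NA_ * .const$e^2 * ionic_strength * 1e3)
  )
  structure(
    list(
      ionic_strength = ionic_strength, temperature = temperature,
      relative_permittivity = relative_permittivity,
      debye_length = lam_m * 1e9
    ),
    class = "debye_params"
  )
}

#' @export
print.debye_params <- function(x, ...) {
  cat(sprintf(
    "<debye_params> I = %g M, T = %g K, eps_r = %g: lambda_D = %.4f nm\n",
    x$ionic_strength, x$temperature, x$relative_permittivity, x$debye_length
  ))
  invisible(x)
}

check_shared_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
    max(abs(a$d_lo - b$d_lo)) > 1e-9 || max(abs(a$d_hi - b$d_hi)) > 1e-9) {
    stop("Profiles must share an identical bin grid.", call. = FALSE)
  }
}

#' Ionic screening factor SF(z) from ion concentration profiles
#'
#' The cumulative net ionic counter-charge between the surface and distance z,
#' normalized by the surface charge magnitude:
#' `SF(z) = integral_0^z F ([Na+] - [Cl-]) dz' / |sigma|`,
#' with F the Faraday constant and concentrations converted to SI (mol/m^3)
#' before integrating. SF(0) = 0; SF = 1 means the surface charge is fully
#' neutralized by intervening ions. The raw curve is reported unclamped — by
#' construction it exceeds 1 at large z when adsorbed DNA pulls in extra
#' counter-ions.
#'
#' The integral is evaluated per bin (piecewise-constant profiles integrate
#' exactly), giving SF on the bin-edge grid.
#'
#' @param na_profile,cl_profile [bin_concentration()] profiles of Na+ and Cl-
#'   on an identical grid.
#' @param sigma Surface charge density, C/m^2, nonzero.
#' @return A tibble of class `screening_result` with columns `d` (bin edges,
#'   nm) and `sf`.
#' @export
screening_factor <- function(na_profile, cl_profile, sigma) {
  if (!is.finite(sigma) || sigma == 0) {
    stop("sigma = 0 leaves the screening factor undefined.", call. = FALSE)
  }
  check_shared_grid(na_profile, cl_profile)
  net <- (na_profile$concentration - cl_profile$concentration) * 1e3 # mol/m^3
  net[is.na(net)] <- 0 # zero-volume bins hold no ions
  dz_m <- (na_profile$d_hi - na_profile$d_lo) * 1e-9
  sf <- c(0, cumsum(.const$F * net * dz_m)) / abs(sigma)
  structure(
    tibble::tibble(d = c(na_profile$d_lo[1], na_profile$d_hi), sf = sf),
    sigma = sigma,
    class = c("screening_result", class(tibble::tibble()))
  )
}

#' Distance at which ionic screening sets in
#'
#' The smallest distance where SF reaches `threshold`, linearly interpolated
#' between grid points. The onset marks where counter-ions begin to neutralize
#' the surface: it moves outward when ions are excluded from a concave region.
#' Returns `NA` (with a message) if SF never reaches the threshold.
#'
#' @param result A [screening_factor()] result.
#' @param threshold Dimensionless SF level defining "onset" (default 0.05).
#' @return Onset distance in nm, or `NA_real_`.
#' @export
screening_onset <- function(result, threshold = 0.05) {
  sf <- result$sf
  d <- result$d
  idx <- which(sf >= threshold)
  if (!length(idx)) {
    message("SF never reaches ", threshold, "; no onset.")
    return(NA_real_)
  }
  i <- idx[1]
  if (i == 1) {
    return(d[1])
  }
  d[i - 1] + (threshold - sf[i - 1]) / (sf[i] - sf[i - 1]) * (d[i] - d[i - 1])
}

#' Unscreened adsorbed DNA charge
#'
#' Weights the DNA backbone-charge profile by how much of the surface charge
#' is still unneutralized at each distance: each charge site at distance d
#' contributes a fraction `1 - min(SF(d), 1)` of its charge as an effective
#' dopant. SF is clamped to `[0, 1]` only inside this weighting, never in the
#' reported curve. The result is clamped to `[0, total adsorbed DNA charge]`.
#'
#' @param dna_profile [bin_concentration()] profile of the `DNA_charge`
#'   species, on the same grid the screening factor was computed on.
#' @param result A [screening_factor()] result.
#' @param area_A Device/patch area, m^2, used for the per-area view.
#' @return A list of class `unscreened_charge`: `n_unscreened_e` (elementary
#'   charges), `n_total_e`, `per_area_e_m2`, `per_area_C_m2`, `fraction`.
#' @export
unscreened_dna_charge <- function(dna_profile, result, area_A) {
  nb <- nrow(dna_profile)
  if (length(result$sf) != nb + 1L ||
    max(abs(result$d - c(dna_profile$d_lo[1], dna_profile$d_hi))) > 1e-9) {
    stop("DNA profile and screening result are on different grids.", call. = FALSE)
  }
  counts <- dna_profile$count
  sf_mid <- (result$sf[-1] + result$sf[-(nb + 1L)]) / 2
  w <- 1 - pmin(pmax(sf_mid, 0), 1)
  total <- sum(counts)
  n_u <- min(max(sum(counts * w), 0), total)
  structure(
    list(
      n_unscreened_e = n_u, n_total_e = total,
      per_area_e_m2 = n_u / area_A,
      per_area_C_m2 = n_u * .const$e / area_A,
      fraction = if (total > 0) n_u / total else NA_real_
    ),
    class = "unscreened_charge"
  )
}

#' @export
print.unscreened_charge <- function(x, ...) {
  cat(sprintf(
    "<unscreened_charge> %.2f of %.0f e unscreened (%.0f%%), %.3g e/m^2\n",
    x$n_unscreened_e, x$n_total_e, 100 * x$fraction, x$per_area_e_m2
  ))
  invisible(x)
}

#' Electrostatic potential profile from a net charge distribution
#'
#' Integrates the 1-D Poisson equation twice:
#' `V(z) = - int int_{z0}^{z} q(z') / (A eps0 eps_r) dz' dz'`,
#' with `V(z0) = 0` and `dV/dz(z0) = 0` as integration constants, where q is
#' the net charge per slab and A the reference area. `z0` defaults to the
#' start of the grid and should lie below all charge. With explicit solvent
#' particles in q the permittivity is the vacuum one (`relative_permittivity
#' = 1`); for implicit-solvent (Gouy-Chapman) charge profiles pass the
#' solvent's relative permittivity.
#'
#' @param charge_profile A [charge_profile_z()] tibble (uniform grid), or any
#'   data frame with `z_mid` and `charge` (C per slab) columns.
#' @param area_A Reference area, m^2, > 0.
#' @param z0 Reference height, nm (default: grid start).
#' @param relative_permittivity Dielectric constant of the medium (default 1).
#' @return A tibble of class `potential_profile` with columns `z` (slab
#'   edges, nm) and `v` (volts).
#' @export
potential_profile <- function(charge_profile, area_A, z0 = NULL,
                              relative_permittivity = 1) {
  stopifnot(area_A > 0)
  zm <- charge_profile$z_mid
  dz <- diff(zm)
  if (length(dz) < 2 || max(abs(dz - dz[1])) > 1e-9 * abs(dz[1])) {
    stop("Charge profile must be on a uniform grid.", call. = FALSE)
  }
  h_m <- dz[1] * 1e-9
  edges <- c(zm[1] - dz[1] / 2, zm + dz[1] / 2)
  if (!is.null(z0)) {
    keep <- edges >= z0 - 1e-9
    first_edge <- which(keep)[1]
    edges <- edges[keep]
    q <- charge_profile$charge[seq(first_edge, length(zm))]
  } else {
    q <- charge_profile$charge
  }
  # field at edge i from all slabs below it; V by trapezoidal integration of
  # -E, which treats each slab's charge as a sheet at its midpoint (exact for
  # the parallel-plate case)
  e_field <- c(0, cumsum(q)) / (area_A * .const$eps0 * relative_permittivity)
  ne <- length(e_field)
  v <- -cumsum(c(0, (e_field[-ne] + e_field[-1]) / 2)) * h_m
  structure(
    tibble::tibble(z = edges, v = v),
    area_A = area_A, relative_permittivity = relative_permittivity,
    class = c("potential_profile", class(tibble::tibble()))
  )
}

#' Double-layer capacitance proxy from a potential profile
#'
#' `C_eff = |sigma| / |V(surface side) - V(bulk plateau)|`, the bulk plateau
#' being the mean over the last `plateau_frac` of the grid. The profile must
#' come from an overall electroneutral system so the potential actually
#' plateaus; if the field at the far end is still a sizeable fraction of its
#' peak the estimate is flagged (`plateau_ok = FALSE`).
#'
#' A dense, surface-hugging double layer gives a small potential drop and a
#' large capacitance; spreading the same counter-charge farther out (as a
#' corrugated sheet does) lowers it.
#'
#' @param potential A [potential_profile()].
#' @param sigma Surface charge density magnitude reference, C/m^2.
#' @param plateau_frac Fraction of the far grid treated as bulk.
#' @param slope_tol Plateau flag threshold: mean |dV/dz| over the plateau
#'   region relative to max |dV/dz| overall (0.1 tolerates the statistical
#'   ripple of frame-averaged charge profiles while still catching an
#'   uncompensated far field).
#' @return A list of class `capacitance_estimate`: `c_eff` (F/m^2),
#'   `delta_v` (V), `plateau_ok`.
#' @export
capacitance_from_profile <- function(potential, sigma, plateau_frac = 0.1,
                                     slope_tol = 0.1) {
  v <- potential$v
  n <- length(v)
  tail_idx <- seq(max(1, floor(n * (1 - plateau_frac))), n)
  v_bulk <- mean(v[tail_idx])
  delta_v <- v[1] - v_bulk
  slopes <- abs(diff(v))
  plateau_ok <- mean(slopes[(tail_idx[-length(tail_idx)])]) <=
    slope_tol * max(slopes)
  if (!plateau_ok) {
    warning("Potential has not plateaued; capacitance estimate is flagged.",
      call. = FALSE
    )
  }
  structure(
    list(
      c_eff = abs(sigma) / abs(delta_v), delta_v = delta_v,
      plateau_ok = plateau_ok
    ),
    class = "capacitance_estimate"
  )
}

#' @export
print.capacitance_estimate <- function(x, ...) {
  cat(sprintf(
    "<capacitance_estimate> C_eff = %.4g F/m^2 (dV = %.4g V%s)\n",
    x$c_eff, x$delta_v, if (x$plateau_ok) "" else ", no plateau"
  ))
  invisible(x)
}
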