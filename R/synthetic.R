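#' Ion bath specification
#'
#' The electrolyte the model surface is immersed in. Defaults are the
#' molecular-dynamics-like bath used throughout: 0.6 M NaCl at 300 K in
#' implicit water (relative permittivity 78.5).
#'
#' @param bulk_concentration mol/L, > 0.
#' @param temperature K, > 0.
#' @param relative_permittivity Dimensionless, > 1.
#' @return An object of class `ion_bath`.
#' @export
ion_bath <- function(bulk_concentration = 0.6, temperature = 300,
                     relative_permittivity = 78.5) {
  if (bulk_concentration <= 0) stop("bulk_concentration must be > 0.", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0.", call. = FALSE)
  if (relative_permittivity <= 1) stop("relative_permittivity must be > 1.", call. = FALSE)
  structure(
    list(
      bulk_concentration = bulk_concentration,
      temperature = temperature,
      relative_permittivity = relative_permittivity
    ),
    class = "ion_bath"
  )
}

#' DNA placement specification
#'
#' Where and how a single-stranded DNA lies on the model surface. The default
#' sequence is the 22-mer probe used in the adsorption simulations. The
#' backbone charge model is one -1 e point charge per base laid along the
#' geometry path at a fixed rise per base, at a stand-off above the sheet
#' typical of a pi-stacking gap.
#'
#' Geometries: `flat` (line along y on a flat sheet), `concave` (along a
#' sinusoid valley trough), `convex` (along a crest), `across` (transverse to
#' the corrugation), `trench_bottom` (along the bottom of the groove).
#'
#' @param sequence Nucleotide string over A/C/G/T.
#' @param geometry One of `"flat"`, `"concave"`, `"convex"`, `"across"`,
#'   `"trench_bottom"`.
#' @param charges_per_base Charge sites per base (default 1, the nominal
#'   phosphate count).
#' @param rise_per_base nm of path per base (default 0.7, extended ssDNA).
#' @param standoff nm between sheet and charge track (default 0.35).
#' @param exclusion_radius nm within which ions are sterically excluded from
#'   a DNA charge site (default 0.5, the backbone's effective radius).
#' @return An object of class `dna_placement`.
#' @export
dna_placement <- function(sequence = "AACCACACAACCTACTACCTCA",
                          geometry = c("flat", "concave", "convex", "across", "trench_bottom"),
                          charges_per_base = 1L,
                          rise_per_base = 0.7,
                          standoff = 0.35,
                          exclusion_radius = 0.5) {
  geometry <- match.arg(geometry)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0 || grepl("[^ACGT]", sequence)) {
    stop("`sequence` must be a nonempty string over A, C, G, T.", call. = FALSE)
  }
  structure(
    list(
      sequence = sequence, geometry = geometry,
      n_bases = nchar(sequence),
      charges_per_base = as.integer(charges_per_base),
      rise_per_base = rise_per_base, standoff = standoff,
      exclusion_radius = exclusion_radius
    ),
    class = "dna_placement"
  )
}

# Coordinates of the DNA backbone charge sites for a placement on a surface.
# The track follows the stated geometry at `standoff` above the sheet and
# wraps through the periodic y (or x) boundary if longer than the box.
dna_charge_sites <- function(dna, surface, box) {
  ok <- switch(dna$geometry,
    flat = surface$kind == "flat",
    concave = ,
    convex = ,
    across = surface$kind == "sinusoid",
    trench_bottom = surface$kind == "trench"
  )
  if (!ok) {
    stop("DNA geometry '", dna$geometry, "' is incompatible with a '",
      surface$kind, "' surface.",
      call. = FALSE
    )
  }
  n_sites <- dna$n_bases * dna$charges_per_base
  step <- dna$rise_per_base / dna$charges_per_base
  s_along <- (seq_len(n_sites) - 0.5) * step
  L <- surface$wavelength
  A <- surface$amplitude
  switch(dna$geometry,
    flat = cbind(
      x = rep(box[1] / 2, n_sites),
      y = s_along %% box[2],
      z = rep(dna$standoff, n_sites)
    ),
    concave = {
      # trough line: sin = -1 at x = 3L/4 (+ periods); pick the one nearest mid-box
      xv <- L * (3 / 4 + round((box[1] / 2) / L - 3 / 4))
      cbind(x = rep(xv, n_sites), y = s_along %% box[2], z = rep(-A + dna$standoff, n_sites))
    },
    convex = {
      xc <- L * (1 / 4 + round((box[1] / 2) / L - 1 / 4))
      cbind(x = rep(xc, n_sites), y = s_along %% box[2], z = rep(A + dna$standoff, n_sites))
    },
    across = {
      xs <- s_along %% box[1]
      cbind(x = xs, y = rep(box[2] / 2, n_sites), z = surface_height(xs, surface) + dna$standoff)
    },
    trench_bottom = {
      Lt <- min(surface$trench_length, box[2])
      y0 <- (box[2] - Lt) / 2
      cbind(
        x = rep(surface$trench_x0, n_sites),
        y = y0 + (s_along %% Lt),
        z = rep(-surface$trench_radius + dna$standoff, n_sites)
      )
    }
  )
}

# Minimum-image (periodic in x and y) distance from each point to the nearest
# site. `pts` n x 3, `sites` m x 3.
min_dist_to_sites <- function(pts, sites, box) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  for (j in seq_len(nrow(sites))) {
    dx <- abs(pts[, 1] - sites[j, 1])
    dx <- pmin(dx, box[1] - dx)
    dy <- abs(pts[, 2] - sites[j, 2])
    dy <- pmin(dy, box[2] - dy)
    dz <- pts[, 3] - sites[j, 3]
    best <- pmin(best, dx^2 + dy^2 + dz^2)
  }
  sqrt(best)
}

# Boltzmann enhancement factor at surface distance d for an ion of given
# valence sign, using the Debye-Hueckel surface potential of the sheet:
# psi(d) = psi0 * exp(-d / lambda_D), psi0 = sigma * lambda_D / (eps0 * eps_r).
ion_enhancement <- function(d, valence, surface, bath) {
  lam <- debye_length(
    bath$bulk_concentration, bath$temperature,
    bath$relative_permittivity
  )$debye_length
  psi0 <- surface$sigma * (lam * 1e-9) /
    (.const$eps0 * bath$relative_permittivity)
  beta_e <- .const$e / (.const$kB * bath$temperature)
  exp(-valence * beta_e * psi0 * exp(-d / lam))
}

# Fixed quasi-uniform direction set on the unit sphere (Fibonacci lattice),
# used to probe how much of an ion's hydration shell the solid truncates.
.shell_dirs <- local({
  k <- 42L
  i <- seq_len(k) - 0.5
  phi <- acos(1 - 2 * i / k)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
})

# Fraction of a hydration shell of radius r_shell around each point that lies
# inside the solid substrate. Compared against the flat-wall value at the
# same surface distance, this measures concave confinement: in a valley the
# wrapped walls truncate more of the shell than a flat wall would.
shell_solid_fraction <- function(pts, surface, r_shell, z_hi) {
  inside <- numeric(nrow(pts))
  for (k in seq_len(nrow(.shell_dirs))) {
    sp <- pts + matrix(.shell_dirs[k, ] * r_shell,
      nrow(pts), 3,
      byrow = TRUE
    )
    inside <- inside + (fast_surface_distance(sp, surface, z_hi) < 0)
  }
  inside / nrow(.shell_dirs)
}

# Memoised (x mod wavelength, z) lookup of the excess shell truncation
# max(0, frac - frac_flat(d)) for sinusoid surfaces; the quantity is purely
# geometric, so it is tabulated once per surface and bilinearly interpolated.
confinement_excess <- function(pts, surface, r_shell, z_hi) {
  if (surface$kind != "sinusoid") {
    d <- surface_distance(pts, surface)
    frac <- shell_solid_fraction(pts, surface, r_shell, z_hi)
    return(pmax(0, frac - pmax(0, 1 - pmax(d, 0) / r_shell) / 2))
  }
  L <- surface$wavelength
  A <- surface$amplitude
  key <- sprintf("pen_%.8g_%.8g_%.6g_%.6g", L, A, r_shell, z_hi)
  tab <- .dist_cache[[key]]
  if (is.null(tab)) {
    xg <- seq(0, L, length.out = 257L)
    zg <- seq(-A - 0.05, min(z_hi, A + 3 * r_shell) + 0.1, by = 0.02)
    grid <- cbind(rep(xg, times = length(zg)), 0, rep(zg, each = length(xg)))
    d <- fast_surface_distance(grid, surface, z_hi)
    frac <- shell_solid_fraction(grid, surface, r_shell, z_hi)
    exc <- pmax(0, frac - pmax(0, 1 - pmax(d, 0) / r_shell) / 2)
    tab <- list(
      xg = xg, zg = zg,
      v = matrix(exc, nrow = length(xg), ncol = length(zg))
    )
    .dist_cache[[key]] <- tab
  }
  out <- numeric(nrow(pts))
  below <- pts[, 3] < max(tab$zg)
  if (any(below)) {
    xr <- pts[below, 1] %% L
    zz <- pts[below, 3]
    ix <- pmin(pmax(findInterval(xr, tab$xg), 1L), length(tab$xg) - 1L)
    iz <- pmin(pmax(findInterval(zz, tab$zg), 1L), length(tab$zg) - 1L)
    fx <- (xr - tab$xg[ix]) / (tab$xg[ix + 1L] - tab$xg[ix])
    fz <- (zz - tab$zg[iz]) / (tab$zg[iz + 1L] - tab$zg[iz])
    out[below] <- (1 - fx) * (1 - fz) * tab$v[cbind(ix, iz)] +
      fx * (1 - fz) * tab$v[cbind(ix + 1L, iz)] +
      (1 - fx) * fz * tab$v[cbind(ix, iz + 1L)] +
      fx * fz * tab$v[cbind(ix + 1L, iz + 1L)]
  }
  out
}

# Screened (Debye-Hueckel) Coulomb potential of the DNA charge track at the
# given points, periodic in x and y: psi = sum_i q_i e^{-s_i/lam} / (4 pi
# eps0 eps_r s_i), s_i floored at the steric exclusion radius. This is what
# makes counter-ions condense around the backbone wherever they can reach it.
dna_dh_potential <- function(pts, sites, box, bath, site_charge_e = -1,
                             s_floor = 0.1) {
  lam <- debye_length(
    bath$bulk_concentration, bath$temperature,
    bath$relative_permittivity
  )$debye_length
  pref <- site_charge_e * .const$e /
    (4 * pi * .const$eps0 * bath$relative_permittivity) # V m
  psi <- numeric(nrow(pts))
  for (j in seq_len(nrow(sites))) {
    dx <- abs(pts[, 1] - sites[j, 1])
    dx <- pmin(dx, box[1] - dx)
    dy <- abs(pts[, 2] - sites[j, 2])
    dy <- pmin(dy, box[2] - dy)
    s <- pmax(sqrt(dx^2 + dy^2 + (pts[, 3] - sites[j, 3])^2), s_floor)
    psi <- psi + pref * exp(-s / lam) / (s * 1e-9)
  }
  psi
}

#' Generate an ion (and DNA) particle configuration near a model surface
#'
#' Samples Na+ and Cl- positions by rejection from a Boltzmann density
#' `c(r) = c_bulk * exp(-z_i * e * psi(r) / kT)` whose potential is the sum
#' of the sheet's Debye-Hueckel double-layer term,
#' `psi0 * exp(-d/lambda_D)` in the distance-from-surface coordinate d, and
#' the screened Coulomb potential of every DNA backbone charge, so
#' counter-ions condense around the backbone wherever it is reachable. Two
#' steric rules carry the confinement physics: ion centres must be at least
#' `ion_radius` from the sheet and at least the DNA `exclusion_radius` from
#' every backbone site. In a concave valley the wrapped sheet blocks most of
#' the region next to the adsorbed DNA, so its counter-ion cloud is displaced
#' outward; this is what moves the screening onset away from the surface and
#' raises the unscreened DNA charge in concave systems.
#'
#' The Na+/Cl- split is adjusted so that total ion charge + DNA charge +
#' sigma * area vanishes to within one elementary charge. The sheet's own
#' charge is carried by `surface_atom` particles laid out uniformly in arc
#' length, each holding an equal share of `sigma * area`.
#'
#' @param surface A [surface_model()].
#' @param bath An [ion_bath()].
#' @param box Box dimensions (nm). Defaults per geometry to the simulated
#'   system sizes (flat 12.5 x 12.5 x 10; sinusoid two exact periods,
#'   10.82 x 12.5 x 10; trench 10 x 10 x 17).
#' @param n_ions_target Total ion count; default derived from the bath
#'   concentration and accessible volume.
#' @param dna Optional [dna_placement()].
#' @param ion_radius Hard-core exclusion distance from the sheet, nm.
#' @param hydration_shell Radius of the first hydration shell probed for
#'   confinement truncation, nm.
#' @param confinement_kT Free-energy cost, in kT per unit of hydration-shell
#'   fraction truncated beyond the flat-wall baseline, of sitting in a
#'   concave pocket. Set 0 to disable confinement exclusion.
#' @param n_surface_atoms Number of sheet charge carriers.
#' @param seed Integer seed; identical spec + seed gives identical frames.
#' @param .calib Internal: a precomputed calibration (ion counts and
#'   rejection bounds) as attached to generated frames, so frame ensembles
#'   skip the per-frame probe. Leave NULL.
#' @return A [particle_frame()] with attributes `bath`, `ion_radius`, `dna`.
#' @export
generate_ion_configuration <- function(surface, bath, box = NULL,
                                       n_ions_target = NULL, dna = NULL,
                                       ion_radius = 0.15,
                                       hydration_shell = 0.35,
                                       confinement_kT = 20,
                                       n_surface_atoms = 1600L,
                                       seed = 1L, .calib = NULL) {
  if (is.null(box)) {
    box <- switch(surface$kind,
      flat = c(12.5, 12.5, 10),
      sinusoid = c(2 * surface$wavelength, 12.5, 10),
      trench = c(10, 10, 17)
    )
  }
  if (!is.null(seed)) set.seed(seed)
  zr <- surface_z_range(surface, box)
  v_prop_nm3 <- box[1] * box[2] * (zr[2] - zr[1])
  area <- surface_area(surface, box)
  sites <- if (!is.null(dna)) dna_charge_sites(dna, surface, box) else NULL

  beta_e <- .const$e / (.const$kB * bath$temperature)

  # Boltzmann weight and accessibility mask at a set of points
  weigh <- function(pts, valence) {
    d <- fast_surface_distance(pts, surface, zr[2])
    keep <- d >= ion_radius
    f <- ion_enhancement(d, valence, surface, bath)
    if (surface$kind != "flat" && confinement_kT > 0) {
      f <- f * exp(-confinement_kT *
        confinement_excess(pts, surface, hydration_shell, zr[2]))
    }
    if (!is.null(sites)) {
      d_dna <- min_dist_to_sites(pts, sites, box) - dna$exclusion_radius
      keep <- keep & d_dna >= 0
      # interstice rule: a hydrated ion cannot sit in a slit narrower than
      # its hydration diameter, i.e. simultaneously within a hydration
      # radius of the sheet and of the DNA surface. On a flat sheet this
      # blocks a strip under the chain; in a concave groove the wrapped wall
      # turns the whole DNA-occupied valley into such an interstice.
      keep <- keep & !(d < hydration_shell & d_dna < hydration_shell)
      psi_dna <- dna_dh_potential(pts, sites, box, bath,
        s_floor = dna$exclusion_radius
      )
      f <- f * exp(-valence * beta_e * psi_dna)
    }
    list(keep = keep, f = f)
  }

  # upper bound on the Boltzmann weight, for rejection sampling: the surface
  # term peaks at contact; the DNA term is probed on contact spheres around
  # every site (deterministic direction set) and given a safety margin
  f_bound <- function(valence) {
    fb <- max(
      ion_enhancement(ion_radius, valence, surface, bath),
      ion_enhancement(zr[2], valence, surface, bath), 1
    )
    if (!is.null(sites)) {
      th <- seq(0, pi, length.out = 7L)
      ph <- seq(0, 2 * pi, length.out = 9L)[-9L]
      dirs <- unique(rbind(
        cbind(rep(sin(th), each = 8) * cos(ph), rep(sin(th), each = 8) * sin(ph),
          rep(cos(th), each = 8)
        )
      ))
      test <- do.call(rbind, lapply(seq_len(nrow(sites)), function(j) {
        sweep(dirs * dna$exclusion_radius, 2, sites[j, ], `+`)
      }))
      psi <- dna_dh_potential(test, sites, box, bath, s_floor = dna$exclusion_radius)
      fb <- fb * max(exp(-valence * beta_e * psi), 1) * 1.25
    }
    fb
  }

  q_surface_e <- surface$sigma * area / .const$e

  if (is.null(.calib)) {
    # seeded MC estimate of the accessible Boltzmann-weighted volumes
    m0 <- 20000L
    probe <- cbind(
      stats::runif(m0, 0, box[1]), stats::runif(m0, 0, box[2]),
      stats::runif(m0, zr[1], zr[2])
    )
    w_na <- weigh(probe, +1)
    w_cl <- weigh(probe, -1)
    conc_nm3 <- bath$bulk_concentration * .const$NA_ * 1e-24 # particles per nm^3
    n_na_gc <- conc_nm3 * v_prop_nm3 * mean(w_na$f * w_na$keep)
    n_cl_gc <- conc_nm3 * v_prop_nm3 * mean(w_cl$f * w_cl$keep)
    v_acc_nm3 <- v_prop_nm3 * mean(w_na$keep)

    q_dna_e <- if (!is.null(sites)) -nrow(sites) else 0
    q_need <- round(-(q_surface_e + q_dna_e)) # required n_Na - n_Cl

    if (is.null(n_ions_target)) {
      n_na <- max(0L, round((n_na_gc + n_cl_gc + q_need) / 2))
      n_cl <- n_na - q_need
    } else {
      cap <- 3 * exp(abs(log(max(
        ion_enhancement(ion_radius, +1, surface, bath),
        ion_enhancement(ion_radius, -1, surface, bath)
      )))) * conc_nm3 * v_acc_nm3
      if (n_ions_target > cap) {
        stop("Box too small to hold ", n_ions_target, " ions at bulk density.",
          call. = FALSE
        )
      }
      n_na <- max(0L, round((n_ions_target + q_need) / 2))
      n_cl <- n_na - q_need
    }
    if (n_cl < 0) stop("Electroneutrality requires a negative Cl- count; check sigma/box.", call. = FALSE)
    .calib <- list(
      n_na = n_na, n_cl = n_cl,
      f_max_na = f_bound(+1), f_max_cl = f_bound(-1)
    )
  }
  n_na <- .calib$n_na
  n_cl <- .calib$n_cl

  sample_species <- function(n, valence) {
    if (n == 0) {
      return(matrix(numeric(0), ncol = 3))
    }
    f_max <- if (valence > 0) .calib$f_max_na else .calib$f_max_cl
    out <- matrix(NA_real_, nrow = n, ncol = 3)
    got <- 0L
    guard <- 0L
    acc_rate <- 0.25
    while (got < n) {
      guard <- guard + 1L
      if (guard > 1000L) stop("Rejection sampling failed to converge.", call. = FALSE)
      m <- min(200000L, max(1000L, ceiling((n - got) / acc_rate * 1.3)))
      pts <- cbind(
        stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
        stats::runif(m, zr[1], zr[2])
      )
      w <- weigh(pts, valence)
      u <- stats::runif(m)
      keep <- w$keep & u < w$f / f_max
      pts <- pts[keep, , drop = FALSE]
      acc_rate <- max((nrow(pts) + 1) / (m + 4), 0.005)
      take <- min(nrow(pts), n - got)
      if (take > 0) {
        out[(got + 1):(got + take), ] <- pts[seq_len(take), , drop = FALSE]
        got <- got + take
      }
    }
    out
  }

  na_pos <- sample_species(n_na, +1)
  cl_pos <- sample_species(n_cl, -1)
  surf_pos <- surface_atom_positions(surface, box, n_surface_atoms)

  parts <- tibble::tibble(
    species = c(
      rep("Na+", n_na), rep("Cl-", n_cl),
      rep("DNA_charge", if (is.null(sites)) 0 else nrow(sites)),
      rep("surface_atom", nrow(surf_pos))
    ),
    x = c(na_pos[, 1], cl_pos[, 1], if (!is.null(sites)) sites[, 1], surf_pos[, 1]),
    y = c(na_pos[, 2], cl_pos[, 2], if (!is.null(sites)) sites[, 2], surf_pos[, 2]),
    z = c(na_pos[, 3], cl_pos[, 3], if (!is.null(sites)) sites[, 3], surf_pos[, 3])
  )
  charges <- default_species_charges()
  charges["surface_atom"] <- q_surface_e / nrow(surf_pos)
  frame <- particle_frame(parts, box = box, surface = surface, charges = charges)
  attr(frame, "bath") <- bath
  attr(frame, "ion_radius") <- ion_radius
  attr(frame, "dna") <- dna
  attr(frame, "calib") <- .calib
  frame
}

#' Generate an ensemble of independent frames of one system
#'
#' Seeds the stream once and draws `n_frames` independent configurations of
#' the same surface/bath/DNA system, for frame-averaged profiles (the
#' synthetic stand-in for time-averaging a production trajectory).
#'
#' @param surface,bath,box,dna,ion_radius,hydration_shell,confinement_kT,n_surface_atoms
#'   As in [generate_ion_configuration()].
#' @param n_frames Number of frames.
#' @param seed Integer seed for the whole ensemble.
#' @return A list of [particle_frame()]s.
#' @export
generate_frames <- function(surface, bath, n_frames, box = NULL, dna = NULL,
                            ion_radius = 0.15, hydration_shell = 0.35,
                            confinement_kT = 20, n_surface_atoms = 1600L,
                            seed = 1L) {
  set.seed(seed)
  calib <- NULL
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    out[[i]] <- generate_ion_configuration(surface, bath,
      box = box, dna = dna,
      ion_radius = ion_radius, hydration_shell = hydration_shell,
      confinement_kT = confinement_kT,
      n_surface_atoms = n_surface_atoms, seed = NULL, .calib = calib
    )
    if (is.null(calib)) calib <- attr(out[[i]], "calib")
  }
  out
}

# Sheet charge carriers laid out uniformly in arc length along x, uniform in y.
surface_atom_positions <- function(surface, box, n_atoms) {
  nx <- max(4L, round(sqrt(n_atoms)))
  ny <- max(4L, round(n_atoms / nx))
  if (surface$kind == "sinusoid") {
    xg <- seq(0, box[1], length.out = 4001L)
    sp <- 2 * pi * surface$amplitude / surface$wavelength *
      cos(2 * pi * xg / surface$wavelength)
    arc <- cumsum(c(0, diff(xg) * sqrt(1 + sp[-1]^2)))
    targets <- (seq_len(nx) - 0.5) / nx * arc[length(arc)]
    xs <- stats::approx(arc, xg, xout = targets)$y
  } else {
    xs <- (seq_len(nx) - 0.5) / nx * box[1]
  }
  ys <- (seq_len(ny) - 0.5) / ny * box[2]
  g <- expand.grid(x = xs, y = ys)
  cbind(x = g$x, y = g$y, z = surface_height(g$x, surface))
}

#' Generate an ambipolar transfer curve with a controllable Dirac point
#'
#' A piecewise power-law V shape,
#' `I(V) = i_min + k_h * max(V_D - V, 0)^p + k_e * max(V - V_D, 0)^p`,
#' plus optional Gaussian current noise. With `noise_sd = 0` the minimum sits
#' exactly at `dirac_v`. The default grid is the measurement sweep, -0.5 to
#' 1 V; default currents are microamp-scale, matching a ~10 kOhm channel at
#' 50 mV drain bias.
#'
#' @param dirac_v Dirac point, V.
#' @param v_grid Gate-voltage grid, V, strictly increasing.
#' @param i_min Minimum (Dirac) current, A.
#' @param k_h,k_e Hole/electron branch coefficients, A/V^p, > 0.
#' @param p Branch exponent (1 gives a V shape).
#' @param noise_sd Gaussian current noise SD, A.
#' @param seed Optional integer seed.
#' @param label Condition label.
#' @return A [transfer_curve()].
#' @export
generate_transfer_curve <- function(dirac_v,
                                    v_grid = seq(-0.5, 1, by = 0.01),
                                    i_min = 5e-6, k_h = 2e-5, k_e = 2e-5,
                                    p = 1, noise_sd = 0, seed = NULL,
                                    label = "") {
  if (k_h <= 0 || k_e <= 0) stop("Branch slopes k_h, k_e must be > 0.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  i <- i_min + k_h * pmax(dirac_v - v_grid, 0)^p + k_e * pmax(v_grid - dirac_v, 0)^p
  if (noise_sd > 0) i <- i + stats::rnorm(length(i), 0, noise_sd)
  i <- pmax(i, i_min * 1e-3) # keep currents physical under heavy noise
  transfer_curve(v_grid, i, label = label)
}

#' Sips dose-response parameters
#'
#' Parameters of the Sips (Langmuir-Freundlich) isotherm used by the
#' dose-response generator and recovered by [fit_sips()]. Defaults describe a
#' crumpled-device calibration: 180 mV saturation shift, half-saturation at
#' 20 aM (K = 5e16 L/mol), Langmuir-like heterogeneity, 3 mV replicate noise.
#'
#' @param dv_max Saturation shift, mV, > 0.
#' @param affinity_K Affinity constant, L/mol, > 0.
#' @param heterogeneity_a Heterogeneity exponent, in (0, 2].
#' @param noise_sd Gaussian shift noise SD, mV, >= 0.
#' @param n_replicates Replicates per concentration (and negative controls).
#' @param seed Integer seed.
#' @return An object of class `sips_params`.
#' @export
sips_params <- function(dv_max = 180, affinity_K = 5e16, heterogeneity_a = 1,
                        noise_sd = 3, n_replicates = 3L, seed = 1L) {
  if (dv_max <= 0) stop("dv_max must be > 0.", call. = FALSE)
  if (affinity_K <= 0) stop("affinity_K must be > 0.", call. = FALSE)
  if (heterogeneity_a <= 0 || heterogeneity_a > 2) {
    stop("heterogeneity_a must lie in (0, 2].", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0.", call. = FALSE)
  structure(
    list(
      dv_max = dv_max, affinity_K = affinity_K,
      heterogeneity_a = heterogeneity_a, noise_sd = noise_sd,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed)
    ),
    class = "sips_params"
  )
}

#' Evaluate the Sips isotherm
#'
#' `shift(C) = dv_max * (K C)^a / (1 + (K C)^a)`, in mV.
#'
#' @param concentration mol/L.
#' @param dv_max,affinity_K,heterogeneity_a Isotherm parameters.
#' @return Shifts, mV.
#' @export
sips_curve <- function(concentration, dv_max, affinity_K, heterogeneity_a) {
  kc <- (affinity_K * concentration)^heterogeneity_a
  dv_max * kc / (1 + kc)
}

#' Generate a Sips-shaped dose-response table with negative controls
#'
#' Replicated |Dirac shift| readings at each requested concentration plus
#' `n_replicates` negative-control rows at zero concentration, all with
#' Gaussian noise of SD `noise_sd`. Reproducible under a fixed seed. The
#' default concentration ladder spans 2 aM to 2 pM in decade steps, the range
#' probed in the hybridization experiments.
#'
#' @param sips A [sips_params()].
#' @param concentrations Positive concentrations, mol/L.
#' @return A [dose_response()].
#' @export
generate_dose_response <- function(sips,
                                   concentrations = 2 * 10^seq(-18, -11)) {
  if (any(concentrations <= 0)) {
    stop("`concentrations` must be positive; controls are added automatically.",
      call. = FALSE
    )
  }
  set.seed(sips$seed)
  conc <- c(rep(0, sips$n_replicates), rep(concentrations, each = sips$n_replicates))
  rep_id <- c(seq_len(sips$n_replicates), rep(seq_len(sips$n_replicates), length(concentrations)))
  mu <- sips_curve(conc, sips$dv_max, sips$affinity_K, sips$heterogeneity_a)
  shift <- mu + if (sips$noise_sd > 0) stats::rnorm(length(mu), 0, sips$noise_sd) else 0
  dose_response(conc, shift, replicate_id = rep_id)
}
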