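# Run code with the global RNG stream untouched (profile bin volumes use a
# fixed internal Monte-Carlo seed and must not perturb a caller's seed).
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "particle_frame")) list(frames) else frames
}

# Shell volumes (nm^3) of distance bins for a surface/box, exact for flat,
# 2-D Monte Carlo (x, z) times Ly for curved sheets.
distance_bin_volumes <- function(surface, box, edges, n_mc = 1e6, mc_seed = 20200324) {
  nb <- length(edges) - 1L
  if (surface$kind == "flat") {
    return(rep(box[1] * box[2], nb) * diff(edges))
  }
  key <- sprintf(
    "vol_%s_%.6g_%.6g_%.6g_%.6g_%.6g_%.6g_%.6g_%d_%.6g",
    surface$kind, surface$wavelength, surface$amplitude, surface$trench_radius,
    box[1], box[2], box[3], max(edges), nb, n_mc
  )
  cached <- .dist_cache[[key]]
  if (!is.null(cached)) {
    return(cached)
  }
  zr <- surface_z_range(surface, box)
  z_hi <- min(box[3], max(edges) + max(0, surface_height(seq(0, box[1], length.out = 401L), surface)))
  with_fixed_seed(mc_seed, {
    xs <- stats::runif(n_mc, 0, box[1])
    zs <- stats::runif(n_mc, zr[1], z_hi)
    d <- fast_surface_distance(cbind(xs, 0, zs), surface, z_hi)
    rect <- box[1] * (z_hi - zr[1])
    keep <- d >= 0 & d <= max(edges)
    counts <- tabulate(
      findInterval(d[keep], edges, rightmost.closed = TRUE, all.inside = TRUE),
      nbins = nb
    )
    vols <- counts / n_mc * rect * box[2]
    .dist_cache[[key]] <- vols
    vols
  })
}

#' Bin a particle frame into a molar concentration profile
#'
#' Histograms a species in the distance-from-surface coordinate and converts
#' counts to molarity, `c_b = count_b / (N_A * V_b)`, where the bin "shell"
#' volume `V_b` is exact for a flat sheet and Monte-Carlo estimated (fixed
#' internal seed, so profiles are deterministic) for curved sheets. A list of
#' frames is averaged; an empty frame gives an all-zero profile. Bins with no
#' accessible volume are flagged with `NA` concentration.
#'
#' Defaults resolve the sub-nanometre double layer: 0.05 nm bins to 5 nm.
#'
#' @param frames A [particle_frame()] or list of frames sharing a geometry.
#' @param species Species label to profile (e.g. `"Na+"`, `"DNA_charge"`).
#' @param bin_width Bin width, nm, > 0.
#' @param d_max Largest distance binned, nm.
#' @param n_mc Monte-Carlo points for curved-bin volumes.
#' @return A tibble of class `concentration_profile` with columns `d_lo`,
#'   `d_hi`, `d_mid`, `count` (mean particles per frame), `bin_volume`
#'   (nm^3) and `concentration` (mol/L), plus attributes `species`,
#'   `frame_count`, `surface`, `box`.
#' @examples
#' fr <- generate_ion_configuration(surface_model("flat"), ion_bath(), seed = 1)
#' prof <- bin_concentration(fr, "Na+")
#' @export
bin_concentration <- function(frames, species, bin_width = 0.05, d_max = 5,
                              n_mc = 1e6) {
  if (bin_width <= 0) stop("bin_width must be > 0.", call. = FALSE)
  frames <- as_frame_list(frames)
  surface <- attr(frames[[1]], "surface")
  box <- attr(frames[[1]], "box")
  edges <- seq(0, d_max, by = bin_width)
  if (max(edges) < d_max) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L

  counts <- rep(0, nb)
  for (fr in frames) {
    sel <- fr$species == species
    if (any(sel)) {
      d <- fast_surface_distance(
        as.matrix(fr[sel, c("x", "y", "z")]), surface, max(edges) + 1
      )
      d <- d[d >= 0 & d <= max(edges)]
      if (length(d)) {
        counts <- counts + tabulate(
          findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE),
          nbins = nb
        )
      }
    }
  }
  counts <- counts / length(frames)
  vols <- distance_bin_volumes(surface, box, edges, n_mc = n_mc)
  conc <- ifelse(vols > 0, counts / (.const$NA_ * vols * 1e-24), NA_real_)

  structure(
    tibble::tibble(
      d_lo = edges[-length(edges)], d_hi = edges[-1],
      d_mid = (edges[-1] + edges[-length(edges)]) / 2,
      count = counts, bin_volume = vols, concentration = conc
    ),
    species = species, frame_count = length(frames),
    surface = surface, box = box,
    class = c("concentration_profile", class(tibble::tibble()))
  )
}

#' Build an analytic Gouy-Chapman concentration profile
#'
#' The closed-form double-layer profile the generator samples from, evaluated
#' on a bin grid and wrapped as a [bin_concentration()]-compatible object.
#' With `linearize = TRUE` the Boltzmann factor is linearized
#' (`c (1 -/+ e psi / kT)`), for which the net counter-charge integrates
#' exactly to `-sigma` and the screening factor is `1 - exp(-z/lambda_D)`.
#'
#' @param species `"Na+"` or `"Cl-"`.
#' @param bath An [ion_bath()].
#' @param sigma Surface charge density, C/m^2.
#' @param bin_width,d_max Grid spec, nm.
#' @param area_nm2 Nominal sheet area used for bin volumes, nm^2.
#' @param linearize Linearize the Boltzmann factor?
#' @return A `concentration_profile`.
#' @export
gouy_chapman_profile <- function(species = c("Na+", "Cl-"), bath = ion_bath(),
                                 sigma = -0.01, bin_width = 0.05, d_max = 5,
                                 area_nm2 = 100, linearize = TRUE) {
  species <- match.arg(species)
  valence <- if (species == "Na+") 1 else -1
  lam <- debye_length(
    bath$bulk_concentration, bath$temperature,
    bath$relative_permittivity
  )$debye_length
  psi0 <- sigma * (lam * 1e-9) / (.const$eps0 * bath$relative_permittivity)
  beta_e <- .const$e / (.const$kB * bath$temperature)
  edges <- seq(0, d_max, by = bin_width)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  arg <- -valence * beta_e * psi0 * exp(-mid / lam)
  conc <- bath$bulk_concentration * if (linearize) 1 + arg else exp(arg)
  vols <- rep(area_nm2 * bin_width, length(mid))
  structure(
    tibble::tibble(
      d_lo = edges[-length(edges)], d_hi = edges[-1], d_mid = mid,
      count = conc * .const$NA_ * vols * 1e-24, bin_volume = vols,
      concentration = conc
    ),
    species = species, frame_count = 1L,
    surface = surface_model("flat", sigma = sigma), box = c(sqrt(area_nm2), sqrt(area_nm2), d_max),
    class = c("concentration_profile", class(tibble::tibble()))
  )
}

#' Bin a frame into a 2-D (x, z) molar concentration map
#'
#' Cell molarity with y-averaging, for flat and sinusoid sheets (the map of a
#' trench groove is not supported). Cell volumes exclude the solid substrate
#' below the sheet; counts are conserved: summed cell counts equal the number
#' of species particles inside the mapped window.
#'
#' @param frames A [particle_frame()] or list of frames.
#' @param species Species label.
#' @param x_width,z_width Cell sizes, nm.
#' @param z_max Top of the mapped window, nm (default 5).
#' @return A tibble of class `concentration_map` with columns `x_mid`,
#'   `z_mid`, `count`, `cell_volume` (nm^3), `concentration` (mol/L).
#' @export
map_concentration_2d <- function(frames, species, x_width = 0.25, z_width = 0.1,
                                 z_max = 5) {
  frames <- as_frame_list(frames)
  surface <- attr(frames[[1]], "surface")
  box <- attr(frames[[1]], "box")
  if (surface$kind == "trench") {
    stop("2-D maps are not supported for trench surfaces.", call. = FALSE)
  }
  zr <- surface_z_range(surface, box)
  x_edges <- seq(0, box[1], by = x_width)
  if (max(x_edges) < box[1]) x_edges <- c(x_edges, box[1])
  z_edges <- seq(zr[1], z_max, by = z_width)
  if (max(z_edges) < z_max) z_edges <- c(z_edges, z_max)
  nx <- length(x_edges) - 1L
  nz <- length(z_edges) - 1L

  counts <- matrix(0, nx, nz)
  for (fr in frames) {
    sel <- fr$species == species & fr$z < max(z_edges)
    if (any(sel)) {
      ix <- findInterval(fr$x[sel], x_edges, rightmost.closed = TRUE, all.inside = TRUE)
      iz <- findInterval(fr$z[sel], z_edges, rightmost.closed = TRUE, all.inside = TRUE)
      for (k in seq_along(ix)) counts[ix[k], iz[k]] <- counts[ix[k], iz[k]] + 1
    }
  }
  counts <- counts / length(frames)

  # accessible (above-sheet) fraction of each cell, by fine-x quadrature
  vol <- matrix(0, nx, nz)
  for (i in seq_len(nx)) {
    xs <- seq(x_edges[i], x_edges[i + 1], length.out = 21L)
    h <- surface_height(xs, surface)
    for (j in seq_len(nz)) {
      frac <- mean(pmin(pmax((z_edges[j + 1] - pmax(h, z_edges[j])) /
        (z_edges[j + 1] - z_edges[j]), 0), 1))
      vol[i, j] <- frac * (x_edges[i + 1] - x_edges[i]) *
        (z_edges[j + 1] - z_edges[j]) * box[2]
    }
  }

  grid <- expand.grid(ix = seq_len(nx), iz = seq_len(nz))
  structure(
    tibble::tibble(
      x_mid = (x_edges[grid$ix] + x_edges[grid$ix + 1]) / 2,
      z_mid = (z_edges[grid$iz] + z_edges[grid$iz + 1]) / 2,
      count = counts[cbind(grid$ix, grid$iz)],
      cell_volume = vol[cbind(grid$ix, grid$iz)],
      concentration = ifelse(vol[cbind(grid$ix, grid$iz)] > 0,
        counts[cbind(grid$ix, grid$iz)] /
          (.const$NA_ * vol[cbind(grid$ix, grid$iz)] * 1e-24),
        NA_real_
      )
    ),
    species = species, frame_count = length(frames),
    surface = surface, box = box,
    class = c("concentration_map", class(tibble::tibble()))
  )
}

#' Cartesian-z net charge profile of a frame
#'
#' Histograms the total charge of all particles (ions, DNA sites and the
#' sheet's own charge carriers) in slabs of the laboratory z coordinate. This
#' is the `q(z)` that feeds [potential_profile()]: the double-layer potential
#' and the capacitance proxy are one-dimensional in z, so the spread of a
#' corrugated sheet's charge across z is what loosens its double layer.
#'
#' @param frames A [particle_frame()] or list of frames.
#' @param bin_width Slab thickness, nm.
#' @param z_range Length-2 numeric; defaults to the full solution domain.
#' @return A tibble of class `charge_profile` with columns `z_lo`, `z_hi`,
#'   `z_mid`, `charge` (Coulomb per slab, frame-averaged).
#' @export
charge_profile_z <- function(frames, bin_width = 0.05, z_range = NULL) {
  frames <- as_frame_list(frames)
  surface <- attr(frames[[1]], "surface")
  box <- attr(frames[[1]], "box")
  charges <- attr(frames[[1]], "charges")
  if (is.null(z_range)) z_range <- surface_z_range(surface, box)
  edges <- seq(z_range[1], z_range[2], by = bin_width)
  if (max(edges) < z_range[2]) edges <- c(edges, max(edges) + bin_width)
  nb <- length(edges) - 1L
  q <- rep(0, nb)
  for (fr in frames) {
    sel <- fr$z >= edges[1] & fr$z <= edges[length(edges)]
    iz <- findInterval(fr$z[sel], edges, rightmost.closed = TRUE, all.inside = TRUE)
    qi <- charges[fr$species[sel]] * .const$e
    q <- q + as.numeric(tapply(qi, factor(iz, levels = seq_len(nb)), sum, default = 0))
  }
  structure(
    tibble::tibble(
      z_lo = edges[-length(edges)], z_hi = edges[-1],
      z_mid = (edges[-1] + edges[-length(edges)]) / 2,
      charge = q / length(frames)
    ),
    surface = surface, box = box, frame_count = length(frames),
    class = c("charge_profile", class(tibble::tibble()))
  )
}
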