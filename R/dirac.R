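#' Dirac-point shift from a carrier density change
#'
#' The electrolyte gate holds the channel at fixed potential, so an induced
#' carrier density change `delta_n` moves the Dirac point by
#' `dV_D = e * delta_n / C_T`, with `C_T` the total gate capacitance per
#' area. Exactly linear and unit-consistent:
#' `e [C] * delta_n [1/m^2] / C_T [F/m^2] = V`.
#'
#' @param delta_n Carrier density change, 1/m^2 (signed).
#' @param c_total Total gate capacitance, F/m^2, > 0.
#' @return Shift in volts.
#' @examples
#' dirac_shift_from_charge(6.25e15, 1e-2) # ~0.1 V
#' @export
dirac_shift_from_charge <- function(delta_n, c_total) {
  if (any(c_total <= 0)) stop("c_total must be > 0.", call. = FALSE)
  .const$e * delta_n / c_total
}

#' Carrier density induced by unscreened DNA charge
#'
#' The induced carrier density is taken directly proportional to the
#' unscreened adsorbed DNA charge density, `delta_n = alpha * N_unscreened`,
#' with a dimensionless coupling `alpha` in (0, 1] (1 = every unscreened
#' charge gates one carrier).
#'
#' @param n_dna_unscreened Unscreened DNA charge density, e/m^2 (or an
#'   [unscreened_dna_charge()] result, whose per-area field is used).
#' @param coupling_alpha Coupling efficiency in (0, 1].
#' @return Carrier density change, 1/m^2.
#' @export
delta_n_from_unscreened <- function(n_dna_unscreened, coupling_alpha = 1) {
  if (coupling_alpha <= 0 || coupling_alpha > 1) {
    stop("coupling_alpha must lie in (0, 1].", call. = FALSE)
  }
  if (inherits(n_dna_unscreened, "unscreened_charge")) {
    n_dna_unscreened <- n_dna_unscreened$per_area_e_m2
  }
  coupling_alpha * n_dna_unscreened
}

#' Mobility ratio implied by a bandgap change
#'
#' Carrier mobility in gapped graphene falls with the gap as
#' `mu ~ Eg^(-3/2)`; the ratio of mobilities between two gap values is
#' `(eg_to / eg_from)^(-3/2)`. Strictly decreasing in `eg_to` and
#' multiplicative along a chain of gaps. The gapless limit is a domain error:
#' use the mixture model's background term for pristine graphene.
#'
#' @param eg_from,eg_to Bandgaps, eV, > 0.
#' @return Dimensionless mobility factor mu(eg_to)/mu(eg_from).
#' @examples
#' mobility_ratio(0.4224, 1.7641) # ~0.117
#' @export
mobility_ratio <- function(eg_from, eg_to) {
  if (any(eg_from <= 0) || any(eg_to <= 0)) {
    stop("Zero or negative gap: mobility_ratio is undefined in the gapless ",
      "limit; model pristine graphene with the mixture's background term.",
      call. = FALSE
    )
  }
  (eg_to / eg_from)^(-3 / 2)
}

#' Bandgap mixture describing hot-spot and background channel regions
#'
#' A two-phase picture of a deformed channel: a fraction `f` of the area
#' ("hot spots", sharply bent regions with adsorbed nucleobases) has gap
#' `eg_hotspot`; the rest has `eg_background`. The defaults are the computed
#' gaps for crumpled graphene without DNA (0.4224 eV) and with an adenine
#' base (1.7641 eV).
#'
#' @param eg_background,eg_hotspot Gaps, eV, >= 0.
#' @param area_fraction_f Hot-spot area fraction in `[0, 1]` (may be left 0
#'   and solved for with [hotspot_area_fraction()]).
#' @return An object of class `bandgap_mixture` (mobility exponent fixed at
#'   -3/2).
#' @export
bandgap_mixture <- function(eg_background = 0.4224, eg_hotspot = 1.7641,
                            area_fraction_f = 0) {
  if (eg_background < 0 || eg_hotspot < 0) stop("Gaps must be >= 0.", call. = FALSE)
  if (area_fraction_f < 0 || area_fraction_f > 1) {
    stop("area_fraction_f must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(
      eg_background = eg_background, eg_hotspot = eg_hotspot,
      area_fraction_f = area_fraction_f, mobility_exponent = -3 / 2
    ),
    class = "bandgap_mixture"
  )
}

#' Dirac shift predicted by the hot-spot mixture model (reconstruction)
#'
#' The model is a declared reconstruction, version `"hotspot-mixture-1"`:
#' the measured shift is the area-weighted hot-spot contribution
#' `dV(f) = f * (e * n_hotspot / C_T) * (eg_hotspot / eg_background)^(3/2)`.
#' Ingredients: (i) the linear Dirac-shift relation `dV = e dn / C_T`;
#' (ii) `mu ~ Eg^(-3/2)` with carrier response taken inversely proportional
#' to mobility, so a gap opening from background to hot-spot value amplifies
#' the per-charge response by `1 / mobility_ratio`; (iii) a per-area induced
#' carrier density `n_hotspot` inside hot spots. The inverse n-mu relation is
#' an assumption of the reconstruction, stated rather than derived.
#'
#' @param f Hot-spot area fraction(s), in `[0, 1]`.
#' @param mixture A [bandgap_mixture()].
#' @param model_params List: `c_total` (F/m^2) and `n_hotspot` (1/m^2, the
#'   carrier density DNA induces inside a hot spot).
#' @return Predicted shift, V.
#' @export
hotspot_shift <- function(f, mixture,
                          model_params = list(c_total = 1e-2, n_hotspot = 1e16)) {
  amp <- 1 / mobility_ratio(mixture$eg_background, mixture$eg_hotspot)
  f * dirac_shift_from_charge(model_params$n_hotspot, model_params$c_total) * amp
}

#' Minimal hot-spot area fraction reproducing a target Dirac shift
#'
#' Inverts the (monotone) [hotspot_shift()] model by bisection on `f` in
#' `[0, 1]` to a relative tolerance of 1e-6. All model assumptions are echoed
#' into the result. If even `f = 1` cannot reach the target the binding
#' parameters are reported in the error.
#'
#' @param target_shift Target shift magnitude, V, >= 0.
#' @param mixture A [bandgap_mixture()].
#' @param model_params See [hotspot_shift()].
#' @return A list of class `hotspot_solution`: `f`, `target_shift`,
#'   `model = "hotspot-mixture-1"`, `mixture`, `model_params`.
#' @export
hotspot_area_fraction <- function(target_shift, mixture,
                                  model_params = list(c_total = 1e-2, n_hotspot = 1e16)) {
  if (target_shift < 0) stop("target_shift must be >= 0.", call. = FALSE)
  shift_at <- function(f) hotspot_shift(f, mixture, model_params)
  if (target_shift == 0) {
    f <- 0
  } else {
    if (shift_at(1) < target_shift) {
      stop(sprintf(
        paste0(
          "Target %.3g V unreachable even at f = 1 (model maximum %.3g V); ",
          "binding parameters: n_hotspot = %.3g, c_total = %.3g, gap ratio = %.3g."
        ),
        target_shift, shift_at(1), model_params$n_hotspot,
        model_params$c_total, mixture$eg_hotspot / mixture$eg_background
      ), call. = FALSE)
    }
    lo <- 0
    hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (shift_at(mid) < target_shift) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-6 * hi && hi < Inf) break
    }
    f <- (lo + hi) / 2
  }
  structure(
    list(
      f = f, target_shift = target_shift, model = "hotspot-mixture-1",
      mixture = mixture, model_params = model_params
    ),
    class = "hotspot_solution"
  )
}

#' @export
print.hotspot_solution <- function(x, ...) {
  cat(sprintf(
    "<hotspot_solution> f = %.4g (%.4g%% of area) for a %.3g V shift [%s]\n",
    x$f, 100 * x$f, x$target_shift, x$model
  ))
  cat(sprintf(
    "  gaps %.4g -> %.4g eV, n_hotspot = %.3g /m^2, C_T = %.3g F/m^2\n",
    x$mixture$eg_background, x$mixture$eg_hotspot,
    x$model_params$n_hotspot, x$model_params$c_total
  ))
  invisible(x)
}
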