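#' Tidy a Sips fit into a one-row-per-parameter tibble
#'
#' @param x A [fit_sips()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.sips_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dv_max", "log10_K", "heterogeneity_a"),
    estimate = c(x$dv_max, x$log10_K, x$heterogeneity_a),
    std.error = c(x$se_dv_max, x$se_log10_K, x$se_a)
  )
}

#' One-row fit summary of a Sips fit
#'
#' @param x A [fit_sips()] result.
#' @param ... Unused.
#' @return A tibble with `affinity_K`, `residual_sd`, `n_obs`, `converged`,
#'   `a_at_bound`.
#' @export
glance.sips_fit <- function(x, ...) {
  tibble::tibble(
    affinity_K = x$affinity_K,
    residual_sd = x$residual_sd,
    n_obs = x$n_obs,
    converged = x$converged,
    a_at_bound = x$a_at_bound
  )
}

#' Tidy a Dirac-point estimate
#'
#' @param x An [extract_dirac_point()] result.
#' @param ... Unused.
#' @return One-row tibble with `v_dirac`, `i_min`, `method`, `tie`.
#' @export
tidy.dirac_estimate <- function(x, ...) {
  tibble::tibble(
    v_dirac = x$v_dirac, i_min = x$i_min,
    method = x$method, tie = x$tie
  )
}

#' Tidy an LOD decision trace
#'
#' @param x An [estimate_lod()] result.
#' @param ... Unused.
#' @return The per-concentration decision trace as a tibble.
#' @export
tidy.lod_estimate <- function(x, ...) x$trace

#' Tidy an unscreened-charge result
#'
#' @param x An [unscreened_dna_charge()] result.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.unscreened_charge <- function(x, ...) {
  tibble::tibble(
    n_unscreened_e = x$n_unscreened_e, n_total_e = x$n_total_e,
    fraction = x$fraction, per_area_e_m2 = x$per_area_e_m2
  )
}
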