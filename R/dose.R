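#' Fit the Sips (Langmuir-Freundlich) isotherm to a dose-response table
#'
#' Nonlinear least squares of `|dV|(C) = dv_max (K C)^a / (1 + (K C)^a)` on
#' the replicate-level absolute shifts, parameterized internally as
#' `(dv_max, log10 K, a)` with `a` bounded in (0, 2]. A multi-start grid over
#' affinity and heterogeneity guards against the flat-likelihood valleys a
#' 12-decade concentration range produces; the best converged start wins.
#'
#' Shift noise on a voltage readout is additive and concentration-independent,
#' so the default objective is unweighted (this is also what makes the
#' reported standard errors calibrated); `weighting = "relative"` divides
#' residuals by the model value instead.
#'
#' @param data A [dose_response()] with at least 3 distinct positive
#'   concentrations.
#' @param weighting `"none"` (default) or `"relative"`.
#' @return A list of class `sips_fit`: `dv_max`, `affinity_K`,
#'   `heterogeneity_a`, `log10_K`, standard errors (`se_dv_max`, `se_log10_K`,
#'   `se_a`), `residual_sd`, `converged`, `a_at_bound`, `n_obs`, `vcov` and
#'   the underlying `nls` object (`fit`).
#' @examples
#' dr <- generate_dose_response(sips_params(noise_sd = 0))
#' fit_sips(dr)
#' @export
fit_sips <- function(data, weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  pos <- data[data$concentration > 0 & !data$is_negative_control, ]
  if (length(unique(pos$concentration)) < 3) {
    stop("Sips fitting needs >= 3 distinct positive concentrations.", call. = FALSE)
  }
  df <- tibble::tibble(conc = pos$concentration, y = abs(pos$shift_mv))

  lk0 <- -log10(exp(mean(log(df$conc))))
  starts <- expand.grid(
    dv_max = max(df$y) * c(1.05, 1.6),
    lk = lk0 + c(-2, -1, 0, 1, 2),
    a = c(0.5, 1, 1.5)
  )
  lower <- c(dv_max = 1e-8, lk = lk0 - 8, a = 0.02)
  upper <- c(dv_max = Inf, lk = lk0 + 8, a = 2)

  best <- NULL
  best_rss <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      if (weighting == "none") {
        stats::nls(
          y ~ dv_max * (10^lk * conc)^a / (1 + (10^lk * conc)^a),
          data = df,
          start = as.list(starts[s, ]),
          lower = lower, upper = upper, algorithm = "port",
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
        )
      } else {
        stats::nls(
          rep(1, nrow(df)) ~ y / (dv_max * (10^lk * conc)^a / (1 + (10^lk * conc)^a)),
          data = df,
          start = as.list(starts[s, ]),
          lower = lower, upper = upper, algorithm = "port",
          control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
        )
      },
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) {
    stop("Sips fit failed to converge from any start.", call. = FALSE)
  }

  cf <- stats::coef(best)
  sm <- summary(best)
  se <- sm$coefficients[, "Std. Error"]
  a_at_bound <- cf["a"] >= upper["a"] - 1e-6 || cf["a"] <= lower["a"] + 1e-6
  if (a_at_bound) {
    warning("Heterogeneity exponent pinned at its bound.", call. = FALSE)
  }
  structure(
    list(
      dv_max = unname(cf["dv_max"]),
      affinity_K = unname(10^cf["lk"]),
      heterogeneity_a = unname(cf["a"]),
      log10_K = unname(cf["lk"]),
      se_dv_max = unname(se["dv_max"]),
      se_log10_K = unname(se["lk"]),
      se_a = unname(se["a"]),
      residual_sd = sm$sigma,
      converged = best$convInfo$isConv %||% TRUE,
      a_at_bound = a_at_bound,
      n_obs = nrow(df),
      vcov = stats::vcov(best),
      weighting = weighting,
      fit = best
    ),
    class = "sips_fit"
  )
}

#' @export
print.sips_fit <- function(x, ...) {
  cat("<sips_fit> |dV|(C) = dv_max (K C)^a / (1 + (K C)^a)\n")
  cat(sprintf("  dv_max = %.2f +/- %.2f mV\n", x$dv_max, x$se_dv_max))
  cat(sprintf(
    "  K      = %.3g L/mol (log10 K = %.3f +/- %.3f)\n",
    x$affinity_K, x$log10_K, x$se_log10_K
  ))
  cat(sprintf("  a      = %.3f +/- %.3f%s\n", x$heterogeneity_a, x$se_a,
    if (x$a_at_bound) " [at bound]" else ""
  ))
  cat(sprintf(
    "  residual SD %.2f mV on %d observations%s\n",
    x$residual_sd, x$n_obs, if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' Limit of detection against negative controls
#'
#' A concentration is detectable when its mean absolute shift exceeds the
#' negative-control band `|nc_mean| + k_sigma * nc_sd`. The LOD is the lowest
#' tested concentration that passes **and** whose higher concentrations all
#' pass too — a single concentration poking above the band while its
#' neighbours overlap the controls is not detection. The full decision trace
#' is returned.
#'
#' @param data A [dose_response()] with >= 2 negative-control replicates.
#' @param k_sigma Band width in control SDs (default 3).
#' @return A list of class `lod_estimate`: `lod_concentration` (mol/L or NA),
#'   `criterion`, `nc_mean`, `nc_sd` (mV, absolute-shift scale), `trace`
#'   (tibble with per-concentration mean shift and pass flag).
#' @export
estimate_lod <- function(data, k_sigma = 3) {
  nc <- data[data$is_negative_control, ]
  if (nrow(nc) < 2) {
    stop("Need >= 2 negative-control replicates.", call. = FALSE)
  }
  nc_mean <- mean(abs(nc$shift_mv))
  nc_sd <- stats::sd(abs(nc$shift_mv))
  band <- nc_mean + k_sigma * nc_sd

  trace <- data[!data$is_negative_control & data$concentration > 0, ] |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(
      mean_abs_shift = mean(abs(.data$shift_mv)),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$concentration) |>
    dplyr::mutate(pass = .data$mean_abs_shift > band)

  # monotone persistence: passes only count if every higher dose also passes
  persistent <- rev(cumprod(rev(trace$pass))) > 0
  lod <- if (any(persistent)) trace$concentration[which(persistent)[1]] else NA_real_
  if (is.na(lod)) message("No concentration clears the control band; LOD absent.")
  structure(
    list(
      lod_concentration = lod,
      criterion = sprintf("mean |shift| > nc_mean + %g * nc_sd, persistent upward", k_sigma),
      nc_mean = nc_mean, nc_sd = nc_sd,
      trace = dplyr::mutate(trace, persistent = persistent)
    ),
    class = "lod_estimate"
  )
}

#' @export
print.lod_estimate <- function(x, ...) {
  if (is.na(x$lod_concentration)) {
    cat("<lod_estimate> no LOD (nothing clears the control band)\n")
  } else {
    cat(sprintf("<lod_estimate> LOD = %.3g mol/L\n", x$lod_concentration))
  }
  cat(sprintf(
    "  controls: %.2f +/- %.2f mV; rule: %s\n",
    x$nc_mean, x$nc_sd, x$criterion
  ))
  invisible(x)
}

#' Molecule count in a sample volume
#'
#' `N = concentration * volume * N_A`, rounded to the nearest molecule (the
#' unrounded value and a 2-significant-figure "approximately" view are also
#' returned). At the headline sensitivities this is ~18 molecules for 600 zM
#' and ~600 for 20 aM in 50 uL.
#'
#' @param concentration mol/L, >= 0 (vectorized).
#' @param volume L, > 0.
#' @return A tibble with columns `concentration`, `volume`,
#'   `molecules_exact`, `molecules`, `molecules_approx`.
#' @examples
#' molecules_from_concentration(c(600e-21, 20e-18), 50e-6)
#' @export
molecules_from_concentration <- function(concentration, volume) {
  if (any(concentration < 0) || any(volume <= 0)) {
    stop("concentration must be >= 0 and volume > 0.", call. = FALSE)
  }
  exact <- concentration * volume * .const$NA_
  tibble::tibble(
    concentration = concentration, volume = volume,
    molecules_exact = exact,
    molecules = round(exact),
    molecules_approx = signif(exact, 2)
  )
}
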