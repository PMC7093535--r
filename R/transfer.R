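#' Extract the Dirac point from a transfer curve
#'
#' Smooths the current with a centered moving average, locates the grid
#' argmin, then refines it with a local parabola fit over points within
#' `fit_halfwidth` of the argmin. A parabola vertex is used only if it stays
#' inside the fit window; otherwise the grid minimum is kept (flagged in
#' `method`). A tie between equal minima resolves to the smallest voltage and
#' is flagged. A minimum at the sweep edge is an error — the sweep window did
#' not capture the Dirac point.
#'
#' The estimator is translation-equivariant (shifting the sweep shifts the
#' estimate identically) and invariant to positive rescaling of the current.
#'
#' @param curve A [transfer_curve()] with at least 7 points.
#' @param smooth_window Moving-average window, points (odd; default 5).
#' @param fit_halfwidth Half-width of the parabola fit window, V (default 0.1).
#' @return A list of class `dirac_estimate`: `v_dirac` (V), `i_min` (A),
#'   `window_used` (V range of the fit), `method`, `tie` flag.
#' @export
extract_dirac_point <- function(curve, smooth_window = 5, fit_halfwidth = 0.1) {
  v <- curve$v_gs
  i <- curve$i_ds
  n <- length(v)
  if (n < 7) stop("Need at least 7 sweep points.", call. = FALSE)
  if (smooth_window < 1) smooth_window <- 1
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1

  half <- (smooth_window - 1) / 2
  sm <- vapply(seq_len(n), function(k) {
    mean(i[max(1, k - half):min(n, k + half)])
  }, numeric(1))

  mins <- which(sm == min(sm))
  tie <- length(mins) > 1
  k <- mins[1]
  if (k == 1 || k == n) {
    stop("Current minimum sits at the sweep edge; widen the sweep window.",
      call. = FALSE
    )
  }

  sel <- which(abs(v - v[k]) <= fit_halfwidth + 1e-12)
  method <- "argmin"
  v_hat <- v[k]
  if (length(sel) >= 3) {
    fit <- stats::lm.fit(cbind(1, v[sel] - v[k], (v[sel] - v[k])^2), sm[sel])
    a <- fit$coefficients[3]
    b <- fit$coefficients[2]
    if (is.finite(a) && a > 0) {
      vertex <- v[k] - b / (2 * a)
      if (vertex >= min(v[sel]) && vertex <= max(v[sel])) {
        v_hat <- vertex
        method <- "parabola"
      }
    }
  }
  structure(
    list(
      v_dirac = unname(v_hat), i_min = i[k],
      window_used = range(v[sel]), method = method, tie = tie
    ),
    class = "dirac_estimate"
  )
}

#' @export
print.dirac_estimate <- function(x, ...) {
  cat(sprintf(
    "<dirac_estimate> V_D = %.4f V (i_min = %.3g A, %s%s)\n",
    x$v_dirac, x$i_min, x$method, if (x$tie) ", tie" else ""
  ))
  invisible(x)
}

#' Dirac shift series across conditions
#'
#' Extracts the Dirac point of every curve and reports the shift of each
#' condition against a baseline, in mV, with replicates aggregated as
#' mean +/- SD. Added negative charge n-dopes graphene, so an adsorbing DNA
#' dose series shows negative (leftward) shifts.
#'
#' @param curves A list of [transfer_curve()]s.
#' @param conditions Vector (same length) labelling each curve's condition;
#'   curves sharing a condition are replicates. Defaults to curve labels.
#' @param baseline The condition to reference shifts against.
#' @param ... Passed to [extract_dirac_point()].
#' @return A tibble of class `shift_series`: `condition`, `n`, `v_dirac_mean`
#'   (V), `shift_mv`, `shift_sd_mv`.
#' @export
shift_series <- function(curves, conditions = NULL, baseline, ...) {
  if (is.null(conditions)) {
    conditions <- vapply(curves, function(cv) attr(cv, "label"), character(1))
  }
  if (!baseline %in% conditions) {
    stop("Baseline condition '", baseline, "' not present.", call. = FALSE)
  }
  vd <- vapply(curves, function(cv) extract_dirac_point(cv, ...)$v_dirac, numeric(1))
  df <- tibble::tibble(condition = conditions, v_dirac = vd) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      v_dirac_mean = mean(.data$v_dirac),
      v_dirac_sd = stats::sd(.data$v_dirac),
      .groups = "drop"
    )
  v0 <- df$v_dirac_mean[df$condition == baseline]
  out <- df |>
    dplyr::mutate(
      shift_mv = (.data$v_dirac_mean - v0) * 1e3,
      shift_sd_mv = ifelse(is.na(.data$v_dirac_sd), 0, .data$v_dirac_sd * 1e3)
    ) |>
    dplyr::select("condition", "n", "v_dirac_mean", "shift_mv", "shift_sd_mv")
  structure(out,
    baseline = baseline,
    class = c("shift_series", class(tibble::tibble()))
  )
}

#' pH sensitivity of the Dirac point
#'
#' Least-squares slope of Dirac shift against pH, in mV per pH unit, with
#' its standard error — the figure of merit of the bare channel as an ion
#' (H+) sensor.
#'
#' @param series A [shift_series()] whose `condition` column is numeric pH
#'   (or coercible), or any data frame with `condition` and `shift_mv`.
#' @return A list of class `ph_sensitivity`: `slope_mv_per_ph`, `se`,
#'   `n_levels`, `fit` (the `lm` object).
#' @export
ph_sensitivity <- function(series) {
  ph <- suppressWarnings(as.numeric(series$condition))
  if (any(is.na(ph))) stop("Conditions must be numeric pH values.", call. = FALSE)
  if (length(unique(ph)) < 3) {
    stop("Need at least 3 pH levels for a slope.", call. = FALSE)
  }
  fit <- stats::lm(shift_mv ~ ph, data = tibble::tibble(ph = ph, shift_mv = series$shift_mv))
  coefs <- summary(fit)$coefficients
  structure(
    list(
      slope_mv_per_ph = unname(coefs["ph", "Estimate"]),
      se = unname(coefs["ph", "Std. Error"]),
      n_levels = length(unique(ph)), fit = fit
    ),
    class = "ph_sensitivity"
  )
}

#' @export
print.ph_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<ph_sensitivity> %.2f +/- %.2f mV per pH unit over %d levels\n",
    x$slope_mv_per_ph, x$se, x$n_levels
  ))
  invisible(x)
}
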