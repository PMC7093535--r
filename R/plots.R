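#' Plot a concentration profile
#'
#' @param object A [bin_concentration()] profile.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concentration_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d_mid, y = .data$concentration)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "distance from surface (nm)", y = "concentration (mol/L)",
      title = paste0("[", attr(object, "species"), "] profile (",
        attr(object, "surface")$kind, " surface)"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a screening-factor curve
#'
#' @param object A [screening_factor()] result.
#' @param threshold Optional onset threshold to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screening_result <- function(object, threshold = 0.05, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$sf)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "distance from surface (nm)", y = "screening factor SF(z)") +
    ggplot2::theme_minimal()
  onset <- screening_onset(object, threshold)
  if (is.finite(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset, linetype = "dashed")
  }
  p
}

#' Plot an ambipolar transfer curve with its Dirac point
#'
#' @param object A [transfer_curve()].
#' @param ... Passed to [extract_dirac_point()].
#' @return A ggplot.
#' @export
autoplot.transfer_curve <- function(object, ...) {
  est <- extract_dirac_point(object, ...)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$v_gs, y = .data$i_ds)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = est$v_dirac, linetype = "dashed") +
    ggplot2::labs(
      x = "V_gs (V)", y = "I_ds (A)",
      title = sprintf("Dirac point at %.3f V", est$v_dirac)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response table, optionally with a Sips fit overlaid
#'
#' @param object A [dose_response()].
#' @param fit Optional [fit_sips()] result.
#' @param ... Unused.
#' @return A ggplot (log10 concentration axis; controls excluded).
#' @export
autoplot.dose_response <- function(object, fit = NULL, ...) {
  pos <- object[object$concentration > 0, ]
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$concentration, y = abs(.data$shift_mv))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (mol/L)", y = "|Dirac shift| (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      concentration = 10^seq(
        log10(min(pos$concentration)), log10(max(pos$concentration)),
        length.out = 200
      )
    )
    grid$shift <- sips_curve(
      grid$concentration, fit$dv_max, fit$affinity_K, fit$heterogeneity_a
    )
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$concentration, y = .data$shift)
    )
  }
  p
}

#' Plot a potential profile
#'
#' @param object A [potential_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.potential_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "V (V)") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D concentration map
#'
#' @param object A [map_concentration_2d()] result.
#' @param ... Unused.
#' @return A ggplot raster of molarity over (x, z).
#' @export
autoplot.concentration_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_mid, y = .data$z_mid,
    fill = .data$concentration
  )) +
    ggplot2::geom_raster() +
    ggplot2::labs(
      x = "x (nm)", y = "z (nm)", fill = "mol/L",
      title = paste0("[", attr(object, "species"), "] map")
    ) +
    ggplot2::theme_minimal()
}
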