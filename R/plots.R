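#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a dose-response curve
#'
#' Dose points (with standard-error bars when available) and the fitted
#' calibration line.
#'
#' @param object A `drc` from [fit_drc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drc <- function(object, ...) {
  pts <- object$points
  if (is.null(pts)) stop("this curve carries no dose points to plot",
                         call. = FALSE)
  dose_col <- intersect(c("dose_gy", "dose"), names(pts))[1L]
  y_col <- intersect(c("index_mean", "index", "value", "mean"), names(pts))[1L]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[dose_col]],
                                         y = .data[[y_col]])) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2)
  if ("index_se" %in% names(pts)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[y_col]] - .data$index_se,
                   ymax = .data[[y_col]] + .data$index_se),
      width = 0.4
    )
  }
  lab <- if (!is.null(object$index_name) && !is.na(object$index_name)) {
    object$index_name
  } else "texture index"
  p + ggplot2::labs(
    x = "absorbed dose (Gy)", y = lab,
    title = sprintf("y = %.4g x + %.4g   (R² = %.3f)",
                    object$slope, object$intercept, object$r_squared)
  )
}

#' Plot linearity and sensitivity maps
#'
#' Heatmaps of R^2 and normalized |slope| over the scanned (e, d) grid,
#' matching how the parameter scan is usually inspected.
#'
#' @param object A `parameter_maps` from [build_parameter_maps()].
#' @param ... Unused.
#' @return A ggplot (faceted by metric).
#' @export
autoplot.parameter_maps <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$grid[, c("e", "d", "r2", "sens_norm")],
    cols = c("r2", "sens_norm"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, c("r2", "sens_norm"),
                        c("linearity R²", "normalized sensitivity"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$e,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "offset distance d (px)", y = "exclusion count e",
                  fill = NULL, title = object$index)
}

#' Plot measured versus prescribed dose
#'
#' @param report A per-dose tibble from [dose_report()].
#' @return A ggplot with the identity line.
#' @export
plot_dose_report <- function(report) {
  stopifnot(is.data.frame(report),
            all(c("dose_gy", "measured_dose") %in% names(report)))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$dose_gy,
                                       y = .data$measured_dose)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$measured_dose - .data$dose_sd,
                   ymax = .data$measured_dose + .data$dose_sd)
    ) +
    ggplot2::labs(x = "prescribed dose (Gy)", y = "measured dose (Gy)")
}
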