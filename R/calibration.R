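#' Collapse per-tile indices to dose points
#'
#' Builds the (dose, index) points a dose-response curve is fitted to. For
#' each image, `e` outliers are excluded from its tile values
#' ([exclude_outliers()]) and the retained tiles are averaged; per dose
#' level, the per-image means are then averaged. The standard error of a
#' dose point is taken over its per-image means when the design has more
#' than one image per dose, and over the retained tiles of the single image
#' otherwise.
#'
#' @param features Per-tile features from [study_tile_features()] (or
#'   [tile_features()] output joined to `dose_gy`/`image_id` columns),
#'   restricted to a single offset distance.
#' @param index Which texture index to use: `"entropy"`, `"contrast"`,
#'   `"energy"` or `"homogeneity"` (the default, the paper-of-record dose
#'   index for this gel system being its inverse difference moment).
#' @param e Outlier-exclusion count per image.
#' @param method Outlier rule, see [exclude_outliers()].
#' @return A tibble with one row per dose level: `dose_gy`, `index_mean`,
#'   `index_se`, `n_images`.
#' @export
dose_points <- function(features, index = "homogeneity", e = 0L,
                        method = "median") {
  stopifnot(is.data.frame(features))
  if (!index %in% names(features)) {
    stop(sprintf("no column `%s` in `features`", index), call. = FALSE)
  }
  if ("d" %in% names(features) && length(unique(features$d)) > 1L) {
    stop("`features` spans several offset distances; filter to one `d` first",
         call. = FALSE)
  }
  if (!"image_id" %in% names(features)) features$image_id <- "image"
  if (!"dose_gy" %in% names(features)) {
    stop("`features` needs a `dose_gy` column", call. = FALSE)
  }
  per_image <- features |>
    dplyr::group_by(.data$dose_gy, .data$image_id) |>
    dplyr::summarise(
      agg = list(aggregate_index(.data[[index]], e = e, method = method)),
      .groups = "drop"
    ) |>
    tidyr::unnest("agg")
  per_image |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::summarise(
      index_mean = mean(.data$mean),
      index_se = if (dplyr::n() > 1L) {
        stats::sd(.data$mean) / sqrt(dplyr::n())
      } else {
        .data$se[1L]
      },
      n_images = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$dose_gy)
}

#' Fit a linear dose-response curve
#'
#' Ordinary least-squares fit of a texture index on absorbed dose,
#' `y = a x + b`. Linearity is the coefficient of determination R^2 and
#' sensitivity the absolute slope |a|. Dose points are weighted equally by
#' default; `weighted = TRUE` weights them by `1 / se^2` when a standard
#' error column is present.
#'
#' @param points A tibble of dose points with columns `dose_gy` (or `dose`)
#'   and `index_mean` (or `index` / `value`), e.g. from [dose_points()]. At
#'   least 3 distinct dose levels are required.
#' @param index_name,magnification,d,e Provenance recorded on the curve.
#' @param weighted Weight points by inverse squared standard error
#'   (`index_se` column required).
#' @return A `drc` object: list with `slope`, `intercept`, `r_squared`,
#'   `sensitivity`, provenance fields, the input `points` and the underlying
#'   `lm` fit. Supports [generics::tidy()], [generics::glance()], `print()`
#'   and [ggplot2::autoplot()].
#' @examples
#' pts <- tibble::tibble(dose_gy = c(5, 10, 15, 20),
#'                       index_mean = c(0.075, 0.106, 0.131, 0.154))
#' fit_drc(pts)
#' @export
fit_drc <- function(points, index_name = NA_character_,
                    magnification = NA_character_, d = NA_integer_,
                    e = NA_integer_, weighted = FALSE) {
  stopifnot(is.data.frame(points))
  dose_col <- intersect(c("dose_gy", "dose"), names(points))[1L]
  y_col <- intersect(c("index_mean", "index", "value", "mean"),
                     names(points))[1L]
  if (is.na(dose_col) || is.na(y_col)) {
    stop("`points` needs a dose column (dose_gy/dose) and an index column (index_mean/index/value)",
         call. = FALSE)
  }
  x <- points[[dose_col]]; y <- points[[y_col]]
  if (length(unique(x)) < 3L) {
    stop("need at least 3 distinct dose levels to fit a dose-response curve",
         call. = FALSE)
  }
  if (stats::var(x) == 0) stop("doses have zero variance", call. = FALSE)
  w <- NULL
  if (weighted) {
    if (!"index_se" %in% names(points)) {
      stop("weighted fit needs an `index_se` column", call. = FALSE)
    }
    w <- 1 / points$index_se^2
  }
  df <- data.frame(dose = x, y = y)
  fit <- if (is.null(w)) stats::lm(y ~ dose, data = df) else {
    stats::lm(y ~ dose, data = df, weights = w)
  }
  co <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else 0
  structure(
    list(
      slope = unname(co[["dose"]]),
      intercept = unname(co[["(Intercept)"]]),
      r_squared = r2,
      sensitivity = abs(unname(co[["dose"]])),
      index_name = index_name,
      magnification = magnification,
      d = d, e = e,
      n_dose_levels = length(unique(x)),
      points = tibble::as_tibble(points),
      fit = fit
    ),
    class = "drc"
  )
}

#' @export
print.drc <- function(x, ...) {
  cat("<dose-response curve>\n")
  cat(sprintf("  y = %.6g * dose + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, sensitivity |slope| = %.6g per Gy\n",
              x$r_squared, x$sensitivity))
  if (!is.na(x$index_name)) {
    cat(sprintf("  index = %s, d = %s, e = %s%s\n", x$index_name, x$d, x$e,
                if (!is.na(x$magnification)) paste0(", ", x$magnification)
                else ""))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.drc <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "dose_gy"),
    estimate = unname(s[, 1L]),
    std.error = unname(s[, 2L]),
    statistic = unname(s[, 3L]),
    p.value = unname(s[, 4L])
  )
}

#' @export
glance.drc <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    sensitivity = x$sensitivity,
    index_name = x$index_name,
    magnification = x$magnification,
    d = x$d,
    e = x$e,
    n_dose_levels = x$n_dose_levels
  )
}

#' Invert a calibration curve to absorbed dose
#'
#' Solves `y = a x + b` for the dose `x = (y - b) / a`. Negative doses are
#' returned as-is with a warning, never silently clamped.
#'
#' @param curve A `drc` from [fit_drc()] (or any list with `slope` and
#'   `intercept`).
#' @param y Measured texture index value(s).
#' @return Estimated absorbed dose(s) in Gy.
#' @examples
#' cal <- list(slope = 0.0052, intercept = 0.051)
#' invert_dose(cal, 0.075) # ~4.62 Gy
#' @export
invert_dose <- function(curve, y) {
  a <- curve$slope; b <- curve$intercept
  if (is.null(a) || is.null(b)) {
    stop("`curve` must carry `slope` and `intercept`", call. = FALSE)
  }
  if (a == 0) stop("calibration slope is zero; dose is not identifiable",
                   call. = FALSE)
  x <- (y - b) / a
  if (any(x < 0)) {
    warning(sprintf("%d estimated dose(s) are negative (index outside the calibrated range)",
                    sum(x < 0)), call. = FALSE)
  }
  x
}

#' Percentage error of a measured dose
#'
#' `100 * (measured - prescribed) / prescribed`, the accuracy figure of a
#' dose verification.
#'
#' @param measured Measured (estimated) dose(s), Gy.
#' @param prescribed Prescribed dose(s), Gy, strictly positive.
#' @return Percentage error(s), in percent.
#' @examples
#' percentage_error(4.62, 5) # -7.6
#' @export
percentage_error <- function(measured, prescribed) {
  if (any(prescribed <= 0)) {
    stop("`prescribed` dose must be > 0 for a percentage error", call. = FALSE)
  }
  100 * (measured - prescribed) / prescribed
}
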