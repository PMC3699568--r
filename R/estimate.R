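#' Estimate absorbed dose per image
#'
#' Applies a fitted calibration to per-tile features of a verification
#' study: for every image, `e` tile outliers are excluded, the retained
#' tiles averaged, and the mean index inverted through the curve. Inversion
#' happens per image (doses from multiple images of one sample are averaged
#' after inversion, not before), so the reported spread reflects image-level
#' variability.
#'
#' @param features Per-tile features from [study_tile_features()] at a
#'   single offset distance; must match the curve's `d` when both are known.
#' @param curve A `drc` from [fit_drc()] (or read back with
#'   [read_calibration()]).
#' @param e Outlier-exclusion count; defaults to the curve's own `e`.
#' @param method Outlier rule, see [exclude_outliers()].
#' @return A tibble with one row per image: `image_id`, `sample_id`,
#'   `replicate_id`, `dose_gy` (prescribed), `index_mean`, `dose_est`.
#' @export
estimate_doses <- function(features, curve, e = NULL, method = "median") {
  stopifnot(is.data.frame(features))
  index <- curve$index_name
  if (is.null(index) || is.na(index)) index <- "homogeneity"
  if ("d" %in% names(features)) {
    dd <- unique(features$d)
    if (length(dd) > 1L) {
      stop("`features` spans several distances; filter to the curve's `d`",
           call. = FALSE)
    }
    if (!is.null(curve$d) && !is.na(curve$d) && dd != curve$d) {
      stop(sprintf("features computed at d = %d but curve calibrated at d = %d",
                   dd, curve$d), call. = FALSE)
    }
  }
  if (is.null(e)) e <- if (!is.null(curve$e) && !is.na(curve$e)) curve$e else 0L
  for (col in c("sample_id", "replicate_id")) {
    if (!col %in% names(features)) features[[col]] <- NA
  }
  per_image <- features |>
    dplyr::group_by(.data$image_id, .data$sample_id, .data$replicate_id,
                    .data$dose_gy) |>
    dplyr::summarise(
      index_mean = aggregate_index(.data[[index]], e = e,
                                   method = method)$mean,
      .groups = "drop"
    )
  per_image$dose_est <- invert_dose(curve, per_image$index_mean)
  per_image
}

#' Per-dose verification report
#'
#' Summarises per-image dose estimates into one row per prescribed dose
#' level: mean measured dose, its spread over images, and the percentage
#' error against the prescription.
#'
#' @param estimates Per-image estimates from [estimate_doses()].
#' @return A tibble: `dose_gy`, `measured_dose`, `dose_sd`, `n_images`,
#'   `percentage_error` (NA where the prescribed dose is 0).
#' @export
dose_report <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("dose_gy", "dose_est") %in% names(estimates)))
  estimates |>
    dplyr::group_by(.data$dose_gy) |>
    dplyr::summarise(
      measured_dose = mean(.data$dose_est),
      dose_sd = stats::sd(.data$dose_est),
      n_images = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percentage_error = ifelse(.data$dose_gy > 0,
                                100 * (.data$measured_dose - .data$dose_gy) /
                                  .data$dose_gy,
                                NA_real_)
    ) |>
    dplyr::arrange(.data$dose_gy)
}
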