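#' Linearity and sensitivity maps over (e, d)
#'
#' For every combination of outlier-exclusion count `e` and offset distance
#' `d`, fits the dose-response curve of the chosen texture index and records
#' its linearity (R^2) and sensitivity (|slope|). Sensitivities are also
#' reported normalized by the grid maximum, which is how combinations are
#' compared within one index/magnification map. A cell whose curve cannot be
#' fitted is an error, never silently skipped.
#'
#' @param features Per-tile study features from [study_tile_features()],
#'   computed over the distances of interest.
#' @param index Texture index to map (default `"homogeneity"`).
#' @param e_values Exclusion counts to scan (default `0:2`).
#' @param d_values Distances to scan; default every distance present in
#'   `features`.
#' @param method Outlier rule, see [exclude_outliers()].
#' @param magnification Provenance tag stored on the maps.
#' @return A `parameter_maps` object: list with `grid` (long tibble `e`, `d`,
#'   `slope`, `intercept`, `r2`, `sens_raw`, `sens_norm`), the scanned
#'   `e_values`/`d_values`, `index`, `method`, `magnification`, and the
#'   input `features` (kept so the optimum can be refitted in full).
#' @export
build_parameter_maps <- function(features, index = "homogeneity",
                                 e_values = 0:2, d_values = NULL,
                                 method = "median",
                                 magnification = NA_character_) {
  stopifnot(is.data.frame(features), "d" %in% names(features))
  if (is.null(d_values)) d_values <- sort(unique(features$d))
  if (!all(d_values %in% features$d)) {
    stop("`d_values` not all present in `features`", call. = FALSE)
  }
  grid <- tidyr::expand_grid(e = as.integer(e_values),
                             d = as.integer(d_values))
  cells <- purrr::pmap_dfr(grid, function(e, d) {
    pts <- dose_points(features[features$d == d, , drop = FALSE],
                       index = index, e = e, method = method)
    cv <- fit_drc(pts, index_name = index, magnification = magnification,
                  d = d, e = e)
    tibble::tibble(e = e, d = d, slope = cv$slope, intercept = cv$intercept,
                   r2 = cv$r_squared, sens_raw = cv$sensitivity)
  })
  smax <- max(cells$sens_raw)
  # a grid whose largest |slope| is numerically zero has no sensitivity to
  # normalize by; report zeros so selection fails loudly
  cells$sens_norm <- if (smax > 1e-12) cells$sens_raw / smax else 0
  structure(
    list(grid = cells, e_values = as.integer(e_values),
         d_values = as.integer(d_values), index = index, method = method,
         magnification = magnification, features = features),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf(
    "<parameter_maps> %s: %d e-values x %d distances; best R^2 = %.4f\n",
    x$index, length(x$e_values), length(x$d_values), max(x$grid$r2)
  ))
  invisible(x)
}

#' @export
tidy.parameter_maps <- function(x, ...) x$grid

#' Select the optimal (e, d) combination
#'
#' Returns the map cell with the highest linearity R^2 among cells whose
#' normalized sensitivity reaches `min_norm_sensitivity`; a highly linear
#' but insensitive curve is useless for dose conversion, so such cells are
#' excluded up front. Ties are broken by higher sensitivity, then smaller
#' `d`, then smaller `e`.
#'
#' @param maps A `parameter_maps` object from [build_parameter_maps()].
#' @param min_norm_sensitivity Normalized-sensitivity floor in (0, 1];
#'   default 0.5.
#' @return A list with the chosen `e`, `d` and the refitted `curve` (a
#'   `drc`).
#' @export
select_optimum <- function(maps, min_norm_sensitivity = 0.5) {
  stopifnot(inherits(maps, "parameter_maps"))
  g <- maps$grid
  ok <- g[g$sens_norm >= min_norm_sensitivity, , drop = FALSE]
  if (nrow(ok) == 0L) {
    best <- g[order(-g$r2), , drop = FALSE][1L, ]
    stop(sprintf(
      "no (e, d) cell reaches normalized sensitivity %.3g; best rejected cell: e = %d, d = %d (R^2 = %.4f, sens_norm = %.3f)",
      min_norm_sensitivity, best$e, best$d, best$r2, best$sens_norm
    ), call. = FALSE)
  }
  ok <- ok[order(-ok$r2, -ok$sens_norm, ok$d, ok$e), , drop = FALSE]
  top <- ok[1L, ]
  pts <- dose_points(maps$features[maps$features$d == top$d, , drop = FALSE],
                     index = maps$index, e = top$e, method = maps$method)
  curve <- fit_drc(pts, index_name = maps$index,
                   magnification = maps$magnification, d = top$d, e = top$e)
  list(e = top$e, d = top$d, curve = curve)
}

#' Distance at which a sensitivity level is first reached
#'
#' For each exclusion-count row of the normalized sensitivity map, finds the
#' smallest distance at which normalized sensitivity first reaches `level`,
#' linearly interpolating between adjacent grid distances, and returns the
#' mean over rows. Rows that never reach the level are dropped with a
#' warning; if no row reaches it, this is an error.
#'
#' @param maps A `parameter_maps` object.
#' @param level Normalized sensitivity level in (0, 1], e.g. `0.9`.
#' @return Mean crossing distance, in pixels (fractional).
#' @export
distance_at_sensitivity <- function(maps, level) {
  stopifnot(inherits(maps, "parameter_maps"), level > 0, level <= 1)
  g <- maps$grid
  crossings <- vapply(maps$e_values, function(e) {
    row <- g[g$e == e, , drop = FALSE]
    row <- row[order(row$d), , drop = FALSE]
    s <- row$sens_norm; dd <- row$d
    hit <- which(s >= level)
    if (length(hit) == 0L) return(NA_real_)
    k <- hit[1L]
    if (k == 1L) return(as.numeric(dd[1L]))
    dd[k - 1L] + (level - s[k - 1L]) / (s[k] - s[k - 1L]) * (dd[k] - dd[k - 1L])
  }, numeric(1))
  if (all(is.na(crossings))) {
    stop(sprintf("no e-row of the sensitivity map reaches level %.3g", level),
         call. = FALSE)
  }
  if (anyNA(crossings)) {
    warning(sprintf("%d e-row(s) never reach sensitivity level %.3g; excluded from the average",
                    sum(is.na(crossings)), level), call. = FALSE)
  }
  mean(crossings, na.rm = TRUE)
}
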