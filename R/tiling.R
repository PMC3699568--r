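#' Tile a micrograph into sub-images
#'
#' Cuts the raster into a non-overlapping, top-left anchored grid of tiles,
#' returned row-major. The grid is given either as a tile count
#' (`rows` x `cols`, default the 4 x 4 = 16-tile protocol layout) or as an
#' explicit tile size (`tile_height` x `tile_width`), from which the counts
#' are derived. Remainder pixels at the bottom/right that do not fill a full
#' tile are cropped with a warning; set `strict = TRUE` to make a
#' non-divisible image an error instead.
#'
#' @param image A [gray_image()].
#' @param rows,cols Number of tile rows/columns (used when `tile_height` /
#'   `tile_width` are `NULL`).
#' @param tile_height,tile_width Tile size in pixels; overrides `rows`/`cols`.
#' @param strict Error (rather than warn) on cropped remainder pixels.
#' @return A list of [gray_image()] tiles in row-major order, with a `grid`
#'   attribute `c(rows, cols)`.
#' @examples
#' img <- gray_image(matrix(0L, 1200, 1600))
#' length(tile_image(img, tile_height = 300, tile_width = 400)) # 16
#' @export
tile_image <- function(image, rows = 4L, cols = 4L,
                       tile_height = NULL, tile_width = NULL,
                       strict = FALSE) {
  image <- as_gray_image(image)
  nr <- nrow(image); nc <- ncol(image)
  if (!is.null(tile_height) || !is.null(tile_width)) {
    if (is.null(tile_height) || is.null(tile_width)) {
      stop("give both `tile_height` and `tile_width`, or neither", call. = FALSE)
    }
    th <- as.integer(tile_height); tw <- as.integer(tile_width)
    if (th > nr || tw > nc) {
      stop(sprintf("tile %d x %d larger than image %d x %d", th, tw, nr, nc),
           call. = FALSE)
    }
    rows <- nr %/% th; cols <- nc %/% tw
  } else {
    rows <- as.integer(rows); cols <- as.integer(cols)
    stopifnot(rows >= 1L, cols >= 1L)
    th <- nr %/% rows; tw <- nc %/% cols
    if (th < 1L || tw < 1L) {
      stop(sprintf("cannot cut a %d x %d image into %d x %d tiles", nr, nc,
                   rows, cols), call. = FALSE)
    }
  }
  crop_r <- nr - rows * th; crop_c <- nc - cols * tw
  if (crop_r > 0L || crop_c > 0L) {
    msg <- sprintf("cropping %d bottom row(s) and %d right column(s) not covered by the tile grid",
                   crop_r, crop_c)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  ps <- attr(image, "pixel_size"); mg <- attr(image, "magnification")
  tiles <- vector("list", rows * cols)
  k <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      k <- k + 1L
      tiles[[k]] <- gray_image(
        unclass(image)[((r - 1L) * th + 1L):(r * th),
                       ((cc - 1L) * tw + 1L):(cc * tw), drop = FALSE],
        pixel_size = ps, magnification = mg
      )
    }
  }
  attr(tiles, "grid") <- c(rows = rows, cols = cols)
  tiles
}

#' Remove statistical outliers from a set of tile index values
#'
#' Implements the exclusion-count rule used throughout the dose-response
#' pipeline: exactly `e` values are removed, one at a time, each time
#' dropping the value with the greatest absolute deviation from the median
#' of the currently retained values. Ties on deviation are broken by removing
#' the larger value; exact value ties by removing the later list position,
#' so the rule is fully deterministic. A z-score variant (deviation from the
#' running mean in units of the running standard deviation) is available via
#' `method = "zscore"`.
#'
#' @param values Numeric vector of per-tile index values.
#' @param e Number of outliers to exclude, `0 <= e <= length(values) - 2`.
#' @param method `"median"` (default) or `"zscore"`.
#' @return A `tile_index_set`: list with `values` (the input, untouched),
#'   `excluded` (positions removed, in removal order), `retained` (logical
#'   mask), `e`, and `method`.
#' @examples
#' exclude_outliers(c(1, 1, 1, 10), e = 1)$excluded # 4
#' @export
exclude_outliers <- function(values, e, method = c("median", "zscore")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values))
  n <- length(values)
  if (anyNA(values)) stop("`values` contains NA", call. = FALSE)
  if (e != floor(e) || e < 0) stop("`e` must be a non-negative integer", call. = FALSE)
  e <- as.integer(e)
  if (e > n - 2L) {
    stop(sprintf("cannot exclude e = %d of %d values (at least 2 must remain)",
                 e, n), call. = FALSE)
  }
  retained <- rep(TRUE, n)
  excluded <- integer(0)
  for (k in seq_len(e)) {
    kept <- values[retained]
    dev <- if (method == "median") {
      abs(values - stats::median(kept))
    } else {
      s <- stats::sd(kept)
      abs(values - mean(kept)) / if (s > 0) s else 1
    }
    dev[!retained] <- -Inf
    cand <- which(dev == max(dev))
    # tie-break: larger value, then later position
    pick <- cand[order(values[cand], cand, decreasing = TRUE)][1L]
    retained[pick] <- FALSE
    excluded <- c(excluded, pick)
  }
  structure(
    list(values = values, excluded = excluded, retained = retained,
         e = e, method = method),
    class = "tile_index_set"
  )
}

#' @export
print.tile_index_set <- function(x, ...) {
  cat(sprintf("<tile_index_set> %d values, e = %d (%s), excluded: %s\n",
              length(x$values), x$e, x$method,
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none"))
  invisible(x)
}

retained_values <- function(x) {
  stopifnot(inherits(x, "tile_index_set"))
  x$values[x$retained]
}

#' Aggregate retained tile values to a mean and standard error
#'
#' The per-image summary used for each dose point: arithmetic mean of the
#' retained values and its standard error, `sd / sqrt(n)` with the n - 1
#' sample standard deviation.
#'
#' @param x Numeric vector of tile values, or a `tile_index_set` from
#'   [exclude_outliers()].
#' @param e Outliers to exclude first (ignored when `x` is already a
#'   `tile_index_set`).
#' @param method Passed to [exclude_outliers()].
#' @return A one-row tibble: `mean`, `se`, `n_retained`, `n_excluded`.
#' @examples
#' aggregate_index(c(1, 1, 1, 10), e = 1) # mean 1, se 0
#' @export
aggregate_index <- function(x, e = 0L, method = "median") {
  ts <- if (inherits(x, "tile_index_set")) x else exclude_outliers(x, e, method)
  v <- retained_values(ts)
  if (length(v) < 2L) stop("need at least 2 retained values", call. = FALSE)
  tibble::tibble(
    mean = mean(v),
    se = stats::sd(v) / sqrt(length(v)),
    n_retained = length(v),
    n_excluded = length(ts$excluded)
  )
}

#' Per-tile texture indices of one micrograph
#'
#' Tiles the image (see [tile_image()]) and computes the direction-averaged
#' texture indices of every tile at each requested offset distance.
#'
#' @inheritParams tile_image
#' @inheritParams texture_features
#' @return A tibble with one row per tile and distance: `tile`, `tile_row`,
#'   `tile_col`, `d`, `entropy`, `contrast`, `energy`, `homogeneity`.
#' @export
tile_features <- function(image, d, rows = 4L, cols = 4L,
                          tile_height = NULL, tile_width = NULL,
                          directions = c(0, 45, 90, 135), symmetric = TRUE,
                          n_levels = 256L, base = exp(1), strict = FALSE) {
  tiles <- tile_image(image, rows, cols, tile_height, tile_width, strict)
  g <- attr(tiles, "grid")
  purrr::imap_dfr(tiles, function(tl, k) {
    dplyr::bind_cols(
      tibble::tibble(
        tile = as.integer(k),
        tile_row = as.integer((k - 1L) %/% g["cols"]),
        tile_col = as.integer((k - 1L) %% g["cols"])
      ),
      texture_features(tl, d, directions, symmetric, n_levels, base)
    )
  })
}

#' Per-tile texture indices for a whole study
#'
#' Maps [tile_features()] over every image of a study manifest. The manifest
#' must carry `image_id`, `dose_gy`, `sample_id`, `replicate_id` and either a
#' list-column `image` of [gray_image()] objects (as produced by
#' [generate_study()]) or a `path` column of image files readable by
#' [read_gray_image()].
#'
#' @param manifest A manifest tibble (see above), or a study object from
#'   [generate_study()].
#' @inheritParams tile_features
#' @return A long tibble: manifest columns joined to per-tile indices, one
#'   row per image x tile x distance.
#' @export
study_tile_features <- function(manifest, d, rows = 4L, cols = 4L,
                                directions = c(0, 45, 90, 135),
                                symmetric = TRUE, n_levels = 256L,
                                base = exp(1)) {
  if (inherits(manifest, "synthetic_study")) manifest <- manifest$manifest
  stopifnot(is.data.frame(manifest))
  need <- c("image_id", "dose_gy", "sample_id", "replicate_id")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  get_image <- if ("image" %in% names(manifest)) {
    function(i) manifest$image[[i]]
  } else if ("path" %in% names(manifest)) {
    function(i) read_gray_image(manifest$path[[i]])
  } else {
    stop("manifest needs an `image` list-column or a `path` column",
         call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    feats <- tile_features(get_image(i), d, rows, cols,
                           directions = directions, symmetric = symmetric,
                           n_levels = n_levels, base = base)
    dplyr::bind_cols(
      manifest[rep(i, nrow(feats)), need],
      feats
    )
  })
}
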