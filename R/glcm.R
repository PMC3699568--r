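#' Gray-level co-occurrence matrices and Haralick texture indices
#'
#' The co-occurrence matrix P(i, j) counts pixel pairs at a fixed offset whose
#' gray levels are i and j. Offsets are specified by a distance `d` (pixels)
#' and a direction among 0, 45, 90 and 135 degrees; with `symmetric = TRUE`
#' (the Haralick convention, and the default) both orderings of each pair are
#' accumulated, so the matrix equals its transpose. Normalizing by the total
#' pair count turns counts into the joint probability p(i, j), from which the
#' four texture indices are computed.
#'
#' Direction-to-offset convention (x = column, y = row, rows increasing
#' downward): 0 deg -> (dx, dy) = (d, 0); 45 deg -> (d, -d); 90 deg ->
#' (0, -d); 135 deg -> (-d, -d). Under symmetric counting the sign convention
#' is observationally irrelevant; it is fixed for reproducibility.
#'
#' @name glcm-module
NULL

.dir_offsets <- list(
  # (drow, dcol); row index increases downward so dy = drow
  `0`   = c(0L, 1L),
  `45`  = c(-1L, 1L),
  `90`  = c(-1L, 0L),
  `135` = c(-1L, -1L)
)

.check_direction <- function(direction) {
  key <- as.character(as.integer(direction))
  if (!key %in% names(.dir_offsets)) {
    stop("`direction` must be one of 0, 45, 90, 135 degrees", call. = FALSE)
  }
  key
}

.check_levels <- function(image, n_levels) {
  mx <- max(image)
  if (mx >= n_levels) {
    stop(sprintf(
      "gray level %d out of range for n_levels = %d (levels must be 0..%d)",
      mx, n_levels, n_levels - 1L
    ), call. = FALSE)
  }
}

new_glcm <- function(m, n_levels, d, directions, symmetric, normalized,
                     total_pairs) {
  structure(m,
            n_levels = n_levels, d = d, directions = directions,
            symmetric = symmetric, normalized = normalized,
            total_pairs = total_pairs,
            class = c("glcm", "matrix", "array"))
}

#' @export
print.glcm <- function(x, ...) {
  a <- attributes(x)
  cat(sprintf(
    "<glcm> %d levels, d = %d, directions = %s, %s, %s, %d pairs\n",
    a$n_levels, a$d, paste(a$directions, collapse = "/"),
    if (a$symmetric) "symmetric" else "asymmetric",
    if (a$normalized) "normalized" else "counts", a$total_pairs
  ))
  invisible(x)
}

#' Compute a gray-level co-occurrence matrix (counts)
#'
#' Counts every in-bounds pixel pair at offset distance `d` along one
#' direction; pairs with either endpoint outside the raster are skipped. With
#' `symmetric = TRUE` each pair contributes in both orderings, doubling the
#' total count and making the matrix symmetric.
#'
#' @param image A [gray_image()] (or integer matrix) with levels in
#'   `0..n_levels - 1`.
#' @param d Offset distance in pixels (positive integer).
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param symmetric Accumulate both pair orderings (default `TRUE`).
#' @param n_levels Number of gray levels Ng (default 256 for 8-bit input).
#' @return An unnormalized `glcm`: an `n_levels x n_levels` count matrix with
#'   a `total_pairs` attribute. An offset admitting no valid pair is an
#'   error, never an all-zero matrix.
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2))
#' glcm(img, d = 1, direction = 0, n_levels = 2)
#' @export
glcm <- function(image, d, direction, symmetric = TRUE, n_levels = 256L) {
  image <- as_gray_image(image)
  stopifnot(length(d) == 1L, d == floor(d))
  d <- as.integer(d)
  if (d < 1L) stop("`d` must be a positive integer", call. = FALSE)
  key <- .check_direction(direction)
  .check_levels(image, n_levels)

  off <- .dir_offsets[[key]] * d
  drow <- off[1L]; dcol <- off[2L]
  nr <- nrow(image); nc <- ncol(image)
  r1 <- max(1L, 1L - drow):min(nr, nr - drow)
  c1 <- max(1L, 1L - dcol):min(nc, nc - dcol)
  if (max(1L, 1L - drow) > min(nr, nr - drow) ||
      max(1L, 1L - dcol) > min(nc, nc - dcol)) {
    stop(sprintf(
      "no valid pixel pairs for d = %d, direction = %s on a %d x %d image",
      d, key, nr, nc
    ), call. = FALSE)
  }
  i <- as.vector(image[r1, c1, drop = FALSE])
  j <- as.vector(image[r1 + drow, c1 + dcol, drop = FALSE])
  counts <- matrix(
    tabulate(i + as.numeric(n_levels) * j + 1, nbins = n_levels^2),
    n_levels, n_levels
  )
  if (symmetric) counts <- counts + t(counts)
  new_glcm(counts,
           n_levels = as.integer(n_levels), d = d, directions = as.integer(key),
           symmetric = symmetric, normalized = FALSE,
           total_pairs = sum(counts))
}

#' Normalize a co-occurrence matrix to a joint probability
#'
#' Divides the count matrix by its total pair count so entries sum to 1 and
#' each entry is the probability of the corresponding gray-level pair.
#'
#' @param counts An unnormalized [glcm()].
#' @return A normalized `glcm` summing to 1.
#' @export
glcm_normalize <- function(counts) {
  if (!inherits(counts, "glcm")) stop("`counts` must be a glcm", call. = FALSE)
  a <- attributes(counts)
  if (isTRUE(a$normalized)) return(counts)
  tot <- a$total_pairs
  if (!isTRUE(tot > 0)) stop("cannot normalize a glcm with zero pairs", call. = FALSE)
  new_glcm(unclass(counts) / tot,
           n_levels = a$n_levels, d = a$d, directions = a$directions,
           symmetric = a$symmetric, normalized = TRUE, total_pairs = tot)
}

#' Direction-averaged normalized co-occurrence matrix
#'
#' Computes the normalized GLCM for each requested direction and returns
#' their element-wise mean. SEM micrographs of gel fibers are isotropic, so
#' the four-direction average (the default) removes any directional bias.
#'
#' @inheritParams glcm
#' @param directions Subset of `c(0, 45, 90, 135)`, non-empty.
#' @return A normalized, direction-averaged `glcm` summing to 1.
#' @export
glcm_average <- function(image, d, directions = c(0, 45, 90, 135),
                         symmetric = TRUE, n_levels = 256L) {
  if (length(directions) < 1L) stop("`directions` must be non-empty", call. = FALSE)
  image <- as_gray_image(image)
  mats <- lapply(directions, function(th) {
    unclass(glcm_normalize(glcm(image, d, th, symmetric, n_levels)))
  })
  avg <- Reduce(`+`, mats) / length(mats)
  new_glcm(avg,
           n_levels = as.integer(n_levels), d = as.integer(d),
           directions = as.integer(directions), symmetric = symmetric,
           normalized = TRUE, total_pairs = NA_integer_)
}

# (i - j)^2 over all cells of an Ng x Ng matrix, cached per Ng
.texdose_cache <- new.env(parent = emptyenv())
.diff2 <- function(n_levels) {
  key <- as.character(n_levels)
  if (is.null(.texdose_cache[[key]])) {
    idx <- seq_len(n_levels) - 1L
    .texdose_cache[[key]] <- outer(idx, idx, function(i, j) (i - j)^2)
  }
  .texdose_cache[[key]]
}

#' Haralick texture indices of a normalized co-occurrence matrix
#'
#' Computes the four second-order texture statistics used as dose indices:
#' * entropy `-sum p log p` (randomness of the gray-level pair distribution;
#'   zero cells contribute 0),
#' * contrast `sum (i - j)^2 p` (local intensity variation),
#' * energy `sum p^2` (uniformity of pair patterns),
#' * homogeneity `sum p / (1 + (i - j)^2)` (inverse difference moment; large
#'   when neighboring pixels are similar).
#'
#' @param p A normalized [glcm()] (e.g. from [glcm_average()]).
#' @param base Logarithm base for entropy; natural log by default.
#' @return A one-row tibble with columns `entropy`, `contrast`, `energy`,
#'   `homogeneity`.
#' @export
texture_indices <- function(p, base = exp(1)) {
  if (!inherits(p, "glcm")) stop("`p` must be a glcm", call. = FALSE)
  if (!isTRUE(attr(p, "normalized"))) {
    stop("`p` must be normalized; see glcm_normalize()", call. = FALSE)
  }
  n_levels <- attr(p, "n_levels")
  d2 <- .diff2(n_levels)
  pv <- as.vector(unclass(p))
  d2v <- as.vector(d2)
  nz <- pv > 0
  pnz <- pv[nz]
  tibble::tibble(
    entropy = -sum(pnz * log(pnz)) / log(base),
    contrast = sum(d2v * pv),
    energy = sum(pv * pv),
    homogeneity = sum(pv / (1 + d2v))
  )
}

#' Texture indices of an image over one or more offset distances
#'
#' Convenience wrapper: for each distance in `d`, builds the
#' direction-averaged normalized GLCM of the whole image and computes the
#' four texture indices.
#'
#' @inheritParams glcm_average
#' @param d Vector of offset distances (pixels).
#' @param base Entropy logarithm base.
#' @return A tibble with one row per distance: columns `d`, `entropy`,
#'   `contrast`, `energy`, `homogeneity`.
#' @examples
#' img <- gray_image(matrix(sample(0:255, 900, replace = TRUE), 30, 30))
#' texture_features(img, d = c(1, 2))
#' @export
texture_features <- function(image, d, directions = c(0, 45, 90, 135),
                             symmetric = TRUE, n_levels = 256L,
                             base = exp(1)) {
  image <- as_gray_image(image)
  purrr::map_dfr(d, function(dd) {
    p <- glcm_average(image, dd, directions, symmetric, n_levels)
    dplyr::bind_cols(tibble::tibble(d = as.integer(dd)),
                     texture_indices(p, base = base))
  })
}
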