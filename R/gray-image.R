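#' Gray-level image
#'
#' Wraps a 2-D integer intensity raster (rows = image height N, columns =
#' width M) as a `gray_image`, the input type of all texture computations.
#' Intensities must be non-negative integers; for 8-bit SEM micrographs they
#' lie in 0..255. Physical scale metadata (pixel size, magnification label)
#' travels with the image but never changes any computation.
#'
#' @param pixels Numeric matrix of integer-valued intensities, `>= 0`.
#' @param pixel_size Optional physical edge length of one pixel, in meters
#'   (e.g. `125.94e-9` for a 500x SEM scan).
#' @param magnification Optional free-text magnification tag (e.g. `"500x"`).
#' @return A `gray_image`: an integer matrix with `pixel_size` and
#'   `magnification` attributes.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2))
#' dim(img)
#' @export
gray_image <- function(pixels, pixel_size = NULL, magnification = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` contains missing values", call. = FALSE)
  if (any(pixels != floor(pixels))) {
    stop("`pixels` must hold integer gray levels", call. = FALSE)
  }
  if (any(pixels < 0)) stop("gray levels must be >= 0", call. = FALSE)
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  }
  structure(
    matrix(as.integer(pixels), nrow(pixels), ncol(pixels)),
    pixel_size = pixel_size,
    magnification = magnification,
    class = c("gray_image", "matrix", "array")
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, levels %d..%d%s%s\n",
    nrow(x), ncol(x), min(x), max(x),
    if (!is.null(attr(x, "pixel_size"))) {
      sprintf(", pixel %.4g m", attr(x, "pixel_size"))
    } else "",
    if (!is.null(attr(x, "magnification"))) {
      paste0(", ", attr(x, "magnification"))
    } else ""
  ))
  invisible(x)
}

#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

as_gray_image <- function(x, ...) {
  if (is_gray_image(x)) x else gray_image(as.matrix(x), ...)
}

#' Requantize gray levels onto a coarser fixed-range scale
#'
#' Maps the fixed 8-bit range 0..255 linearly onto `0..n_levels - 1`
#' (`floor(g * n_levels / 256)`). The mapping is fixed-range rather than
#' min-max so that tiles cut from one micrograph share a common gray scale.
#'
#' @param image A [gray_image()] with intensities in 0..255.
#' @param n_levels Target number of gray levels (2..256).
#' @return A [gray_image()] with intensities in `0..n_levels - 1`.
#' @export
requantize <- function(image, n_levels) {
  image <- as_gray_image(image)
  stopifnot(n_levels >= 2, n_levels <= 256)
  if (max(image) > 255L) {
    stop("requantize() expects 8-bit input (levels 0..255)", call. = FALSE)
  }
  q <- matrix(as.integer(floor(as.numeric(image) * n_levels / 256)),
              nrow(image), ncol(image))
  gray_image(q,
             pixel_size = attr(image, "pixel_size"),
             magnification = attr(image, "magnification"))
}

#' Physical field of view of a micrograph
#'
#' Area covered by the raster, `(N * pixel_size) * (M * pixel_size)`,
#' expressed in square millimeters. Requires `pixel_size` (meters) to be
#' attached to the image.
#'
#' @param image A [gray_image()] carrying a `pixel_size` attribute.
#' @return Field of view in mm^2.
#' @examples
#' img <- gray_image(matrix(0L, 1200, 1600), pixel_size = 1.26e-6)
#' field_of_view(img) # ~3.05 mm^2
#' @export
field_of_view <- function(image) {
  ps <- attr(image, "pixel_size")
  if (is.null(ps)) {
    stop("image has no `pixel_size`; attach one via gray_image()", call. = FALSE)
  }
  (nrow(image) * ps * 1e3) * (ncol(image) * ps * 1e3)
}
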