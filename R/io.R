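#' Read an 8-bit grayscale micrograph
#'
#' Loads a PNG or TIFF file as a [gray_image()]. Input must be
#' single-channel 8-bit; 16-bit files are rejected unless
#' `allow_16bit = TRUE` (which rescales to 8 bits), and multi-channel files
#' are rejected unless `luminance = TRUE`, in which case the fixed Rec. 601
#' weights (0.299, 0.587, 0.114) collapse RGB to luminance.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param luminance Allow RGB input, converting by Rec. 601 luminance.
#' @param allow_16bit Allow 16-bit input, rescaling onto 0..255.
#' @param pixel_size,magnification Optional metadata attached to the image.
#' @return A [gray_image()] with levels 0..255.
#' @export
read_gray_image <- function(path, luminance = FALSE, allow_16bit = FALSE,
                            pixel_size = NULL, magnification = NULL) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path, info = TRUE)
    bits <- attr(arr, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
  } else {
    stop(sprintf("unsupported image format `.%s` (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  if (!is.null(bits) && bits > 8 && !allow_16bit) {
    stop(sprintf("%d-bit input: pass allow_16bit = TRUE to rescale to 8 bits",
                 bits), call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (!luminance) {
      stop(sprintf("%d-channel input: pass luminance = TRUE to convert via Rec. 601 weights",
                   nch), call. = FALSE)
    }
    if (nch < 3L) arr <- arr[, , 1L] else {
      message("converting RGB to luminance (Rec. 601 weights 0.299/0.587/0.114)")
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    }
  }
  gray_image(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)),
             pixel_size = pixel_size, magnification = magnification)
}

#' Write a gray image to PNG or TIFF
#'
#' @param image A [gray_image()] with levels 0..255.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  if (max(image) > 255L) stop("image exceeds 8-bit range", call. = FALSE)
  m <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L)
  } else {
    stop(sprintf("unsupported image format `.%s` (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Read / write a study manifest
#'
#' A manifest is the CSV table binding image files to their study metadata:
#' columns `path`, `dose_gy`, `sample_id`, `replicate_id`, and optionally
#' `magnification` and `seed`. `image_id` is derived from the file name when
#' absent.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: a tibble; `write_manifest()`: `path`,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "dose_gy", "sample_id", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$dose_gy < 0)) stop("manifest has negative doses", call. = FALSE)
  if (!"image_id" %in% names(df)) {
    df$image_id <- tools::file_path_sans_ext(basename(df$path))
  }
  # resolve image paths relative to the manifest's directory
  rel <- !file.exists(df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(is.data.frame(manifest))
  cols <- intersect(c("image_id", "path", "dose_gy", "sample_id",
                      "replicate_id", "magnification", "seed"),
                    names(manifest))
  utils::write.csv(as.data.frame(manifest[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Renders every image of a [generate_study()] result to 8-bit files and
#' writes the accompanying `manifest.csv`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return The manifest tibble (with a `path` column), invisibly.
#' @export
write_study <- function(study, dir, format = c("png", "tiff")) {
  stopifnot(inherits(study, "synthetic_study"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- study$manifest
  m$path <- file.path(dir, sprintf("%s.%s", m$image_id, format))
  purrr::walk2(m$image, m$path, write_gray_image)
  out <- m[, c("image_id", "path", "dose_gy", "sample_id", "replicate_id",
               "seed")]
  write_manifest(out, file.path(dir, "manifest.csv"))
  invisible(out)
}

#' Save / load a calibration record
#'
#' The calibration JSON carries everything needed to invert doses later:
#' index name, magnification tag, (d, e), slope, intercept, R^2, raw
#' sensitivity, the number of dose levels and the package version. Reading
#' it back yields a `drc` usable with [invert_dose()] and
#' [estimate_doses()].
#'
#' @param curve A `drc` from [fit_drc()].
#' @param path JSON file path.
#' @return `write_calibration()`: `path`, invisibly; `read_calibration()`:
#'   a `drc`.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "drc"))
  rec <- list(
    index_name = curve$index_name,
    magnification_tag = curve$magnification,
    d = curve$d, e = curve$e,
    slope = curve$slope, intercept = curve$intercept,
    r_squared = curve$r_squared, sensitivity_raw = curve$sensitivity,
    n_dose_levels = curve$n_dose_levels,
    tool_version = as.character(utils::packageVersion("texdose"))
  )
  # 17 significant digits: doubles survive the decimal round trip bit-exactly
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path),
                               call. = FALSE)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("slope", "intercept")
  if (!all(need %in% names(rec))) {
    stop("calibration record lacks slope/intercept", call. = FALSE)
  }
  null2na <- function(x, cast = identity) if (is.null(x)) cast(NA) else cast(x)
  structure(
    list(
      slope = rec$slope, intercept = rec$intercept,
      r_squared = null2na(rec$r_squared, as.numeric),
      sensitivity = abs(rec$slope),
      index_name = null2na(rec$index_name, as.character),
      magnification = null2na(rec$magnification_tag, as.character),
      d = null2na(rec$d, as.integer), e = null2na(rec$e, as.integer),
      n_dose_levels = null2na(rec$n_dose_levels, as.integer),
      points = NULL, fit = NULL
    ),
    class = "drc"
  )
}
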