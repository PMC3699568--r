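#' Configuration of the synthetic SEM texture generator
#'
#' The generator emulates 8-bit SEM-like micrographs of a freeze-dried
#' polymer gel: a field of randomly oriented bright fiber segments on a dim
#' background, isotropically smoothed by an amount that grows with absorbed
#' dose (polymerization makes the real micrographs smoother), plus detector
#' noise and occasional bright impurity blobs. It is a texture emulator, not
#' a physical model of polymerization.
#'
#' The dose-to-blur mapping (`smoothing_law`) defaults to the linear law
#' `sigma = sigma0 + sigma_per_gy * dose` (pixels); it must be strictly
#' increasing over `dose_levels`. The default constants are tuned so the
#' four-direction homogeneity of the rendered textures responds close to
#' linearly over 0-20 Gy, mirroring the near-linear dose response of the
#' real readout.
#'
#' @param image_height,image_width Raster size in pixels (default the full
#'   1200 x 1600 micrograph; tests and the bundled end-to-end check use a
#'   300 x 400 single-tile size for speed).
#' @param dose_levels Dose levels of a study, Gy.
#' @param fiber_count Number of fiber segments; default scales with area
#'   (one fiber per 150 px^2, a densely overlapping field whose statistics
#'   are stable from tile to tile).
#' @param fiber_length_range,fiber_width_range Fiber segment length and
#'   full width (diameter) ranges, pixels. At the 125.94 nm pixel size of a
#'   500x scan the defaults correspond to strands of about 2.5-10 um by
#'   0.5-1.8 um, the fine end of the fiber dimensions seen in gel
#'   micrographs; fine, numerous fibers keep single tiles statistically
#'   representative.
#' @param fiber_amp_range Range of the additive intensity of one fiber, on
#'   the 0..1 scale.
#' @param smoothing_law Function dose (Gy) -> Gaussian blur sigma (pixels);
#'   default linear, see above.
#' @param sigma0,sigma_per_gy Constants of the default linear smoothing law.
#' @param roughness_sd Pixel-scale surface roughness of the unsmoothed
#'   fiber field (additive white noise applied before the dose-dependent
#'   smoothing), on the 0..1 intensity scale. This is what the dose "heals":
#'   smoothing attenuates it, so homogeneity grows with dose.
#' @param noise_sd Additive Gaussian detector noise applied after
#'   smoothing, on the 0..1 scale (0.01 is about 2.5 gray levels); it is
#'   dose-independent and sets the noise floor of the texture indices.
#' @param impurity_rate Expected number of bright impurity blobs per image
#'   (Poisson).
#' @param seed Default master seed for studies generated from this config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(image_height = 1200L, image_width = 1600L,
                         dose_levels = c(0, 5, 10, 15, 20),
                         fiber_count = NULL,
                         fiber_length_range = c(20, 80),
                         fiber_width_range = c(4, 14),
                         fiber_amp_range = c(0.008, 0.025),
                         smoothing_law = NULL,
                         sigma0 = 1.6, sigma_per_gy = 0.16,
                         roughness_sd = 0.3,
                         noise_sd = 0.01, impurity_rate = 0.3,
                         seed = 1L) {
  stopifnot(image_height >= 2, image_width >= 2,
            length(dose_levels) >= 1, all(dose_levels >= 0),
            all(fiber_length_range > 0), all(fiber_width_range > 0),
            length(fiber_length_range) == 2, length(fiber_width_range) == 2,
            length(fiber_amp_range) == 2, all(fiber_amp_range > 0),
            roughness_sd >= 0, noise_sd >= 0, impurity_rate >= 0)
  if (is.null(fiber_count)) {
    fiber_count <- max(10L, round(image_height * image_width / 75))
  }
  if (is.null(smoothing_law)) {
    force(sigma0); force(sigma_per_gy)
    smoothing_law <- function(dose) sigma0 + sigma_per_gy * dose
  }
  doses <- sort(unique(dose_levels))
  sig <- vapply(doses, smoothing_law, numeric(1))
  if (length(sig) > 1 && any(diff(sig) <= 0)) {
    stop("`smoothing_law` must be strictly increasing over `dose_levels`",
         call. = FALSE)
  }
  if (any(sig <= 0)) stop("`smoothing_law` must be positive", call. = FALSE)
  structure(
    list(image_height = as.integer(image_height),
         image_width = as.integer(image_width),
         dose_levels = dose_levels,
         fiber_count = as.integer(fiber_count),
         fiber_length_range = fiber_length_range,
         fiber_width_range = fiber_width_range,
         fiber_amp_range = fiber_amp_range,
         smoothing_law = smoothing_law,
         roughness_sd = roughness_sd,
         noise_sd = noise_sd, impurity_rate = impurity_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Deterministic sub-seed in 1..2^31-1 from a sequence of integer tags.
derive_seed <- function(...) {
  v <- as.numeric(c(...))
  h <- 0
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  as.integer(h) + 1L
}

# Anti-aliased capsule (segment with radius) patch: returns the bounding-box
# rows/cols and the additive intensity profile, or NULL when fully outside.
# The caller adds patches in place, so stamping thousands of fibers does not
# copy the canvas.
.capsule_patch <- function(nr, nc, r0, c0, angle, len, radius, amp, aa = 1) {
  dr <- sin(angle) * len / 2; dc <- cos(angle) * len / 2
  ra <- r0 - dr; ca <- c0 - dc; rb <- r0 + dr; cb <- c0 + dc
  pad <- radius + aa
  rlo <- max(1L, floor(min(ra, rb) - pad)); rhi <- min(nr, ceiling(max(ra, rb) + pad))
  clo <- max(1L, floor(min(ca, cb) - pad)); chi <- min(nc, ceiling(max(ca, cb) + pad))
  if (rlo > rhi || clo > chi) return(NULL)
  rr <- rlo:rhi; cc <- clo:chi
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  # distance from each pixel to the segment a-b
  vr <- rb - ra; vc <- cb - ca
  l2 <- vr * vr + vc * vc
  t <- if (l2 > 0) pmin(1, pmax(0, ((pr - ra) * vr + (pc - ca) * vc) / l2)) else 0
  dist <- sqrt((pr - (ra + t * vr))^2 + (pc - (ca + t * vc))^2)
  list(rr = rr, cc = cc,
       prof = amp * pmin(1, pmax(0, (radius + aa - dist) / aa)))
}

# Gaussian blob patch (impurity artifact).
.blob_patch <- function(nr, nc, r0, c0, radius, amp) {
  pad <- ceiling(3 * radius)
  rlo <- max(1L, floor(r0 - pad)); rhi <- min(nr, ceiling(r0 + pad))
  clo <- max(1L, floor(c0 - pad)); chi <- min(nc, ceiling(c0 + pad))
  if (rlo > rhi || clo > chi) return(NULL)
  rr <- rlo:rhi; cc <- clo:chi
  pr <- matrix(rr, length(rr), length(cc))
  pc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  d2 <- (pr - r0)^2 + (pc - c0)^2
  list(rr = rr, cc = cc, prof = amp * exp(-d2 / (2 * radius^2)))
}

#' Render one dose-dependent synthetic micrograph
#'
#' Renders the fiber field, applies the dose-dependent Gaussian smoothing,
#' adds intensity noise, stamps impurity blobs (drawn Poisson with mean
#' `impurity_rate`), clips to the unit range and quantizes to 8 bits. The
#' output is a pure function of `(dose, config, seed)`.
#'
#' @param dose Absorbed dose, Gy (`>= 0`).
#' @param config A [synth_config()].
#' @param seed Integer seed for this image.
#' @return A [gray_image()] of size `image_height x image_width`, levels
#'   0..255.
#' @examples
#' cfg <- synth_config(image_height = 60, image_width = 80, fiber_count = 6)
#' img <- generate_texture(5, cfg, seed = 1)
#' @export
generate_texture <- function(dose, config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), dose >= 0)
  set.seed(seed)
  H <- config$image_height; W <- config$image_width
  canvas <- matrix(0.3, H, W)
  for (k in seq_len(config$fiber_count)) {
    r0 <- stats::runif(1, 1, H)
    c0 <- stats::runif(1, 1, W)
    angle <- stats::runif(1, 0, pi)
    len <- stats::runif(1, config$fiber_length_range[1],
                        config$fiber_length_range[2])
    radius <- stats::runif(1, config$fiber_width_range[1],
                           config$fiber_width_range[2]) / 2
    amp <- stats::runif(1, config$fiber_amp_range[1],
                        config$fiber_amp_range[2])
    p <- .capsule_patch(H, W, r0, c0, angle, len, radius, amp)
    if (!is.null(p)) canvas[p$rr, p$cc] <- canvas[p$rr, p$cc] + p$prof
  }
  canvas <- pmin(canvas, 1.2) # clip extreme fiber overlap before smoothing
  if (config$roughness_sd > 0) {
    canvas <- canvas + stats::rnorm(H * W, 0, config$roughness_sd)
  }
  sigma <- config$smoothing_law(dose)
  # cap the kernel so very small rasters (test sizes) remain blurrable
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                min(H, W) - 1L + (min(H, W) %% 2L))
  canvas <- EBImage::gblur(canvas, sigma = sigma, radius = radius)
  if (config$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(H * W, 0, config$noise_sd)
  }
  n_blobs <- stats::rpois(1, config$impurity_rate)
  for (k in seq_len(n_blobs)) {
    p <- .blob_patch(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                     radius = stats::runif(1, 8, 16),
                     amp = stats::runif(1, 0.5, 0.8))
    if (!is.null(p)) canvas[p$rr, p$cc] <- canvas[p$rr, p$cc] + p$prof
  }
  px <- pmin(pmax(canvas, 0), 1)
  gray_image(matrix(as.integer(round(px * 255)), H, W))
}

#' Generate a full synthetic study
#'
#' Builds the image set of one of the three study layouts:
#' * `screening`: one image per dose level,
#' * `calibration`: four sample tubes per dose level, one image each,
#' * `verification`: four sample tubes per non-zero dose level, three
#'   images each (12 images per dose).
#'
#' Per-image seeds are derived deterministically from
#' `(seed, dose index, sample, replicate)`, so any single image can be
#' regenerated without rebuilding the study.
#'
#' @param config A [synth_config()].
#' @param design `"screening"`, `"calibration"` or `"verification"`.
#' @param seed Master seed; defaults to the config's.
#' @return A `synthetic_study`: list with `manifest` (tibble `image_id`,
#'   `dose_gy`, `sample_id`, `replicate_id`, `seed`, and list-column
#'   `image`), `design`, `config`, `seed`.
#' @export
generate_study <- function(config, design = c("calibration", "screening",
                                              "verification"),
                           seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  design <- match.arg(design)
  doses <- sort(unique(config$dose_levels))
  if (design == "verification") doses <- doses[doses > 0]
  n_samples <- switch(design, screening = 1L, calibration = 4L,
                      verification = 4L)
  n_reps <- switch(design, screening = 1L, calibration = 1L,
                   verification = 3L)
  layout <- tidyr::expand_grid(
    dose_idx = seq_along(doses),
    sample = seq_len(n_samples),
    replicate = seq_len(n_reps)
  )
  manifest <- layout |>
    dplyr::mutate(
      dose_gy = doses[.data$dose_idx],
      sample_id = sprintf("d%02g_s%d", .data$dose_gy, .data$sample),
      replicate_id = .data$replicate,
      seed = purrr::pmap_int(
        list(.data$dose_idx, .data$sample, .data$replicate),
        function(di, s, r) derive_seed(seed, di, s, r)
      ),
      image_id = sprintf("%s_r%d", .data$sample_id, .data$replicate)
    )
  manifest$image <- purrr::map2(manifest$dose_gy, manifest$seed,
                                function(dg, sd) generate_texture(dg, config, sd))
  structure(
    list(manifest = manifest[, c("image_id", "dose_gy", "sample_id",
                                 "replicate_id", "seed", "image")],
         design = design, config = config, seed = as.integer(seed)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %s design: %d images (%d x %d px), doses %s Gy\n",
              x$design, nrow(x$manifest), x$config$image_height,
              x$config$image_width,
              paste(sort(unique(x$manifest$dose_gy)), collapse = "/")))
  invisible(x)
}

#' End-to-end dose recovery on synthetic studies
#'
#' The self-test of the whole pipeline: generates an independent calibration
#' study and verification study from one config, optimizes (e, d) on the
#' calibration study, fits the dose-response curve, estimates the doses of
#' the verification images, and reports the per-dose mean percentage error.
#'
#' @param config A [synth_config()].
#' @param seed Master seed; calibration and verification studies use
#'   sub-seeds derived from it.
#' @param index Texture index used as the dose index (default homogeneity).
#' @param d_values Offset distances scanned during optimization.
#' @param e_values Exclusion counts scanned during optimization.
#' @param min_norm_sensitivity Sensitivity floor for [select_optimum()].
#' @param r2_floor Calibration R^2 below which the report flags failure.
#' @return A `recovery_report`: list with the `maps`, chosen `e`/`d`,
#'   `curve`, `r_squared`, per-dose `report` tibble, `mean_pct_error`,
#'   `max_abs_pct_error` and `calibration_ok`.
#' @export
end_to_end_recovery <- function(config, seed = config$seed,
                                index = "homogeneity",
                                d_values = seq(2L, 30L, by = 4L),
                                e_values = 0:2,
                                min_norm_sensitivity = 0.5,
                                r2_floor = 0.9) {
  cal <- generate_study(config, "calibration", seed = derive_seed(seed, 101))
  feats <- study_tile_features(cal, d = d_values)
  maps <- build_parameter_maps(feats, index = index, e_values = e_values)
  opt <- select_optimum(maps, min_norm_sensitivity = min_norm_sensitivity)
  ver <- generate_study(config, "verification", seed = derive_seed(seed, 202))
  vfeats <- study_tile_features(ver, d = opt$d)
  est <- estimate_doses(vfeats, opt$curve)
  rep <- dose_report(est)
  structure(
    list(maps = maps, e = opt$e, d = opt$d, curve = opt$curve,
         r_squared = opt$curve$r_squared, estimates = est, report = rep,
         mean_pct_error = mean(rep$percentage_error, na.rm = TRUE),
         max_abs_pct_error = max(abs(rep$percentage_error), na.rm = TRUE),
         calibration_ok = opt$curve$r_squared >= r2_floor,
         seed = seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> index %s, optimum e = %d, d = %d, R^2 = %.4f%s\n",
              x$curve$index_name, x$e, x$d, x$r_squared,
              if (x$calibration_ok) "" else " [calibration FAILED floor]"))
  print(x$report)
  cat(sprintf("mean percentage error %.2f%%, max |error| %.2f%%\n",
              x$mean_pct_error, x$max_abs_pct_error))
  invisible(x)
}
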