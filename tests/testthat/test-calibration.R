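tbl2_points <- tibble::tibble(
  dose_gy = c(5, 10, 15, 20),
  index_mean = c(0.075, 0.106, 0.131, 0.154)
)

test_that("dose-response fits recover exact and published arithmetic", {
  pts <- tibble::tibble(dose_gy = c(0, 5, 10, 20), index_mean = 2 * c(0, 5, 10, 20) + 1)
  cv <- fit_drc(pts)
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 1)
  expect_equal(cv$r_squared, 1)

  # closed form on the verification-table means: Sxy/Sxx = 0.655/125
  cv2 <- fit_drc(tbl2_points)
  expect_equal(cv2$slope, 0.655 / 125, tolerance = 1e-12)
  expect_equal(cv2$intercept, 0.051, tolerance = 1e-12)
  expect_equal(cv2$sensitivity, abs(cv2$slope))

  # constant response: slope 0, R^2 defined as 0
  cv3 <- fit_drc(tibble::tibble(dose_gy = c(0, 5, 10), index_mean = rep(0.2, 3)))
  expect_equal(cv3$slope, 0)
  expect_equal(cv3$sensitivity, 0)
  expect_equal(cv3$r_squared, 0)

  expect_error(fit_drc(tbl2_points[1:2, ]), "3 distinct dose")
  expect_error(fit_drc(tibble::tibble(dose_gy = rep(5, 4), index_mean = 1:4)),
               "3 distinct dose")
})

test_that("OLS matches the normal equations and R2 is affine-invariant in dose", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    x <- sort(runif(n, 0, 20)); y <- 0.004 * x + 0.05 + rnorm(n, 0, 0.003)
    pts <- tibble::tibble(dose_gy = x, index_mean = y)
    cv <- fit_drc(pts)
    sxy <- sum((x - mean(x)) * (y - mean(y))); sxx <- sum((x - mean(x))^2)
    expect_equal(cv$slope, sxy / sxx, tolerance = 1e-10)
    expect_equal(cv$intercept, mean(y) - sxy / sxx * mean(x), tolerance = 1e-10)
    cv_resc <- fit_drc(tibble::tibble(dose_gy = 3 * x + 7, index_mean = y))
    expect_equal(cv_resc$r_squared, cv$r_squared, tolerance = 1e-10)
  }
})

test_that("tidy and glance expose the fit in broom form", {
  cv <- fit_drc(tbl2_points, index_name = "homogeneity", d = 27L, e = 0L)
  td <- tidy(cv)
  expect_equal(td$term, c("intercept", "dose_gy"))
  expect_equal(td$estimate[2], cv$slope)
  gl <- glance(cv)
  expect_equal(gl$r.squared, cv$r_squared)
  expect_equal(gl$d, 27L)
})

test_that("dose inversion round-trips and guards the degenerate slope", {
  cv <- fit_drc(tbl2_points)
  for (x in c(0, 1.7, 12.3, 20)) {
    expect_equal(invert_dose(cv, cv$slope * x + cv$intercept), x,
                 tolerance = 1e-9)
  }
  expect_equal(invert_dose(list(slope = 0.0052, intercept = 0.051), 0.051), 0)
  expect_error(invert_dose(list(slope = 0, intercept = 0.05), 0.07), "zero")
  expect_warning(neg <- invert_dose(list(slope = 0.01, intercept = 0.05), 0.04),
                 "negative")
  expect_equal(neg, -1)
})

test_that("percentage errors follow the signed definition", {
  expect_equal(percentage_error(4.62, 5), -7.6)
  expect_equal(percentage_error(10.58, 10), 5.8)
  expect_equal(percentage_error(7.5, 7.5), 0)
  expect_error(percentage_error(5, 0), "> 0")
})

test_that("fitted slope and intercept cover the truth across replicates", {
  # known linear law + Gaussian index noise, 4 samples/dose at 0..20 Gy
  set.seed(99)
  a <- 0.005; b <- 0.05; doses <- c(0, 5, 10, 15, 20)
  ok <- 0L; n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    x <- rep(doses, each = 4)
    y <- a * x + b + rnorm(length(x), 0, 0.005)
    cv <- fit_drc(tibble::tibble(dose_gy = x, index_mean = y))
    se <- tidy(cv)$std.error
    hit <- abs(cv$slope - a) <= 3 * se[2] && abs(cv$intercept - b) <= 3 * se[1]
    ok <- ok + hit
  }
  expect_gte(ok / n_rep, 0.95)
})

make_linear_features <- function(doses, d_values, slope_by_d, intercept = 0.05,
                                 n_images = 2, n_tiles = 4, jitter = 0) {
  tidyr::expand_grid(dose_gy = doses, img = seq_len(n_images),
                     tile = seq_len(n_tiles), d = d_values) |>
    dplyr::mutate(
      image_id = sprintf("d%s_i%d", dose_gy, img),
      sample_id = image_id, replicate_id = 1L,
      homogeneity = intercept + slope_by_d[as.character(d)] * dose_gy +
        jitter * sin(seq_along(dose_gy))
    )
}

test_that("parameter maps agree with independent per-cell fits", {
  doses <- c(0, 5, 10, 15, 20)
  slope_by_d <- c(`1` = 0.002, `2` = 0.005)
  feats <- make_linear_features(doses, c(1, 2), slope_by_d, jitter = 1e-4)
  maps <- build_parameter_maps(feats, e_values = 0:1)
  expect_equal(nrow(maps$grid), 4)
  for (i in seq_len(nrow(maps$grid))) {
    cell <- maps$grid[i, ]
    ref <- fit_drc(dose_points(feats[feats$d == cell$d, ], e = cell$e))
    expect_equal(cell$r2, ref$r_squared, tolerance = 1e-12)
    expect_equal(cell$sens_raw, ref$sensitivity, tolerance = 1e-12)
  }
  expect_equal(max(maps$grid$sens_norm), 1)

  # exactly linear, identical tiles: all cells R^2 = 1; normalized
  # sensitivity 1 wherever the slope equals the grid maximum
  flat <- make_linear_features(doses, c(1, 2), c(`1` = 0.004, `2` = 0.004))
  m2 <- build_parameter_maps(flat, e_values = 0:1)
  expect_true(all(abs(m2$grid$r2 - 1) < 1e-9))
  expect_true(all(abs(m2$grid$sens_norm - 1) < 1e-9))

  expect_error(
    build_parameter_maps(make_linear_features(5, 1, c(`1` = 0.002))),
    "3 distinct dose"
  )
})

test_that("optimum selection honors the sensitivity floor and tie-breaks", {
  doses <- c(0, 5, 10, 15, 20)
  # d = 1: perfectly linear but weak slope; d = 2: strong slope, slightly bent
  feats <- tidyr::expand_grid(dose_gy = doses, img = 1:2, tile = 1:4,
                              d = c(1L, 2L)) |>
    dplyr::mutate(
      image_id = sprintf("d%s_i%d", dose_gy, img),
      sample_id = image_id, replicate_id = 1L,
      homogeneity = ifelse(d == 1, 0.05 + 0.001 * dose_gy,
                           0.05 + 0.01 * dose_gy + 2e-4 * (dose_gy / 20)^2)
    )
  maps <- build_parameter_maps(feats, e_values = 0:1)
  opt <- select_optimum(maps, min_norm_sensitivity = 0.5)
  expect_equal(opt$d, 2L) # the d = 1 cells (R^2 = 1) fall below the floor
  expect_lt(opt$curve$r_squared, 1)

  # all-equal map: ties resolve to the smallest d, then smallest e
  flat <- make_linear_features(doses, c(1, 2), c(`1` = 0.004, `2` = 0.004))
  opt2 <- select_optimum(build_parameter_maps(flat, e_values = 0:1))
  expect_equal(c(opt2$e, opt2$d), c(0L, 1L))

  # zero-slope map: nothing passes the floor
  zero <- make_linear_features(doses, 1, c(`1` = 0))
  expect_error(select_optimum(build_parameter_maps(zero, e_values = 0:1)),
               "best rejected")
})

test_that("sensitivity crossing distances interpolate linearly", {
  fake <- function(e_values, d_values, rows) {
    structure(list(
      grid = tidyr::expand_grid(e = e_values, d = d_values) |>
        dplyr::mutate(sens_norm = unlist(rows)),
      e_values = e_values, d_values = d_values
    ), class = "parameter_maps")
  }
  m <- fake(0L, c(1L, 2L, 3L), list(c(0.5, 0.9, 1)))
  expect_equal(distance_at_sensitivity(m, 0.9), 2)
  m2 <- fake(0L, c(1L, 2L), list(c(0.5, 1)))
  expect_equal(distance_at_sensitivity(m2, 0.75), 1.5)
  m3 <- fake(c(0L, 1L), c(1L, 2L, 3L),
             list(c(0.5, 0.9, 1), c(0.2, 0.6, 0.9)))
  expect_equal(distance_at_sensitivity(m3, 0.9), 2.5)
  expect_warning(v <- distance_at_sensitivity(m3, 0.95), "excluded")
  expect_equal(v, 2.5) # only the first row reaches 0.95

  m4 <- fake(0L, c(1L, 2L), list(c(0.1, 0.2)))
  expect_error(distance_at_sensitivity(m4, 0.9), "no e-row")
})

test_that("an idealized linear index law inverts with negligible error", {
  # the noiseless limit of the pipeline: indices exactly linear in dose
  doses <- c(0, 5, 10, 15, 20)
  feats <- make_linear_features(doses, 10L, c(`10` = 0.005), n_images = 4)
  curve <- fit_drc(dose_points(feats), index_name = "homogeneity", d = 10L,
                   e = 0L)
  ver <- make_linear_features(c(5, 10, 15, 20), 10L, c(`10` = 0.005),
                              n_images = 3)
  rep <- dose_report(estimate_doses(ver, curve))
  expect_true(all(abs(rep$percentage_error) < 0.1))
})
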