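test_that("pair counting matches hand-enumerated examples", {
  # constant 2x2 image: two horizontal pairs, both orderings
  g <- glcm(gray_image(matrix(5L, 2, 2)), d = 1, direction = 0)
  expect_equal(unclass(g)[6, 6], 4)
  expect_equal(attr(g, "total_pairs"), 4)
  expect_equal(sum(g), 4)

  # rows [[0,1],[0,1]]: columns 0 then 1
  img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  g <- glcm(img, d = 1, direction = 0, n_levels = 2)
  expect_equal(unclass(g), matrix(c(0, 2, 2, 0), 2, 2), ignore_attr = TRUE)

  # offset exceeding width - 1: no valid pairs is an error
  expect_error(glcm(img, d = 2, direction = 0, n_levels = 2),
               "no valid pixel pairs")
})

test_that("out-of-range intensities and bad arguments are rejected by name", {
  img <- gray_image(matrix(c(0L, 3L, 200L, 1L), 2, 2))
  expect_error(glcm(img, 1, 0, n_levels = 8), "200")
  expect_error(glcm(img, 0, 0), "positive")
  expect_error(glcm(img, 1, 30), "direction")
})

test_that("normalization preserves proportions and sums to one", {
  img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  p <- glcm_normalize(glcm(img, 1, 0, n_levels = 2))
  expect_equal(unclass(p), matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_error(glcm_normalize(matrix(1, 2, 2)), "glcm")

  p1 <- glcm_normalize(glcm(gray_image(matrix(5L, 2, 2)), 1, 0))
  expect_equal(unclass(p1)[6, 6], 1)
})

test_that("texture indices reproduce closed-form values", {
  # constant image: the degenerate extreme (0, 0, 1, 1)
  ti <- texture_indices(glcm_normalize(glcm(gray_image(matrix(5L, 3, 3)), 1, 0)))
  expect_equal(unlist(ti), c(entropy = 0, contrast = 0, energy = 1,
                             homogeneity = 1))

  # p = 0.5 at (0,1) and (1,0)
  img <- gray_image(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  p <- glcm_normalize(glcm(img, 1, 0, n_levels = 2))
  ti <- texture_indices(p)
  expect_equal(ti$entropy, log(2))
  expect_equal(ti$contrast, 1)
  expect_equal(ti$energy, 0.5)
  expect_equal(ti$homogeneity, 0.5)
  # configurable log base
  expect_equal(texture_indices(p, base = 2)$entropy, 1)

  # uniform p over k cells attains maximum entropy log k
  img2 <- gray_image(matrix(c(0L, 1L, 2L, 3L), 2, 2))
  p2 <- glcm_normalize(glcm(img2, 1, 90, n_levels = 4))
  expect_equal(texture_indices(p2)$entropy, log(4))

  expect_error(texture_indices(glcm(img, 1, 0, n_levels = 2)), "normalized")
})

test_that("counts agree with the brute-force oracle on random images", {
  set.seed(11)
  for (rep in 1:100) {
    n_levels <- sample(2:8, 1)
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    d <- sample(1:4, 1)
    dir <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    img <- random_image(nr, nc, n_levels)
    got <- glcm(img, d, dir, symmetric = sym, n_levels = n_levels)
    expect_equal(unclass(got), brute_glcm(img, d, dir, sym, n_levels),
                 ignore_attr = TRUE)
    if (sym) expect_identical(unclass(got), t(unclass(got)))
  }
})

test_that("direction averaging equals the mean of per-direction matrices", {
  set.seed(21)
  img <- random_image(6, 6, 8)
  avg <- glcm_average(img, 2, n_levels = 8)
  ref <- Reduce(`+`, lapply(c(0, 45, 90, 135), function(th) {
    cm <- brute_glcm(img, 2, th, TRUE, 8)
    cm / sum(cm)
  })) / 4
  expect_equal(unclass(avg), ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(avg), 1, tolerance = 1e-9)

  # trivial case: all-zero 3x3 image concentrates all mass at (0, 0)
  p0 <- glcm_average(gray_image(matrix(0L, 3, 3)), 1, n_levels = 4)
  expect_equal(unclass(p0)[1, 1], 1)
})

test_that("index bounds hold for random normalized matrices", {
  set.seed(31)
  for (rep in 1:25) {
    n_levels <- sample(2:8, 1)
    img <- random_image(8, 8, n_levels)
    ti <- texture_indices(glcm_average(img, sample(1:3, 1),
                                       n_levels = n_levels))
    expect_gte(ti$entropy, 0)
    expect_lte(ti$entropy, log(n_levels^2))
    expect_gte(ti$contrast, 0)
    expect_lte(ti$contrast, (n_levels - 1)^2)
    expect_gte(ti$energy, 1 / n_levels^2)
    expect_lte(ti$energy, 1)
    expect_gt(ti$homogeneity, 0)
    expect_lte(ti$homogeneity, 1)
  }
})

test_that("four-direction averaged indices are rotation and transpose invariant", {
  set.seed(41)
  img <- random_image(9, 7, 8)
  base <- texture_features(img, d = 2, n_levels = 8)
  m <- unclass(img)
  variants <- list(rotate90(m), rotate90(rotate90(m)),
                   rotate90(rotate90(rotate90(m))), t(m))
  for (v in variants) {
    got <- texture_features(gray_image(v), d = 2, n_levels = 8)
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("blurring lowers entropy/contrast and raises homogeneity", {
  set.seed(51)
  field <- matrix(runif(64 * 64), 64, 64)
  sigmas <- c(0.5, 1, 2, 3, 4)
  feats <- purrr::map_dfr(sigmas, function(s) {
    sm <- EBImage::gblur(field, sigma = s)
    sm <- pmin(pmax(sm, 0), 1)
    img <- gray_image(matrix(as.integer(round(sm * 255)), 64, 64))
    texture_features(img, d = 2)
  })
  lvl <- seq_along(sigmas)
  expect_lte(cor(feats$entropy, lvl, method = "spearman"), -0.9)
  expect_lte(cor(feats$contrast, lvl, method = "spearman"), -0.9)
  expect_gte(cor(feats$homogeneity, lvl, method = "spearman"), 0.9)
})
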