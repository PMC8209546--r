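test_that("optical density satisfies the log identities and clipping", {
  img <- array(100, c(4, 4, 3))
  od <- optical_density(img, I0 = 100)
  expect_equal(od$od, matrix(0, 4, 4))
  od10 <- optical_density(array(10, c(4, 4, 3)), I0 = 100)
  expect_equal(od10$od, matrix(1, 4, 4))
  od0 <- optical_density(array(0, c(4, 4, 3)), I0 = 100, od_max = 3)
  expect_equal(od0$od, matrix(3, 4, 4))
  expect_error(optical_density(img, I0 = 0),
               class = "itfpipe_invalid_parameter")
})

test_that("fiber enhancement raises on-fiber contrast and is ~0 on flat input", {
  flat <- matrix(0.2, 64, 64)
  enh <- enhance_fibers(flat, n_iter = 1, resolution = 1)
  expect_lt(max(abs(enh)), 0.02)

  bar <- matrix(0.05, 96, 96)
  bar[46:50, 11:86] <- 0.5
  truth <- matrix(FALSE, 96, 96); truth[46:50, 11:86] <- TRUE
  e1 <- enhance_fibers(bar, n_iter = 1, scales_um = c(3, 5), resolution = 1)
  expect_gt(mean(e1[truth]), mean(e1[!truth]))
  # iterating never degrades fiber/background separability (noisy input so
  # the ranking statistic is not saturated at 1 from the start)
  set.seed(4)
  noisy <- bar + matrix(rnorm(96 * 96, 0, 0.15), 96, 96)
  sep <- vapply(c(1, 3), function(it) {
    roc_auc(enhance_fibers(noisy, n_iter = it, scales_um = c(3, 5),
                           resolution = 1), truth)
  }, numeric(1))
  expect_gte(sep[2], sep[1] * 0.95)
  expect_gt(sep[2], 0.8)
  expect_error(enhance_fibers(bar, scales_um = numeric(0)),
               class = "itfpipe_invalid_parameter")
})

test_that("pixel features: 6 named features, finite, zero local SD on constant input", {
  const <- matrix(0.3, 32, 32)
  fs <- pixel_features(const, enhanced = const, window_px = 9, resolution = 1)
  expect_equal(ncol(fs$features), 6L)
  expect_equal(colnames(fs$features),
               c("od", "enhanced", "local_mean", "local_sd", "ridge",
                 "anisotropy"))
  expect_lt(max(abs(fs$features[, "local_sd"])), 1e-6)

  img <- generate_fiber_image(fiber_image_spec(width_px = 128, height_px = 128,
                                               n_fibers = 5, seed = 2))
  od <- optical_density(img$image)
  fs2 <- pixel_features(od, resolution = 0.46)
  expect_true(all(is.finite(fs2$features)))
  expect_error(pixel_features(const, enhanced = const, window_px = 8),
               class = "itfpipe_invalid_parameter")
  expect_error(pixel_features(const, enhanced = const, window_px = 99),
               class = "itfpipe_invalid_parameter")
})

test_that("logistic pixel model: separable data, sign, determinism, errors", {
  set.seed(1)
  x <- cbind(f1 = c(runif(200, 0, 1), runif(200, 2, 3)), f2 = rnorm(400))
  y <- rep(0:1, each = 200)
  m <- fit_pixel_logit(x, y, n_sample = 400, seed = 9)
  expect_equal(roc_auc(plogis(m$coef[1] + x %*% m$coef[-1]), y), 1.0)
  expect_gt(m$coef["f1"], 0)
  m2 <- fit_pixel_logit(x, y, n_sample = 400, seed = 9)
  expect_identical(m$coef, m2$coef)
  expect_error(fit_pixel_logit(x, rep(1, 400)),
               class = "itfpipe_degenerate_training")
})

test_that("model JSON round trip preserves predictions exactly", {
  set.seed(2)
  x <- cbind(a = rnorm(50), b = rnorm(50))
  m <- fit_pixel_logit(x, as.integer(x[, 1] + 0.3 * rnorm(50) > 0),
                       n_sample = 50, seed = 1)
  f <- tempfile(fileext = ".json")
  model_to_json(m, f)
  m2 <- model_from_json(f)
  expect_identical(probability_map(m, x), probability_map(m2, x))
})

test_that("probability map: logistic identities and feature-order invariance", {
  x <- cbind(a = runif(20), b = runif(20))
  m0 <- structure(list(feature_names = c("a", "b"),
                       coef = c(`(Intercept)` = 0, a = 0, b = 0)),
                  class = "logit_model")
  expect_equal(probability_map(m0, x), rep(0.5, 20))
  m_neg <- m0; m_neg$coef[1] <- -50
  expect_lt(max(probability_map(m_neg, x)), 1e-10)
  # permuting feature columns leaves the map unchanged
  m1 <- m0; m1$coef <- c(`(Intercept)` = 0.2, a = 1.5, b = -0.7)
  expect_equal(probability_map(m1, x), probability_map(m1, x[, c("b", "a")]))
  # monotone in a positively weighted feature
  x2 <- x; x2[, "a"] <- x2[, "a"] + 1
  expect_true(all(probability_map(m1, x2) >= probability_map(m1, x)))
  expect_error(probability_map(m1, cbind(z = runif(5))),
               class = "itfpipe_schema")
})

test_that("segmentation matches a flood-fill oracle and is threshold-monotone", {
  p <- matrix(0, 40, 40)
  p[5:12, 5:12] <- 0.9
  p[25:35, 20:30] <- 0.8
  p[20, 2] <- 0.99  # single pixel, below min area
  seg <- segment_fibers(p, threshold = 0.5, min_area_um2 = 10, resolution = 1)
  expect_equal(seg$n_fibers, 2L)
  expect_equal(seg$n_fibers, oracle_count_components(p >= 0.5 &
                                                       p != 0.99))
  expect_equal(sort(unique(as.vector(seg$labels))), 0:2)

  seg0 <- segment_fibers(matrix(0, 10, 10), resolution = 1)
  expect_equal(seg0$n_fibers, 0L)
  a1 <- sum(segment_fibers(p, threshold = 0.4, resolution = 1)$labels > 0)
  a2 <- sum(segment_fibers(p, threshold = 0.85, resolution = 1)$labels > 0)
  expect_lte(a2, a1)
  expect_error(segment_fibers(p, threshold = 0),
               class = "itfpipe_invalid_parameter")
})

test_that("roc_auc reproduces enumerated pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_error(roc_auc(runif(5), rep(1, 5)), class = "itfpipe_undefined_auc")
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(roc_auc(s, y), oracle_auc_pairwise(s, y), tolerance = 1e-12)
  }
})

test_that("segmentation on default synthetic images: AUC >= 0.95, count within 10%", {
  img <- generate_fiber_image(fiber_image_spec(seed = 31))
  od <- optical_density(img$image)
  enh <- enhance_fibers(od, resolution = 0.46)
  fs <- pixel_features(od, enh, resolution = 0.46)
  m <- fit_pixel_logit(fs, as.vector(img$truth_mask), seed = 1)
  pm <- probability_map(m, fs)
  expect_gte(roc_auc(pm, img$truth_mask), 0.95)
  seg <- segment_fibers(pm, resolution = 0.46)
  planted <- nrow(img$truth_table)
  expect_lte(abs(seg$n_fibers - planted) / planted, 0.10)
})
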