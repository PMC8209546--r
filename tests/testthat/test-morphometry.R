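test_that("tissue area: blank tile is 0; uniform tile matches closed form", {
  blank <- matrix(0, 100, 100)          # OD 0 everywhere (white)
  expect_equal(tissue_area(blank, resolution = 0.46), 0)
  full <- matrix(0.2, 1000, 1000)
  expect_equal(tissue_area(full, resolution = 0.46), (1000 * 0.46e-3)^2)
  expect_equal(tissue_area(full, resolution = 0.46), 0.2116)
})

test_that("tissue area on synthetic images tracks the generator tissue mask", {
  img <- generate_fiber_image(fiber_image_spec(seed = 13, hole_fraction = 0.1))
  od <- optical_density(img$image, I0 = 255)
  got <- tissue_area(od, resolution = 0.46)
  want <- mean(img$tissue_mask) * (512 * 0.46e-3)^2
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("disk geometry: isoperimetric identities, no branches", {
  d <- outer(seq(-60, 60), seq(-60, 60), function(i, j) i^2 + j^2 <= 50^2)
  m <- measure_fiber(d, resolution = 1)
  expect_equal(m$shape, 1, tolerance = 0.05)
  expect_lt(abs(m$deformity) / (4 * pi * m$area), 0.05)  # deficit ~ 0
  expect_equal(m$aspect, 1, tolerance = 0.05)
  expect_equal(m$vertices, 0)
  expect_equal(m$perimeter, 2 * pi * 50, tolerance = 0.02 * 2 * pi * 50)
  expect_gt(m$solidity, 0.95)
})

test_that("bar geometry: width, height, aspect, vertices, fractal dimension", {
  b <- matrix(FALSE, 30, 120); b[11:20, 11:110] <- TRUE
  m <- measure_fiber(b, resolution = 1)
  expect_equal(m$width, 10, tolerance = 0.05)
  expect_equal(m$height, 100, tolerance = 0.05 * 100)
  expect_equal(m$aspect, 10, tolerance = 0.1 * 10)
  expect_equal(m$vertices, 0)
  expect_gte(m$fractal_dimension, 1.0)
  expect_lte(m$fractal_dimension, 1.1)
  # physical units scale with resolution
  m046 <- measure_fiber(b, resolution = 0.46)
  expect_equal(m046$width, 10 * 0.46, tolerance = 0.03)
  expect_equal(m046$area, m$area * 0.46^2)
})

test_that("Y junction has exactly one merged branch vertex", {
  y <- matrix(FALSE, 140, 140)
  y[10:70, 68:72] <- TRUE
  for (t in 0:60) {
    y[70 + t, (68:72) - round(t * 0.7)] <- TRUE
    y[70 + t, (68:72) + round(t * 0.7)] <- TRUE
  }
  m <- measure_fiber(y, resolution = 1)
  expect_equal(m$vertices, 1)
})

test_that("box-counting dimension: thin segment ~1, filled square ~2", {
  seg <- matrix(FALSE, 5, 130); seg[3, 2:129] <- TRUE
  expect_gte(box_count_dimension(seg), 1.0)
  expect_lte(box_count_dimension(seg), 1.15)
  sq <- matrix(TRUE, 128, 128)
  expect_gte(box_count_dimension(sq), 1.85)
  expect_lte(box_count_dimension(sq), 2.0)
})

test_that("scale equivariance: lengths double, areas quadruple, shapes invariant", {
  mk <- function(scale) {
    b <- matrix(FALSE, 10 * scale + 20, 100 * scale + 20)
    b[10 + seq_len(10 * scale), 10 + seq_len(100 * scale)] <- TRUE
    b
  }
  m1 <- measure_fiber(mk(1), resolution = 1)
  m2 <- measure_fiber(mk(2), resolution = 0.5)   # same physical object
  for (len_par in c("perimeter", "width", "height", "skeleton_length"))
    expect_equal(m2[[len_par]], m1[[len_par]], tolerance = 0.05 * m1[[len_par]])
  expect_equal(m2$area, m1$area, tolerance = 0.05 * m1$area)
  for (dimless in c("shape", "aspect", "solidity", "perimeter_ratio",
                    "fractal_dimension"))
    expect_equal(m2[[dimless]], m1[[dimless]],
                 tolerance = 0.05 * max(m1[[dimless]], 1))
  expect_equal(m2$vertices, m1$vertices)
})

test_that("rotation invariance of area/shape/aspect within 5%", {
  # measurements are averaged over sub-pixel placement phases: a single
  # fixed phase aliases the raster lattice differently at 0 and 45 degrees
  phases <- list(c(0.11, 0.43), c(0.37, 0.81), c(0.63, 0.19), c(0.89, 0.57))
  mean_measure <- function(a) {
    ms <- lapply(phases, function(ph)
      measure_fiber(render_bar(100, 10, a, phase = ph), 1))
    vapply(c("area", "shape", "aspect"),
           function(p) mean(vapply(ms, `[[`, numeric(1), p)), numeric(1))
  }
  m <- vapply(c(0, 45, 90), mean_measure, numeric(3))
  for (p in c("area", "shape", "aspect")) {
    v <- m[p, ]
    expect_lt(diff(range(v)) / mean(v), 0.05)
  }
})

test_that("planted fiber width is recovered within 15% on default images", {
  ws <- c()
  planted <- c()
  for (sd in 1:2) {
    img <- generate_fiber_image(fiber_image_spec(seed = sd))
    lab <- itfpipe:::label_components_cpp(img$truth_mask, TRUE)
    m <- measure_fibers(lab, resolution = 0.46)
    ws <- c(ws, m$width)
    planted <- c(planted, img$truth_table$width_um)
  }
  expect_lt(abs(mean(ws) - mean(planted)) / mean(planted), 0.15)
})

test_that("ROI summary: density and %SA ratios, bounds, errors", {
  morphs <- data.frame(fiber_id = 1:50, area = rep(100, 50))
  s <- summarize_roi(morphs, core_area_mm2 = 0.5)
  expect_equal(s$density, 100)
  expect_equal(s$pct_sa, 100 * 50 * 100 / 0.5e6)
  s2 <- summarize_roi(data.frame(fiber_id = 1, area = 0.5e6), 0.5)
  expect_equal(s2$pct_sa, 100)
  expect_error(summarize_roi(morphs, 0), class = "itfpipe_division_error")
  expect_error(measure_fiber(matrix(c(TRUE, FALSE), 1), 1),
               class = "itfpipe_undefined_morphometry")
})

test_that("full-image ROI summary recovers planted density within 10%", {
  img <- generate_fiber_image(fiber_image_spec(seed = 17, hole_fraction = 0))
  lab <- itfpipe:::label_components_cpp(img$truth_mask, TRUE)
  morphs <- measure_fibers(lab, resolution = 0.46)
  core <- (512 * 0.46e-3)^2
  s <- summarize_roi(morphs, core)
  want <- nrow(img$truth_table) / core
  expect_lt(abs(s$density - want) / want, 0.10)
})
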