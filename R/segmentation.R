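#' Optical density of a brightfield image
#'
#' `OD_c = -log10(I_c / I0_c)` per channel, clipped to `[0, od_max]`;
#' high where the silver stain absorbs strongly.  `I0` defaults to the
#' per-channel 99th-percentile intensity of the tile (a background/white
#' estimate); pass `I0 = 255` to reference pure white instead (recommended
#' for tissue-area measurement, where pale intact tissue must stay above
#' zero OD).
#'
#' @param image H x W x 3 array (or a single matrix) of 8-bit intensities.
#' @param I0 reference white per channel (scalar recycled), `> 0`.
#' @param od_max clipping value applied where intensity is 0.
#' @return Object of class `od_map`: list with `od` (channel-averaged
#'   matrix), `od_channels` (array, absent for matrix input), `I0`,
#'   `od_max`.
#' @export
optical_density <- function(image, I0 = NULL, od_max = 3) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  nch <- dim(image)[3]
  if (is.null(I0))
    I0 <- vapply(seq_len(nch),
                 function(c) stats::quantile(image[, , c], 0.99, names = FALSE),
                 numeric(1))
  I0 <- rep_len(I0, nch)
  abort_if(any(I0 <= 0), "I0 must be positive", "itfpipe_invalid_parameter")
  od <- array(0, dim(image))
  for (c in seq_len(nch)) {
    v <- -log10(pmax(image[, , c], .Machine$double.eps) / I0[c])
    v[image[, , c] == 0] <- od_max
    od[, , c] <- pmin(pmax(v, 0), od_max)
  }
  avg <- if (nch == 1L) od[, , 1L] else apply(od, c(1L, 2L), mean)
  structure(list(od = avg,
                 od_channels = if (nch > 1L) od else NULL,
                 I0 = I0, od_max = od_max),
            class = "od_map")
}

# multiscale ridge response: largest negative second directional
# derivative (scale-normalized Hessian eigenvalue) across scales
ridge_response <- function(m, sigmas_px) {
  out <- matrix(0, nrow(m), ncol(m))
  for (s in sigmas_px) {
    g0 <- gaussian_kernel(s, 0L)
    g2 <- gaussian_kernel(s, 2L)
    g1 <- gaussian_kernel(s, 1L)
    ixx <- conv_sep_cpp(m, g2, g0)
    iyy <- conv_sep_cpp(m, g0, g2)
    ixy <- conv_sep_cpp(m, g1, g1)
    tr <- ixx + iyy
    dt <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
    lam_min <- (tr - dt) / 2
    resp <- s^2 * pmax(-lam_min, 0)
    out <- pmax(out, resp)
  }
  out
}

#' Iterative enhancement of curvilinear fibers in an OD map
#'
#' Each iteration subtracts a large-kernel median background and adds a
#' multiscale ridge response (the most negative scale-normalized second
#' directional derivative across the given scales), then renormalizes to
#' the input OD range.  Iterating sharpens thin dark fibers against
#' diffuse background staining.
#'
#' @param od an [optical_density()] result (or plain matrix).
#' @param n_iter number of enhancement iterations (>= 1).
#' @param scales_um ridge scales, expressed as fiber widths in microns.
#' @param resolution microns per pixel.
#' @param background_radius_um radius of the median background kernel.
#' @return Matrix of enhanced OD values, >= 0, same shape as input.
#' @export
enhance_fibers <- function(od, n_iter = 2L, scales_um = c(2, 5, 8),
                           resolution = 0.46, background_radius_um = 20) {
  m <- if (inherits(od, "od_map")) od$od else od
  abort_if(length(scales_um) == 0, "scales_um must be non-empty",
           "itfpipe_invalid_parameter")
  abort_if(n_iter < 1, "n_iter must be >= 1", "itfpipe_invalid_parameter")
  sigmas <- pmax(0.6, scales_um / (2 * resolution))
  bg_r <- max(2L, as.integer(round(background_radius_um / resolution)))
  top <- max(m)
  if (top <= 0) return(m * 0)
  for (it in seq_len(n_iter)) {
    bg <- median_filter_cpp(m, bg_r)
    detail <- pmax(m - bg, 0)
    rr <- ridge_response(m, sigmas)
    m <- detail + rr
    mx <- max(m)
    # cap at the input OD range; never amplify an essentially flat map
    if (mx > top) m <- m * (top / mx)
  }
  m
}

#' Per-pixel feature stack for the logistic fiber classifier
#'
#' Six features per pixel: raw OD, enhanced OD, local mean and SD of the
#' enhanced OD in a square window, single-scale ridge response, and the
#' structure-tensor anisotropy (eigenvalue contrast) in the window -- a
#' neighborhood description of whether the pixel sits on an elongated
#' dark structure.
#'
#' @param od an [optical_density()] result (or raw OD matrix).
#' @param enhanced matrix from [enhance_fibers()]; computed on the fly
#'   with defaults when `NULL`.
#' @param window_px odd window size >= 3.
#' @param resolution microns per pixel (used when `enhanced` is `NULL`).
#' @return Object of class `feature_stack`: list with `features`
#'   (n_pixels x 6 matrix, column names fixed), `dim` (image dim).
#' @export
pixel_features <- function(od, enhanced = NULL, window_px = 9L,
                           resolution = 0.46) {
  m <- if (inherits(od, "od_map")) od$od else od
  abort_if(window_px < 3L || window_px %% 2L == 0L,
           "window_px must be an odd integer >= 3", "itfpipe_invalid_parameter")
  abort_if(window_px > min(dim(m)), "window larger than image",
           "itfpipe_invalid_parameter")
  if (is.null(enhanced)) enhanced <- enhance_fibers(m, resolution = resolution)
  r <- (window_px - 1L) %/% 2L
  npx <- box_count_px(nrow(m), ncol(m), r)
  s1 <- box_sum(enhanced, r)
  s2 <- box_sum(enhanced^2, r)
  loc_mean <- s1 / npx
  loc_var <- pmax(s2 / npx - loc_mean^2, 0)
  loc_sd <- sqrt(loc_var)
  rr <- ridge_response(m, max(1, 2.5 / (2 * resolution)))
  # structure tensor anisotropy
  g1 <- gaussian_kernel(1, 1L); g0 <- gaussian_kernel(1, 0L)
  gx <- conv_sep_cpp(m, g1, g0)
  gy <- conv_sep_cpp(m, g0, g1)
  jxx <- box_sum(gx * gx, r) / npx
  jyy <- box_sum(gy * gy, r) / npx
  jxy <- box_sum(gx * gy, r) / npx
  dt <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  aniso <- dt / (jxx + jyy + 1e-12)
  feats <- cbind(od = as.vector(m), enhanced = as.vector(enhanced),
                 local_mean = as.vector(loc_mean), local_sd = as.vector(loc_sd),
                 ridge = as.vector(rr), anisotropy = as.vector(aniso))
  structure(list(features = feats, dim = dim(m)), class = "feature_stack")
}

#' Fit the logistic pixel model on a class-balanced sample
#'
#' Maximum-likelihood logistic regression of fiber/background labels on
#' the pixel feature stack, fitted on a class-balanced random sample of
#' pixels.  Deterministic for a fixed seed.
#'
#' @param features a `feature_stack` (or plain feature matrix).
#' @param labels binary vector (1 = fiber pixel), one per pixel.
#' @param n_sample total pixels sampled (half per class; sampling is with
#'   replacement when a class has fewer pixels).
#' @param seed integer RNG seed.
#' @return Object of class `logit_model`: list with `feature_names`,
#'   `coef` (named, including `(Intercept)`), `n`, `seed`.
#' @export
fit_pixel_logit <- function(features, labels, n_sample = 20000L, seed = 1L) {
  x <- if (inherits(features, "feature_stack")) features$features else features
  labels <- as.integer(labels)
  abort_if(!all(labels %in% c(0L, 1L)), "labels must be binary",
           "itfpipe_invalid_parameter")
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  abort_if(length(pos) == 0L || length(neg) == 0L,
           "both classes must be present", "itfpipe_degenerate_training")
  set.seed(seed)
  k <- max(1L, n_sample %/% 2L)
  take <- c(sample(pos, k, replace = length(pos) < k),
            sample(neg, k, replace = length(neg) < k))
  xs <- cbind(`(Intercept)` = 1, x[take, , drop = FALSE])
  fit <- suppressWarnings(
    glm.fit(xs, labels[take], family = binomial()))
  structure(list(feature_names = colnames(x), coef = fit$coefficients,
                 n = 2L * k, seed = seed),
            class = "logit_model")
}

#' Serialize / restore a logistic pixel model as JSON
#'
#' Coefficients are written at full double precision so that a round trip
#' preserves predictions exactly.
#' @param model a `logit_model`.
#' @param path file path.
#' @return `model_to_json()` the path invisibly; `model_from_json()` the model.
#' @export
model_to_json <- function(model, path) {
  coef_txt <- stats::setNames(sprintf("%.17g", model$coef), names(model$coef))
  jsonlite::write_json(list(feature_names = model$feature_names,
                            coef = as.list(coef_txt),
                            n = model$n, seed = model$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- vapply(o$coef, as.numeric, numeric(1))
  structure(list(feature_names = o$feature_names, coef = coef,
                 n = o$n, seed = o$seed),
            class = "logit_model")
}

#' Per-pixel fiber probability map
#'
#' `p = logistic(intercept + w . x)`; features are matched to the model by
#' name, so column order is irrelevant.
#'
#' @param model a `logit_model`.
#' @param features a `feature_stack` (probability map is reshaped to the
#'   image) or a plain feature matrix (vector returned).
#' @return Matrix (or vector) of probabilities in \[0, 1\].
#' @export
probability_map <- function(model, features) {
  fs <- inherits(features, "feature_stack")
  x <- if (fs) features$features else features
  abort_if(!setequal(colnames(x), model$feature_names),
           "feature names do not match the model", "itfpipe_schema")
  x <- x[, model$feature_names, drop = FALSE]
  eta <- model$coef[1] + drop(x %*% model$coef[-1])
  p <- plogis(eta)
  if (fs) matrix(p, features$dim[1], features$dim[2]) else p
}

#' Threshold a probability map into labeled fibers
#'
#' Pixels with `p >= threshold` are kept, 8-connected components are
#' labeled, and components smaller than `min_area_um2` are removed;
#' remaining labels are contiguous `1..K`.
#'
#' @param prob probability matrix in \[0, 1\].
#' @param threshold probability cutoff in (0, 1).
#' @param min_area_um2 minimum component area in square microns.
#' @param resolution microns per pixel.
#' @return Object of class `fiber_set`: list with `labels` (integer
#'   matrix), `n_fibers`, `resolution`, `min_area_um2`, `threshold`.
#' @export
segment_fibers <- function(prob, threshold = 0.5, min_area_um2 = 10,
                           resolution = 0.46) {
  abort_if(threshold <= 0 || threshold >= 1, "threshold must be in (0,1)",
           "itfpipe_invalid_parameter")
  mask <- prob >= threshold
  lab <- label_components_cpp(mask, eight = TRUE)
  if (max(lab) > 0L) {
    areas <- tabulate(lab, nbins = max(lab)) * resolution^2
    keep <- which(areas >= min_area_um2)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  structure(list(labels = lab, n_fibers = max(lab), resolution = resolution,
                 min_area_um2 = min_area_um2, threshold = threshold),
            class = "fiber_set")
}

#' Pixel-wise ROC AUC of a probability map against a truth mask
#'
#' The probability that a randomly chosen fiber pixel outscores a randomly
#' chosen background pixel, ties counting one half; computed with the
#' rank-sum (Mann-Whitney) statistic.
#'
#' @param prob probability matrix or vector of scores.
#' @param truth_mask logical/0-1 labels, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(prob, truth_mask) {
  s <- as.vector(prob)
  y <- as.logical(as.vector(truth_mask))
  abort_if(length(s) != length(y), "length mismatch", "itfpipe_schema")
  n1 <- sum(y); n0 <- sum(!y)
  abort_if(n1 == 0L || n0 == 0L, "truth must contain both classes",
           "itfpipe_undefined_auc")
  r <- rank(s)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}
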