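#' Specification of a synthetic silver-stained fiber image
#'
#' Describes a brightfield tile emulating Gomori-type silver staining:
#' dark, wavy, branching reticular fibers on a pale tissue background,
#' with optional bright "holes" of damaged tissue.  All geometric
#' parameters are in physical units so the same spec can be rendered at
#' any pixel resolution.
#'
#' @param width_px,height_px image size in pixels.
#' @param resolution microns per pixel (whole-slide scans at 20x are
#'   typically 0.46 um/px, the default).
#' @param n_fibers number of fibers planted.
#' @param mean_fiber_width mean fiber width in microns.
#' @param width_cv coefficient of variation of fiber width across fibers.
#' @param mean_fiber_length mean fiber length in microns.
#' @param curvature waviness: standard deviation (radians) of the random
#'   per-step turning angle of the centerline walk; 0 gives straight fibers.
#' @param branch_prob expected number of branches per 100 um of fiber.
#' @param fiber_intensity_mean,background_intensity_mean 8-bit gray levels;
#'   fibers must be darker than background.
#' @param hole_intensity_mean gray level of damaged-tissue holes (brighter
#'   than intact background).
#' @param noise_sd additive Gaussian pixel noise, gray levels.
#' @param blur_sigma Gaussian optical blur in pixels.
#' @param hole_fraction fraction of the tile punched out as holes.
#' @param seed integer RNG seed; generation is bit-reproducible.
#' @return An object of class `fiber_image_spec`.
#' @export
fiber_image_spec <- function(width_px = 512L, height_px = 512L,
                             resolution = 0.46, n_fibers = 20L,
                             mean_fiber_width = 5, width_cv = 0.2,
                             mean_fiber_length = 60, curvature = 0.25,
                             branch_prob = 1, fiber_intensity_mean = 90,
                             background_intensity_mean = 200,
                             hole_intensity_mean = 250,
                             noise_sd = 8, blur_sigma = 1,
                             hole_fraction = 0.05, seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               resolution = resolution, n_fibers = as.integer(n_fibers),
               mean_fiber_width = mean_fiber_width, width_cv = width_cv,
               mean_fiber_length = mean_fiber_length, curvature = curvature,
               branch_prob = branch_prob,
               fiber_intensity_mean = fiber_intensity_mean,
               background_intensity_mean = background_intensity_mean,
               hole_intensity_mean = hole_intensity_mean,
               noise_sd = noise_sd, blur_sigma = blur_sigma,
               hole_fraction = hole_fraction, seed = as.integer(seed))
  abort_if(spec$width_px <= 0L || spec$height_px <= 0L,
           "image dimensions must be positive", "itfpipe_invalid_spec")
  abort_if(spec$resolution <= 0, "resolution must be > 0", "itfpipe_invalid_spec")
  abort_if(spec$fiber_intensity_mean >= spec$background_intensity_mean,
           "fibers must be darker than background", "itfpipe_invalid_spec")
  abort_if(spec$hole_fraction < 0 || spec$hole_fraction > 1,
           "hole_fraction must be in [0,1]", "itfpipe_invalid_spec")
  abort_if(spec$width_cv < 0 || spec$curvature < 0 || spec$n_fibers < 0,
           "negative spec parameter", "itfpipe_invalid_spec")
  structure(spec, class = "fiber_image_spec")
}

# smoothed random-walk centerline returned as n x 2 pixel coordinates
fiber_centerline <- function(x0, y0, theta0, len_px, curvature, step = 2) {
  n_steps <- max(2L, ceiling(len_px / step))
  turns <- rnorm(n_steps, 0, curvature)
  theta <- theta0 + cumsum(turns)
  xs <- x0 + c(0, cumsum(cos(theta) * step))
  ys <- y0 + c(0, cumsum(sin(theta) * step))
  if (n_steps >= 4L) {  # cubic spline smoothing through every 2nd knot
    idx <- unique(c(seq(1L, length(xs), by = 2L), length(xs)))
    t_in <- idx; t_out <- seq(1, length(xs), length.out = 4L * length(xs))
    xs <- spline(t_in, xs[idx], xout = t_out)$y
    ys <- spline(t_in, ys[idx], xout = t_out)$y
  }
  cbind(xs, ys)
}

# stamp disks of radius r (px) centred on path points into a logical matrix
stamp_path <- function(mask, path, radius_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- max(0.5, radius_px)
  ri <- ceiling(r)
  off <- expand.grid(di = -ri:ri, dj = -ri:ri)
  off <- off[off$di^2 + off$dj^2 <= r^2, , drop = FALSE]
  pi_ <- round(path[, 2]); pj <- round(path[, 1])   # y -> row, x -> col
  keep <- pi_ >= 1 - ri & pi_ <= nr + ri & pj >= 1 - ri & pj <= nc + ri
  pi_ <- pi_[keep]; pj <- pj[keep]
  if (!length(pi_)) return(mask)
  ii <- rep(pi_, each = nrow(off)) + off$di
  jj <- rep(pj, each = nrow(off)) + off$dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  mask[cbind(ii[ok], jj[ok])] <- TRUE
  mask
}

#' Generate a synthetic fiber image with ground truth
#'
#' Renders the fibers described by a [fiber_image_spec()]: smoothed
#' random-walk centerlines dilated to their planted width, with Bernoulli
#' branching per step, on a noisy pale background; Gaussian blur is applied
#' and elliptical holes are carved out of the tissue.  Fibers are placed
#' with light rejection sampling so most planted fibers remain separate
#' connected components.
#'
#' @param spec a [fiber_image_spec()].
#' @return A list of class `synthetic_fiber_image` with elements
#'   `image` (H x W x 3 array, 0-255), `truth_mask` (logical matrix),
#'   `tissue_mask` (logical matrix, holes are `FALSE`),
#'   `truth_table` (data.frame: fiber_id, width_um, length_um, n_branches),
#'   and `spec`.
#' @export
generate_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_image_spec"))
  set.seed(spec$seed)
  nr <- spec$height_px; nc <- spec$width_px; r_um <- spec$resolution
  tissue <- matrix(TRUE, nr, nc)

  # elliptical holes until the requested fraction is reached
  if (spec$hole_fraction > 0) {
    target <- spec$hole_fraction * nr * nc
    guard <- 0L
    while (sum(!tissue) < target && guard < 100L) {
      guard <- guard + 1L
      ci <- runif(1, 1, nr); cj <- runif(1, 1, nc)
      a <- runif(1, 0.04, 0.12) * min(nr, nc); b <- runif(1, 0.04, 0.12) * min(nr, nc)
      phi <- runif(1, 0, pi)
      ii <- matrix(seq_len(nr), nr, nc) - ci
      jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cj
      u <- cos(phi) * jj + sin(phi) * ii
      v <- -sin(phi) * jj + cos(phi) * ii
      tissue[u^2 / a^2 + v^2 / b^2 <= 1] <- FALSE
    }
  }

  truth <- matrix(FALSE, nr, nc)
  occupied <- !tissue  # fibers avoid holes and each other's footprint
  rows <- vector("list", spec$n_fibers)
  n <- spec$n_fibers
  if (n > 0L) {
    for (f in seq_len(n)) {
      w_um <- max(0.8, spec$mean_fiber_width *
                    (1 + spec$width_cv * rnorm(1)))
      len_um <- max(10, spec$mean_fiber_length * exp(rnorm(1, 0, 0.35)))
      rad_px <- w_um / 2 / r_um
      len_px <- len_um / r_um
      placed <- FALSE
      for (try in 1:25) {
        x0 <- runif(1, 1, nc); y0 <- runif(1, 1, nr)
        th <- runif(1, 0, 2 * pi)
        path <- fiber_centerline(x0, y0, th, len_px, spec$curvature)
        pr <- round(path[, 2]); pc <- round(path[, 1])
        inb <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
        if (mean(inb) < 0.6) next
        if (any(occupied[cbind(pr[inb], pc[inb])])) next
        placed <- TRUE
        break
      }
      if (!placed) { rows[[f]] <- NULL; next }
      fm <- matrix(FALSE, nr, nc)
      fm <- stamp_path(fm, path, rad_px)
      paths <- list(path)
      # Bernoulli branching per centerline step
      n_branches <- 0L
      step_um <- 2 * r_um * nrow(path) / max(1, nrow(path))  # ~per-point step
      p_branch <- spec$branch_prob * (2 * r_um / 4) / 100    # path points are ~0.5 px apart after spline
      if (spec$branch_prob > 0) {
        br <- which(runif(nrow(path)) < p_branch)
        for (b in br) {
          blen <- len_px * runif(1, 0.2, 0.5)
          bth <- atan2(path[min(b + 1, nrow(path)), 2] - path[b, 2],
                       path[min(b + 1, nrow(path)), 1] - path[b, 1]) +
                 sample(c(-1, 1), 1) * runif(1, pi / 6, pi / 3)
          bpath <- fiber_centerline(path[b, 1], path[b, 2], bth, blen,
                                    spec$curvature)
          bpr <- round(bpath[, 2]); bpc <- round(bpath[, 1])
          binb <- bpr >= 1 & bpr <= nr & bpc >= 1 & bpc <= nc
          # skip branches that would collide with another fiber or a hole
          if (any(occupied[cbind(bpr[binb], bpc[binb])])) next
          fm <- stamp_path(fm, bpath, rad_px * runif(1, 0.7, 1))
          paths[[length(paths) + 1L]] <- bpath
          n_branches <- n_branches + 1L
        }
      }
      truth <- truth | fm
      for (pp in paths)
        occupied <- stamp_path(occupied, pp, 2 * rad_px + 4)
      rows[[f]] <- data.frame(fiber_id = f, width_um = w_um,
                              length_um = len_um, n_branches = n_branches)
    }
  }
  truth <- truth & tissue
  truth_table <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(truth_table))
    truth_table <- data.frame(fiber_id = integer(), width_um = numeric(),
                              length_um = numeric(), n_branches = integer())

  # render intensity: pale background, dark fibers, bright holes
  img <- matrix(spec$background_intensity_mean, nr, nc)
  img[truth] <- spec$fiber_intensity_mean
  img[!tissue] <- spec$hole_intensity_mean
  if (spec$blur_sigma > 0) {
    k <- gaussian_kernel(spec$blur_sigma)
    img <- conv_sep_cpp(img, k, k)
  }
  img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 255)
  # slight warm tint so the three channels are not identical
  rgb <- array(0, c(nr, nc, 3L))
  rgb[, , 1] <- img
  rgb[, , 2] <- img * 0.96
  rgb[, , 3] <- img * 0.90
  rgb <- round(pmin(pmax(rgb, 0), 255))
  storage.mode(rgb) <- "integer"

  structure(list(image = rgb, truth_mask = truth, tissue_mask = tissue,
                 truth_table = truth_table, spec = spec),
            class = "synthetic_fiber_image")
}

#' @noRd
gaussian_kernel <- function(sigma, order = 0L, radius = NULL) {
  r <- radius %||% max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) return(-x / sigma^2 * g)
  if (order == 2L) return((x^2 - sigma^2) / sigma^4 * g)
  stop("unsupported derivative order")
}
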