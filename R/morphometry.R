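#' Intact-tissue (core) area of a tile
#'
#' Area of pixels whose channel-averaged OD is at least `od_min`, after a
#' morphological closing that fills pinholes smaller than `close_um`
#' across; holes and damaged (unstained, bright) tissue fall below the OD
#' floor and are excluded.  Compute the OD against a pure-white reference
#' (`optical_density(img, I0 = 255)`) so pale intact tissue keeps a
#' positive OD.
#'
#' @param od an [optical_density()] result or OD matrix.
#' @param od_min OD threshold for "stained tissue".
#' @param resolution microns per pixel.
#' @param close_um pinholes smaller than this are filled.
#' @return Core area in mm^2.
#' @export
tissue_area <- function(od, od_min = 0.05, resolution = 0.46, close_um = 20) {
  m <- if (inherits(od, "od_map")) od$od else od
  abort_if(od_min < 0, "od_min must be >= 0", "itfpipe_invalid_parameter")
  mask <- m >= od_min
  # fill pinholes: background components whose extent is below close_um
  bg <- label_components_cpp(!mask, eight = FALSE)
  if (max(bg) > 0L) {
    lim_px <- close_um / resolution
    idx <- which(bg > 0L, arr.ind = TRUE)
    labs <- bg[bg > 0L]
    ext_i <- tapply(idx[, 1], labs, function(v) diff(range(v)) + 1)
    ext_j <- tapply(idx[, 2], labs, function(v) diff(range(v)) + 1)
    small <- as.integer(names(ext_i))[pmax(ext_i, ext_j) < lim_px]
    if (length(small)) mask[bg %in% small] <- TRUE
  }
  sum(mask) * (resolution / 1000)^2
}

# 4-direction Cauchy-Crofton perimeter estimate (pixels)
crofton_perimeter <- function(mask) {
  m <- mask * 1L
  nh <- sum(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])) +
    sum(m[, 1]) + sum(m[, ncol(m)])
  nv <- sum(abs(m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])) +
    sum(m[1, ]) + sum(m[nrow(m), ])
  d1 <- sum(abs(m[-1, -1, drop = FALSE] - m[-nrow(m), -ncol(m), drop = FALSE]))
  d2 <- sum(abs(m[-1, -ncol(m), drop = FALSE] - m[-nrow(m), -1, drop = FALSE]))
  # border diagonal exits
  d1 <- d1 + sum(m[1, ]) + sum(m[, 1]) + sum(m[nrow(m), ]) + sum(m[, ncol(m)])
  d2 <- d2 + sum(m[1, ]) + sum(m[, 1]) + sum(m[nrow(m), ]) + sum(m[, ncol(m)])
  pi / 8 * (nh + nv + (d1 + d2) / sqrt(2))
}

#' Box-counting fractal dimension of a binary mask
#'
#' Least-squares slope of `log N(s)` against `log s` over dyadic box sizes,
#' where `N(s)` is the number of `s x s` grid boxes containing mask pixels.
#' A thin straight segment gives ~1, a filled square ~2.
#'
#' @param mask logical matrix.
#' @param sizes dyadic box sizes in pixels.
#' @param clamp clip the estimate into \[1, 2\].
#' @return Estimated dimension.
#' @export
box_count_dimension <- function(mask, sizes = 2^(0:6), clamp = TRUE) {
  idx <- which(mask, arr.ind = TRUE)
  abort_if(nrow(idx) == 0L, "empty mask", "itfpipe_undefined_morphometry")
  i0 <- idx[, 1] - min(idx[, 1]); j0 <- idx[, 2] - min(idx[, 2])
  ns <- vapply(sizes, function(s) {
    length(unique((i0 %/% s) * 1e9 + (j0 %/% s)))
  }, numeric(1))
  keep <- ns >= 1
  x <- log(sizes[keep]); y <- log(ns[keep])
  if (length(unique(y)) == 1L) return(if (clamp) 1 else 0)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fd <- -slope
  if (clamp) min(max(fd, 1), 2) else fd
}

# merge skeleton branch pixels closer than merge_px into single vertices
count_vertices <- function(skel, merge_px = 3) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  nb <- box_sum(skel * 1, 1L) - skel * 1  # 8-neighbour counts
  br <- which(skel & nb >= 3, arr.ind = TRUE)
  if (nrow(br) == 0L) return(0L)
  if (nrow(br) == 1L) return(1L)
  d <- as.matrix(dist(br))
  adj <- d <= merge_px
  # connected components of the branch-pixel proximity graph
  n <- nrow(br); comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  max(comp)
}

# skeleton length in px: sum of 8-neighbour graph edges (1 or sqrt(2))
skeleton_length_px <- function(skel) {
  n_ax <- sum(skel[, -1] & skel[, -ncol(skel)]) +
    sum(skel[-1, ] & skel[-nrow(skel), ])
  n_di <- sum(skel[-1, -1] & skel[-nrow(skel), -ncol(skel)]) +
    sum(skel[-1, -ncol(skel)] & skel[-nrow(skel), -1])
  n_ax + sqrt(2) * n_di
}

#' Morphometry of one segmented fiber
#'
#' Computes the thirteen per-fiber morphometric parameters: area,
#' perimeter (Crofton), convex perimeter, perimeter ratio
#' (convex/actual), width (2 x mean medial-axis distance), height
#' (maximum Feret diameter), skeleton length, aspect (height/width),
#' vertices (merged skeleton branch points), box-counting fractal
#' dimension, shape factor `P^2 / (4 pi A)`, isoperimetric deformity
#' `P^2 - 4 pi A`, and solidity (area / convex area).  ROI-level density
#' and %SA complete the fifteen-parameter suite (see [summarize_roi()]).
#'
#' @param mask logical matrix covering one connected component.
#' @param resolution microns per pixel.
#' @return One-row data.frame of the 13 per-fiber parameters.
#' @export
measure_fiber <- function(mask, resolution = 0.46) {
  n_px <- sum(mask)
  abort_if(n_px < 2L, "degenerate component (< 2 pixels)",
           "itfpipe_undefined_morphometry")
  r <- resolution
  area <- n_px * r^2
  per_px <- crofton_perimeter(mask)
  perimeter <- per_px * r

  idx <- which(mask, arr.ind = TRUE)
  # convex hull over boundary-pixel corner points (so solidity <= 1)
  nbcnt <- box_sum(mask * 1, 1L)
  boundary <- idx[nbcnt[idx] < 9, , drop = FALSE]
  if (nrow(boundary) == 0L) boundary <- idx
  corners <- rbind(
    cbind(boundary[, 1] - 0.5, boundary[, 2] - 0.5),
    cbind(boundary[, 1] - 0.5, boundary[, 2] + 0.5),
    cbind(boundary[, 1] + 0.5, boundary[, 2] - 0.5),
    cbind(boundary[, 1] + 0.5, boundary[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hull <- corners[h, , drop = FALSE]
  nh <- nrow(hull)
  e <- hull[c(seq_len(nh)[-1], 1L), , drop = FALSE] - hull
  convex_perimeter <- sum(sqrt(rowSums(e^2))) * r
  convex_area <- abs(sum(hull[, 1] * hull[c(seq_len(nh)[-1], 1L), 2] -
                           hull[c(seq_len(nh)[-1], 1L), 1] * hull[, 2])) / 2 * r^2
  # max Feret diameter over hull points
  height <- sqrt(max(as.vector(dist(hull))^2)) * r

  skel <- thin_cpp(mask)
  dt <- distance_transform_cpp(mask)
  sk_idx <- which(skel)
  width <- if (length(sk_idx)) 2 * mean(dt[sk_idx]) * r else 2 * max(dt) * r
  skeleton_length <- skeleton_length_px(skel) * r
  vertices <- count_vertices(skel)

  # box-count the medial axis rather than the filled mask: the statistic
  # then reflects the fiber's course (1 for straight, higher for wavy or
  # branched) independently of its cross-sectional width and of the
  # rendering resolution
  fd_mask <- if (sum(skel) >= 2L) skel else mask
  fractal_dimension <- box_count_dimension(fd_mask)

  aspect <- max(height / max(width, .Machine$double.eps), 1)
  shape <- perimeter^2 / (4 * pi * area)
  deformity <- perimeter^2 - 4 * pi * area
  data.frame(area = area, perimeter = perimeter,
             convex_perimeter = convex_perimeter,
             perimeter_ratio = min(convex_perimeter / perimeter, 1),
             width = width, height = height,
             skeleton_length = skeleton_length, aspect = aspect,
             vertices = vertices, fractal_dimension = fractal_dimension,
             shape = shape, deformity = deformity,
             solidity = min(area / convex_area, 1))
}

#' Morphometry table for every fiber in a segmentation
#'
#' @param fibers a `fiber_set` from [segment_fibers()] (or a labeled
#'   integer matrix plus `resolution`).
#' @param resolution microns per pixel (taken from the fiber set if absent).
#' @param min_px components smaller than this many pixels are skipped.
#' @return data.frame, one row per fiber (`fiber_id` + 13 parameters).
#' @export
measure_fibers <- function(fibers, resolution = NULL, min_px = 4L) {
  if (inherits(fibers, "fiber_set")) {
    lab <- fibers$labels
    resolution <- resolution %||% fibers$resolution
  } else {
    lab <- fibers
    abort_if(is.null(resolution), "resolution required",
             "itfpipe_invalid_parameter")
  }
  k <- max(lab)
  if (k == 0L)
    return(cbind(data.frame(fiber_id = integer()),
                 measure_fiber(matrix(TRUE, 2, 1), 1)[0, ]))
  idx_all <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    pix <- idx_all[labs == f, , drop = FALSE]
    if (nrow(pix) < min_px) next
    i1 <- range(pix[, 1]); j1 <- range(pix[, 2])
    sub <- matrix(FALSE, i1[2] - i1[1] + 3L, j1[2] - j1[1] + 3L)
    sub[cbind(pix[, 1] - i1[1] + 2L, pix[, 2] - j1[1] + 2L)] <- TRUE
    rows[[f]] <- cbind(data.frame(fiber_id = f),
                       measure_fiber(sub, resolution))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- cbind(data.frame(fiber_id = integer()),
                 measure_fiber(matrix(TRUE, 2, 1), 1)[0, ])
  rownames(out) <- NULL
  out
}

#' ROI-level fiber summary: density and percent stained area
#'
#' Total fibers, core (tissue) area and the summed fiber area give the
#' fiber density (fibers/mm^2) and the percentage of stained area (%SA);
#' per-parameter unweighted means over fibers complete the record.
#'
#' @param morphs per-fiber morphometry data.frame from [measure_fibers()].
#' @param core_area_mm2 intact tissue area from [tissue_area()], mm^2.
#' @return One-row data.frame: `total_fibers`, `core_area_mm2`,
#'   `sum_fiber_area_um2`, `density`, `pct_sa`, then `mean_<parameter>`
#'   for each of the 13 per-fiber parameters.
#' @export
summarize_roi <- function(morphs, core_area_mm2) {
  abort_if(core_area_mm2 <= 0, "core area must be positive",
           "itfpipe_division_error")
  total <- nrow(morphs)
  sum_area <- sum(morphs$area)
  params <- setdiff(names(morphs), "fiber_id")
  means <- if (total)
    as.list(colMeans(morphs[params]))
  else stats::setNames(as.list(rep(NA_real_, length(params))), params)
  names(means) <- paste0("mean_", names(means))
  cbind(data.frame(total_fibers = total, core_area_mm2 = core_area_mm2,
                   sum_fiber_area_um2 = sum_area,
                   density = total / core_area_mm2,
                   pct_sa = 100 * sum_area / (core_area_mm2 * 1e6)),
        as.data.frame(means))
}
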