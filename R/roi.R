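#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#' @noRd
clip_polygon_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prev <- pts[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi_) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, val, coord) {
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- as.matrix(poly)
  pts <- clip_edge(pts, \(p) p[1] >= xmin, \(p, q) ix(p, q, xmin, 1))
  pts <- clip_edge(pts, \(p) p[1] <= xmax, \(p, q) ix(p, q, xmax, 1))
  pts <- clip_edge(pts, \(p) p[2] >= ymin, \(p, q) ix(p, q, ymin, 2))
  pts <- clip_edge(pts, \(p) p[2] <= ymax, \(p, q) ix(p, q, ymax, 2))
  pts
}

#' @noRd
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (is.null(n) || n < 3L) return(0)
  j <- c(seq_len(n)[-1], 1L)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

#' Categorize a rectangular ROI against annotation polygons
#'
#' The tumor fraction is the fraction of the rectangle covered by tumor
#' polygons; an ROI is `tumor` at >= 0.95, `myometrium` at <= 0.05, `itf`
#' (invasive tumor front, the 50/50 tumor-myometrium interface band) in
#' \[0.4, 0.6\], and `uncategorized` otherwise.
#'
#' @param rect numeric `c(x, y, w, h)` in microns (origin top-left).
#' @param tumor_polygons list of n x 2 matrices (x, y in microns).
#' @param myometrium_polygons list of n x 2 matrices; may be empty if
#'   tumor polygons are given.
#' @param id optional ROI identifier.
#' @return Object of class `roi_spec`: list with `id`, `rect`,
#'   `size_class` (`large_5x4mm`, `small_1mm2` or `custom`),
#'   `tumor_fraction`, `category`.
#' @export
categorize_roi <- function(rect, tumor_polygons, myometrium_polygons = list(),
                           id = "roi") {
  abort_if(length(tumor_polygons) == 0L && length(myometrium_polygons) == 0L,
           "no annotation polygons supplied", "itfpipe_annotation_missing")
  x <- rect[1]; y <- rect[2]; w <- rect[3]; h <- rect[4]
  a_rect <- w * h
  a_tum <- sum(vapply(tumor_polygons, function(p)
    polygon_area(clip_polygon_rect(p, x, y, x + w, y + h)), numeric(1)))
  frac <- min(a_tum / a_rect, 1)
  category <- if (frac >= 0.95) "tumor"
  else if (frac <= 0.05) "myometrium"
  else if (frac >= 0.4 && frac <= 0.6) "itf"
  else "uncategorized"
  dims <- sort(c(w, h))
  size_class <- if (all(dims == c(1000, 1000))) "small_1mm2"
  else if (all(dims == c(4000, 5000))) "large_5x4mm"
  else "custom"
  structure(list(id = id, rect = rect, size_class = size_class,
                 tumor_fraction = frac, category = category),
            class = "roi_spec")
}

#' Read ROI polygons from a GeoJSON file
#'
#' Coordinates are in microns, origin top-left, y increasing downwards.
#' Features may carry a `class` property (e.g. "tumor", "myometrium").
#'
#' @param path GeoJSON file.
#' @return Named list of n x 2 coordinate matrices (outer rings), names
#'   taken from the `class`/`name` property when present.
#' @export
read_roi_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (!is.null(g$features)) g$features else list(g)
  out <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    if (is.null(geom$type) || geom$type != "Polygon") next
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    nm <- f$properties$class %||% f$properties$name %||%
      paste0("poly", length(out) + 1L)
    out[[length(out) + 1L]] <- m
    names(out)[length(out)] <- nm
  }
  out
}

#' Two-group comparison with variance F-test gated t-test
#'
#' The Fisher-Snedecor F statistic (larger over smaller sample variance,
#' two-sided p) decides the t-test flavor: pooled-variance Student t when
#' the variances are compatible (`f_p >= alpha_var`), Welch otherwise.
#' Significance stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param values_a,values_b per-sample values (e.g. per-sample parameter
#'   means), length >= 2 each.
#' @param alpha_var F-test level gating the choice of t flavor.
#' @param parameter optional parameter name carried into the result.
#' @return One-row data.frame of class `group_comparison`: parameter,
#'   mean/sd/n per group, `f_stat`, `f_p`, `variance_equal`, `t_stat`,
#'   `t_p`, `stars`.
#' @export
compare_groups <- function(values_a, values_b, alpha_var = 0.05,
                           parameter = NA_character_) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  abort_if(length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b) ||
             any(!is.finite(c(a, b))),
           "need >= 2 finite values per group", "itfpipe_insufficient_data")
  va <- var(a); vb <- var(b)
  dfa <- length(a) - 1L; dfb <- length(b) - 1L
  if (va == 0 && vb == 0) {
    f_stat <- 1; f_p <- 1
  } else {
    if (va >= vb) {
      f_stat <- va / max(vb, .Machine$double.xmin)
      f_p <- min(2 * pf(f_stat, dfa, dfb, lower.tail = FALSE), 1)
    } else {
      f_stat <- vb / max(va, .Machine$double.xmin)
      f_p <- min(2 * pf(f_stat, dfb, dfa, lower.tail = FALSE), 1)
    }
  }
  variance_equal <- f_p >= alpha_var
  if (va == 0 && vb == 0) {
    t_stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    t_p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tt <- t.test(a, b, var.equal = variance_equal)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  stars <- if (t_p < 0.001) "***" else if (t_p < 0.01) "**"
  else if (t_p < 0.05) "*" else ""
  structure(data.frame(parameter = parameter,
                       mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                       mean_b = mean(b), sd_b = sd(b), n_b = length(b),
                       f_stat = f_stat, f_p = f_p,
                       variance_equal = variance_equal,
                       t_stat = t_stat, t_p = t_p, stars = stars,
                       stringsAsFactors = FALSE),
            class = c("group_comparison", "data.frame"))
}

#' Comparison table over parameters and group contrasts
#'
#' One [compare_groups()] row per parameter per pairwise contrast of the
#' grouping variable.  No multiplicity correction is applied by default
#' (set `adjust = "BH"` to add a `t_p_adj` column).  Rows with
#' insufficient data are kept with `NA` statistics rather than aborting
#' the table.
#'
#' @param data data.frame of per-sample summaries; one row per sample.
#' @param parameters character vector of numeric column names to compare.
#' @param group name of the grouping column.
#' @param alpha_var F-test gate, see [compare_groups()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per parameter x contrast; contrast
#'   columns `group_a`, `group_b`.
#' @export
build_comparison_table <- function(data, parameters, group,
                                   alpha_var = 0.05, adjust = "none") {
  abort_if(!group %in% names(data), "grouping column not found",
           "itfpipe_invalid_parameter")
  lv <- unique(as.character(data[[group]]))
  abort_if(length(lv) < 2L, "need >= 2 groups", "itfpipe_insufficient_data")
  contrasts <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- list()
  for (ct in contrasts) {
    for (p in parameters) {
      va <- data[[p]][data[[group]] == ct[1]]
      vb <- data[[p]][data[[group]] == ct[2]]
      row <- tryCatch(compare_groups(va, vb, alpha_var, parameter = p),
                      itfpipe_insufficient_data = function(e) {
                        data.frame(parameter = p, mean_a = NA, sd_a = NA,
                                   n_a = length(va), mean_b = NA, sd_b = NA,
                                   n_b = length(vb), f_stat = NA, f_p = NA,
                                   variance_equal = NA, t_stat = NA,
                                   t_p = NA, stars = NA_character_)
                      })
      row$group_a <- ct[1]; row$group_b <- ct[2]
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  out <- do.call(rbind, rows)
  if (identical(adjust, "BH")) out$t_p_adj <- p.adjust(out$t_p, "BH")
  rownames(out) <- NULL
  out
}
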