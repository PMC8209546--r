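#' Remove cells near the ROI border
#'
#' Cells within `margin_um` of any ROI edge are dropped (border-artifact
#' control); the retained effective area `(w - 2m)(h - 2m)` is attached
#' for use as the density denominator.
#'
#' @param cells data.frame with `x`, `y` in microns.
#' @param roi_rect numeric `c(x, y, w, h)` in microns.
#' @param margin_um margin width, >= 0 and < half the smaller side.
#' @return The filtered data.frame with attribute `effective_area_mm2`.
#' @export
exclude_border_cells <- function(cells, roi_rect, margin_um = 20) {
  abort_if(margin_um < 0, "margin must be >= 0", "itfpipe_invalid_parameter")
  w <- roi_rect[3]; h <- roi_rect[4]
  abort_if(margin_um >= min(w, h) / 2, "margin leaves no interior area",
           "itfpipe_degenerate_area")
  x0 <- roi_rect[1] + margin_um; x1 <- roi_rect[1] + w - margin_um
  y0 <- roi_rect[2] + margin_um; y1 <- roi_rect[2] + h - margin_um
  keep <- cells$x >= x0 & cells$x <= x1 & cells$y >= y0 & cells$y <= y1
  out <- cells[keep, , drop = FALSE]
  attr(out, "effective_area_mm2") <- (w - 2 * margin_um) *
    (h - 2 * margin_um) / 1e6
  out
}

#' Phenotype densities for one ROI
#'
#' Densities (cells/mm^2) per phenotype over the closed set
#' CD68, CD3, CD8, CD20, CK, other; `total_immune` is the summed density
#' of the four immune markers (CD8 is reported separately from CD3, not
#' folded into it).
#'
#' @param cells phenotyped cell table (after border exclusion).
#' @param area_mm2 effective ROI area; taken from the
#'   `effective_area_mm2` attribute when `NULL`.
#' @param roi_id optional identifier carried into the result.
#' @return One-row data.frame: `roi_id`, one density column per
#'   phenotype, `total_cells` (density of all cells), `total_immune`.
#' @export
immune_summary <- function(cells, area_mm2 = NULL, roi_id = NA_character_) {
  area_mm2 <- area_mm2 %||% attr(cells, "effective_area_mm2")
  abort_if(is.null(area_mm2) || area_mm2 <= 0, "effective area must be > 0",
           "itfpipe_invalid_parameter")
  ph <- as.character(cells$phenotype)
  bad <- setdiff(unique(ph), PHENOTYPES)
  abort_if(length(bad) > 0,
           paste("unknown phenotype:", paste(bad, collapse = ", ")),
           "itfpipe_schema")
  counts <- vapply(PHENOTYPES, function(p) sum(ph == p), numeric(1))
  dens <- counts / area_mm2
  out <- data.frame(roi_id = roi_id, as.list(dens),
                    total_cells = sum(dens),
                    total_immune = sum(dens[c("CD68", "CD3", "CD8", "CD20")]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Density summaries for every ROI in a cell table
#'
#' Applies border exclusion and [immune_summary()] per `roi_id`.
#'
#' @param cells cell table with `x`, `y`, `phenotype`, `roi_id` and
#'   optionally `roi_category`.
#' @param roi_rect rectangle `c(x, y, w, h)` shared by all ROIs (microns).
#' @param margin_um border margin.
#' @return data.frame, one row per ROI (with `roi_category` if present).
#' @export
immune_summaries <- function(cells, roi_rect = c(0, 0, 1000, 1000),
                             margin_um = 20) {
  ids <- unique(cells$roi_id)
  rows <- lapply(ids, function(id) {
    sub <- cells[cells$roi_id == id, , drop = FALSE]
    trimmed <- exclude_border_cells(sub, roi_rect, margin_um)
    s <- immune_summary(trimmed, roi_id = id)
    if ("roi_category" %in% names(sub))
      s$roi_category <- sub$roi_category[1]
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of immune densities
#'
#' Delegates to [build_comparison_table()] over the per-sample mean
#' densities of each marker (plus the total-cell and total-immune
#' aggregates).
#'
#' @param summaries data.frame of per-sample density summaries including a
#'   grouping column.
#' @param group name of the grouping column (e.g. tumor type).
#' @param parameters density columns to compare.
#' @return Comparison table as in [build_comparison_table()].
#' @export
compare_immune_groups <- function(summaries, group,
                                  parameters = c(PHENOTYPES, "total_cells",
                                                 "total_immune")) {
  build_comparison_table(summaries, parameters, group)
}
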