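PHENOTYPES <- c("CD68", "CD3", "CD8", "CD20", "CK", "other")
ROI_CATEGORIES <- c("tumor", "myometrium", "itf")

#' Specification of a synthetic phenotyped cell field
#'
#' Emulates the tabular output of a multiplex immunofluorescence cell
#' classifier: marked point patterns of immune phenotypes at
#' ROI-category-specific densities.  Defaults follow the reported
#' magnitudes for uterine tumors (macrophages most abundant; CD8 around
#' 132 cells/mm2 in adenocarcinoma tumor areas vs 12 in leiomyosarcoma).
#'
#' @param roi_size_mm numeric length-2, ROI width and height in mm.
#' @param densities named list: ROI category -> named numeric vector of
#'   densities (cells/mm2) over the phenotypes
#'   `r paste(PHENOTYPES, collapse = ", ")`.
#' @param clustering 0 for complete spatial randomness (Poisson); > 0 for
#'   a Thomas cluster process with this mean number of offspring per
#'   parent (same expected counts, overdispersed quadrat counts).
#' @param cluster_sd_um Gaussian scatter of offspring around parents, um.
#' @param n_rois_per_category replicate ROIs per category.
#' @param seed integer RNG seed.
#' @return Object of class `cell_field_spec`.
#' @export
cell_field_spec <- function(roi_size_mm = c(1, 1),
                            densities = default_cell_densities(),
                            clustering = 0, cluster_sd_um = 25,
                            n_rois_per_category = 1L, seed = 1L) {
  abort_if(!is.list(densities) || is.null(names(densities)),
           "densities must be a named list keyed by ROI category",
           "itfpipe_invalid_spec")
  for (cat in names(densities)) {
    d <- densities[[cat]]
    abort_if(is.null(names(d)) || !all(names(d) %in% PHENOTYPES),
             paste0("unknown phenotype key in category '", cat, "'"),
             "itfpipe_invalid_spec")
    abort_if(any(d < 0), "densities must be >= 0", "itfpipe_invalid_spec")
  }
  abort_if(any(roi_size_mm <= 0), "ROI size must be positive",
           "itfpipe_invalid_spec")
  structure(list(roi_size_mm = roi_size_mm, densities = densities,
                 clustering = clustering, cluster_sd_um = cluster_sd_um,
                 n_rois_per_category = as.integer(n_rois_per_category),
                 seed = as.integer(seed)),
            class = "cell_field_spec")
}

#' Default phenotype densities per ROI category (cells/mm2)
#' @return Named list of named numeric vectors.
#' @export
default_cell_densities <- function() {
  list(
    tumor      = c(CD68 = 300, CD3 = 250, CD8 = 132, CD20 = 40, CK = 900, other = 1500),
    myometrium = c(CD68 = 150, CD3 = 80,  CD8 = 40,  CD20 = 10, CK = 5,   other = 1200),
    itf        = c(CD68 = 400, CD3 = 350, CD8 = 180, CD20 = 60, CK = 450, other = 1400)
  )
}

#' Generate a synthetic phenotyped cell table
#'
#' For each ROI category and phenotype, draws `Poisson(density x area)`
#' cells with uniform positions (or a Thomas cluster process when
#' `clustering > 0`; points falling outside the ROI are re-drawn uniformly
#' so expected counts are preserved).
#'
#' @param spec a [cell_field_spec()].
#' @return data.frame with columns `x`, `y` (um), `phenotype`, `roi_id`,
#'   `roi_category`.
#' @export
generate_cell_table <- function(spec) {
  stopifnot(inherits(spec, "cell_field_spec"))
  set.seed(spec$seed)
  w_um <- spec$roi_size_mm[1] * 1000
  h_um <- spec$roi_size_mm[2] * 1000
  area <- spec$roi_size_mm[1] * spec$roi_size_mm[2]
  out <- list()
  for (cat in names(spec$densities)) {
    for (rep_i in seq_len(spec$n_rois_per_category)) {
      roi_id <- paste0(cat, "_", rep_i)
      for (ph in names(spec$densities[[cat]])) {
        n <- rpois(1, spec$densities[[cat]][[ph]] * area)
        if (n == 0) next
        if (spec$clustering > 0) {
          mu <- spec$clustering
          n_par <- max(1L, rpois(1, n / mu))
          px <- runif(n_par, 0, w_um); py <- runif(n_par, 0, h_um)
          par_of <- sample.int(n_par, n, replace = TRUE)
          x <- px[par_of] + rnorm(n, 0, spec$cluster_sd_um)
          y <- py[par_of] + rnorm(n, 0, spec$cluster_sd_um)
          bad <- x < 0 | x > w_um | y < 0 | y > h_um
          x[bad] <- runif(sum(bad), 0, w_um)
          y[bad] <- runif(sum(bad), 0, h_um)
        } else {
          x <- runif(n, 0, w_um); y <- runif(n, 0, h_um)
        }
        out[[length(out) + 1L]] <- data.frame(
          x = x, y = y, phenotype = ph, roi_id = roi_id, roi_category = cat)
      }
    }
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), phenotype = character(),
                      roi_id = character(), roi_category = character()))
  do.call(rbind, out)
}
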