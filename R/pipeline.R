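#' Default pipeline configuration
#'
#' Nested key-value configuration covering every stage, with the package
#' defaults.  Seeds are mandatory and explicit so that a rerun with the
#' same config is bit-identical.
#'
#' @param seed master seed; stage seeds derive from it deterministically.
#' @return Nested named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    seed = seed,
    simulate = list(
      fibers = list(n_images_per_group = 3L, width_px = 256L, height_px = 256L,
                    resolution = 0.46, noise_sd = 8, hole_fraction = 0.05,
                    group_a = list(n_fibers = 18L, mean_fiber_width = 5,
                                   curvature = 0.25, branch_prob = 1.5),
                    group_b = list(n_fibers = 30L, mean_fiber_width = 3.5,
                                   curvature = 0.4, branch_prob = 1)),
      cells = list(clustering = 0, n_rois_per_category = 3L),
      methyl = list(n_cpgs = 2000L, n_samples_a = 10L, n_samples_b = 10L,
                    dm_fraction = 0.035, delta_beta = 0.2),
      expr = list(log2fc = 2, nb_dispersion = 0.1,
                  n_coupled_hyper_down = 9L, n_coupled_hypo_up = 11L)
    ),
    segment = list(threshold = 0.5, min_area_um2 = 10, window_px = 9L,
                   n_iter = 2L, scales_um = c(2, 5, 8), n_sample = 20000L),
    morphometry = list(od_min = 0.05),
    immune = list(margin_um = 20),
    methyl = list(p_max = 0.01, fdr = 0.05),
    integrate = list(min_delta = 0.05, q_max = 0.05)
  )
}

# recursive structural validation against the default schema
validate_against <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  abort_if(length(unknown) > 0,
           paste0("unknown config key: ", path, unknown[1]),
           "itfpipe_config_error")
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      validate_against(cfg[[k]], ref[[k]], paste0(path, k, "$"))
  }
  invisible(TRUE)
}

# deep merge of user overrides onto defaults
merge_config <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]) &&
                     !is.null(names(base[[k]])))
      merge_config(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' @param overrides nested list of overrides onto [default_config()];
#'   unknown keys are rejected with the offending key named.
#' @param seed master seed.
#' @return Validated config of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), seed = 1L) {
  base <- default_config(seed)
  validate_against(overrides, base)
  cfg <- merge_config(base, overrides)
  abort_if(is.null(cfg$seed), "seed is mandatory", "itfpipe_config_error")
  structure(cfg, class = c("pipeline_config", "list"))
}

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full profiling pipeline
#'
#' Executes simulate, segment, morphometry, compare, immune, methyl and
#' integrate in dependency order, writing every output file under
#' `out_dir` and a `manifest.json` listing each file with its MD5 hash,
#' the master seed and the configuration.  A rerun with the same config
#' reproduces every output bit-identically.
#'
#' @param config a `pipeline_config` (or overrides list).
#' @param out_dir output directory, created if absent.
#' @param quiet suppress progress messages.
#' @return The manifest (invisibly), a list with `seed`, `files`
#'   (data.frame path/md5), `metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  abort_if(missing(out_dir) || is.null(out_dir),
           "config missing a required path: out_dir", "itfpipe_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  files <- character(0)
  metrics <- list()
  emit <- function(path) { files <<- c(files, path); path }

  ## -- simulate: fiber images for two groups ------------------------------
  say("stage: simulate")
  fc <- config$simulate$fibers
  make_group <- function(grp, grp_cfg, seed0) {
    lapply(seq_len(fc$n_images_per_group), function(i) {
      spec <- do.call(fiber_image_spec, c(
        list(width_px = fc$width_px, height_px = fc$height_px,
             resolution = fc$resolution, noise_sd = fc$noise_sd,
             hole_fraction = fc$hole_fraction, seed = seed0 + i),
        grp_cfg))
      generate_fiber_image(spec)
    })
  }
  imgs <- list(A = make_group("A", fc$group_a, seed * 100L),
               B = make_group("B", fc$group_b, seed * 100L + 50L))
  for (g in names(imgs)) for (i in seq_along(imgs[[g]])) {
    base <- file.path(out_dir, sprintf("fiber_%s_%02d", g, i))
    emit(write_ppm(imgs[[g]][[i]]$image, paste0(base, ".ppm")))
    emit(write_pgm(imgs[[g]][[i]]$truth_mask * 255, paste0(base, "_truth.pgm")))
  }

  ## -- segment: train logistic model on group A+B first images ------------
  say("stage: segment")
  sg <- config$segment
  featurize <- function(img) {
    od <- optical_density(img$image)
    enh <- enhance_fibers(od, n_iter = sg$n_iter, scales_um = sg$scales_um,
                          resolution = fc$resolution)
    pixel_features(od, enh, window_px = sg$window_px,
                   resolution = fc$resolution)
  }
  train_imgs <- list(imgs$A[[1]], imgs$B[[1]])
  tr_feats <- lapply(train_imgs, featurize)
  X <- do.call(rbind, lapply(tr_feats, `[[`, "features"))
  yv <- unlist(lapply(train_imgs, function(im) as.vector(im$truth_mask)))
  model <- fit_pixel_logit(X, yv, n_sample = sg$n_sample, seed = seed)
  emit(model_to_json(model, file.path(out_dir, "model.json")))

  seg_rows <- list(); morph_rows <- list()
  for (g in names(imgs)) for (i in seq_along(imgs[[g]])) {
    im <- imgs[[g]][[i]]
    fs <- featurize(im)
    pm <- probability_map(model, fs)
    auc <- roc_auc(pm, im$truth_mask)
    seg <- segment_fibers(pm, threshold = sg$threshold,
                          min_area_um2 = sg$min_area_um2,
                          resolution = fc$resolution)
    seg_rows[[length(seg_rows) + 1L]] <-
      data.frame(group = g, image = i, auc = auc, n_fibers = seg$n_fibers)
    ## -- morphometry ------------------------------------------------------
    od_white <- optical_density(im$image, I0 = 255)
    core <- tissue_area(od_white, od_min = config$morphometry$od_min,
                        resolution = fc$resolution)
    morphs <- measure_fibers(seg)
    s <- summarize_roi(morphs, core)
    morph_rows[[length(morph_rows) + 1L]] <-
      cbind(data.frame(group = g, image = i), s)
  }
  seg_df <- do.call(rbind, seg_rows)
  morph_df <- do.call(rbind, morph_rows)
  emit(write_df(seg_df, file.path(out_dir, "segmentation_metrics.csv")))
  emit(write_df(morph_df, file.path(out_dir, "roi_morphometry.csv")))
  metrics$mean_auc <- mean(seg_df$auc)

  ## -- compare: morphometric group comparison -----------------------------
  say("stage: compare")
  params <- grep("^mean_|^density$|^pct_sa$", names(morph_df), value = TRUE)
  cmp <- build_comparison_table(morph_df, params, "group")
  emit(write_df(cmp, file.path(out_dir, "morphometry_comparison.csv")))

  ## -- immune -------------------------------------------------------------
  say("stage: immune")
  cc <- config$simulate$cells
  dens <- default_cell_densities()
  dens_b <- dens
  dens_b$tumor["CD8"] <- 12  # colder tumor in group B
  dens_b$tumor["CD3"] <- 90
  cells_a <- generate_cell_table(cell_field_spec(
    densities = dens, clustering = cc$clustering,
    n_rois_per_category = cc$n_rois_per_category, seed = seed * 100L + 7L))
  cells_b <- generate_cell_table(cell_field_spec(
    densities = dens_b, clustering = cc$clustering,
    n_rois_per_category = cc$n_rois_per_category, seed = seed * 100L + 8L))
  cells_a$tumor_type <- "A"; cells_b$tumor_type <- "B"
  cells <- rbind(cells_a, cells_b)
  emit(write_df(cells, file.path(out_dir, "cells.csv")))
  summ <- do.call(rbind, lapply(split(cells, cells$tumor_type), function(ct) {
    s <- immune_summaries(ct, margin_um = config$immune$margin_um)
    s$tumor_type <- ct$tumor_type[1]
    s
  }))
  rownames(summ) <- NULL
  emit(write_df(summ, file.path(out_dir, "immune_summaries.csv")))
  icmp <- compare_immune_groups(summ[summ$roi_category == "tumor", ],
                                "tumor_type")
  emit(write_df(icmp, file.path(out_dir, "immune_comparison.csv")))

  ## -- methyl -------------------------------------------------------------
  say("stage: methyl")
  mc <- config$simulate$methyl
  mset <- generate_methylation_dataset(methyl_spec(
    n_cpgs = mc$n_cpgs, n_samples_a = mc$n_samples_a,
    n_samples_b = mc$n_samples_b, dm_fraction = mc$dm_fraction,
    delta_beta = mc$delta_beta, seed = seed * 100L + 21L))
  emit(write_matrix_tsv(mset$beta, file.path(out_dir, "beta.tsv"), "cpg_id"))
  emit(write_matrix_tsv(mset$detp, file.path(out_dir, "detp.tsv"), "cpg_id"))
  emit(write_df(mset$annotation, file.path(out_dir, "probe_annotation.csv")))
  filt <- filter_probes(mset$beta, mset$detp, mset$annotation,
                        p_max = config$methyl$p_max)
  dm <- dmcpg_test(filt$beta, mset$groups, fdr = config$methyl$fdr)
  emit(write_df(dm, file.path(out_dir, "dmcpg.csv")))
  dist_tab <- genomic_distribution(dm, filt$annotation)
  emit(write_df(dist_tab$context, file.path(out_dir, "dm_context.csv")))
  emit(write_df(dist_tab$region, file.path(out_dir, "dm_region.csv")))
  sig <- promoter_cgi_signature(dm, filt$annotation)
  emit(write_df(sig$gene_map, file.path(out_dir, "promoter_cgi_signature.csv")))
  conc <- cluster_and_concordance(filt$beta, sig$cpgs, mset$groups)
  metrics$n_valid_cpgs <- filt$n_valid
  metrics$n_dmcpgs <- sum(dm$significant)
  metrics$signature_cpgs <- sig$n_cpgs
  metrics$signature_genes <- sig$n_genes
  metrics$r_squared <- conc$r_squared

  ## -- integrate ----------------------------------------------------------
  say("stage: integrate")
  ec <- config$simulate$expr
  eset <- generate_expression_dataset(expr_spec(
    n_samples_a = mc$n_samples_a, n_samples_b = mc$n_samples_b,
    nb_dispersion = ec$nb_dispersion, log2fc = ec$log2fc,
    n_coupled_hyper_down = ec$n_coupled_hyper_down,
    n_coupled_hypo_up = ec$n_coupled_hypo_up,
    seed = seed * 100L + 33L), mset$truth)
  emit(write_matrix_tsv(eset$counts, file.path(out_dir, "counts.tsv"), "gene"))
  de <- surrogate_de(eset$counts, eset$groups)
  emit(write_df(de, file.path(out_dir, "de.csv")))
  dirs <- gene_methylation_direction(sig, dm,
                                     min_delta = config$integrate$min_delta)
  esig <- build_signature(dirs, de, sig, q_max = config$integrate$q_max)
  emit(write_df(data.frame(
    gene_symbol = c(esig$hyper_down, esig$hypo_up),
    class = rep(c("hyper_down", "hypo_up"),
                c(length(esig$hyper_down), length(esig$hypo_up)))),
    file.path(out_dir, "epigenetic_signature.csv")))
  jsonlite::write_json(list(hyper_down = esig$hyper_down,
                            hypo_up = esig$hypo_up),
                       emit(file.path(out_dir, "epigenetic_signature.json")))
  metrics$hyper_down <- length(esig$hyper_down)
  metrics$hypo_up <- length(esig$hypo_up)
  metrics$signature_ari <- if (esig$n_genes >= 1 && nrow(esig$cpgs) >= 2)
    signature_separation(filt$beta, esig, mset$groups) else NA_real_

  ## -- manifest ------------------------------------------------------------
  rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
             normalizePath(files))
  manifest <- list(seed = seed,
                   config = unclass(config),
                   files = data.frame(path = rel,
                                      md5 = unname(tools::md5sum(files)),
                                      stringsAsFactors = FALSE),
                   metrics = metrics)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
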