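#' Held-out segmentation benchmark
#'
#' Generates `n_images` synthetic 1-mm2 silver-stain tiles (80 fibers of
#' mean width 5 um, pixel noise SD 8), trains the logistic pixel
#' classifier on the first half using the ground-truth masks as labels,
#' and evaluates the pooled pixel-wise ROC AUC on the held-out half.
#' Tiles are rendered at 0.92 um/px (half the canonical 0.46 um/px scan
#' resolution) so twenty 1-mm2 tiles fit a desk-scale compute budget;
#' physical parameters are unchanged.
#'
#' @param n_images total images; the first `n_train` are training tiles.
#' @param n_train training tiles.
#' @param seed base seed; image i uses `seed * 100 + i`.
#' @param width_px,height_px,resolution tile raster geometry.
#' @param n_fibers,mean_fiber_width,noise_sd generator parameters.
#' @param n_sample_per_image class-balanced pixels sampled per training tile.
#' @param quiet suppress progress messages.
#' @return list: `auc` (pooled held-out AUC), `n_test_pixels`,
#'   `per_image` (data.frame with per-tile AUC for the test tiles),
#'   `model` (the fitted `logit_model`).
#' @export
fiber_benchmark <- function(n_images = 20L, n_train = 10L, seed = 42L,
                            width_px = 1088L, height_px = 1088L,
                            resolution = 0.92, n_fibers = 80L,
                            mean_fiber_width = 5, noise_sd = 8,
                            n_sample_per_image = 6000L, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  featurize <- function(img) {
    od <- optical_density(img$image)
    enh <- enhance_fibers(od, n_iter = 2L, scales_um = c(2, 5, 8),
                          resolution = resolution)
    pixel_features(od, enh, window_px = 9L, resolution = resolution)
  }
  make_img <- function(i) generate_fiber_image(fiber_image_spec(
    width_px = width_px, height_px = height_px, resolution = resolution,
    n_fibers = n_fibers, mean_fiber_width = mean_fiber_width,
    noise_sd = noise_sd, seed = (seed * 100L + i) %% .Machine$integer.max))

  # train: class-balanced pixel sample from each training tile
  xs <- vector("list", n_train); ys <- vector("list", n_train)
  for (i in seq_len(n_train)) {
    say("train tile ", i)
    img <- make_img(i)
    fs <- featurize(img)
    y <- as.integer(as.vector(img$truth_mask))
    set.seed(seed + i)
    k <- n_sample_per_image %/% 2L
    pos <- which(y == 1L); neg <- which(y == 0L)
    take <- c(sample(pos, min(k, length(pos))),
              sample(neg, min(k, length(neg))))
    xs[[i]] <- fs$features[take, , drop = FALSE]
    ys[[i]] <- y[take]
  }
  model <- fit_pixel_logit(do.call(rbind, xs), unlist(ys),
                           n_sample = n_train * n_sample_per_image,
                           seed = seed)
  # test: pooled pixel-wise AUC over the held-out tiles
  scores <- vector("list", n_images - n_train)
  labels <- vector("list", n_images - n_train)
  per_image <- data.frame(image = integer(), auc = numeric())
  for (i in seq.int(n_train + 1L, n_images)) {
    say("test tile ", i)
    img <- make_img(i)
    fs <- featurize(img)
    p <- probability_map(model, fs)
    j <- i - n_train
    scores[[j]] <- as.vector(p)
    labels[[j]] <- as.vector(img$truth_mask)
    per_image <- rbind(per_image,
                       data.frame(image = i, auc = roc_auc(p, img$truth_mask)))
  }
  s <- unlist(scores); y <- unlist(labels)
  list(auc = roc_auc(s, y), n_test_pixels = length(s),
       per_image = per_image, model = model)
}

#' End-to-end epigenetic signature recovery at default settings
#'
#' Runs the default methylation and expression simulations (5,000 CpGs,
#' delta-beta 0.2, 10 vs 10 samples; coupled 9 hypermethylated-down and
#' 11 hypomethylated-up genes), then the full filter / test / signature /
#' integration chain at default thresholds.
#'
#' @param seed RNG seed for both generators.
#' @return list: `n_genes`, `hyper_down`, `hypo_up`, `matches_planted`
#'   (logical), `ari` (signature clustering vs true groups), `n_gene_universe`.
#' @export
signature_benchmark <- function(seed = 7L) {
  md <- generate_methylation_dataset(methyl_spec(seed = seed))
  ed <- generate_expression_dataset(expr_spec(seed = seed), md$truth)
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  sig <- promoter_cgi_signature(dm, filt$annotation)
  de <- surrogate_de(ed$counts, ed$groups)
  dirs <- gene_methylation_direction(sig, dm)
  esig <- build_signature(dirs, de, sig)
  planted_hd <- sort(ed$truth$gene_symbol[ed$truth$coupled & ed$truth$expr_sign < 0])
  planted_hu <- sort(ed$truth$gene_symbol[ed$truth$coupled & ed$truth$expr_sign > 0])
  list(n_genes = esig$n_genes,
       hyper_down = length(esig$hyper_down), hypo_up = length(esig$hypo_up),
       matches_planted = identical(esig$hyper_down, planted_hd) &&
         identical(esig$hypo_up, planted_hu),
       ari = if (nrow(esig$cpgs) >= 2)
         signature_separation(filt$beta, esig, md$groups) else NA_real_,
       n_gene_universe = length(md$truth$gene_universe))
}
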