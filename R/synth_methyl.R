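CPG_CONTEXTS <- c("island", "shore", "shelf", "open_sea")
GENE_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon", "body", "3UTR", "IGR")

#' Specification of a synthetic EPIC-style methylation dataset
#'
#' Bimodal beta-values for two sample groups with a planted fraction of
#' differentially methylated CpGs, a probe annotation (CpG context, gene
#' region, gene symbol, SNP flag) and a detection p-value matrix.  The
#' defaults mirror a desk-scale version of the study design that motivated
#' the pipeline: ~3.5% of CpGs differentially methylated between two ITF
#' sample groups (the full-array counterpart being 23,296 of 665,840 CpGs).
#'
#' @param n_cpgs number of CpG probes (default 5,000; the full array has
#'   ~850K, reduced so the pipeline runs in minutes).
#' @param n_samples_a,n_samples_b samples per group.
#' @param dm_fraction fraction of CpGs planted as differentially
#'   methylated (default 0.035).
#' @param delta_beta planted group-mean beta difference for DM CpGs,
#'   applied as the equivalent logit-scale shift of group B at each CpG's
#'   baseline (baselines of planted CpGs are drawn in \[0.25, 0.75\] so the
#'   shifted mean stays inside (0, 1)).
#' @param precision concentration of the per-sample Beta noise,
#'   `beta ~ Beta(mu * k, (1 - mu) * k)`; k = 50 gives a beta-value SD of
#'   about 0.04-0.07, typical of array replicates.
#' @param context_props 4 x 7 matrix of probe proportions over CpG context
#'   (rows) x gene region (columns); must sum to 1.
#' @param snp_fraction fraction of probes flagged as SNP-overlapping.
#' @param detp_fail_fraction per-(probe, sample) probability of a failed
#'   detection p-value (> 0.01).
#' @param n_genes size of the gene universe shared with the expression
#'   generator.
#' @param n_promoter_island_genes genes given planted promoter CpG-island
#'   DM CpGs, split evenly between hyper- and hypomethylated (in group A).
#' @param cpgs_per_gene planted promoter-island CpGs per such gene.
#' @param seed integer RNG seed.
#' @return Object of class `methyl_spec`.
#' @export
methyl_spec <- function(n_cpgs = 5000L, n_samples_a = 10L, n_samples_b = 10L,
                        dm_fraction = 0.035, delta_beta = 0.2,
                        precision = 50, context_props = default_context_props(),
                        snp_fraction = 0.02, detp_fail_fraction = 0.002,
                        n_genes = 2000L, n_promoter_island_genes = 40L,
                        cpgs_per_gene = 3L, seed = 1L) {
  abort_if(n_samples_a < 2L || n_samples_b < 2L,
           "need at least 2 samples per group", "itfpipe_invalid_spec")
  abort_if(dm_fraction < 0 || dm_fraction > 1 || snp_fraction < 0 ||
             snp_fraction > 1 || detp_fail_fraction < 0 || detp_fail_fraction > 1,
           "fractions must be in [0,1]", "itfpipe_invalid_spec")
  abort_if(abs(sum(context_props) - 1) > 1e-8,
           "context_props must sum to 1", "itfpipe_invalid_spec")
  structure(list(n_cpgs = as.integer(n_cpgs),
                 n_samples_a = as.integer(n_samples_a),
                 n_samples_b = as.integer(n_samples_b),
                 dm_fraction = dm_fraction, delta_beta = delta_beta,
                 precision = precision, context_props = context_props,
                 snp_fraction = snp_fraction,
                 detp_fail_fraction = detp_fail_fraction,
                 n_genes = as.integer(n_genes),
                 n_promoter_island_genes = as.integer(n_promoter_island_genes),
                 cpgs_per_gene = as.integer(cpgs_per_gene),
                 seed = as.integer(seed)),
            class = "methyl_spec")
}

#' EPIC-like joint proportions of CpG context x gene region
#' @return 4 x 7 matrix summing to 1.
#' @export
default_context_props <- function() {
  ctx <- c(island = 0.31, shore = 0.23, shelf = 0.10, open_sea = 0.36)
  reg <- c(TSS1500 = 0.13, TSS200 = 0.08, `5UTR` = 0.09, `1stExon` = 0.04,
           body = 0.36, `3UTR` = 0.03, IGR = 0.27)
  m <- outer(ctx, reg)
  m / sum(m)
}

#' Generate a synthetic methylation dataset with planted truth
#'
#' @param spec a [methyl_spec()].
#' @return list of class `methyl_dataset`: `beta` (CpG x sample matrix),
#'   `detp` (same shape), `annotation` (data.frame: cpg_id, chrom, pos,
#'   cpg_context, gene_region, gene_symbol, snp_flag), `groups` (named
#'   character vector sample -> "A"/"B"), and `truth` (list: `cpg`
#'   data.frame of planted CpGs with signed direction, `genes` data.frame
#'   of genes with planted promoter-island direction, `gene_universe`).
#' @export
generate_methylation_dataset <- function(spec) {
  stopifnot(inherits(spec, "methyl_spec"))
  set.seed(spec$seed)
  n <- spec$n_cpgs
  ns <- spec$n_samples_a + spec$n_samples_b
  cpg_ids <- sprintf("cg%08d", seq_len(n))
  samples <- c(sprintf("A%02d", seq_len(spec$n_samples_a)),
               sprintf("B%02d", seq_len(spec$n_samples_b)))
  groups <- stats::setNames(rep(c("A", "B"),
                                c(spec$n_samples_a, spec$n_samples_b)), samples)
  gene_universe <- sprintf("GENE%04d", seq_len(spec$n_genes))

  # context/region assignment from the joint proportion table
  cells <- expand.grid(cpg_context = CPG_CONTEXTS, gene_region = GENE_REGIONS,
                       stringsAsFactors = FALSE)
  probs <- as.vector(default_to_cells(spec$context_props))
  cell_idx <- sample.int(nrow(cells), n, replace = TRUE, prob = probs)
  annot <- data.frame(cpg_id = cpg_ids,
                      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
                      pos = sample.int(2e8, n, replace = TRUE),
                      cpg_context = cells$cpg_context[cell_idx],
                      gene_region = cells$gene_region[cell_idx],
                      gene_symbol = "", snp_flag = FALSE,
                      stringsAsFactors = FALSE)
  non_igr <- annot$gene_region != "IGR"
  annot$gene_symbol[non_igr] <- sample(gene_universe, sum(non_igr), replace = TRUE)

  # planted DM CpGs: promoter-island gene blocks first, remainder scattered
  n_dm <- round(spec$dm_fraction * n)
  n_block_genes <- spec$n_promoter_island_genes
  n_block <- min(n_dm, n_block_genes * spec$cpgs_per_gene)
  dm_idx <- integer(0); dm_dir <- integer(0)
  sig_genes <- character(0); sig_gene_dir <- integer(0)
  if (n_block > 0 && n_block_genes > 0) {
    blk_genes <- sample(gene_universe, n_block_genes)
    dirs <- rep(c(1L, -1L), length.out = n_block_genes)
    idx_pool <- seq_len(n)
    take <- sample(idx_pool, n_block)
    # rewrite these probes as promoter-island probes of the block genes
    gene_of <- rep(blk_genes, each = spec$cpgs_per_gene)[seq_len(n_block)]
    dir_of <- rep(dirs, each = spec$cpgs_per_gene)[seq_len(n_block)]
    annot$cpg_context[take] <- "island"
    annot$gene_region[take] <- sample(c("TSS1500", "TSS200"), n_block, TRUE)
    annot$gene_symbol[take] <- gene_of
    dm_idx <- take; dm_dir <- dir_of
    # only genes that actually received planted CpGs enter the truth
    got <- !duplicated(gene_of)
    sig_genes <- gene_of[got]; sig_gene_dir <- dir_of[got]
  }
  n_rest <- n_dm - length(dm_idx)
  if (n_rest > 0) {
    rest <- sample(setdiff(seq_len(n), dm_idx), n_rest)
    dm_idx <- c(dm_idx, rest)
    dm_dir <- c(dm_dir, sample(c(1L, -1L), n_rest, replace = TRUE))
  }
  if (spec$delta_beta == 0) dm_dir <- rep(0L, length(dm_idx))

  # SNP flags avoid planted probes so truth survives filtering
  n_snp <- round(spec$snp_fraction * n)
  if (n_snp > 0)
    annot$snp_flag[sample(setdiff(seq_len(n), dm_idx), n_snp)] <- TRUE

  # baseline means: bimodal mixture; planted CpGs kept away from the bounds
  mu <- numeric(n)
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  mu[comp == 1L] <- rbeta(sum(comp == 1L), 2, 10)
  mu[comp == 2L] <- rbeta(sum(comp == 2L), 10, 2)
  mu[comp == 3L] <- runif(sum(comp == 3L), 0.2, 0.8)
  mu[dm_idx] <- runif(length(dm_idx), 0.25, 0.75)

  mu_mat <- matrix(mu, n, ns)
  colnames(mu_mat) <- samples
  if (length(dm_idx) && spec$delta_beta != 0) {
    # group B shifted on the logit scale by the amount equivalent to a
    # beta-scale difference of delta_beta at the CpG's baseline
    is_b <- groups == "B"
    mu_b <- pmin(pmax(mu[dm_idx] - dm_dir * spec$delta_beta, 0.02), 0.98)
    shift <- qlogis(mu_b) - qlogis(mu[dm_idx])
    mu_mat[dm_idx, is_b] <- plogis(qlogis(mu[dm_idx]) + shift)
  }
  k <- spec$precision
  beta <- matrix(rbeta(n * ns, mu_mat * k, (1 - mu_mat) * k), n, ns,
                 dimnames = list(cpg_ids, samples))

  detp <- matrix(runif(n * ns, 0, 0.009), n, ns,
                 dimnames = list(cpg_ids, samples))
  fail <- matrix(runif(n * ns) < spec$detp_fail_fraction, n, ns)
  detp[fail] <- runif(sum(fail), 0.011, 0.2)

  truth_cpg <- data.frame(cpg_id = cpg_ids[dm_idx], direction = dm_dir,
                          stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_symbol = sig_genes,
                            direction = if (spec$delta_beta == 0)
                              rep(0L, length(sig_genes)) else sig_gene_dir,
                            stringsAsFactors = FALSE)
  structure(list(beta = beta, detp = detp, annotation = annot, groups = groups,
                 truth = list(cpg = truth_cpg, genes = truth_genes,
                              gene_universe = gene_universe),
                 spec = spec),
            class = "methyl_dataset")
}

# reorder a context x region matrix into the expand.grid cell order
default_to_cells <- function(m) {
  m <- m[CPG_CONTEXTS, GENE_REGIONS]
  as.vector(m)  # expand.grid varies context fastest, matching column-major
}

#' Specification of a synthetic expression count dataset
#'
#' Negative-binomial counts with planted differentially expressed genes.
#' A configurable number of planted DE genes is anti-coupled to the
#' methylation truth: by default 9 promoter-island hypermethylated genes
#' are downregulated and 11 hypomethylated genes are upregulated, matching
#' the composition of the epigenetic signature the integration stage
#' should recover.
#'
#' @param n_samples_a,n_samples_b samples per group.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param log2fc planted absolute log2 fold change of DE genes.
#' @param n_coupled_hyper_down,n_coupled_hypo_up numbers of
#'   methylation-coupled DE genes (defaults 9 and 11).
#' @param n_extra_up,n_extra_down planted DE genes independent of
#'   methylation (drawn from genes without planted methylation direction).
#' @param seed integer RNG seed.
#' @return Object of class `expr_spec`.
#' @export
expr_spec <- function(n_samples_a = 10L, n_samples_b = 10L,
                      nb_dispersion = 0.1, log2fc = 2,
                      n_coupled_hyper_down = 9L, n_coupled_hypo_up = 11L,
                      n_extra_up = 40L, n_extra_down = 40L, seed = 1L) {
  abort_if(n_samples_a < 2L || n_samples_b < 2L,
           "need at least 2 samples per group", "itfpipe_invalid_spec")
  structure(list(n_samples_a = as.integer(n_samples_a),
                 n_samples_b = as.integer(n_samples_b),
                 nb_dispersion = nb_dispersion, log2fc = log2fc,
                 n_coupled_hyper_down = as.integer(n_coupled_hyper_down),
                 n_coupled_hypo_up = as.integer(n_coupled_hypo_up),
                 n_extra_up = as.integer(n_extra_up),
                 n_extra_down = as.integer(n_extra_down),
                 seed = as.integer(seed)),
            class = "expr_spec")
}

#' Generate a synthetic expression count matrix anti-coupled to methylation
#'
#' @param spec an [expr_spec()].
#' @param methyl_truth the `truth` element of a [generate_methylation_dataset()]
#'   result (provides the gene universe and planted promoter-island
#'   methylation directions).
#' @return list of class `expr_dataset`: `counts` (gene x sample integer
#'   matrix), `groups`, and `truth` (data.frame: gene_symbol, log2fc,
#'   expr_sign, methyl_direction (0 when uncoupled), coupled).
#' @export
generate_expression_dataset <- function(spec, methyl_truth) {
  stopifnot(inherits(spec, "expr_spec"))
  set.seed(spec$seed + 1L)
  genes <- methyl_truth$gene_universe
  mg <- methyl_truth$genes
  hyper <- mg$gene_symbol[mg$direction == 1L]
  hypo <- mg$gene_symbol[mg$direction == -1L]
  abort_if(spec$log2fc != 0 &&
             (spec$n_coupled_hyper_down > length(hyper) ||
              spec$n_coupled_hypo_up > length(hypo)),
           "coupling request exceeds genes with planted methylation direction",
           "itfpipe_invalid_spec")
  ns <- spec$n_samples_a + spec$n_samples_b
  samples <- c(sprintf("A%02d", seq_len(spec$n_samples_a)),
               sprintf("B%02d", seq_len(spec$n_samples_b)))
  groups <- stats::setNames(rep(c("A", "B"),
                                c(spec$n_samples_a, spec$n_samples_b)), samples)

  lfc <- stats::setNames(numeric(length(genes)), genes)
  coupled <- stats::setNames(logical(length(genes)), genes)
  if (spec$log2fc != 0) {
    g_hd <- if (spec$n_coupled_hyper_down > 0) hyper[seq_len(spec$n_coupled_hyper_down)] else character(0)
    g_hu <- if (spec$n_coupled_hypo_up > 0) hypo[seq_len(spec$n_coupled_hypo_up)] else character(0)
    lfc[g_hd] <- -spec$log2fc     # hypermethylated in A, downregulated in A
    lfc[g_hu] <- spec$log2fc
    coupled[c(g_hd, g_hu)] <- TRUE
    free <- setdiff(genes, mg$gene_symbol)
    extra <- sample(free, spec$n_extra_up + spec$n_extra_down)
    lfc[extra[seq_len(spec$n_extra_up)]] <- spec$log2fc
    if (spec$n_extra_down > 0)
      lfc[extra[spec$n_extra_up + seq_len(spec$n_extra_down)]] <- -spec$log2fc
  }

  base <- exp(rnorm(length(genes), 5, 1.2))
  libfac <- runif(ns, 0.7, 1.3)
  mu <- outer(base, rep(1, ns))
  is_a <- groups == "A"
  mu[, is_a] <- mu[, is_a] * 2^(lfc / 2)
  mu[, !is_a] <- mu[, !is_a] * 2^(-lfc / 2)
  mu <- sweep(mu, 2, libfac, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                   nrow = length(genes), dimnames = list(genes, samples))

  md <- stats::setNames(rep(0L, length(genes)), genes)
  md[mg$gene_symbol] <- mg$direction
  truth <- data.frame(gene_symbol = genes, log2fc = unname(lfc),
                      expr_sign = sign(unname(lfc)),
                      methyl_direction = unname(md[genes]),
                      coupled = unname(coupled), stringsAsFactors = FALSE)
  truth <- truth[truth$log2fc != 0 | truth$coupled, , drop = FALSE]
  structure(list(counts = counts, groups = groups, truth = truth, spec = spec),
            class = "expr_dataset")
}
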