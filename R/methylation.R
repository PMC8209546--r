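#' Quantile normalization of a beta-value matrix
#'
#' Each sample's sorted values are replaced by the rank-wise mean across
#' samples; ties receive the mean over their rank span.  Backed by
#' `limma::normalizeQuantiles`.
#'
#' @param beta CpG x sample matrix of beta values.
#' @return Normalized matrix, same dimnames, values still in \[0, 1\].
#' @export
quantile_normalize <- function(beta) {
  abort_if(!is.numeric(beta), "beta matrix must be numeric", "itfpipe_schema")
  abort_if(ncol(beta) < 2L, "need >= 2 samples", "itfpipe_invalid_parameter")
  out <- limma::normalizeQuantiles(as.matrix(beta), ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}

#' Filter probes by SNP flag and detection p-value
#'
#' Two-step filtering: probes flagged as SNP-overlapping are removed,
#' then probes whose detection p-value exceeds `p_max` in any sample are
#' removed (whole-probe removal keeps the matrix rectangular).
#'
#' @param beta CpG x sample beta matrix.
#' @param detp detection p-value matrix, same shape.
#' @param annotation probe annotation data.frame with `cpg_id`,
#'   `snp_flag`; must cover every probe.
#' @param p_max detection p-value ceiling (default 0.01).
#' @return list: `beta`, `detp`, `annotation` (filtered, in matrix row
#'   order), `n_valid` (retained probe count).
#' @export
filter_probes <- function(beta, detp, annotation, p_max = 0.01) {
  abort_if(!identical(dim(beta), dim(detp)), "beta/detp shapes differ",
           "itfpipe_schema")
  ids <- rownames(beta)
  abort_if(!all(ids %in% annotation$cpg_id),
           "annotation missing for some probes", "itfpipe_schema")
  ann <- annotation[match(ids, annotation$cpg_id), , drop = FALSE]
  keep <- !ann$snp_flag
  keep <- keep & rowSums(detp > p_max) == 0L
  list(beta = beta[keep, , drop = FALSE], detp = detp[keep, , drop = FALSE],
       annotation = ann[keep, , drop = FALSE], n_valid = sum(keep))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact for combined n <= `exact_max` without ties; normal approximation
#' with tie correction (and continuity correction) otherwise; returns 1
#' for fully tied data.
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined sample size for the exact test.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L) {
  if (length(unique(c(x, y))) == 1L) return(1)
  n <- length(x) + length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0L
  suppressWarnings(
    wilcox.test(x, y, exact = (n <= exact_max) && !has_ties,
                correct = TRUE)$p.value)
}

#' Differential methylation test across all CpGs
#'
#' Per-CpG two-sided Wilcoxon rank-sum between the two groups with
#' Benjamini-Hochberg adjustment; a CpG is significant when its q-value
#' is below `fdr`.
#'
#' @param beta CpG x sample beta matrix (filtered, normalized).
#' @param groups named vector mapping sample (column) names to two group
#'   labels; the first level alphabetically is group A.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return data.frame of class `dmcpg_table`: `cpg_id`, `delta_beta`
#'   (mean A - mean B), `wilcoxon_p`, `fdr_q`, `significant`.
#' @export
dmcpg_test <- function(beta, groups, fdr = 0.05) {
  g <- as.character(groups[colnames(beta)])
  abort_if(anyNA(g), "groups missing for some samples",
           "itfpipe_invalid_grouping")
  lv <- sort(unique(g))   # group A = first level alphabetically
  abort_if(length(lv) != 2L, "exactly two groups required",
           "itfpipe_invalid_grouping")
  ia <- which(g == lv[1]); ib <- which(g == lv[2])
  abort_if(length(ia) < 2L || length(ib) < 2L, "need >= 2 samples per group",
           "itfpipe_invalid_grouping")
  delta <- rowMeans(beta[, ia, drop = FALSE]) -
    rowMeans(beta[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(beta)), function(i)
    wilcoxon_rank_sum(beta[i, ia], beta[i, ib]), numeric(1))
  q <- p.adjust(p, method = "BH")
  structure(data.frame(cpg_id = rownames(beta), delta_beta = delta,
                       wilcoxon_p = p, fdr_q = q, significant = q < fdr,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("dmcpg_table", "data.frame"))
}

#' Genomic distribution of significant DMCpGs
#'
#' Cross-tabulates significant CpGs over CpG context and gene region;
#' marginal percentages sum to 100 on each axis.
#'
#' @param dm a `dmcpg_table`.
#' @param annotation probe annotation covering the DMCpGs.
#' @return list: `joint` (context x region count matrix), `context`
#'   and `region` (data.frames with counts and percentages), `total`.
#' @export
genomic_distribution <- function(dm, annotation) {
  abort_if(nrow(dm) == 0L, "empty DMCpG table", "itfpipe_invalid_parameter")
  sig <- dm$cpg_id[dm$significant]
  ann <- annotation[match(sig, annotation$cpg_id), , drop = FALSE]
  ctx <- factor(ann$cpg_context, levels = CPG_CONTEXTS)
  reg <- factor(ann$gene_region, levels = GENE_REGIONS)
  joint <- table(ctx, reg)
  n <- length(sig)
  ctx_df <- data.frame(cpg_context = CPG_CONTEXTS,
                       count = as.integer(table(ctx)),
                       pct = if (n) 100 * as.integer(table(ctx)) / n else 0)
  reg_df <- data.frame(gene_region = GENE_REGIONS,
                       count = as.integer(table(reg)),
                       pct = if (n) 100 * as.integer(table(reg)) / n else 0)
  list(joint = unclass(joint), context = ctx_df, region = reg_df, total = n)
}

#' Promoter CpG-island methylation signature
#'
#' Significant CpGs located in CpG islands within promoter regions
#' (TSS1500 or TSS200 by default), with their gene mapping (empty gene
#' symbols dropped from the map).
#'
#' @param dm a `dmcpg_table`.
#' @param annotation probe annotation.
#' @param promoter_regions gene regions counted as promoter.
#' @return list: `cpgs` (character vector), `gene_map` (data.frame
#'   cpg_id, gene_symbol), `n_cpgs`, `n_genes` (distinct symbols).
#' @export
promoter_cgi_signature <- function(dm, annotation,
                                   promoter_regions = c("TSS1500", "TSS200")) {
  sig <- dm$cpg_id[dm$significant]
  ann <- annotation[match(sig, annotation$cpg_id), , drop = FALSE]
  keep <- ann$cpg_context == "island" & ann$gene_region %in% promoter_regions
  cpgs <- sig[keep]
  gm <- data.frame(cpg_id = cpgs,
                   gene_symbol = ann$gene_symbol[keep],
                   stringsAsFactors = FALSE)
  gm <- gm[!is.na(gm$gene_symbol) & gm$gene_symbol != "", , drop = FALSE]
  list(cpgs = cpgs, gene_map = gm, n_cpgs = length(cpgs),
       n_genes = length(unique(gm$gene_symbol)))
}

#' Hierarchical clustering on a CpG set and group-mean concordance
#'
#' Samples are clustered on the beta sub-matrix of the given CpGs
#' (Euclidean distance, average linkage).  The concordance R^2 is the
#' squared Pearson correlation of per-CpG group means computed over ALL
#' CpGs of the matrix (the genome-wide scatter-plot statistic), not just
#' the signature.
#'
#' @param beta CpG x sample matrix.
#' @param cpgs CpG ids to cluster on (>= 2).
#' @param groups named sample -> group vector.
#' @return list: `hclust` (the tree), `order` (sample order),
#'   `clusters` (2-cut labels), `r_squared`.
#' @export
cluster_and_concordance <- function(beta, cpgs, groups) {
  cpgs <- intersect(cpgs, rownames(beta))
  abort_if(length(cpgs) < 2L, "need >= 2 CpGs in the signature",
           "itfpipe_insufficient_signature")
  sub <- beta[cpgs, , drop = FALSE]
  hc <- hclust(dist(t(sub)), method = "average")
  cl <- cutree(hc, k = 2L)
  g <- as.character(groups[colnames(beta)])
  lv <- unique(g)
  ma <- rowMeans(beta[, g == lv[1], drop = FALSE])
  mb <- rowMeans(beta[, g == lv[2], drop = FALSE])
  list(hclust = hc, order = colnames(sub)[hc$order], clusters = cl,
       r_squared = cor(ma, mb)^2)
}
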