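#' Surrogate differential-expression test on a count matrix
#'
#' A deliberately simple stand-in for a full negative-binomial DE engine:
#' median-of-ratios library-size normalization, per-gene two-sided
#' Wilcoxon rank-sum on `log2(normalized + 1)`, Benjamini-Hochberg
#' adjustment; `log2fc` is the difference of group means of
#' `log2(normalized + 1)` (group A minus group B).  Users with an
#' externally computed DE table can bypass this entirely.
#'
#' @param counts gene x sample count matrix.
#' @param groups named sample -> group vector (two groups; the first
#'   level alphabetically is group A, so relabeling exactly negates
#'   log2fc).
#' @return data.frame of class `de_table`: `gene_symbol`, `log2fc`,
#'   `p`, `adj_p`.
#' @export
surrogate_de <- function(counts, groups) {
  g <- as.character(groups[colnames(counts)])
  lv <- sort(unique(g))   # group A = first level alphabetically
  abort_if(length(lv) != 2L, "exactly two groups required",
           "itfpipe_invalid_grouping")
  abort_if(min(table(g)) < 2L, "need >= 2 samples per group",
           "itfpipe_invalid_grouping")
  # median-of-ratios size factors over genes with all-positive counts
  logc <- log(counts)
  ok <- is.finite(rowMeans(logc))
  abort_if(!any(ok), "no gene with all-positive counts for normalization",
           "itfpipe_schema")
  logmeans <- rowMeans(logc[ok, , drop = FALSE])
  sf <- apply(counts[ok, , drop = FALSE], 2,
              function(cc) exp(stats::median(log(cc) - logmeans)))
  norm <- sweep(counts, 2, sf, `/`)
  l <- log2(norm + 1)
  ia <- which(g == lv[1]); ib <- which(g == lv[2])
  lfc <- rowMeans(l[, ia, drop = FALSE]) - rowMeans(l[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(l)), function(i)
    wilcoxon_rank_sum(l[i, ia], l[i, ib]), numeric(1))
  structure(data.frame(gene_symbol = rownames(counts), log2fc = lfc,
                       p = p, adj_p = p.adjust(p, "BH"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"))
}

#' Collapse signature CpGs to a per-gene methylation direction
#'
#' Per gene, the direction is the sign of the mean `delta_beta` over its
#' signature CpGs; genes with `|mean| < min_delta`, or whose CpG signs
#' are tied with no majority, are dropped.
#'
#' @param signature result of [promoter_cgi_signature()] (uses `gene_map`).
#' @param dm the `dmcpg_table` providing `delta_beta` per CpG.
#' @param min_delta minimum absolute mean delta-beta (default 0.05).
#' @return data.frame: `gene_symbol`, `mean_delta_beta`, `direction`
#'   (+1 hypermethylated in A, -1 hypomethylated), `n_cpgs`.
#' @export
gene_methylation_direction <- function(signature, dm, min_delta = 0.05) {
  gm <- signature$gene_map
  abort_if(!all(gm$cpg_id %in% dm$cpg_id),
           "signature CpG missing from DMCpG table", "itfpipe_schema")
  if (nrow(gm) == 0L)
    return(data.frame(gene_symbol = character(), mean_delta_beta = numeric(),
                      direction = integer(), n_cpgs = integer()))
  db <- dm$delta_beta[match(gm$cpg_id, dm$cpg_id)]
  sp <- split(db, gm$gene_symbol)
  md <- vapply(sp, mean, numeric(1))
  npos <- vapply(sp, function(v) sum(v > 0), numeric(1))
  nneg <- vapply(sp, function(v) sum(v < 0), numeric(1))
  keep <- abs(md) >= min_delta & npos != nneg
  data.frame(gene_symbol = names(sp)[keep],
             mean_delta_beta = unname(md[keep]),
             direction = as.integer(sign(md[keep])),
             n_cpgs = unname(vapply(sp, length, numeric(1))[keep]),
             stringsAsFactors = FALSE)
}

#' Build the epigenetic signature from methylation and expression
#'
#' Intersects per-gene methylation direction with differential-expression
#' direction at `adj_p < q_max`: genes hypermethylated in group A with
#' downregulated expression in A form `hyper_down`; hypomethylated and
#' upregulated genes form `hypo_up`.
#'
#' @param directions output of [gene_methylation_direction()].
#' @param de a `de_table` (gene_symbol, log2fc, adj_p).
#' @param signature the [promoter_cgi_signature()] result (for the CpG
#'   back-mapping of member genes).
#' @param q_max adjusted-p threshold for the DE arm.
#' @return Object of class `epigenetic_signature`: list with `hyper_down`,
#'   `hypo_up` (gene character vectors), `cpgs` (data.frame cpg_id,
#'   gene_symbol restricted to member genes), `n_genes`.
#' @export
build_signature <- function(directions, de, signature = NULL, q_max = 0.05) {
  de_sig <- de[!is.na(de$adj_p) & de$adj_p < q_max, , drop = FALSE]
  m <- merge(directions, de_sig, by = "gene_symbol")
  hyper_down <- sort(m$gene_symbol[m$direction == 1L & m$log2fc < 0])
  hypo_up <- sort(m$gene_symbol[m$direction == -1L & m$log2fc > 0])
  members <- c(hyper_down, hypo_up)
  cpgs <- if (!is.null(signature))
    signature$gene_map[signature$gene_map$gene_symbol %in% members, ,
                       drop = FALSE]
  else data.frame(cpg_id = character(), gene_symbol = character())
  structure(list(hyper_down = hyper_down, hypo_up = hypo_up, cpgs = cpgs,
                 n_genes = length(members)),
            class = "epigenetic_signature")
}

#' Does the signature separate the groups?
#'
#' Samples are clustered on the beta values of the signature CpGs
#' (Euclidean distance, average linkage, cut into two clusters); returns
#' the adjusted Rand index against the true group labels.
#'
#' @param beta CpG x sample matrix.
#' @param signature an `epigenetic_signature` (or a CpG id vector).
#' @param groups named sample -> group vector.
#' @return ARI in \[-1, 1\]; 1 means perfect recovery of the groups.
#' @export
signature_separation <- function(beta, signature, groups) {
  cpgs <- if (inherits(signature, "epigenetic_signature"))
    unique(signature$cpgs$cpg_id) else signature
  cpgs <- intersect(cpgs, rownames(beta))
  abort_if(length(cpgs) < 2L, "empty or singleton signature",
           "itfpipe_insufficient_signature")
  hc <- hclust(dist(t(beta[cpgs, , drop = FALSE])), method = "average")
  cl <- cutree(hc, k = 2L)
  adjusted_rand_index(cl, as.character(groups[colnames(beta)]))
}
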