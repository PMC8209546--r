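test_that("quantile normalization: identities and the sort-average oracle", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)) / 10
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, 1]), c(0.25, 0.35, 0.45))
  expect_equal(sort(qn[, 2]), c(0.25, 0.35, 0.45))

  # identical multisets are unchanged up to reordering
  m2 <- cbind(a = c(0.3, 0.1, 0.2), b = c(0.1, 0.2, 0.3))
  qn2 <- quantile_normalize(m2)
  expect_equal(sort(qn2[, 1]), sort(m2[, 1]))
  expect_equal(qn2[, 2], m2[, 2])

  cst <- matrix(0.4, 5, 3)
  expect_equal(quantile_normalize(cst), cst, ignore_attr = TRUE)

  # oracle: columnwise sort, rowwise mean, reassign by rank (no ties)
  set.seed(6)
  m3 <- matrix(runif(40), 10, 4)
  qn3 <- quantile_normalize(m3)
  ref_means <- rowMeans(apply(m3, 2, sort))
  want <- apply(m3, 2, function(col) ref_means[rank(col)])
  expect_equal(qn3, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("probe filtering matches manual enumeration", {
  beta <- matrix(0.5, 5, 3, dimnames = list(paste0("cg", 1:5), paste0("s", 1:3)))
  detp <- matrix(0.001, 5, 3, dimnames = dimnames(beta))
  detp["cg3", 2] <- 0.02
  ann <- data.frame(cpg_id = paste0("cg", 1:5), snp_flag = c(TRUE, rep(FALSE, 4)))
  f <- filter_probes(beta, detp, ann)
  expect_equal(f$n_valid, 3L)                 # cg1 is SNP, cg3 fails detp
  expect_setequal(rownames(f$beta), c("cg2", "cg4", "cg5"))
  ann$snp_flag <- FALSE
  expect_equal(filter_probes(beta, detp, ann, p_max = 1)$n_valid, 5L)
  expect_error(filter_probes(beta, detp, ann[1:3, ]), class = "itfpipe_schema")
})

test_that("expected retained probe count under Bernoulli filtering", {
  keep <- vapply(1:5, function(sd) {
    md <- generate_methylation_dataset(methyl_spec(n_cpgs = 2000, seed = sd))
    filter_probes(md$beta, md$detp, md$annotation)$n_valid
  }, numeric(1))
  want <- 2000 * (1 - 0.02) * (1 - 0.002)^20
  expect_lt(abs(mean(keep) - want) / want, 0.02)
})

test_that("Wilcoxon rank-sum: exact enumeration oracle, separation, ties", {
  expect_equal(wilcoxon_rank_sum(c(0.1, 0.15, 0.2), c(0.8, 0.85, 0.9)), 0.1)
  expect_equal(wilcoxon_rank_sum(rep(0.4, 5), rep(0.4, 6)), 1)
  set.seed(77)
  for (i in 1:50) {
    nx <- sample(2:4, 1); ny <- sample(2:4, 1)
    x <- round(runif(nx), 3); y <- round(runif(ny), 3)
    if (anyDuplicated(c(x, y))) next  # exact path is tie-free by contract
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcox_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the step-up definition and is monotone", {
  expect_equal(p.adjust(rep(0.03, 7), "BH"), rep(0.03, 7))  # flat p -> q = p
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))
    q <- p.adjust(p, "BH")
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))    # monotone in p-rank
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("DMCpG calling: sensitivity >= 0.9 and observed FDR <= 0.1 at defaults", {
  md <- generate_methylation_dataset(methyl_spec(seed = 42))
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  truth_ids <- md$truth$cpg$cpg_id
  surviving <- intersect(truth_ids, dm$cpg_id)
  sens <- mean(dm$significant[match(surviving, dm$cpg_id)])
  called <- dm$cpg_id[dm$significant]
  fdr_obs <- if (length(called)) mean(!(called %in% truth_ids)) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr_obs, 0.1)
  expect_true(all(dm$significant == (dm$fdr_q < 0.05)))
  expect_true(all(abs(dm$delta_beta) <= 1))
})

test_that("global null: fraction significant at FDR 0.05 stays <= 0.05", {
  md <- generate_methylation_dataset(methyl_spec(
    n_cpgs = 2000, delta_beta = 0, seed = 404))
  dm <- dmcpg_test(md$beta, md$groups)
  expect_lte(mean(dm$significant), 0.05)
})

test_that("genomic distribution: totals, percentages, degenerate all-island case", {
  md <- generate_methylation_dataset(methyl_spec(seed = 2))
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  gd <- genomic_distribution(dm, filt$annotation)
  expect_equal(gd$total, sum(dm$significant))
  expect_equal(sum(gd$context$pct), 100, tolerance = 1e-9)
  expect_equal(sum(gd$region$pct), 100, tolerance = 1e-9)
  expect_equal(sum(gd$joint), gd$total)

  # force everything into islands
  ann2 <- filt$annotation
  ann2$cpg_context <- "island"
  gd2 <- genomic_distribution(dm, ann2)
  expect_equal(gd2$context$pct[gd2$context$cpg_context == "island"], 100)
})

test_that("promoter CGI signature: subset property and gene counting", {
  md <- generate_methylation_dataset(methyl_spec(seed = 2))
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  sig <- promoter_cgi_signature(dm, filt$annotation)
  expect_true(all(sig$cpgs %in% dm$cpg_id[dm$significant]))
  ann_sig <- filt$annotation[match(sig$cpgs, filt$annotation$cpg_id), ]
  expect_true(all(ann_sig$cpg_context == "island"))
  expect_true(all(ann_sig$gene_region %in% c("TSS1500", "TSS200")))
  expect_equal(sig$n_genes, length(unique(sig$gene_map$gene_symbol)))

  # tiny constructed case: 3 CpGs on 2 genes
  dm3 <- data.frame(cpg_id = c("c1", "c2", "c3"), delta_beta = 0.2,
                    wilcoxon_p = 0.001, fdr_q = 0.001, significant = TRUE)
  ann3 <- data.frame(cpg_id = c("c1", "c2", "c3"), cpg_context = "island",
                     gene_region = "TSS200",
                     gene_symbol = c("G1", "G1", "G2"), snp_flag = FALSE)
  s3 <- promoter_cgi_signature(dm3, ann3)
  expect_equal(s3$n_genes, 2L)

  # no island-promoter DMCpGs -> empty signature
  ann3$cpg_context <- "open_sea"
  expect_equal(promoter_cgi_signature(dm3, ann3)$n_cpgs, 0L)
})

test_that("clustering recovers planted groups; dendrogram has n-1 merges", {
  md <- generate_methylation_dataset(methyl_spec(
    n_cpgs = 1000, delta_beta = 0.3, seed = 5))
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  sig <- promoter_cgi_signature(dm, filt$annotation)
  cc <- cluster_and_concordance(filt$beta, sig$cpgs, md$groups)
  expect_equal(adjusted_rand_index(cc$clusters, md$groups[names(cc$clusters)]),
               1.0)
  expect_equal(nrow(cc$hclust$merge), ncol(md$beta) - 1L)
  expect_gt(cc$r_squared, 0.9)   # groups share the global methylation pattern
  expect_error(cluster_and_concordance(filt$beta, character(0), md$groups),
               class = "itfpipe_insufficient_signature")
})
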