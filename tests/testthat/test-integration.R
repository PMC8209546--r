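test_that("surrogate DE: antisymmetry, null control, planted recovery", {
  w <- small_methyl_world(seed = 19)
  counts <- w$ed$counts; groups <- w$ed$groups
  de <- surrogate_de(counts, groups)
  swapped <- stats::setNames(ifelse(groups == "A", "B", "A"), names(groups))
  de2 <- surrogate_de(counts, swapped)
  expect_equal(de$log2fc, -de2$log2fc, tolerance = 1e-12)
  expect_equal(de$p, de2$p, tolerance = 1e-12)

  planted <- w$ed$truth$gene_symbol[w$ed$truth$log2fc != 0]
  called <- de$gene_symbol[de$adj_p < 0.05]
  sens <- mean(planted %in% called)
  expect_gte(sens, 0.9)
  # direction of recovered fold changes matches the plant
  got <- de[match(planted, de$gene_symbol), ]
  tr <- w$ed$truth[match(planted, w$ed$truth$gene_symbol), ]
  expect_gt(mean(sign(got$log2fc) == tr$expr_sign), 0.95)

  # identical groups -> false-positive fraction controlled
  md0 <- generate_methylation_dataset(methyl_spec(
    n_cpgs = 400, n_genes = 500, seed = 3))
  e0 <- generate_expression_dataset(expr_spec(log2fc = 0, seed = 3), md0$truth)
  de0 <- surrogate_de(e0$counts, e0$groups)
  expect_lte(mean(de0$adj_p < 0.05), 0.05)
})

test_that("gene methylation direction follows mean delta-beta with floor and majority", {
  dm <- data.frame(cpg_id = paste0("c", 1:7),
                   delta_beta = c(0.2, 0.3, 0.2, -0.2, 0.3, 0.1, -0.05),
                   wilcoxon_p = 0, fdr_q = 0, significant = TRUE)
  sig <- list(gene_map = data.frame(
    cpg_id = paste0("c", 1:7),
    gene_symbol = c("G1", "G1", "G2", "G2", "G3", "G3", "G3")))
  d <- gene_methylation_direction(sig, dm)
  expect_equal(d$direction[d$gene_symbol == "G1"], 1L)      # {+0.2,+0.3}
  expect_false("G2" %in% d$gene_symbol)                     # {+0.2,-0.2} cancels
  g3 <- d[d$gene_symbol == "G3", ]                          # {+0.3,+0.1,-0.05}
  expect_equal(g3$direction, 1L)
  expect_equal(g3$mean_delta_beta, mean(c(0.3, 0.1, -0.05)), tolerance = 1e-12)
})

test_that("build_signature equals brute-force set logic", {
  dirs <- data.frame(gene_symbol = c("A", "B", "C"),
                     mean_delta_beta = c(0.2, -0.2, 0.2),
                     direction = c(1L, -1L, 1L), n_cpgs = 1L)
  de <- data.frame(gene_symbol = c("A", "B", "C"),
                   log2fc = c(-2, 1.5, 0.5), adj_p = c(0.001, 0.001, 0.001))
  s <- build_signature(dirs, de)
  expect_equal(s$hyper_down, "A")
  expect_equal(s$hypo_up, "B")
  expect_equal(s$n_genes, 2L)

  set.seed(55)
  for (i in 1:20) {
    n <- 60
    genes <- paste0("g", seq_len(n))
    dirs <- data.frame(gene_symbol = genes, mean_delta_beta = 0,
                       direction = sample(c(-1L, 1L), n, TRUE), n_cpgs = 1L)
    de <- data.frame(gene_symbol = sample(genes), log2fc = rnorm(n),
                     adj_p = runif(n, 0, 0.1))
    s <- build_signature(dirs, de)
    # brute force over the cross product
    hd <- hu <- character(0)
    for (g in genes) {
      dd <- dirs$direction[dirs$gene_symbol == g]
      row <- de[de$gene_symbol == g, ]
      if (row$adj_p >= 0.05) next
      if (dd == 1L && row$log2fc < 0) hd <- c(hd, g)
      if (dd == -1L && row$log2fc > 0) hu <- c(hu, g)
    }
    expect_equal(s$hyper_down, sort(hd))
    expect_equal(s$hypo_up, sort(hu))
    expect_length(intersect(s$hyper_down, s$hypo_up), 0)
  }
})

test_that("empty DE table gives an empty signature", {
  dirs <- data.frame(gene_symbol = "A", mean_delta_beta = 0.2,
                     direction = 1L, n_cpgs = 1L)
  de <- data.frame(gene_symbol = character(), log2fc = numeric(),
                   adj_p = numeric())
  s <- build_signature(dirs, de)
  expect_equal(s$n_genes, 0L)
})

test_that("signature separation: planted bimodal -> ARI 1; invariances; null ~ 0", {
  md <- generate_methylation_dataset(methyl_spec(n_cpgs = 1000, seed = 6))
  cpgs <- md$truth$cpg$cpg_id[1:30]
  sig <- structure(list(cpgs = data.frame(cpg_id = cpgs, gene_symbol = "G")),
                   class = "epigenetic_signature")
  expect_equal(signature_separation(md$beta, sig, md$groups), 1.0)
  # invariant to group label swap
  swapped <- stats::setNames(ifelse(md$groups == "A", "B", "A"),
                             names(md$groups))
  expect_equal(signature_separation(md$beta, sig, swapped), 1.0)
  expect_error(signature_separation(md$beta,
                                    structure(list(cpgs = data.frame(
                                      cpg_id = character(),
                                      gene_symbol = character())),
                                      class = "epigenetic_signature"),
                                    md$groups),
               class = "itfpipe_insufficient_signature")
  # random labels: near-zero ARI on average
  set.seed(31)
  null_cpgs <- setdiff(rownames(md$beta), md$truth$cpg$cpg_id)
  aris <- vapply(1:20, function(i) {
    rl <- stats::setNames(sample(md$groups), names(md$groups))
    sig_i <- structure(list(cpgs = data.frame(
      cpg_id = sample(null_cpgs, 40), gene_symbol = "G")),
      class = "epigenetic_signature")
    signature_separation(md$beta, sig_i, rl)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("end-to-end: default synthetic run recovers the planted 9/11 signature exactly", {
  md <- generate_methylation_dataset(methyl_spec(seed = 7))
  ed <- generate_expression_dataset(expr_spec(seed = 7), md$truth)
  filt <- filter_probes(md$beta, md$detp, md$annotation)
  dm <- dmcpg_test(filt$beta, md$groups)
  sig <- promoter_cgi_signature(dm, filt$annotation)
  de <- surrogate_de(ed$counts, ed$groups)
  dirs <- gene_methylation_direction(sig, dm)
  esig <- build_signature(dirs, de, sig)
  planted_hd <- sort(ed$truth$gene_symbol[ed$truth$coupled & ed$truth$expr_sign < 0])
  planted_hu <- sort(ed$truth$gene_symbol[ed$truth$coupled & ed$truth$expr_sign > 0])
  expect_identical(esig$hyper_down, planted_hd)
  expect_identical(esig$hypo_up, planted_hu)
  expect_equal(esig$n_genes, 20L)
  expect_equal(signature_separation(filt$beta, esig, md$groups), 1.0)
})
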