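test_that("TSS occupancy averages the track over the +/- 2 kbp window", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      tss = c(10000, 50000), strand = "+",
                      stringsAsFactors = FALSE)
  const <- data.frame(chrom = "chr1", start = 0, end = 100000, score = 1)
  occ <- tss_occupancy(const, genes)
  expect_equal(occ$per_gene$occupancy, c(1, 1))

  zero <- const; zero$score <- 0
  expect_equal(tss_occupancy(zero, genes)$per_gene$occupancy, c(0, 0))

  # detected genes with 2x signal: contrast recovers the ratio
  track <- data.frame(chrom = "chr1",
                      start = c(8000, 48000), end = c(12000, 52000),
                      score = c(2, 1))
  res <- tss_occupancy(track, genes, detected = "g1")
  expect_equal(unname(res$medians["detected"] / res$medians["other"]), 2)
  expect_s3_class(res$test, "htest")

  # window truncated at the chromosome start is normalized by covered width
  g_edge <- data.frame(gene_id = "gE", chrom = "chr1", tss = 500,
                       strand = "+", stringsAsFactors = FALSE)
  occ_e <- tss_occupancy(const, g_edge, chrom_lengths = c(chr1 = 100000))
  expect_equal(occ_e$per_gene$occupancy, 1)
})

test_that("intervening CTCF counts use strict betweenness of peak midpoints", {
  ctcf <- data.frame(chrom = "chr1",
                     start = c(150, 250, 550), end = c(250, 350, 650),
                     stringsAsFactors = FALSE)   # midpoints 200, 300, 600
  vp <- list(chrom = "chr1", pos = 100)
  gene <- list(chrom = "chr1", tss = 500)
  expect_equal(ctcf_between(vp, gene, ctcf), 2L)
  # symmetry
  expect_equal(ctcf_between(list(chrom = "chr1", pos = 500),
                            list(chrom = "chr1", tss = 100), ctcf), 2L)
  # no peaks between
  expect_equal(ctcf_between(list(chrom = "chr1", pos = 601),
                            list(chrom = "chr1", tss = 700), ctcf), 0L)
  # endpoints are exclusive
  expect_equal(ctcf_between(list(chrom = "chr1", pos = 200),
                            list(chrom = "chr1", tss = 600), ctcf), 1L)
  # additivity: splitting at an intermediate point not at a midpoint sums
  a <- ctcf_between(list(chrom = "chr1", pos = 100),
                    list(chrom = "chr1", tss = 400), ctcf)
  b <- ctcf_between(list(chrom = "chr1", pos = 400),
                    list(chrom = "chr1", tss = 700), ctcf)
  expect_equal(a + b, ctcf_between(list(chrom = "chr1", pos = 100),
                                   list(chrom = "chr1", tss = 700), ctcf))
  expect_error(ctcf_between(list(chrom = "chr2", pos = 1), gene, ctcf),
               "different chromosomes")
})

test_that("eQTL concordance splits eQTL genes into interacting vs near non-interacting", {
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                      tss = seq(1e5, 1e6, length.out = 10), strand = "+",
                      stringsAsFactors = FALSE)
  vp <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 5e5,
                   stringsAsFactors = FALSE)
  cand <- data.frame(snp_id = "rs1", gene_id = paste0("g", 1:7),
                     stringsAsFactors = FALSE)
  # 10 eQTL genes, 7 of them candidates
  eqtl <- data.frame(snp_id = "rs1", gene_id = paste0("g", 1:10),
                     stringsAsFactors = FALSE)
  res <- eqtl_concordance(eqtl, cand, genes, vp)
  expect_equal(res$per_snp$frac_interacting, 0.7)
  expect_equal(res$total_interacting_fraction, 0.7)
  expect_equal(res$total_noninteracting_fraction, 0.3)

  # eQTL genes outside the annotation are dropped before scoring
  eqtl2 <- rbind(eqtl, data.frame(snp_id = "rs1", gene_id = "not_annotated"))
  res2 <- eqtl_concordance(eqtl2, cand, genes, vp)
  expect_equal(res2$n_dropped, 1L)
  expect_equal(res2$per_snp$n_eqtl, 10L)

  # constructed subset of candidates gives concordance 1
  eqtl3 <- data.frame(snp_id = "rs1", gene_id = paste0("g", 1:5),
                      stringsAsFactors = FALSE)
  expect_equal(eqtl_concordance(eqtl3, cand, genes, vp)$total_interacting_fraction, 1)
})

test_that("gene-set concordance is the recovered fraction of the first set", {
  expect_equal(geneset_concordance(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(geneset_concordance(c("a", "b"), c("c")), 0)
  expect_equal(geneset_concordance(c("a", "b", "c", "d"), c("a", "b", "x")), 0.5)
  expect_error(geneset_concordance(character(), "a"), "empty")
})

test_that("replicate synthetic runs give high gene-set concordance at strong effect", {
  # same planted truth, different coverage noise (different cell types act
  # as biological replicates of the same viewpoint)
  cfg <- strong_config(seed = 31, n_viewpoints = 2)
  res <- run_fourc_study(simulate_study(cfg))
  sets <- split(res$candidates$gene_id, res$candidates$cell_type)
  cc <- geneset_concordance(sets[[1]], sets[[2]])
  expect_gte(cc, 0.9)
})

test_that("enrichment score matches the brute-force running sum", {
  r6 <- setNames(c(3, 2, 1, -1, -2, -3), paste0("g", 1:6))
  # hand walk for set {g1,g2}: hits weight 3/5, 2/5; misses -1/4 each
  running <- cumsum(c(3 / 5, 2 / 5, -1 / 4, -1 / 4, -1 / 4, -1 / 4))
  expect_equal(gsea_es(r6, c("g1", "g2"))$es, running[which.max(abs(running))])
  expect_equal(gsea_es(r6, c("g1", "g2"))$es, 1.0)
  expect_equal(gsea_es(r6, c("g3", "g4"))$running,
               cumsum(c(-1 / 4, -1 / 4, 1 / 2, 1 / 2, -1 / 4, -1 / 4)))

  # degenerate sets
  expect_equal(gsea_es(r6, "g1")$es, 1.0)        # single top hit
  expect_equal(gsea_es(r6, names(r6))$es, 1.0)   # whole list
  expect_error(gsea_es(r6, "absent"), "no genes")

  # randomized cases against an independent dense computation
  set.seed(77)
  r <- setNames(rnorm(60, 0, 2), paste0("x", 1:60))
  for (i in 1:10) {
    gs <- sample(names(r), sample(3:15, 1))
    sr <- sort(r, decreasing = TRUE)
    hits <- names(sr) %in% gs
    w <- abs(sr)
    inc <- ifelse(hits, w / sum(w[hits]), -1 / (60 - sum(hits)))
    run <- cumsum(inc)
    expect_equal(gsea_es(r, gs)$es, run[which.max(abs(run))], tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  r <- setNames(sort(rnorm(80, 0, 2), decreasing = TRUE), paste0("g", 1:80))
  for (i in 1:8) {
    gs <- sample(names(r), sample(4:16, 1))
    ref <- fgsea::calcGseaStat(r, selectedStats = which(names(r) %in% gs),
                               gseaParam = 1)
    expect_equal(gsea_es(r, gs)$es, ref, tolerance = 1e-9)
  }
})

test_that("ES is bounded by 1 and invariant under positive metric rescaling", {
  set.seed(5)
  r <- setNames(rnorm(100), paste0("g", 1:100))
  for (i in 1:20) {
    gs <- sample(names(r), 12)
    es <- gsea_es(r, gs)$es
    expect_lte(abs(es), 1)
    expect_equal(gsea_es(r * 7.5, gs)$es, es, tolerance = 1e-12)
  }
})

test_that("permutation significance is reproducible and respects its bounds", {
  set.seed(6)
  r <- setNames(rnorm(150), paste0("g", 1:150))
  gs <- sample(names(r), 10)
  a <- gsea_significance(r, gs, n_perm = 200, seed = 99)
  b <- gsea_significance(r, gs, n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_gte(a$p_value, 1 / (a$n_perm + 1))
  expect_lte(a$p_value, 1)
  expect_error(gsea_significance(r, gs, n_perm = 50), "100")
  expect_error(gsea_significance(r, names(r), n_perm = 200), "smaller")

  # a strongly enriched planted set attains the minimum attainable p
  r2 <- setNames(sort(abs(rnorm(150)) + 0.1, decreasing = TRUE),
                 paste0("g", 1:150))
  top <- names(r2)[1:10]
  res <- gsea_significance(r2, top, n_perm = 500, seed = 42)
  expect_equal(res$p_value, 1 / (res$n_null_same_sign + 1))
  expect_gt(res$nes, 1)
})

test_that("sparse permutation ES agrees with the dense running-sum ES", {
  set.seed(11)
  r <- setNames(rnorm(80, 0, 1.5), paste0("g", 1:80))
  sr <- sort(r, decreasing = TRUE)
  w <- abs(sr)
  for (i in 1:25) {
    pos <- sort(sample.int(80, sample(2:20, 1)))
    sparse <- fourcgenes:::es_from_positions(pos, w, 80)
    dense <- gsea_es(sr, names(sr)[pos])$es
    expect_equal(sparse, dense, tolerance = 1e-12)
  }
})
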