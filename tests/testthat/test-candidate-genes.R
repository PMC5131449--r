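segments_fix <- data.frame(chrom = "chr1", start = 100000L, end = 120000L,
                           min_p = 1e-12, stringsAsFactors = FALSE)

test_that("TSS-to-segment distance rule is inclusive at 5 kbp", {
  genes <- data.frame(
    gene_id = c("inside", "at5000", "at5001", "upstream_at5000", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    tss = c(110000, 120000 - 1 + 5000, 120000 - 1 + 5001, 100000 - 5000,
            110000),
    strand = "+", stringsAsFactors = FALSE)
  hits <- genes_near_segments(genes, segments_fix, max_dist = 5000)
  expect_setequal(hits$gene_id, c("inside", "at5000", "upstream_at5000"))
  expect_equal(hits$distance[hits$gene_id == "inside"], 0)
  expect_equal(hits$distance[hits$gene_id == "at5000"], 5000)
  expect_true(all(hits$min_p == 1e-12))
})

test_that("any qualifying alternative TSS qualifies the gene, with the min p kept", {
  segs <- rbind(segments_fix,
                data.frame(chrom = "chr1", start = 500000L, end = 510000L,
                           min_p = 1e-30))
  genes <- data.frame(gene_id = c("gA", "gA"), chrom = "chr1",
                      tss = c(505000, 900000), strand = "+",
                      stringsAsFactors = FALSE)
  hits <- genes_near_segments(genes, segs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$min_p, 1e-30)
})

test_that("locus activity requires a variant (tag or LD partner) inside a peak", {
  vp <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "chr1",
                   pos = c(1000, 5000, 9000), stringsAsFactors = FALSE)
  ld <- data.frame(tag_snp = c("rs2", "rs3"), variant_chrom = "chr1",
                   variant_pos = c(20000, 30000), stringsAsFactors = FALSE)
  peaks <- list(
    ctA = data.frame(chrom = "chr1", start = c(900, 19500),
                     end = c(1100, 20500), stringsAsFactors = FALSE)
  )
  expect_warning(act <- assess_locus_activity(vp, ld, peaks), "LD")
  expect_equal(act$active, c(TRUE, TRUE, FALSE))  # tag in peak; LD in peak; neither
})

test_that("expression filter is strict and rpkm follows its definition", {
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     log2_rpkm = c(-0.5, 0, -0.51), stringsAsFactors = FALSE)
  expect_setequal(expression_filter(expr), "b")

  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)   # doubling the library halves RPKM
  expect_equal(rpkm(10, 2000, 1e6), 5)
  expect_error(rpkm(10, 0, 1e6), "positive")
})

make_candidate_inputs <- function() {
  vp <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 110000,
                   stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(110500, 118000, 121000), strand = "+",
                      stringsAsFactors = FALSE)
  inter <- data.frame(snp_id = "rs1", cell_type = "ctA",
                      gene_id = c("g1", "g2", "g3"), min_p = 1e-10,
                      distance = 0, stringsAsFactors = FALSE)
  act <- data.frame(snp_id = "rs1", cell_type = "ctA", active = TRUE,
                    stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = c("g1", "g2", "g3"), cell_type = "ctA",
                     log2_rpkm = c(2, -1, 0.5), stringsAsFactors = FALSE)
  list(vp = vp, genes = genes, inter = inter, act = act, expr = expr)
}

test_that("candidate assembly intersects the three criteria", {
  x <- make_candidate_inputs()
  cand <- assemble_candidates(x$inter, x$act, x$expr, x$vp, x$genes,
                              known_genes = "g1")
  # g2 fails expression (-1); g1 and g3 pass; g1 is known so not novel
  expect_setequal(cand$gene_id, c("g1", "g3"))
  expect_equal(cand$novel[cand$gene_id == "g1"], FALSE)
  expect_equal(cand$novel[cand$gene_id == "g3"], TRUE)
  expect_equal(cand$distance_bp[cand$gene_id == "g1"], 500)

  # inactive locus removes everything
  act_off <- x$act; act_off$active <- FALSE
  expect_equal(nrow(assemble_candidates(x$inter, act_off, x$expr, x$vp,
                                        x$genes)), 0L)

  # gene missing from the expression table is dropped with a warning
  expr2 <- x$expr[x$expr$gene_id != "g3", ]
  expect_warning(
    cand2 <- assemble_candidates(x$inter, x$act, expr2, x$vp, x$genes),
    "not expressed")
  expect_setequal(cand2$gene_id, "g1")
})

test_that("relaxing any cutoff never removes a candidate (filter monotonicity)", {
  cfg <- strong_config(seed = 13, n_viewpoints = 2)
  res <- run_fourc_study(cfg)
  base <- unique(paste(res$candidates$snp_id, res$candidates$gene_id,
                       res$candidates$cell_type))
  relaxed <- list(
    run_fourc_study(simulate_study(cfg), max_dist = 20000),
    run_fourc_study(simulate_study(cfg), expression_cutoff = -2),
    run_fourc_study(simulate_study(cfg), threshold = 1e-4)
  )
  for (r in relaxed) {
    keys <- unique(paste(r$candidates$snp_id, r$candidates$gene_id,
                         r$candidates$cell_type))
    expect_true(all(base %in% keys))
  }
})

test_that("cell-type overlap counts partition the distinct genes", {
  cand <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g4", "g5"),
    cell_type = c("A", "A", "B", "C", "C", "C"),
    stringsAsFactors = FALSE)
  v <- celltype_overlap(cand, cell_types = c("A", "B", "C"))
  expect_equal(sum(v$count), attr(v, "total"))
  expect_equal(attr(v, "total"), 5L)
  expect_equal(v$count[v$region == "A"], 1L)     # g1
  expect_equal(v$count[v$region == "A&B"], 1L)   # g2
  expect_equal(v$count[v$region == "C"], 3L)

  # identical sets: everything in the triple region
  cand2 <- expand.grid(gene_id = paste0("g", 1:5), cell_type = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  v2 <- celltype_overlap(cand2, cell_types = c("A", "B", "C"))
  expect_equal(v2$count[v2$region == "A&B&C"], 5L)
  expect_equal(sum(v2$count), 5L)

  # disjoint sets of sizes 2, 3, 4
  cand3 <- data.frame(
    gene_id = c(paste0("a", 1:2), paste0("b", 1:3), paste0("c", 1:4)),
    cell_type = rep(c("A", "B", "C"), c(2, 3, 4)), stringsAsFactors = FALSE)
  v3 <- celltype_overlap(cand3, cell_types = c("A", "B", "C"))
  expect_equal(v3$count[match(c("A", "B", "C"), v3$region)], c(2L, 3L, 4L))
  expect_true(all(v3$count[grepl("&", v3$region)] == 0L))
})

test_that("distance statistics report per-cell-type medians and a partitioning histogram", {
  cand <- data.frame(gene_id = paste0("g", 1:6),
                     cell_type = rep(c("A", "B"), each = 3),
                     distance_bp = c(1e5, 2e5, 3e5, 0, 5e4, 1e6),
                     stringsAsFactors = FALSE)
  ds <- distance_stats(cand)
  expect_equal(unname(ds$medians["A"]), 2e5)
  expect_equal(unname(ds$medians["B"]), 5e4)
  expect_equal(sum(ds$histogram$count), 6L)
  expect_equal(ds$medians[["A"]], median(c(1e5, 2e5, 3e5)))
})
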