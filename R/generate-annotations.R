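#' Generate matching annotation tables for a synthetic 4C study
#'
#' Builds every annotation the candidate-gene and downstream modules
#' consume, consistent with the planted ground truth: a TSS table with true
#' target genes inside planted contacts and decoy genes kept away from all
#' expected-signal regions, per-cell-type H3K27ac peaks over the tag SNP or
#' an LD partner of each enhancer-active locus, CTCF peaks, an LD variant
#' table, per-cell-type expression spanning the log2(RPKM) = -0.5 cutoff, an
#' eQTL table drawn from the true targets, a ranked differential-expression
#' table in which true targets receive elevated metrics, and a known-gene
#' list for novelty flagging.
#'
#' @param config A [sim_config()].
#' @param viewpoints Viewpoint table from [make_viewpoints()].
#' @param truths Named list (by `snp_id`) of `truth` elements returned by
#'   [simulate_coverage()].
#' @return List of class `fourc_annotations` with elements `genes`,
#'   `peaks` (list of BED-like data.frames by cell type), `ctcf`, `ld`,
#'   `expression`, `eqtl`, `ranked_de`, `known_genes` and `truth`
#'   (`targets`, `activity`, `expressed`).
#' @export
generate_annotations <- function(config, viewpoints, truths) {
  validate_sim_config(config)
  stopifnot(all(viewpoints$snp_id %in% names(truths)))
  len <- config$chromosome_length

  # pooled expected-signal intervals keep decoy TSS away from every region
  # where any viewpoint's 4C signal is expected
  all_signal <- do.call(rbind, lapply(viewpoints$snp_id,
                                      function(s) truths[[s]]$signal))

  genes_list <- list()
  targets_list <- list()
  for (i in seq_len(nrow(viewpoints))) {
    snp <- viewpoints$snp_id[i]
    chrom <- viewpoints$chrom[i]
    planted <- truths[[snp]]$planted
    sig <- all_signal[all_signal$chrom == chrom, , drop = FALSE]
    with_seed(substream_seed(config$seed, i, 0L) + 29L, {
      tgt_tss <- unlist(lapply(seq_len(nrow(planted)), function(j) {
        floor(runif(config$genes_per_contact,
                    planted$start[j] + 1, planted$end[j] - 1))
      }))
      tgt_ids <- sprintf("G_%s_T%d", snp, seq_along(tgt_tss))
      dec_tss <- numeric(0)
      tries <- 0L
      while (length(dec_tss) < config$n_decoy_genes && tries < 5000L) {
        tries <- tries + 1L
        cand <- floor(runif(1L, 0.01 * len, 0.99 * len))
        d <- point_interval_distance(cand, sig$start, sig$end)
        if (length(d) > 0L && min(d) < config$decoy_margin) next
        dec_tss <- c(dec_tss, cand)
      }
      dec_ids <- sprintf("G_%s_D%d", snp, seq_along(dec_tss))
      genes_list[[i]] <- data.frame(
        gene_id = c(tgt_ids, dec_ids), chrom = chrom,
        tss = c(tgt_tss, dec_tss),
        strand = sample(c("+", "-"), length(tgt_tss) + length(dec_tss),
                        replace = TRUE),
        stringsAsFactors = FALSE
      )
      targets_list[[i]] <- data.frame(
        snp_id = snp, gene_id = tgt_ids, chrom = chrom, tss = tgt_tss,
        stringsAsFactors = FALSE
      )
    })
  }
  genes <- do.call(rbind, genes_list)
  targets <- do.call(rbind, targets_list)

  # LD partners around each tag SNP
  ld <- do.call(rbind, lapply(seq_len(nrow(viewpoints)), function(i) {
    with_seed(substream_seed(config$seed, i, 0L) + 31L, {
      off <- floor(runif(config$n_ld_partners, -config$ld_span, config$ld_span))
      data.frame(tag_snp = viewpoints$snp_id[i],
                 variant_chrom = viewpoints$chrom[i],
                 variant_pos = pmin(pmax(viewpoints$pos[i] + off, 0), len - 1),
                 stringsAsFactors = FALSE)
    })
  }))

  # enhancer activity per cell type: a fixed fraction of loci carries an
  # H3K27ac peak over its tag SNP or one LD partner
  activity_list <- list()
  peaks <- setNames(vector("list", config$n_cell_types), config$cell_types)
  for (ci in seq_len(config$n_cell_types)) {
    ct <- config$cell_types[ci]
    n_active <- round(config$active_fraction[ci] * nrow(viewpoints))
    active_idx <- with_seed(substream_seed(config$seed, 0L, ci) + 37L,
                            sort(sample.int(nrow(viewpoints), n_active)))
    pk <- list()
    for (i in active_idx) {
      snp <- viewpoints$snp_id[i]
      vars <- c(viewpoints$pos[i],
                ld$variant_pos[ld$tag_snp == snp])
      anchor <- with_seed(substream_seed(config$seed, i, ci) + 41L,
                          sample(vars, 1L))
      pk[[length(pk) + 1L]] <- data.frame(
        chrom = viewpoints$chrom[i],
        start = max(0, anchor - 750), end = min(len, anchor + 750),
        stringsAsFactors = FALSE
      )
    }
    peaks[[ct]] <- if (length(pk) > 0L) do.call(rbind, pk) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    activity_list[[ci]] <- data.frame(
      snp_id = viewpoints$snp_id, cell_type = ct,
      active = seq_len(nrow(viewpoints)) %in% active_idx,
      stringsAsFactors = FALSE
    )
  }
  activity <- do.call(rbind, activity_list)

  # CTCF peaks scattered uniformly per chromosome
  ctcf <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(k) {
    with_seed(substream_seed(config$seed, 0L, k) + 43L, {
      s <- sort(floor(runif(config$ctcf_per_chrom, 0, len - 400)))
      data.frame(chrom = chrom_names(config)[k], start = s, end = s + 400,
                 stringsAsFactors = FALSE)
    })
  }))

  # expression per cell type: targets always above the cutoff, a fixed
  # fraction of decoys above, the rest below
  expression <- do.call(rbind, lapply(seq_len(config$n_cell_types), function(ci) {
    ct <- config$cell_types[ci]
    with_seed(substream_seed(config$seed, 0L, ci) + 47L, {
      is_target <- genes$gene_id %in% targets$gene_id
      val <- numeric(nrow(genes))
      val[is_target] <- pmax(stats::rnorm(sum(is_target), 3, 1), 0)
      dec <- which(!is_target)
      on_frac <- runif(length(dec)) < config$expressed_decoy_fraction
      val[dec[on_frac]] <- pmax(stats::rnorm(sum(on_frac), 2, 1), 0)
      val[dec[!on_frac]] <- -0.5 - runif(sum(!on_frac), 0.01, 3)
      data.frame(gene_id = genes$gene_id, cell_type = ct, log2_rpkm = val,
                 stringsAsFactors = FALSE)
    })
  }))
  expressed <- expression[expression$log2_rpkm > -0.5, c("gene_id", "cell_type")]

  # eQTL genes per SNP: drawn from that SNP's true targets
  eqtl <- do.call(rbind, lapply(seq_len(nrow(viewpoints)), function(i) {
    snp <- viewpoints$snp_id[i]
    tg <- targets$gene_id[targets$snp_id == snp]
    n <- ceiling(config$eqtl_fraction * length(tg))
    if (n == 0L) return(NULL)
    sel <- with_seed(substream_seed(config$seed, i, 0L) + 53L,
                     sample(tg, n))
    data.frame(snp_id = snp, gene_id = sel, stringsAsFactors = FALSE)
  }))

  # ranked differential-expression table: true targets elevated
  ranked_de <- with_seed(substream_seed(config$seed, 0L, 0L) + 59L, {
    metric <- stats::rnorm(nrow(genes))
    metric[genes$gene_id %in% targets$gene_id] <-
      metric[genes$gene_id %in% targets$gene_id] + config$de_effect
    df <- data.frame(gene_id = genes$gene_id, metric = metric,
                     stringsAsFactors = FALSE)
    df[order(-df$metric), , drop = FALSE]
  })
  rownames(ranked_de) <- NULL

  known_genes <- with_seed(substream_seed(config$seed, 0L, 0L) + 61L, {
    n <- floor(config$known_fraction * nrow(targets))
    if (n > 0L) sort(sample(targets$gene_id, n)) else character()
  })

  structure(
    list(genes = genes, peaks = peaks, ctcf = ctcf, ld = ld,
         expression = expression, eqtl = eqtl, ranked_de = ranked_de,
         known_genes = known_genes,
         truth = list(targets = targets, activity = activity,
                      expressed = expressed)),
    class = "fourc_annotations"
  )
}

#' Write the ground-truth sidecar as JSON
#'
#' @param truth The `truth` element of [generate_annotations()] output (or
#'   any list of data.frames / vectors).
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x
}
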