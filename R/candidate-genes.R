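#' Criterion 1: genes whose TSS co-localizes with significant 4C signal
#'
#' A gene qualifies when the distance from any of its TSS records to the
#' nearest covered base of a significant interaction segment is at most
#' `max_dist` bp (inclusive; distance 0 when the TSS falls inside a
#' segment). Multiple TSS records per gene are allowed and any qualifying
#' TSS qualifies the gene. Each qualifying gene carries the minimum
#' segment p-value among its qualifying segments.
#'
#' @param genes Gene annotation data.frame: `gene_id`, `chrom`, `tss`,
#'   `strand`.
#' @param segments Segment data.frame (`chrom`, `start`, `end`, `min_p`),
#'   e.g. `scan_and_call(...)$segments`.
#' @param max_dist Maximum TSS-to-segment distance, bp (inclusive).
#' @return data.frame: `gene_id`, `min_p`, `distance` (bp to the nearest
#'   qualifying segment).
#' @export
genes_near_segments <- function(genes, segments, max_dist = 5000) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  if (nrow(segments) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), min_p = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    same <- segments$chrom == genes$chrom[i]
    if (!any(same)) return(NULL)
    d <- point_interval_distance(genes$tss[i], segments$start[same],
                                 segments$end[same])
    ok <- d <= max_dist
    if (!any(ok)) return(NULL)
    data.frame(gene_id = genes$gene_id[i],
               min_p = min(segments$min_p[same][ok]),
               distance = min(d[ok]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), min_p = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  # collapse alternative TSS records: any qualifying TSS qualifies the gene
  agg <- lapply(split(out, out$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], min_p = min(g$min_p),
               distance = min(g$distance), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Criterion 2: enhancer activity of each locus per cell type
#'
#' A locus is active in a cell type when its tag SNP or any variant in LD
#' with it overlaps an H3K27ac peak of that cell type (point-in-interval on
#' 0-based half-open peaks). SNPs missing from the LD table are assessed on
#' the tag SNP alone, with a warning.
#'
#' @param viewpoints Viewpoint table (`snp_id`, `chrom`, `pos`).
#' @param ld_table data.frame `tag_snp`, `variant_chrom`, `variant_pos`.
#' @param peaks Named list, per cell type, of peak data.frames (`chrom`,
#'   `start`, `end`).
#' @return data.frame: `snp_id`, `cell_type`, `active`, `n_variants_in_peaks`.
#' @export
assess_locus_activity <- function(viewpoints, ld_table, peaks) {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  missing <- setdiff(viewpoints$snp_id, unique(ld_table$tag_snp))
  if (length(missing) > 0L) {
    warning(sprintf("no LD partners for %d SNP(s) (%s ...): assessing tag SNP only",
                    length(missing), missing[1L]))
  }
  rows <- list()
  for (ct in names(peaks)) {
    pk <- peaks[[ct]]
    for (i in seq_len(nrow(viewpoints))) {
      snp <- viewpoints$snp_id[i]
      ld <- ld_table[ld_table$tag_snp == snp, , drop = FALSE]
      vchrom <- c(as.character(viewpoints$chrom[i]), as.character(ld$variant_chrom))
      vpos <- c(viewpoints$pos[i], ld$variant_pos)
      n_in <- 0L
      if (nrow(pk) > 0L) {
        for (v in seq_along(vpos)) {
          inpk <- pk$chrom == vchrom[v] & pk$start <= vpos[v] & vpos[v] < pk$end
          if (any(inpk)) n_in <- n_in + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, cell_type = ct, active = n_in > 0L,
        n_variants_in_peaks = n_in, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Criterion 3: expressed genes
#'
#' Strict inequality per the filtering rule: a gene passes when
#' log2(RPKM) > `cutoff`; a value exactly at the cutoff fails.
#'
#' @param expr data.frame with `gene_id` and `log2_rpkm` (optionally
#'   `cell_type`).
#' @param cell_type When given and `expr` has a `cell_type` column,
#'   restricts to that cell type.
#' @param cutoff Expression cutoff on the log2(RPKM) scale.
#' @return Character vector of expressed gene ids.
#' @export
expression_filter <- function(expr, cell_type = NULL, cutoff = -0.5) {
  stopifnot(all(c("gene_id", "log2_rpkm") %in% names(expr)))
  if (!is.null(cell_type) && "cell_type" %in% names(expr)) {
    expr <- expr[expr$cell_type == cell_type, , drop = FALSE]
  }
  unique(expr$gene_id[expr$log2_rpkm > cutoff])
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = count / (gene_length/1000) / (library_size/1e6). A zero count
#' gives RPKM 0, whose log2 of -Inf fails the expression filter.
#'
#' @param count Mapped reads for the gene.
#' @param gene_length Transcript length, bp (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return RPKM value(s); vectorized.
#' @export
rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0) || any(library_size <= 0)) {
    stop("gene_length and library_size must be positive")
  }
  count / (gene_length / 1000) / (library_size / 1e6)
}

#' Assemble the candidate-gene table from the three criteria
#'
#' Intersects, per cell type and viewpoint, the chromatin-interaction genes
#' (criterion 1), enhancer-active loci (criterion 2) and expressed genes
#' (criterion 3). Genes absent from the expression table are treated as not
#' expressed and counted in a warning. The novelty flag marks genes not in
#' the supplied GWAS-reported list.
#'
#' @param interactions data.frame stacking [genes_near_segments()] output
#'   with `snp_id` and `cell_type` columns (`snp_id`, `cell_type`,
#'   `gene_id`, `min_p`, `distance`).
#' @param activity [assess_locus_activity()] output.
#' @param expression Expression table (`gene_id`, `cell_type`, `log2_rpkm`).
#' @param viewpoints Viewpoint table (for viewpoint-to-TSS distances).
#' @param genes Gene annotation (`gene_id`, `chrom`, `tss`).
#' @param known_genes Character vector of GWAS-reported gene ids.
#' @param expression_cutoff Passed to [expression_filter()].
#' @return data.frame of candidate records ordered by (`snp_id`,
#'   `gene_id`, `cell_type`): `gene_id`, `cell_type`, `snp_id`, `p`,
#'   `distance_bp` (|TSS - viewpoint position|), `log2_rpkm`, `novel`.
#' @export
assemble_candidates <- function(interactions, activity, expression,
                                viewpoints, genes, known_genes = character(),
                                expression_cutoff = -0.5) {
  need <- c("snp_id", "cell_type", "gene_id", "min_p", "distance")
  stopifnot(all(need %in% names(interactions)))
  empty <- data.frame(gene_id = character(), cell_type = character(),
                      snp_id = character(), p = numeric(),
                      distance_bp = numeric(), log2_rpkm = numeric(),
                      novel = logical(), stringsAsFactors = FALSE)
  if (nrow(interactions) == 0L) return(empty)
  act_key <- paste(activity$snp_id, activity$cell_type, sep = "\r")
  rows <- list()
  n_missing_expr <- 0L
  for (ct in unique(interactions$cell_type)) {
    expressed <- expression_filter(expression, cell_type = ct,
                                   cutoff = expression_cutoff)
    sub <- interactions[interactions$cell_type == ct, , drop = FALSE]
    act <- activity$active[match(paste(sub$snp_id, ct, sep = "\r"), act_key)]
    act[is.na(act)] <- FALSE
    known_expr <- unique(expression$gene_id[
      if ("cell_type" %in% names(expression)) expression$cell_type == ct else TRUE])
    n_missing_expr <- n_missing_expr + sum(act & !sub$gene_id %in% known_expr)
    pass <- act & sub$gene_id %in% expressed
    if (!any(pass)) next
    sub <- sub[pass, , drop = FALSE]
    ex <- expression
    if ("cell_type" %in% names(ex)) ex <- ex[ex$cell_type == ct, , drop = FALSE]
    vp_pos <- viewpoints$pos[match(sub$snp_id, viewpoints$snp_id)]
    tss <- genes$tss[match(sub$gene_id, genes$gene_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sub$gene_id, cell_type = ct, snp_id = sub$snp_id,
      p = sub$min_p, distance_bp = abs(tss - vp_pos),
      log2_rpkm = ex$log2_rpkm[match(sub$gene_id, ex$gene_id)],
      novel = !sub$gene_id %in% known_genes, stringsAsFactors = FALSE
    )
  }
  if (n_missing_expr > 0L) {
    warning(sprintf("%d interaction gene record(s) absent from the expression table: treated as not expressed",
                    n_missing_expr))
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$snp_id, out$gene_id, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cell-type overlap (Venn) counts of candidate genes
#'
#' Partitions the distinct candidate genes by the exact combination of cell
#' types in which they were identified. The disjoint region counts sum to
#' the total number of distinct genes.
#'
#' @param candidates [assemble_candidates()] output.
#' @param cell_types Optional cell-type ordering; defaults to sorted unique
#'   values present.
#' @return data.frame: `region` (cell types joined by "&"), `count`; with
#'   attribute `total` = number of distinct genes.
#' @export
celltype_overlap <- function(candidates, cell_types = NULL) {
  if (is.null(cell_types)) cell_types <- sort(unique(candidates$cell_type))
  if (length(cell_types) < 1L) stop("at least one cell type required")
  sets <- lapply(cell_types, function(ct) {
    unique(candidates$gene_id[candidates$cell_type == ct])
  })
  names(sets) <- cell_types
  all_genes <- unique(unlist(sets))
  sig <- vapply(all_genes, function(g) {
    paste(cell_types[vapply(sets, function(s) g %in% s, logical(1L))],
          collapse = "&")
  }, character(1L))
  # enumerate all non-empty combinations so absent regions report 0
  combos <- unlist(lapply(seq_along(cell_types), function(m) {
    apply(utils::combn(cell_types, m), 2L, paste, collapse = "&")
  }))
  out <- data.frame(region = combos,
                    count = as.integer(table(factor(sig, levels = combos))),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(all_genes)
  out
}

#' Viewpoint-to-gene distance statistics of the candidates
#'
#' Distance is |TSS - viewpoint position| per candidate record. Returns
#' per-cell-type medians and a binned histogram of all distances.
#'
#' @param candidates [assemble_candidates()] output (carries `distance_bp`).
#' @param binwidth Histogram bin width, bp.
#' @return List: `medians` (named numeric, bp, per cell type), `distances`
#'   (data.frame `cell_type`, `distance_bp`), `histogram` (data.frame
#'   `bin_start`, `bin_end`, `count`).
#' @export
distance_stats <- function(candidates, binwidth = 100000) {
  d <- candidates$distance_bp
  medians <- vapply(split(d, candidates$cell_type), stats::median, numeric(1L))
  if (length(d) == 0L) {
    hist_df <- data.frame(bin_start = numeric(), bin_end = numeric(),
                          count = integer())
  } else {
    breaks <- seq(0, (max(d) %/% binwidth + 1) * binwidth, by = binwidth)
    counts <- tabulate(findInterval(d, breaks), nbins = length(breaks) - 1L)
    hist_df <- data.frame(bin_start = breaks[-length(breaks)],
                          bin_end = breaks[-1L], count = counts)
  }
  list(medians = medians,
       distances = data.frame(cell_type = candidates$cell_type,
                              distance_bp = d, stringsAsFactors = FALSE),
       histogram = hist_df)
}
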