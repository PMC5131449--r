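#' Mean signal occupancy around transcription start sites
#'
#' Computes, for every gene, the mean of an interval signal track over
#' [TSS - halfwidth, TSS + halfwidth), normalized by the width actually
#' covered by the chromosome when the window is truncated at an edge.
#' When a set of 4C-detected genes is supplied, the detected vs other
#' genes contrast is summarized by group medians and a Wilcoxon rank-sum
#' test.
#'
#' @param track Signal data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `score`. Bases not covered by any interval score 0.
#' @param genes Gene annotation (`gene_id`, `chrom`, `tss`).
#' @param halfwidth Window half-width, bp.
#' @param detected Optional character vector of 4C-detected gene ids.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   truncate windows; defaults to the rightmost track end per chromosome.
#' @return List: `per_gene` (data.frame `gene_id`, `occupancy`, `detected`),
#'   `medians` (named numeric, groups `detected`/`other` when `detected`
#'   given), `test` (htest or NULL).
#' @export
tss_occupancy <- function(track, genes, halfwidth = 2000, detected = NULL,
                          chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(track)))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(track$end, track$chrom), max, numeric(1L))
  }
  occ <- vapply(seq_len(nrow(genes)), function(i) {
    chrom <- genes$chrom[i]
    len <- chrom_lengths[[chrom]]
    if (is.null(len) || is.na(len)) len <- Inf
    lo <- max(0, genes$tss[i] - halfwidth)
    hi <- min(len, genes$tss[i] + halfwidth)
    if (hi <= lo) return(NA_real_)
    tr <- track[track$chrom == chrom, , drop = FALSE]
    ov <- pmin(tr$end, hi) - pmax(tr$start, lo)
    ov[ov < 0] <- 0
    sum(ov * tr$score) / (hi - lo)
  }, numeric(1L))
  per_gene <- data.frame(gene_id = genes$gene_id, occupancy = occ,
                         stringsAsFactors = FALSE)
  medians <- c(all = stats::median(occ, na.rm = TRUE))
  test <- NULL
  if (!is.null(detected)) {
    per_gene$detected <- per_gene$gene_id %in% detected
    g1 <- per_gene$occupancy[per_gene$detected]
    g2 <- per_gene$occupancy[!per_gene$detected]
    medians <- c(detected = stats::median(g1, na.rm = TRUE),
                 other = stats::median(g2, na.rm = TRUE))
    if (length(g1) > 0L && length(g2) > 0L) {
      test <- stats::wilcox.test(g1, g2, exact = FALSE)
    }
  }
  list(per_gene = per_gene, medians = medians, test = test)
}

#' Count CTCF sites between a viewpoint and a gene TSS
#'
#' Counts CTCF peaks whose midpoint lies strictly between the viewpoint
#' position and the TSS (exclusive of both endpoints). Symmetric in the
#' two positions; both loci must lie on the same chromosome.
#'
#' @param viewpoint List/row with `chrom` and `pos`.
#' @param gene List/row with `chrom` and `tss`.
#' @param ctcf Peak data.frame (`chrom`, `start`, `end`).
#' @return Integer count.
#' @export
ctcf_between <- function(viewpoint, gene, ctcf) {
  if (as.character(viewpoint$chrom) != as.character(gene$chrom)) {
    stop("viewpoint and gene lie on different chromosomes; intervening CTCF count is undefined")
  }
  lo <- min(viewpoint$pos, gene$tss)
  hi <- max(viewpoint$pos, gene$tss)
  pk <- ctcf[ctcf$chrom == as.character(gene$chrom), , drop = FALSE]
  if (nrow(pk) == 0L) return(0L)
  mid <- (pk$start + pk$end) %/% 2
  sum(mid > lo & mid < hi)
}

#' eQTL concordance with 4C-identified genes
#'
#' For each SNP, splits its eQTL genes (restricted to the annotation
#' universe; transcripts absent from the annotation are dropped first) into
#' those found among the SNP's 4C candidate genes (interacting) and those
#' found among the non-interacting genes within `window` bp of the
#' viewpoint, and reports the fractions per SNP and pooled.
#'
#' @param eqtl data.frame `snp_id`, `gene_id`.
#' @param candidates [assemble_candidates()] output (any cell type counts
#'   as interacting).
#' @param genes Gene annotation (the universe; `gene_id`, `chrom`, `tss`).
#' @param viewpoints Viewpoint table (`snp_id`, `chrom`, `pos`).
#' @param window Control window around the viewpoint, bp.
#' @return List: `per_snp` (data.frame `snp_id`, `n_eqtl`,
#'   `n_interacting`, `n_noninteracting_near`, `frac_interacting`),
#'   `total_interacting_fraction`, `total_noninteracting_fraction`,
#'   `n_dropped` (eQTL genes outside the annotation).
#' @export
eqtl_concordance <- function(eqtl, candidates, genes, viewpoints,
                             window = 2e6) {
  n0 <- nrow(eqtl)
  eqtl <- eqtl[eqtl$gene_id %in% genes$gene_id, , drop = FALSE]
  n_dropped <- n0 - nrow(eqtl)
  per <- lapply(unique(eqtl$snp_id), function(snp) {
    eg <- unique(eqtl$gene_id[eqtl$snp_id == snp])
    cand <- unique(candidates$gene_id[candidates$snp_id == snp])
    vp <- viewpoints[viewpoints$snp_id == snp, , drop = FALSE]
    near <- character()
    if (nrow(vp) == 1L) {
      sel <- genes$chrom == as.character(vp$chrom) &
        abs(genes$tss - vp$pos) <= window
      near <- unique(genes$gene_id[sel])
    }
    nonint_near <- setdiff(near, cand)
    data.frame(snp_id = snp, n_eqtl = length(eg),
               n_interacting = length(intersect(eg, cand)),
               n_noninteracting_near = length(intersect(eg, nonint_near)),
               frac_interacting = length(intersect(eg, cand)) / length(eg),
               stringsAsFactors = FALSE)
  })
  per_snp <- do.call(rbind, per)
  tot <- sum(per_snp$n_eqtl)
  list(per_snp = per_snp,
       total_interacting_fraction = if (tot > 0) sum(per_snp$n_interacting) / tot else NaN,
       total_noninteracting_fraction = if (tot > 0) sum(per_snp$n_noninteracting_near) / tot else NaN,
       n_dropped = n_dropped)
}

#' Fraction of one gene set recovered in another
#'
#' |A intersect B| / |A|, the concordance statistic used for replicate and
#' cross-platform (Hi-C) comparisons of identified gene sets.
#'
#' @param set_a,set_b Character vectors of gene ids; `set_a` must be
#'   non-empty.
#' @return Fraction in [0,1].
#' @export
geneset_concordance <- function(set_a, set_b) {
  set_a <- unique(set_a)
  if (length(set_a) == 0L) stop("set_a is empty; concordance is undefined")
  length(intersect(set_a, set_b)) / length(set_a)
}

#' Gene set enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Walks down the ranked list; at a gene-set member ("hit") the running sum
#' increases by |metric|^`weight_exponent` normalized over set members, at
#' a non-member it decreases by 1/(N - N_set). The enrichment score ES is
#' the signed extremum of the running sum, so |ES| <= 1 and ES is invariant
#' under positive rescaling of the metric.
#'
#' @param ranked data.frame `gene_id`, `metric` (or a named numeric
#'   vector); sorted by decreasing metric internally. Gene ids must be
#'   unique and metrics finite.
#' @param gene_set Character vector; must intersect the ranked genes.
#' @param weight_exponent Weight on |metric| at hits (0 gives the classic
#'   unweighted KS statistic).
#' @return List: `es`, `running` (running-sum profile over list positions),
#'   `hit_positions`.
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  r <- as_ranked_list(ranked)
  hits <- names(r) %in% gene_set
  if (!any(hits)) stop("gene_set shares no genes with the ranked list")
  n <- length(r)
  n_hit <- sum(hits)
  w <- abs(r)^weight_exponent
  denom <- sum(w[hits])
  inc <- numeric(n)
  if (denom > 0) {
    inc[hits] <- w[hits] / denom
  } else {
    inc[hits] <- 1 / n_hit       # all-zero metrics: equal hit weights
  }
  if (n > n_hit) inc[!hits] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hit_positions = which(hits))
}

as_ranked_list <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene_id", "metric") %in% names(ranked)))
    r <- setNames(ranked$metric, ranked$gene_id)
  } else {
    r <- ranked
  }
  if (is.null(names(r)) || anyDuplicated(names(r))) {
    stop("ranked list requires unique gene ids")
  }
  if (any(!is.finite(r))) stop("ranking metrics must be finite")
  sort(r, decreasing = TRUE)
}

# ES from hit positions only: O(n_hit) per permutation. Candidates for the
# extremum are the running sum right after each hit and right before each
# hit; verified against the dense cumsum in the tests.
es_from_positions <- function(pos, w_all, n, denom_null = NULL) {
  pos <- sort(pos)
  h <- length(pos)
  w <- w_all[pos]
  denom <- sum(w)
  hit_cum <- if (denom > 0) cumsum(w) / denom else seq_len(h) / h
  miss <- if (n > h) 1 / (n - h) else 0
  after <- hit_cum - miss * (pos - seq_len(h))
  before <- c(0, hit_cum[-h]) - miss * (pos - 1 - (seq_len(h) - 1L))
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Permutation significance of a gene-set enrichment score
#'
#' Builds the null by drawing `n_perm` random gene sets of the same size
#' (without replacement) from the ranked genes. Significance is assessed
#' against the same-signed portion of the null, the standard convention
#' for the signed running-sum ES: for a positive observed ES,
#' p = (1 + #\{null >= ES among positive nulls\}) / (1 + #positive nulls),
#' mirrored for a negative ES. This sign-conditional comparison keeps the
#' test calibrated (a random set rejects at rate alpha). NES is ES divided
#' by the mean magnitude of the same-signed null scores.
#'
#' @param ranked As in [gsea_es()].
#' @param gene_set Character vector; its overlap with the ranked list must
#'   be non-empty and smaller than the list.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional seed; results are reproducible given it.
#' @param weight_exponent Passed to the ES computation.
#' @return List of class `gsea_result`: `es`, `nes`, `p_value`, `n_perm`,
#'   `n_null_same_sign`, `set_size`.
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000, seed = NULL,
                              weight_exponent = 1) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  r <- as_ranked_list(ranked)
  n <- length(r)
  obs_pos <- which(names(r) %in% gene_set)
  if (length(obs_pos) == 0L) stop("gene_set shares no genes with the ranked list")
  if (length(obs_pos) >= n) stop("gene_set must be smaller than the ranked list")
  w_all <- abs(r)^weight_exponent
  es <- es_from_positions(obs_pos, w_all, n)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      es_from_positions(sample.int(n, length(obs_pos)), w_all, n)
    }, numeric(1L))
  })
  if (es >= 0) {
    same <- null_es[null_es >= 0]
    p <- (1 + sum(same >= es)) / (1 + length(same))
  } else {
    same <- null_es[null_es < 0]
    p <- (1 + sum(same <= es)) / (1 + length(same))
  }
  nes <- if (length(same) > 0L && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  structure(
    list(es = es, nes = nes, p_value = p, n_perm = n_perm,
         n_null_same_sign = length(same), set_size = length(obs_pos)),
    class = "gsea_result"
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES=%.3f, NES=%.3f, p=%.4g (%d permutations, set size %d)\n",
              x$es, x$nes, x$p_value, x$n_perm, x$set_size))
  invisible(x)
}
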