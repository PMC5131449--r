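#' Simulation configuration for the synthetic 4C study
#'
#' Bundles and validates every tunable of the synthetic-data generator.
#' Defaults describe the emulated study design: 92 GWAS tag-SNP viewpoints
#' assayed in three cell types (monocytes, lymphocytes, DLD-1 intestinal
#' epithelial cells), a DpnII site density of ~4 per kbp (one GATC per 256 bp
#' expected in random sequence), and per-cell-type enhancer-active locus
#' fractions of 68/92, 73/92 and 52/92. Chromosome number and length are kept
#' at desk scale; coverage-decay halflife, background coverage and planted
#' contact strength are modeling choices documented in the package vignette.
#'
#' @param seed Integer master seed; all randomness fans out from it through
#'   deterministic per-chromosome / per-viewpoint / per-cell-type substreams,
#'   so adding a viewpoint never perturbs the data of the others.
#' @param n_chromosomes,chromosome_length Genome shape (bp).
#' @param gatc_density Expected GATC sites per kbp.
#' @param background_coverage Probability in (0,1) that a background fragend
#'   is covered.
#' @param viewpoint_decay_halflife Distance (bp) at which the near-viewpoint
#'   coverage probability halves: coverage decays as 2^(-d/halflife).
#' @param planted_contacts Optional data.frame (`chrom`, `start`, `end`,
#'   `prob`) of fixed contact regions applied to every viewpoint on the
#'   matching chromosome; when `NULL`, contacts are planted per viewpoint.
#' @param n_viewpoints,n_cell_types,cell_types Study design.
#' @param n_contacts_per_viewpoint,planted_coverage,planted_span,min_contact_distance
#'   Auto-planting: contacts per viewpoint, their coverage probability, their
#'   span (bp) and their minimum distance (bp) from the viewpoint.
#' @param depth Reads emitted per covered fragend.
#' @param genes_per_contact,n_decoy_genes,decoy_margin Gene annotation: true
#'   targets per planted contact; decoy genes per viewpoint; minimum distance
#'   (bp) of a decoy TSS from any expected-signal interval.
#' @param active_fraction Per-cell-type fraction of loci whose enhancer is
#'   active (recycled across `cell_types`).
#' @param n_ld_partners,ld_span LD table: partners per tag SNP, placed within
#'   `ld_span` bp.
#' @param ctcf_per_chrom CTCF peaks per chromosome.
#' @param expressed_decoy_fraction Fraction of decoy genes expressed above
#'   the log2(RPKM) = -0.5 cutoff (true targets are always expressed).
#' @param eqtl_fraction Fraction of each viewpoint's true targets reported as
#'   its eQTL genes.
#' @param known_fraction Fraction of true targets included in the
#'   "GWAS-reported" known-gene list (the rest are novel).
#' @param de_effect Mean ranking-metric elevation of true targets in the
#'   ranked differential-expression table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 8L,
                       chromosome_length = 2e6,
                       gatc_density = 4,
                       background_coverage = 0.05,
                       viewpoint_decay_halflife = 20000,
                       planted_contacts = NULL,
                       n_viewpoints = 92L,
                       n_cell_types = 3L,
                       cell_types = c("monocytes", "lymphocytes", "DLD1"),
                       n_contacts_per_viewpoint = 2L,
                       planted_coverage = 0.8,
                       planted_span = 30000,
                       min_contact_distance = 250000,
                       depth = 1L,
                       genes_per_contact = 1L,
                       n_decoy_genes = 3L,
                       decoy_margin = 50000,
                       active_fraction = c(68, 73, 52) / 92,
                       n_ld_partners = 5L,
                       ld_span = 100000,
                       ctcf_per_chrom = 50L,
                       expressed_decoy_fraction = 0.5,
                       eqtl_fraction = 1,
                       known_fraction = 0.3,
                       de_effect = 2.5) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length, gatc_density = gatc_density,
    background_coverage = background_coverage,
    viewpoint_decay_halflife = viewpoint_decay_halflife,
    planted_contacts = planted_contacts,
    n_viewpoints = as.integer(n_viewpoints),
    n_cell_types = as.integer(n_cell_types),
    cell_types = rep_len(cell_types, n_cell_types),
    n_contacts_per_viewpoint = as.integer(n_contacts_per_viewpoint),
    planted_coverage = planted_coverage, planted_span = planted_span,
    min_contact_distance = min_contact_distance, depth = as.integer(depth),
    genes_per_contact = as.integer(genes_per_contact),
    n_decoy_genes = as.integer(n_decoy_genes), decoy_margin = decoy_margin,
    active_fraction = rep_len(active_fraction, n_cell_types),
    n_ld_partners = as.integer(n_ld_partners), ld_span = ld_span,
    ctcf_per_chrom = as.integer(ctcf_per_chrom),
    expressed_decoy_fraction = expressed_decoy_fraction,
    eqtl_fraction = eqtl_fraction, known_fraction = known_fraction,
    de_effect = de_effect
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$n_viewpoints >= 1L,
            cfg$n_cell_types >= 1L, cfg$gatc_density >= 0,
            cfg$viewpoint_decay_halflife > 0, cfg$planted_span > 0,
            cfg$depth >= 1L)
  if (cfg$chromosome_length <= 0) stop("chromosome_length must be positive")
  for (p in c(cfg$background_coverage, cfg$planted_coverage)) {
    if (!(p > 0 && p < 1)) stop("coverage probabilities must lie in (0,1)")
  }
  if (cfg$planted_coverage <= cfg$background_coverage) {
    stop("planted_coverage must exceed background_coverage")
  }
  pc <- cfg$planted_contacts
  if (!is.null(pc)) {
    stopifnot(is.data.frame(pc),
              all(c("chrom", "start", "end", "prob") %in% names(pc)))
    if (any(pc$start < 0 | pc$end > cfg$chromosome_length | pc$start >= pc$end)) {
      stop("planted contact intervals must lie within chromosome bounds")
    }
    if (any(pc$prob <= cfg$background_coverage | pc$prob >= 1)) {
      stop("planted contact probabilities must lie in (background_coverage, 1)")
    }
  }
  invisible(cfg)
}

chrom_names <- function(cfg) sprintf("chr%d", seq_len(cfg$n_chromosomes))

#' Generate a synthetic genome with controlled GATC site placement
#'
#' Site positions are drawn first (Poisson count at `gatc_density` per kbp,
#' uniform placement with a minimal 4-bp separation), then the intervening
#' background sequence is sampled GATC-free, and finally the sites are
#' injected at the chosen positions. The final sequence therefore contains
#' GATC at exactly the placed positions — the residual background rate of
#' accidental sites is zero — so the fragend count is controllable. With
#' `gatc_density = 0` the sequence contains no GATC at all.
#'
#' @param config A [sim_config()].
#' @return Named [Biostrings::DNAStringSet] of chromosome sequences;
#'   deterministic given `config$seed`.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  len <- as.integer(config$chromosome_length)
  seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
    with_seed(substream_seed(config$seed, 0L, i), {
      n_sites <- stats::rpois(1L, len * config$gatc_density / 1000)
      pos <- sort(sample.int(max(len - 4L, 1L), min(n_sites, max(len - 4L, 1L)))) - 1L
      if (length(pos) > 1L) pos <- pos[c(TRUE, diff(pos) >= 4L)]
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      # scrub accidental GATC from the background: flipping the A removes a
      # site and cannot create one (no 4-mer window gains G,A,T,C), so one
      # pass suffices
      if (len >= 4L) {
        acc <- which(base[1:(len - 3L)] == "G" & base[2:(len - 2L)] == "A" &
                       base[3:(len - 1L)] == "T" & base[4:len] == "C")
        base[acc + 1L] <- "C"
      }
      base[pos + 1L] <- "G"
      base[pos + 2L] <- "A"
      base[pos + 3L] <- "T"
      base[pos + 4L] <- "C"
      paste(base, collapse = "")
    })
  }, character(1L))
  Biostrings::DNAStringSet(setNames(seqs, chrom_names(config)))
}

# Random primer panel: fixed-length distinct primers are mutually
# non-prefixing by construction.
random_primers <- function(n, len = 20L) {
  repeat {
    p <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1L))
    if (!anyDuplicated(p)) return(p)
  }
}

#' Lay out synthetic viewpoints across the genome
#'
#' Viewpoints (tag SNPs) are assigned to chromosomes round-robin and placed
#' at the midpoint of a mappable fragend in the central portion of the
#' chromosome, so the +/-100 kbp calibration flank fits inside it. Each
#' receives a distinct fixed-length primer.
#'
#' @param config A [sim_config()].
#' @param library A `fragend_library` built from [generate_genome()] output.
#' @return Viewpoint data.frame: `snp_id`, `chrom`, `pos`, `primer`,
#'   `cell_types` (list column).
#' @export
make_viewpoints <- function(config, library) {
  validate_sim_config(config)
  len <- config$chromosome_length
  chroms <- chrom_names(config)
  with_seed(substream_seed(config$seed, 0L, 0L), {
    primers <- random_primers(config$n_viewpoints)
    pos <- numeric(config$n_viewpoints)
    chrom <- character(config$n_viewpoints)
    for (i in seq_len(config$n_viewpoints)) {
      chrom[i] <- chroms[((i - 1L) %% config$n_chromosomes) + 1L]
      fe <- mappable_fragends(library, chrom[i])
      central <- fe$mid > 0.15 * len & fe$mid < 0.85 * len
      if (!any(central)) stop("no mappable fragend in the central chromosome region")
      pos[i] <- sample(fe$mid[central], 1L)
    }
    data.frame(snp_id = sprintf("rs%06d", seq_len(config$n_viewpoints)),
               chrom = chrom, pos = pos, primer = primers,
               cell_types = I(rep(list(config$cell_types),
                                  config$n_viewpoints)),
               stringsAsFactors = FALSE)
  })
}

# Planted contact intervals for one viewpoint: either the fixed global list
# restricted to its chromosome, or auto-planted at >= min_contact_distance
# from the viewpoint, mutually disjoint.
planted_for_viewpoint <- function(config, viewpoint, vp_index) {
  if (!is.null(config$planted_contacts)) {
    pc <- config$planted_contacts
    pc <- pc[pc$chrom == viewpoint$chrom, , drop = FALSE]
    rownames(pc) <- NULL
    return(pc)
  }
  len <- config$chromosome_length
  span <- config$planted_span
  with_seed(substream_seed(config$seed, vp_index, 0L) + 13L, {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      prob = numeric(), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(out) < config$n_contacts_per_viewpoint && tries < 1000L) {
      tries <- tries + 1L
      start <- floor(runif(1L, 0.02 * len, 0.98 * len - span))
      end <- start + span
      d <- point_interval_distance(viewpoint$pos, start, end)
      if (d < config$min_contact_distance) next
      if (nrow(out) > 0L &&
          any(pmax(out$start, start) < pmin(out$end, end) + config$decoy_margin)) next
      out <- rbind(out, data.frame(chrom = viewpoint$chrom, start = start,
                                   end = end, prob = config$planted_coverage,
                                   stringsAsFactors = FALSE))
    }
    if (nrow(out) < config$n_contacts_per_viewpoint) {
      stop("could not place planted contacts; chromosome too short for the requested layout")
    }
    out[order(out$start), , drop = FALSE]
  })
}

# Intervals where real 4C signal is expected: planted contacts plus the
# viewpoint-proximal zone, out to where the decay curve meets background.
signal_intervals <- function(config, viewpoint, planted) {
  z <- ceiling(config$viewpoint_decay_halflife *
                 log2(1 / config$background_coverage))
  zone <- data.frame(chrom = viewpoint$chrom,
                     start = max(0, viewpoint$pos - z),
                     end = min(config$chromosome_length, viewpoint$pos + z),
                     prob = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(planted[, c("chrom", "start", "end", "prob")], zone)
  out[order(out$start), , drop = FALSE]
}

#' Simulate a binary fragend coverage profile with planted contacts
#'
#' Each mappable fragend of the viewpoint chromosome is covered by an
#' independent Bernoulli draw with probability
#' `max(background, 2^(-d/halflife), planted prob)`, where `d` is the
#' distance from the fragend midpoint to the viewpoint and the planted
#' probability applies inside planted contact intervals. The max (rather
#' than a sum) keeps each fragend a single Bernoulli draw with a
#' well-defined stratum probability.
#'
#' @param library A `fragend_library`.
#' @param viewpoint One viewpoint row (see [make_viewpoints()]).
#' @param config A [sim_config()].
#' @param vp_index Viewpoint index used for the RNG substream.
#' @param cell_type Cell-type label (also selects its RNG substream).
#' @return List with `profile` (a `coverage_profile`) and `truth` (list:
#'   `planted`, `signal` intervals, `viewpoint_zone_halfwidth`).
#' @export
simulate_coverage <- function(library, viewpoint, config, vp_index = 1L,
                              cell_type = config$cell_types[1L]) {
  validate_sim_config(config)
  chrom <- as.character(viewpoint$chrom)
  if (!chrom %in% names(library$chrom_lengths)) {
    stop(sprintf("viewpoint chromosome '%s' absent from fragend library", chrom))
  }
  if (viewpoint$pos < 0 || viewpoint$pos >= library$chrom_lengths[[chrom]]) {
    stop("viewpoint position outside its chromosome")
  }
  fe <- mappable_fragends(library, chrom)
  planted <- planted_for_viewpoint(config, viewpoint, vp_index)
  d <- abs(fe$mid - viewpoint$pos)
  p <- pmax(config$background_coverage, 2^(-d / config$viewpoint_decay_halflife))
  for (j in seq_len(nrow(planted))) {
    inside <- fe$mid >= planted$start[j] & fe$mid < planted$end[j]
    p[inside] <- pmax(p[inside], planted$prob[j])
  }
  ct_index <- match(cell_type, config$cell_types)
  if (is.na(ct_index)) ct_index <- config$n_cell_types + 1L
  covered <- with_seed(substream_seed(config$seed, vp_index, ct_index),
                       as.integer(runif(nrow(fe)) < p))
  fe$count <- covered
  fe$covered <- covered
  rownames(fe) <- NULL
  profile <- new_coverage_profile(
    snp_id = as.character(viewpoint$snp_id), cell_type = cell_type,
    chrom = chrom, viewpoint_pos = as.numeric(viewpoint$pos), fragends = fe
  )
  truth <- list(
    planted = planted,
    signal = signal_intervals(config, viewpoint, planted),
    viewpoint_zone_halfwidth = ceiling(config$viewpoint_decay_halflife *
                                         log2(1 / config$background_coverage))
  )
  list(profile = profile, truth = truth)
}

#' Emit synthetic 4C reads from a coverage profile
#'
#' The inverse of the mapping step: every covered fragend yields `depth`
#' reads consisting of the viewpoint primer followed by the fragend's
#' mapping 16-mer; uncovered fragends yield none. Running the reads back
#' through [demultiplex()] and [map_reads()] recovers the covered set
#' exactly when all 16-mers are unique.
#'
#' @param profile A `coverage_profile` whose `fragends` carry `seq16`.
#' @param viewpoint Viewpoint row supplying the primer.
#' @param depth Reads per covered fragend (>= 1).
#' @return Named character vector of read sequences.
#' @export
emit_reads <- function(profile, viewpoint, depth = 1L) {
  if (!is.numeric(depth) || depth < 1L) stop("depth must be >= 1")
  depth <- as.integer(depth)
  fe <- profile$fragends
  if (!"seq16" %in% names(fe)) stop("profile fragends lack mapping 16-mers")
  cov <- fe[fe$covered == 1L, , drop = FALSE]
  if (nrow(cov) == 0L) return(setNames(character(), character()))
  reads <- rep(paste0(viewpoint$primer, cov$seq16), each = depth)
  names(reads) <- sprintf("%s_%s_f%d_r%d", profile$snp_id, profile$cell_type,
                          rep(seq_len(nrow(cov)), each = depth),
                          rep(seq_len(depth), nrow(cov)))
  reads
}
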