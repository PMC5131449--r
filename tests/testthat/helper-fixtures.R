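# Shared fixture builders. Everything is generated in code; no data files.

# Single-site toy chromosome: 16 A's, GATC, 16 T's.
toy_single_site <- function() {
  c(chr1 = paste0(strrep("A", 16), "GATC", strrep("T", 16)))
}

# Small deterministic library with n GATC sites separated by random unique
# 20-bp spacers (flanks are 16 bp, so every fragend is mappable and, with
# overwhelming probability at these sizes, unique).
toy_library <- function(n_sites = 10, seed = 42, spacer = 20) {
  set.seed(seed)
  chunks <- vapply(seq_len(n_sites + 1), function(i) {
    paste(sample(c("A", "C", "T"), spacer, replace = TRUE), collapse = "")
  }, character(1))
  seqs <- paste(chunks, collapse = "GATC")
  build_fragend_library(c(chr1 = seqs))
}

# Hand-built coverage profile from a covered vector; fragends every 250 bp.
manual_profile <- function(covered, spacing = 250, chrom = "chr1",
                           viewpoint_pos = NULL, snp_id = "rsX",
                           cell_type = "ct") {
  n <- length(covered)
  start <- as.integer(seq(0L, by = spacing, length.out = n))
  fe <- data.frame(chrom = rep(chrom, n), start = start, end = start + 16L,
                   mid = start + 8L, count = as.integer(covered),
                   covered = as.integer(covered), stringsAsFactors = FALSE)
  if (is.null(viewpoint_pos)) viewpoint_pos <- fe$mid[ceiling(n / 2)]
  fourcgenes:::new_coverage_profile(snp_id, cell_type, chrom, viewpoint_pos, fe)
}

# Small strong-effect study configuration: one viewpoint per chromosome,
# every locus active, every decoy expressed status randomized.
strong_config <- function(seed = 5, n_viewpoints = 3) {
  sim_config(seed = seed, n_chromosomes = n_viewpoints,
             chromosome_length = 1e6, n_viewpoints = n_viewpoints,
             planted_coverage = 0.9, background_coverage = 0.04,
             active_fraction = 1, expressed_decoy_fraction = 0.5)
}
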