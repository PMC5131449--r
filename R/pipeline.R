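#' Simulate a complete synthetic 4C study
#'
#' Generates the genome, digests it into the fragend library, lays out the
#' viewpoints, simulates one binary coverage profile per viewpoint x cell
#' type with planted contacts, and builds the matching annotation tables.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param keep_profiles Keep the full coverage profiles in the returned
#'   object (set `FALSE` for large designs; per-profile summaries are
#'   always kept).
#' @return List of class `fourc_study`: `config`, `library`, `viewpoints`,
#'   `profiles` (named `snp_id.cell_type`, when kept), `truths` (per
#'   `snp_id`), `annotations`.
#' @export
simulate_study <- function(config, keep_profiles = TRUE) {
  validate_sim_config(config)
  genome <- generate_genome(config)
  library <- build_fragend_library(genome)
  viewpoints <- make_viewpoints(config, library)
  profiles <- list()
  truths <- list()
  for (i in seq_len(nrow(viewpoints))) {
    vp <- viewpoints[i, , drop = FALSE]
    for (ct in config$cell_types) {
      sim <- simulate_coverage(library, vp, config, vp_index = i,
                               cell_type = ct)
      if (keep_profiles) {
        profiles[[paste(vp$snp_id, ct, sep = ".")]] <- sim$profile
      }
      truths[[vp$snp_id]] <- sim$truth   # same planted truth across cell types
    }
  }
  annotations <- generate_annotations(config, viewpoints, truths)
  structure(
    list(config = config, library = library, viewpoints = viewpoints,
         profiles = if (keep_profiles) profiles else NULL,
         truths = truths, annotations = annotations),
    class = "fourc_study"
  )
}

#' Run the full 4C candidate-gene pipeline on a synthetic study
#'
#' For every viewpoint x cell type dataset: simulates (or reuses) the
#' coverage profile, calibrates the window size and background rate, calls
#' significant interaction segments, applies the three candidate-gene
#' criteria (TSS within 5 kbp of significant signal; enhancer activity of
#' the locus; expression above log2(RPKM) cutoff), and summarizes cell-type
#' overlaps and viewpoint-to-gene distances.
#'
#' @param config A [sim_config()], or a ready-made `fourc_study`.
#' @param threshold Window significance cutoff.
#' @param max_dist Criterion-1 TSS distance, bp.
#' @param expression_cutoff Criterion-3 cutoff, log2(RPKM).
#' @param keep_profiles Keep per-dataset coverage profiles in the result.
#' @param ... Further arguments to [scan_and_call()].
#' @return List of class `fourc_result`: `study` (without profiles unless
#'   kept), `calls` (per dataset), `dataset_summary` (one row per
#'   viewpoint x cell type), `n_datasets`, `interactions`, `candidates`,
#'   `venn`, `distance`.
#' @export
run_fourc_study <- function(config, threshold = 1e-8, max_dist = 5000,
                            expression_cutoff = -0.5, keep_profiles = FALSE,
                            ...) {
  if (inherits(config, "fourc_study")) {
    study <- config
    config <- study$config
    prebuilt <- !is.null(study$profiles)
  } else {
    study <- simulate_study(config, keep_profiles = FALSE)
    prebuilt <- FALSE
  }
  ann <- study$annotations
  viewpoints <- study$viewpoints
  calls <- list()
  summaries <- list()
  inter_rows <- list()
  for (i in seq_len(nrow(viewpoints))) {
    vp <- viewpoints[i, , drop = FALSE]
    for (ct in config$cell_types) {
      key <- paste(vp$snp_id, ct, sep = ".")
      profile <- if (prebuilt) study$profiles[[key]] else
        simulate_coverage(study$library, vp, config, vp_index = i,
                          cell_type = ct)$profile
      cl <- scan_and_call(profile, threshold = threshold, ...)
      calls[[key]] <- cl
      summaries[[key]] <- data.frame(
        snp_id = vp$snp_id, cell_type = ct, chrom = vp$chrom,
        n_fragends = nrow(profile$fragends),
        n_covered = sum(profile$fragends$covered),
        k = cl$k, p0 = cl$p0, n_segments = nrow(cl$segments),
        stringsAsFactors = FALSE
      )
      hits <- genes_near_segments(ann$genes, cl$segments, max_dist = max_dist)
      if (nrow(hits) > 0L) {
        hits$snp_id <- vp$snp_id
        hits$cell_type <- ct
        inter_rows[[key]] <- hits
      }
    }
  }
  dataset_summary <- do.call(rbind, summaries)
  rownames(dataset_summary) <- NULL
  interactions <- if (length(inter_rows) > 0L) do.call(rbind, inter_rows) else
    data.frame(gene_id = character(), min_p = numeric(), distance = numeric(),
               snp_id = character(), cell_type = character(),
               stringsAsFactors = FALSE)
  rownames(interactions) <- NULL
  activity <- assess_locus_activity(viewpoints, ann$ld, ann$peaks)
  candidates <- assemble_candidates(interactions, activity, ann$expression,
                                    viewpoints, ann$genes,
                                    known_genes = ann$known_genes,
                                    expression_cutoff = expression_cutoff)
  venn <- if (nrow(candidates) > 0L)
    celltype_overlap(candidates, cell_types = config$cell_types) else NULL
  dist <- if (nrow(candidates) > 0L) distance_stats(candidates) else NULL
  if (!keep_profiles) study$profiles <- NULL
  structure(
    list(study = study, calls = calls, dataset_summary = dataset_summary,
         n_datasets = nrow(dataset_summary), interactions = interactions,
         candidates = candidates, venn = venn, distance = dist),
    class = "fourc_result"
  )
}

#' @export
print.fourc_result <- function(x, ...) {
  cat(sprintf("fourc_result: %d interaction datasets (%d viewpoints x %d cell types)\n",
              x$n_datasets, length(unique(x$dataset_summary$snp_id)),
              length(unique(x$dataset_summary$cell_type))))
  cat(sprintf("  %d candidate records, %d distinct candidate genes (%d novel)\n",
              nrow(x$candidates), length(unique(x$candidates$gene_id)),
              length(unique(x$candidates$gene_id[x$candidates$novel]))))
  if (!is.null(x$distance)) {
    m <- x$distance$medians
    cat(sprintf("  median viewpoint-to-gene distance: %s\n",
                paste(sprintf("%s %.0f kbp", names(m), m / 1000),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Export the main pipeline tables to a directory
#'
#' Writes `candidates.tsv`, `venn.tsv`, `distances.tsv`,
#' `dataset_summary.tsv`, one segment BED per dataset and the ground-truth
#' JSON sidecar.
#'
#' @param result A `fourc_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_results <- function(result, dir) {
  stopifnot(inherits(result, "fourc_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$candidates, file.path(dir, "candidates.tsv"))
  if (!is.null(result$venn)) write_tsv(result$venn, file.path(dir, "venn.tsv"))
  if (!is.null(result$distance)) {
    write_tsv(result$distance$distances, file.path(dir, "distances.tsv"))
  }
  write_tsv(result$dataset_summary, file.path(dir, "dataset_summary.tsv"))
  for (key in names(result$calls)) {
    write_segments_bed(result$calls[[key]],
                       file.path(dir, paste0(key, ".segments.bed")))
  }
  write_ground_truth(result$study$annotations$truth,
                     file.path(dir, "ground_truth.json"))
  invisible(dir)
}
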