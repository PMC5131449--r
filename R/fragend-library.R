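#' Build an in silico fragend library from a genome
#'
#' Digests a genome in silico with a restriction enzyme (DpnII, recognition
#' site GATC, by default) and records the two fragment ends ("fragends")
#' flanking every site. Each fragend carries the 16-mer used for exact read
#' mapping: the 16 bases reading away from the cut on its side of the site,
#' excluding the recognition site itself. For the upstream fragend this read
#' direction is the minus strand, so its mapping 16-mer is the reverse
#' complement of the 16 reference bases immediately 5' of the site.
#'
#' A fragend is mappable when its flank holds a full 16 unambiguous bases
#' (sites near a chromosome end or closer than 16 bp to the adjacent site
#' yield shorter, non-mappable fragends). Uniqueness — whether the 16-mer
#' occurs at exactly one fragend genome-wide — is a separate flag; reads are
#' mapped, and coverage profiles defined, over unique-mappable fragends
#' only. The recognition site is palindromic, so sites are detected on the
#' forward strand only.
#'
#' @param genome A named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences over A/C/G/T. Other letters never match
#'   the recognition site and simply interrupt flanks.
#' @param site Recognition site; must equal its reverse complement.
#' @param flank_width Mapping flank width in bases.
#' @return An object of class `fragend_library`: a list with
#'   `fragends` (data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `mid`, `side` ("up"/"down"), `seq16`, `len`, `unique`, `mappable`),
#'   `chrom_lengths`, `site`, and `flank_width`.
#' @examples
#' lib <- build_fragend_library(c(chr1 = paste0(strrep("A", 16), "GATC", strrep("T", 16))))
#' lib$fragends
#' @export
build_fragend_library <- function(genome, site = "GATC", flank_width = 16L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("genome sequences must carry unique chromosome names")
  }
  site_dna <- Biostrings::DNAString(site)
  if (as.character(Biostrings::reverseComplement(site_dna)) != site) {
    stop("recognition site must be palindromic; forward-strand search assumes it")
  }
  site_len <- nchar(site)
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  short <- chrom_lengths < flank_width
  if (any(short)) {
    warning(sprintf("chromosome(s) shorter than %d bp yield no fragends: %s",
                    flank_width, paste(names(genome)[short], collapse = ", ")))
  }

  per_chrom <- lapply(seq_along(genome), function(i) {
    chrom <- names(genome)[i]
    len <- chrom_lengths[[i]]
    if (len < flank_width) return(NULL)
    hits <- Biostrings::matchPattern(site_dna, genome[[i]])
    if (length(hits) == 0L) return(NULL)
    g <- BiocGenerics::start(hits) - 1L   # 0-based site starts
    site_end <- g + site_len
    # flanks truncated by the adjacent site or the chromosome edge
    up_lo <- pmax(c(0L, site_end[-length(g)]), g - flank_width)
    dn_hi <- pmin(c(g[-1L], len), site_end + flank_width)
    up_len <- g - up_lo
    dn_len <- dn_hi - site_end
    seq <- genome[[i]]
    up_seq <- rep(NA_character_, length(g))
    dn_seq <- rep(NA_character_, length(g))
    full_up <- up_len == flank_width
    full_dn <- dn_len == flank_width
    if (any(full_up)) {
      v <- Biostrings::Views(seq, start = up_lo[full_up] + 1L, end = g[full_up])
      up_seq[full_up] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(v)))
    }
    if (any(full_dn)) {
      v <- Biostrings::Views(seq, start = site_end[full_dn] + 1L,
                             end = dn_hi[full_dn])
      dn_seq[full_dn] <- as.character(Biostrings::DNAStringSet(v))
    }
    df <- rbind(
      data.frame(chrom = chrom, start = up_lo, end = g, side = "up",
                 seq16 = up_seq, len = up_len, stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start = site_end, end = dn_hi, side = "down",
                 seq16 = dn_seq, len = dn_len, stringsAsFactors = FALSE)
    )
    df[order(df$start, df$end), , drop = FALSE]
  })
  fragends <- do.call(rbind, per_chrom)
  if (is.null(fragends)) {
    fragends <- data.frame(chrom = character(), start = integer(),
                           end = integer(), side = character(),
                           seq16 = character(), len = integer(),
                           stringsAsFactors = FALSE)
  }
  # ambiguous-letter flanks (N etc.) are never mappable
  has_seq <- !is.na(fragends$seq16) &
    !grepl("[^ACGT]", fragends$seq16)
  fragends$seq16[!has_seq] <- NA_character_
  dup <- duplicated(fragends$seq16, incomparables = NA) |
    duplicated(fragends$seq16, incomparables = NA, fromLast = TRUE)
  fragends$unique <- has_seq & !dup
  # mappable = full-length unambiguous flank; uniqueness is a separate flag,
  # and coverage profiles are defined over unique-mappable fragends
  fragends$mappable <- fragends$len == flank_width & has_seq
  fragends$mid <- as.integer((fragends$start + fragends$end) %/% 2L)
  rownames(fragends) <- NULL
  structure(
    list(fragends = fragends, chrom_lengths = chrom_lengths,
         site = site, flank_width = as.integer(flank_width)),
    class = "fragend_library"
  )
}

#' @export
print.fragend_library <- function(x, ...) {
  cat(sprintf("fragend_library: %d fragends (%d mappable, %d unique-mappable) over %d chromosome(s), site %s\n",
              nrow(x$fragends), sum(x$fragends$mappable),
              sum(x$fragends$mappable & x$fragends$unique),
              length(x$chrom_lengths), x$site))
  invisible(x)
}

# Unique-mappable fragends of one chromosome, in coordinate order: the
# units over which coverage profiles are defined.
mappable_fragends <- function(library, chrom) {
  fe <- library$fragends
  fe[fe$chrom == chrom & fe$mappable & fe$unique, , drop = FALSE]
}

#' Read a viewpoint table
#'
#' The table must carry columns `snp_id`, `chrom`, `pos` (0-based bp),
#' `primer` and `cell_types` (comma-separated labels).
#'
#' @param path TSV file path.
#' @return data.frame with `cell_types` split into a list column.
#' @export
read_viewpoints <- function(path) {
  vp <- read_tsv_strict(path, c("snp_id", "chrom", "pos", "primer", "cell_types"),
                        "viewpoint")
  vp$cell_types <- strsplit(as.character(vp$cell_types), ",", fixed = TRUE)
  validate_viewpoints(vp)
  vp
}

validate_viewpoints <- function(viewpoints) {
  stopifnot(is.data.frame(viewpoints),
            all(c("snp_id", "chrom", "pos", "primer") %in% names(viewpoints)))
  if (any(!nzchar(viewpoints$primer))) stop("viewpoint primers must be non-empty")
  if (anyDuplicated(viewpoints$snp_id)) stop("duplicate viewpoint snp_id")
  p <- viewpoints$primer
  if (length(p) > 1L) {
    for (i in seq_along(p)) {
      clash <- p[-i][startsWith(p[-i], p[i])]
      if (length(clash) > 0L) {
        stop(sprintf("primer '%s' is a prefix of primer '%s': viewpoints cannot be demultiplexed unambiguously",
                     p[i], clash[1L]))
      }
    }
  }
  invisible(viewpoints)
}

#' Demultiplex 4C reads by viewpoint primer
#'
#' Assigns each read to the unique viewpoint whose primer sequence is an
#' exact prefix of the read, strips the primer, and drops (but counts)
#' unassigned reads. Primers are validated to be mutually non-prefixing, so
#' assignment is unambiguous.
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param viewpoints Viewpoint table (see [read_viewpoints()]).
#' @return List with `payloads` (named list, per `snp_id`, of primer-stripped
#'   read sequences) and `n_unassigned`.
#' @export
demultiplex <- function(reads, viewpoints) {
  validate_viewpoints(viewpoints)
  reads <- as.character(reads)
  assigned <- logical(length(reads))
  payloads <- vector("list", nrow(viewpoints))
  names(payloads) <- viewpoints$snp_id
  for (i in seq_len(nrow(viewpoints))) {
    primer <- viewpoints$primer[i]
    sel <- startsWith(reads, primer)
    payloads[[i]] <- substring(reads[sel], nchar(primer) + 1L)
    assigned <- assigned | sel
  }
  list(payloads = payloads, n_unassigned = sum(!assigned))
}

#' Map primer-stripped reads to fragends
#'
#' Trims each payload to its first 16 bases and looks it up, exactly and
#' with no mismatches, among the mapping 16-mers of the library's unique
#' fragends. Reads matching a non-unique 16-mer (multi-hit) or no fragend
#' are discarded and counted. The binary coverage status of a fragend is 1
#' when at least one read maps to it. The returned profile is restricted to
#' the mappable fragends of the viewpoint chromosome (4C interaction
#' calling is cis-only); whole-genome per-chromosome mapped-read counts are
#' retained for QC.
#'
#' @param payloads Character vector of primer-stripped read sequences
#'   (length >= 16 each).
#' @param library A `fragend_library`.
#' @param viewpoint One-row data.frame (or list) with `snp_id`, `chrom`,
#'   `pos`; a `cell_type` entry, when present, labels the profile.
#' @return A `coverage_profile`: list with `snp_id`, `cell_type`, `chrom`,
#'   `viewpoint_pos`, `fragends` (cis mappable fragends with `count` and
#'   `covered`), and `counts` (n_assigned, n_mapped, n_multi, n_unmapped,
#'   mapped_per_chrom).
#' @export
map_reads <- function(payloads, library, viewpoint) {
  stopifnot(inherits(library, "fragend_library"))
  chrom <- as.character(viewpoint$chrom)
  if (!chrom %in% names(library$chrom_lengths)) {
    stop(sprintf("viewpoint chromosome '%s' absent from fragend library", chrom))
  }
  payloads <- as.character(payloads)
  if (length(payloads) == 0L) {
    warning("empty read set: returning an all-uncovered profile")
  }
  if (any(nchar(payloads) < library$flank_width)) {
    stop(sprintf("all payloads must be at least %d bases", library$flank_width))
  }
  mers <- substr(payloads, 1L, library$flank_width)
  fe <- library$fragends
  uniq_idx <- which(fe$mappable & fe$unique)
  hit <- match(mers, fe$seq16[uniq_idx])
  nonuniq <- fe$seq16[!fe$unique & !is.na(fe$seq16)]
  n_multi <- sum(is.na(hit) & mers %in% nonuniq)
  n_unmapped <- sum(is.na(hit)) - n_multi
  counts_all <- tabulate(hit, nbins = length(uniq_idx))
  mapped_per_chrom <- tapply(counts_all, fe$chrom[uniq_idx], sum)

  cis_idx <- which(fe$chrom == chrom & fe$mappable & fe$unique)
  cis <- fe[cis_idx, , drop = FALSE]
  cis$count <- counts_all[match(cis_idx, uniq_idx)]
  cis$covered <- as.integer(cis$count >= 1L)
  rownames(cis) <- NULL
  new_coverage_profile(
    snp_id = as.character(viewpoint$snp_id),
    cell_type = if (!is.null(viewpoint$cell_type)) as.character(viewpoint$cell_type) else NA_character_,
    chrom = chrom,
    viewpoint_pos = as.numeric(viewpoint$pos),
    fragends = cis,
    counts = list(
      n_assigned = length(payloads),
      n_mapped = sum(!is.na(hit)),
      n_multi = n_multi,
      n_unmapped = n_unmapped,
      mapped_per_chrom = as.list(mapped_per_chrom)
    )
  )
}

new_coverage_profile <- function(snp_id, cell_type, chrom, viewpoint_pos,
                                 fragends, counts = list()) {
  stopifnot(all(c("chrom", "start", "end", "mid", "covered") %in% names(fragends)))
  if (!"count" %in% names(fragends)) fragends$count <- fragends$covered
  stopifnot(all(fragends$covered == as.integer(fragends$count >= 1L)))
  structure(
    list(snp_id = snp_id, cell_type = cell_type, chrom = chrom,
         viewpoint_pos = viewpoint_pos, fragends = fragends, counts = counts),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s [%s]: %s:%d, %d fragends, %d covered (%.1f%%)\n",
              x$snp_id, x$cell_type, x$chrom, round(x$viewpoint_pos),
              nrow(x$fragends), sum(x$fragends$covered),
              100 * mean(x$fragends$covered)))
  invisible(x)
}

#' Write / read a binary fragend coverage track
#'
#' One BED record per mappable fragend of the viewpoint chromosome, with the
#' covered/non-covered (1 or 0) status in the score column; suitable for
#' genome-browser display. `read_coverage_bed()` restores the binary profile
#' (read counts are not stored in BED and come back equal to the status).
#'
#' @param profile A `coverage_profile`.
#' @param path Output BED path.
#' @param snp_id,cell_type,chrom,viewpoint_pos Profile metadata to attach on
#'   read-back (BED does not store them).
#' @return `write_coverage_bed()` the path, invisibly; `read_coverage_bed()`
#'   a `coverage_profile`.
#' @export
write_coverage_bed <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  fe <- profile$fragends
  header <- sprintf("track name=\"%s.%s.cov\" description=\"4C fragend coverage %s %s\"",
                    profile$cell_type, profile$snp_id, profile$snp_id,
                    profile$cell_type)
  if (nrow(fe) == 0L) {
    writeLines(c(sprintf("# empty coverage profile %s %s", profile$snp_id,
                         profile$cell_type), header), path)
    return(invisible(path))
  }
  gr <- df_to_granges(fe,
                      name = sprintf("%s_fe%d", profile$snp_id,
                                     seq_len(nrow(fe))),
                      score = fe$covered)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_coverage_bed
#' @export
read_coverage_bed <- function(path, snp_id = NA_character_,
                              cell_type = NA_character_, chrom = NULL,
                              viewpoint_pos = NA_real_) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || startsWith(first, "#")) {
    fe <- data.frame(chrom = character(), start = integer(), end = integer(),
                     mid = integer(), count = integer(), covered = integer(),
                     stringsAsFactors = FALSE)
    return(new_coverage_profile(snp_id, cell_type, chrom %||% NA_character_,
                                viewpoint_pos, fe))
  }
  gr <- rtracklayer::import.bed(path)
  fe <- granges_to_df(gr)
  fe$mid <- as.integer((fe$start + fe$end) %/% 2L)
  fe$covered <- as.integer(gr$score >= 1)
  fe$count <- fe$covered
  new_coverage_profile(snp_id, cell_type, chrom %||% fe$chrom[1L],
                       viewpoint_pos, fe)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read 4C reads as FASTQ
#'
#' Thin wrappers over [Biostrings::writeXStringSet()] for the synthetic
#' reads produced by [emit_reads()]. Quality strings are uninformative
#' placeholders: the pipeline maps by exact sequence match only.
#'
#' @param reads Character vector (named or not) of read sequences.
#' @param path FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(reads)))
  names(x) <- if (!is.null(names(reads))) names(reads) else
    sprintf("read_%d", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
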