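# Internal helpers shared across modules.

#' @importFrom stats runif median setNames
#' @importFrom utils read.delim write.table
NULL

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic per-viewpoint / per-cell-type substream seed. Arithmetic
# derivation (not sample()) so that adding a viewpoint or cell type never
# perturbs the streams of the existing ones. Kept below 2^31 - 1.
substream_seed <- function(seed, viewpoint_index, celltype_index = 0L) {
  (as.numeric(seed) %% 1e5) * 20011 +
    viewpoint_index * 7919 + celltype_index * 104729
}

# Distance in bp from a point to a 0-based half-open interval [start, end):
# 0 if the point falls on a covered base, otherwise distance to the nearest
# covered base. Vectorized over intervals.
point_interval_distance <- function(pos, start, end) {
  d <- numeric(length(start))
  left <- pos < start
  right <- pos >= end
  d[left] <- start[left] - pos
  d[right] <- pos - (end[right] - 1L)
  d
}

# data.frame(chrom, start, end) with 0-based half-open coords -> GRanges.
df_to_granges <- function(df, ...) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    ...
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a BED file as a plain interval table
#'
#' Thin wrapper over [rtracklayer::import.bed()] returning a data.frame
#' with 0-based half-open `start`/`end` columns (plus `name`/`score` when
#' present), the coordinate convention used throughout the package.
#'
#' @param path BED file path.
#' @return data.frame: `chrom`, `start`, `end`, and any name/score columns.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import.bed(path)
  df <- granges_to_df(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}

read_tsv_strict <- function(path, required, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table '%s' lacks column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
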