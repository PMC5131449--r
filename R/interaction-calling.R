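#' Adaptive running-window size for a viewpoint
#'
#' The running-window width k (in fragends) is calibrated per viewpoint so
#' that a window contains on average `target_covered` covered fragends in
#' the region around the viewpoint: k = target / r, where r is the covered
#' fraction among mappable fragends within `flank` bp of the viewpoint,
#' rounded half away from zero. When 100 of 150 flanking fragends are
#' covered and the target is 20, k = 30. Because r <= 1, k never falls
#' below `target_covered`.
#'
#' @param profile A `coverage_profile`.
#' @param flank Calibration flank around the viewpoint, bp.
#' @param target_covered Average covered fragends a window should contain.
#' @return Integer window size k (fragends).
#' @export
compute_window_size <- function(profile, flank = 100000, target_covered = 20) {
  stopifnot(inherits(profile, "coverage_profile"))
  fe <- profile$fragends
  near <- abs(fe$mid - profile$viewpoint_pos) <= flank
  total <- sum(near)
  covered <- sum(fe$covered[near])
  if (total == 0L || covered == 0L) {
    stop(sprintf("viewpoint %s failed QC: no covered fragend within %d bp; cannot calibrate window size",
                 profile$snp_id, flank))
  }
  as.integer(round_half_away(target_covered * total / covered))
}

#' Background coverage rate for the binomial null
#'
#' The null coverage probability p0 is the covered fraction over all
#' mappable fragends of the viewpoint chromosome, excluding the
#' viewpoint-proximal region (+/- `exclusion` bp) whose decay-dominated
#' coverage would inflate the background. p0 is clamped to
#' [1/(n+2), (n+1)/(n+2)] so it is always strictly inside (0,1).
#'
#' @param profile A `coverage_profile`.
#' @param exclusion Viewpoint exclusion radius, bp.
#' @return Background probability p0.
#' @export
background_rate <- function(profile, exclusion = 100000) {
  stopifnot(inherits(profile, "coverage_profile"))
  fe <- profile$fragends
  far <- abs(fe$mid - profile$viewpoint_pos) > exclusion
  n <- sum(far)
  if (n == 0L) {
    stop("all fragends lie inside the viewpoint exclusion zone; cannot estimate background")
  }
  if (n < 1000L) {
    warning(sprintf("only %d fragends outside the exclusion zone; background estimate is noisy", n))
  }
  p0 <- sum(fe$covered[far]) / n
  min(max(p0, 1 / (n + 2)), (n + 1) / (n + 2))
}

#' Upper-tail binomial p-value for a window
#'
#' p = P(X >= x) for X ~ Binomial(k, p0): the upper tail including x, via
#' the binomial cumulative distribution function. By convention p(0) = 1.
#'
#' @param x Covered fragends in the window (0 <= x <= k); vectorized.
#' @param k Window size in fragends.
#' @param p0 Background coverage probability in (0,1).
#' @return p-value(s) in (0, 1].
#' @export
binomial_pvalue <- function(x, k, p0) {
  if (any(x < 0 | x > k)) stop("x must satisfy 0 <= x <= k")
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie strictly in (0,1)")
  stats::pbinom(x - 1, size = k, prob = p0, lower.tail = FALSE)
}

#' Scan a coverage profile and call significant interaction segments
#'
#' Slides a window of k consecutive mappable fragends one fragend at a time
#' across the whole viewpoint chromosome, scores each window's covered
#' count against Binomial(k, p0), marks windows with p < `threshold` as
#' significant 4C signal, and merges overlapping or adjacent significant
#' windows into interaction segments. Windows lying wholly inside the
#' viewpoint self-circle zone (viewpoint fragend +/- `self_circle`
#' fragends) are excluded from calling.
#'
#' @param profile A `coverage_profile`.
#' @param threshold Significance cutoff on the window p-value (strict <).
#' @param k Window size; computed via [compute_window_size()] when `NULL`.
#' @param p0 Background rate; computed via [background_rate()] when `NULL`.
#' @param flank,target_covered Passed to [compute_window_size()].
#' @param exclusion Passed to [background_rate()].
#' @param self_circle Self-circle zone radius in fragends around the
#'   viewpoint fragend; `NA` disables the exclusion.
#' @return Object of class `interaction_calls`: list with `segments`
#'   (data.frame: `chrom`, `start`, `end`, `min_p`, `n_windows`,
#'   `distance`), `k`, `p0`, `threshold`, `snp_id`, `cell_type`,
#'   `viewpoint_pos` and `n_windows_scanned`.
#' @export
scan_and_call <- function(profile, threshold = 1e-8, k = NULL, p0 = NULL,
                          flank = 100000, target_covered = 20,
                          exclusion = 100000, self_circle = 2L) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (is.null(k)) k <- compute_window_size(profile, flank, target_covered)
  if (is.null(p0)) p0 <- background_rate(profile, exclusion)
  fe <- profile$fragends
  n <- nrow(fe)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      min_p = numeric(), n_windows = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  res <- structure(
    list(segments = empty, k = k, p0 = p0, threshold = threshold,
         snp_id = profile$snp_id, cell_type = profile$cell_type,
         viewpoint_pos = profile$viewpoint_pos, n_windows_scanned = 0L),
    class = "interaction_calls"
  )
  if (n < k) {
    warning(sprintf("chromosome has %d mappable fragends, fewer than window size %d: no windows", n, k))
    return(res)
  }
  cs <- c(0L, cumsum(fe$covered))
  starts <- seq_len(n - k + 1L)             # window i covers fragends [i, i+k-1]
  x <- cs[starts + k] - cs[starts]
  keep <- rep(TRUE, length(starts))
  if (!is.na(self_circle)) {
    v <- which.min(abs(fe$mid - profile$viewpoint_pos))
    keep <- !(starts >= v - self_circle & starts + k - 1L <= v + self_circle)
  }
  p <- binomial_pvalue(x, k, p0)
  sig <- which(keep & p < threshold)
  res$n_windows_scanned <- sum(keep)
  if (length(sig) == 0L) return(res)
  # windows i and j overlap iff |i-j| < k and are adjacent iff |i-j| == k
  brk <- which(diff(sig) > k)
  seg_first <- sig[c(1L, brk + 1L)]
  seg_last <- sig[c(brk, length(sig))]
  segs <- do.call(rbind, lapply(seq_along(seg_first), function(s) {
    members <- sig[sig >= seg_first[s] & sig <= seg_last[s]]
    start <- fe$start[seg_first[s]]
    end <- fe$end[seg_last[s] + k - 1L]
    data.frame(chrom = profile$chrom, start = start, end = end,
               min_p = min(p[members]), n_windows = length(members),
               distance = point_interval_distance(profile$viewpoint_pos,
                                                  start, end),
               stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  res$segments <- segs
  res
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("interaction_calls %s [%s]: k=%d, p0=%.4g, %d segment(s) at p < %g\n",
              x$snp_id, x$cell_type, x$k, x$p0, nrow(x$segments), x$threshold))
  invisible(x)
}

#' Write / read interaction segments as BED
#'
#' One record per segment; name is the viewpoint SNP id and the score is
#' -log10(minimum window p-value), capped at 1000.
#'
#' @param calls An `interaction_calls` object (or a bare segment
#'   data.frame plus `snp_id`).
#' @param path BED path.
#' @param snp_id Name column value when `calls` is a bare data.frame.
#' @return `write_segments_bed()` the path, invisibly; `read_segments_bed()`
#'   a data.frame (`chrom`, `start`, `end`, `snp_id`, `score`).
#' @export
write_segments_bed <- function(calls, path, snp_id = NULL) {
  if (inherits(calls, "interaction_calls")) {
    segs <- calls$segments
    snp_id <- calls$snp_id
  } else {
    segs <- calls
    if (is.null(snp_id)) stop("snp_id required when writing a bare segment table")
  }
  if (nrow(segs) == 0L) {
    writeLines(sprintf("# no significant segments for %s", snp_id), path)
    return(invisible(path))
  }
  score <- pmin(1000, -log10(segs$min_p))
  score[!is.finite(score)] <- 1000
  gr <- df_to_granges(segs, name = rep(snp_id, nrow(segs)),
                      score = round(score, 2))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || startsWith(first, "#")) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      snp_id = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import.bed(path)
  df <- granges_to_df(gr)
  df$snp_id <- gr$name
  df$score <- gr$score
  df
}
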