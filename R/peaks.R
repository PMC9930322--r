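#' Construct a peak set
#'
#' @param peaks `GRanges` of peaks.
#' @param factor Factor name (e.g. `"GLIS3"`).
#' @param source_library Label of the ChIP library the peaks came from.
#' @return A `peak_set` object.
#' @export
peak_set <- function(peaks, factor, source_library = factor) {
  stopifnot(methods::is(peaks, "GRanges"))
  structure(list(factor = factor, peaks = peaks,
                 source_library = source_library),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set '", x$factor, "': ", length(x$peaks), " peak(s)\n", sep = "")
  invisible(x)
}

# Sliding windows across every chromosome (0-based starts at multiples of
# step_bp, width window_bp, clipped at the chromosome end).
sliding_windows <- function(chrom_sizes, window_bp, step_bp) {
  grs <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    starts <- seq(0, max(0, len - 1), by = step_bp)
    ends <- pmin(starts + window_bp, len)
    keep <- ends > starts
    gr0(chrom, starts[keep], ends[keep])
  })
  suppressWarnings(do.call(c, grs))
}

# Shared window scorer for the factor and histone callers: fold and
# Poisson upper-tail p against the scaled control, BH across all windows.
# The expected count is floored at the genome-wide window rate (and at an
# absolute pseudocount), so zero-count control windows cannot manufacture
# enrichment out of sampling noise.
score_windows <- function(chip, control, chrom_sizes, window_bp, step_bp,
                          min_fold, fdr, pseudocount = 0.5) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (chip$total_count == 0) stop("ChIP library is empty")
  windows <- sliding_windows(chrom_sizes, window_bp, step_bp)
  obs <- count_overlapping(windows, chip)
  # genome-wide expected chip count per window under uniform placement
  lam_global <- chip$total_count *
    pmin(1, (GenomicRanges::width(windows) + chip$fragment_length - 1) /
           genome_size(chrom_sizes))
  if (is.null(control)) {
    expected <- pmax(lam_global, pseudocount)
  } else {
    if (control$total_count == 0) stop("control library is empty")
    ctrl <- count_overlapping(windows, control)
    expected <- pmax(ctrl * (chip$total_count / control$total_count),
                     lam_global, pseudocount)
  }
  p <- poisson_upper_tail(obs, expected)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- (obs / expected >= min_fold) & (padj < fdr)
  list(windows = windows, obs = obs, keep = keep)
}

#' Call factor-style peaks against an input control
#'
#' A simplified sliding-window caller: windows of `window_bp` every
#' `step_bp` are scored against the library-size-scaled control count,
#' floored at a pseudocount of 0.5 and at the genome-wide uniform window
#' rate (so sparse control windows cannot inflate fold estimates); a
#' window is significant when its
#' observed/expected fold is at least `min_fold` and its Poisson upper-tail
#' p-value survives Benjamini-Hochberg correction at `fdr`. Overlapping
#' significant windows are merged and each merged run is reported as one
#' fixed-width peak at its maximum-count window (leftmost on ties).
#'
#' @param chip,control [fragment_set()] libraries; `control = NULL` uses a
#'   uniform pseudo-input.
#' @param chrom_sizes Named chromosome lengths.
#' @param factor Factor name attached to the result.
#' @param window_bp,step_bp Window geometry (defaults 300/75).
#' @param min_fold Minimum observed/expected fold (8 for the stringent
#'   profile, 4 for the permissive one).
#' @param fdr BH-adjusted p-value ceiling (1e-5 stringent, 1e-3 permissive).
#' @return A [peak_set()].
#' @export
call_peaks_factor <- function(chip, control, chrom_sizes, factor = chip$label,
                              window_bp = 300L, step_bp = 75L,
                              min_fold = 8, fdr = 1e-5) {
  sc <- score_windows(chip, control, chrom_sizes, window_bp, step_bp,
                      min_fold, fdr)
  hits <- sc$windows[sc$keep]
  if (length(hits) == 0)
    return(peak_set(GenomicRanges::GRanges(), factor,
                    source_library = chip$label))
  counts <- sc$obs[sc$keep]
  runs <- GenomicRanges::reduce(hits, min.gapwidth = 0L)
  run_of_hit <- GenomicRanges::findOverlaps(hits, runs, select = "first")
  best <- tapply(seq_along(hits), run_of_hit,
                 function(idx) idx[which.max(counts[idx])])
  peaks <- hits[as.integer(best)]
  peaks <- sort_gr(peaks)
  peak_set(peaks, factor, source_library = chip$label)
}

#' Resize peaks to fixed width around their midpoints
#'
#' Each peak becomes `[mid - floor(width/2), mid - floor(width/2) + width)`
#' in 0-based coordinates, where `mid = floor((start + end)/2)`, clipped at
#' chromosome bounds; duplicate resized peaks are removed.
#'
#' @param peaks A [peak_set()] or `GRanges`.
#' @param width Target width (default 300 bp).
#' @param chrom_sizes Named chromosome lengths.
#' @return Same class as `peaks`.
#' @export
resize_peaks <- function(peaks, width = 300L, chrom_sizes) {
  stopifnot(width >= 1)
  gr <- if (methods::is(peaks, "peak_set")) peaks$peaks else peaks
  if (length(gr) == 0) return(peaks)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  clen <- unname(chrom_sizes[chrom])
  m <- mid0(gr)
  s <- m - width %/% 2L
  e <- s + width
  shift_r <- pmax(0, -s)
  s <- s + shift_r; e <- e + shift_r
  shift_l <- pmax(0, e - clen)
  s <- pmax(0, s - shift_l); e <- e - shift_l
  out <- unique(sort_gr(gr0(chrom, s, e)))
  if (methods::is(peaks, "peak_set"))
    peak_set(out, peaks$factor, peaks$source_library)
  else out
}

#' Collapse pooled peak sets into multi-factor regions
#'
#' Pools peaks from all sets and merges intervals that overlap, book-end,
#' or are separated by at most `gap_bp` (the bedtools `merge -d` rule),
#' transitively. The result is sorted, disjoint, and every pairwise gap
#' exceeds `gap_bp`.
#'
#' @param peaksets List of [peak_set()] objects and/or `GRanges`.
#' @param gap_bp Maximum gap merged across (default 50).
#' @return A sorted disjoint `GRanges` of collapsed regions.
#' @export
collapse_peaksets <- function(peaksets, gap_bp = 50L) {
  if (methods::is(peaksets, "GRanges") || methods::is(peaksets, "peak_set"))
    peaksets <- list(peaksets)
  if (length(peaksets) == 0) stop("at least one peak set required")
  grs <- lapply(peaksets, function(p)
    if (methods::is(p, "peak_set")) p$peaks else p)
  pooled <- suppressWarnings(do.call(c, unname(lapply(grs, function(g) {
    S4Vectors::mcols(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  }))))
  if (length(pooled) == 0) return(GenomicRanges::GRanges())
  sort_gr(GenomicRanges::reduce(pooled, min.gapwidth = gap_bp + 1L))
}
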