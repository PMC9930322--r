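#' Call broad histone-mark regions
#'
#' Same window scorer as [call_peaks_factor()] but tuned for broad marks:
#' default minimum fold 2, and significant windows are merged whenever the
#' gap between them is smaller than `min_dist_bp`. Regions keep their
#' merged variable width (no resizing).
#'
#' @param chip,control [fragment_set()] libraries (`control = NULL` for a
#'   uniform pseudo-input).
#' @param chrom_sizes Named chromosome lengths.
#' @param window_bp Scoring window (500 for H3K4me3-like, 1000 for
#'   H3K27me3-like profiles).
#' @param min_dist_bp Merge distance (1000 / 2500 for the two profiles).
#' @param step_bp Window step; defaults to `window_bp / 4`.
#' @param min_fold Minimum fold over control (default 2).
#' @param fdr BH-adjusted p ceiling (default 0.001).
#' @return Sorted disjoint `GRanges` of variable-width regions.
#' @export
call_regions_histone <- function(chip, control, chrom_sizes,
                                 window_bp = 500L, min_dist_bp = 1000L,
                                 step_bp = max(1L, window_bp %/% 4L),
                                 min_fold = 2, fdr = 1e-3) {
  sc <- score_windows(chip, control, chrom_sizes, window_bp, step_bp,
                      min_fold, fdr)
  hits <- sc$windows[sc$keep]
  if (length(hits) == 0) return(GenomicRanges::GRanges())
  # reduce() merges ranges whose gap is < min.gapwidth
  sort_gr(GenomicRanges::reduce(hits, min.gapwidth = min_dist_bp))
}

#' Union of per-sample region sets
#'
#' The unified peak set across samples: plain interval union (overlapping
#' or book-ended intervals merged), sorted and disjoint. Idempotent,
#' commutative, and associative.
#'
#' @param per_sample_regions List of `GRanges`.
#' @return Sorted disjoint `GRanges`.
#' @export
union_region_sets <- function(per_sample_regions) {
  if (methods::is(per_sample_regions, "GRanges"))
    per_sample_regions <- list(per_sample_regions)
  if (length(per_sample_regions) == 0)
    stop("at least one region collection required")
  pooled <- suppressWarnings(do.call(c, unname(lapply(per_sample_regions, function(g) {
    S4Vectors::mcols(g) <- NULL
    GenomicRanges::strand(g) <- "*"
    g
  }))))
  if (length(pooled) == 0) return(GenomicRanges::GRanges())
  sort_gr(GenomicRanges::reduce(pooled, min.gapwidth = 1L))
}

#' TSS flank signal with global-TSS normalization
#'
#' For every gene, counts fragments overlapping the `[tss - flank_bp,
#' tss + flank_bp)` window, then normalizes by the summed flank count over
#' ALL annotated genes (not the subset of interest), scaled per million:
#' `normalized = raw / global_total * 1e6`. Invariant under uniform library
#' scaling.
#'
#' @param frags_by_sample Named list of [fragment_set()] (already extended).
#' @param annotation A [genome_annotation()].
#' @param flank_bp Flank half-width (default 1000).
#' @param genes_of_interest Optional gene ids to report (normalization
#'   still uses all genes).
#' @param mark Mark name recorded in the output (default `""`).
#' @return `data.frame` (`gene_id`, `sample`, `mark`, `raw`, `normalized`).
#' @export
tss_flank_signal <- function(frags_by_sample, annotation, flank_bp = 1000L,
                             genes_of_interest = NULL, mark = "") {
  if (methods::is(frags_by_sample, "fragment_set"))
    frags_by_sample <- stats::setNames(list(frags_by_sample),
                                       frags_by_sample$label)
  genes <- annotation$genes
  if (nrow(genes) == 0) stop("annotation has no genes")
  flanks <- gr0(genes$chrom, pmax(genes$tss - flank_bp, 0),
                genes$tss + flank_bp)
  keep_genes <- genes$gene_id
  if (!is.null(genes_of_interest)) {
    missing <- setdiff(genes_of_interest, genes$gene_id)
    if (length(missing))
      stop("genes of interest absent from annotation: ",
           paste(utils::head(missing, 3), collapse = ", "))
    keep_genes <- genes_of_interest
  }
  out <- lapply(names(frags_by_sample), function(s) {
    raw <- count_overlapping(flanks, frags_by_sample[[s]])
    global_total <- sum(raw)
    if (global_total == 0)
      stop("no fragments overlap any TSS flank for sample ", s)
    idx <- match(keep_genes, genes$gene_id)
    data.frame(gene_id = keep_genes, sample = s, mark = mark,
               raw = raw[idx], normalized = raw[idx] / global_total * 1e6,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tukey box summaries of TSS signal per gene group
#'
#' Quartiles use linear interpolation between closest ranks; whiskers
#' extend to the most extreme value within 1.5 * IQR of the quartiles;
#' values outside the whiskers are outliers.
#'
#' @param table Output of [tss_flank_signal()].
#' @param groups Named list of gene-id vectors.
#' @param value Column to summarize (default `"normalized"`).
#' @return `data.frame` per (group, sample, mark): `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
group_signal_summary <- function(table, groups, value = "normalized") {
  if (length(groups) == 0 || is.null(names(groups)))
    stop("groups must be a non-empty named list")
  combos <- unique(table[, c("sample", "mark")])
  rows <- list()
  for (g in names(groups)) {
    sel_gene <- table$gene_id %in% groups[[g]]
    if (!any(sel_gene))
      stop("group '", g, "' matches no gene in the signal table")
    for (i in seq_len(nrow(combos))) {
      sel <- sel_gene & table$sample == combos$sample[i] &
        table$mark == combos$mark[i]
      v <- table[[value]][sel]
      if (length(v) == 0)
        stop("group '", g, "' matches no gene in the signal table")
      q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
      iqr <- q[3] - q[1]
      lo_lim <- q[1] - 1.5 * iqr
      hi_lim <- q[3] + 1.5 * iqr
      inside <- v[v >= lo_lim & v <= hi_lim]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, sample = combos$sample[i], mark = combos$mark[i],
        n = length(v), median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(inside), whisker_high = max(inside),
        n_outliers = sum(v < lo_lim | v > hi_lim),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
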