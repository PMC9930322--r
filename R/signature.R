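#' Score a region's fragment count against the random-overlap null
#'
#' The null model places each of the library's `N` fragments uniformly on
#' the genome: a fragment of length `f` overlaps a fixed region of length
#' `L` with probability `p = min(1, (L + f - 1) / G)` where `G` is the
#' total genome length, so the null overlap count is Binomial(N, p),
#' evaluated as its Poisson approximation with `lambda = N * p`. The
#' reported p-value is the upper tail `P(X >= count)`; a region is flagged
#' positive when the p-value falls strictly below `cutoff`.
#'
#' @param regions `GRanges` of regions (e.g. collapsed regions).
#' @param frags A [fragment_set()].
#' @param chrom_sizes Named chromosome lengths.
#' @param cutoff Positivity cutoff on the p-value (default 1e-6, strict).
#' @return `data.frame` with one row per region: `count`, `lambda`,
#'   `pvalue`, `positive`.
#' @export
score_region_positivity <- function(regions, frags, chrom_sizes,
                                    cutoff = 1e-6) {
  G <- genome_size(chrom_sizes)
  if (G <= 0) stop("total genome size must be positive")
  if (frags$total_count < 1) stop("fragment library is empty")
  count <- count_overlapping(regions, frags)
  L <- GenomicRanges::width(regions)
  p <- pmin(1, (L + frags$fragment_length - 1) / G)
  lambda <- frags$total_count * p
  pvalue <- poisson_upper_tail(count, lambda)
  data.frame(count = count, lambda = lambda, pvalue = pvalue,
             positive = pvalue < cutoff)
}

#' Build a co-binding signature label from per-factor flags
#'
#' @param flags Named logical vector in display order.
#' @return Canonical label such as `"G+N+P-"`.
#' @export
signature_label <- function(flags) {
  paste0(names(flags), ifelse(flags, "+", "-"), collapse = "")
}

# Parse "G+N+P-" into a named logical vector given the factor order.
parse_signature_label <- function(label, factor_order) {
  expected_n <- sum(nchar(factor_order)) + length(factor_order)
  if (nchar(label) != expected_n)
    stop("signature label '", label, "' does not match factor order ",
         paste(factor_order, collapse = ","))
  flags <- logical(length(factor_order))
  pos <- 1L
  for (i in seq_along(factor_order)) {
    f <- factor_order[i]
    if (substr(label, pos, pos + nchar(f) - 1L) != f)
      stop("signature label '", label, "' does not match factor order")
    sign <- substr(label, pos + nchar(f), pos + nchar(f))
    if (!sign %in% c("+", "-"))
      stop("signature label '", label, "' has invalid flag '", sign, "'")
    flags[i] <- sign == "+"
    pos <- pos + nchar(f) + 1L
  }
  stats::setNames(flags, factor_order)
}

#' Score collapsed regions against every factor library
#'
#' Applies [score_region_positivity()] per factor and attaches per-factor
#' counts, p-values, positivity flags, and the canonical co-binding
#' signature label (factors in `factor_order`) to each region.
#'
#' @param regions `GRanges` of collapsed regions.
#' @param libraries Named list of [fragment_set()] objects, one per factor.
#' @param chrom_sizes Named chromosome lengths.
#' @param cutoff Positivity cutoff (default 1e-6).
#' @param factor_order Factor display order (default `names(libraries)`).
#' @return `regions` with metadata columns `count_<factor>`, `p_<factor>`,
#'   `flag_<factor>` and `signature`.
#' @export
build_signature_matrix <- function(regions, libraries, chrom_sizes,
                                   cutoff = 1e-6,
                                   factor_order = names(libraries)) {
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    stop("libraries must be a named list (factor -> fragment_set)")
  missing <- setdiff(factor_order, names(libraries))
  if (length(missing))
    stop("no library for factor(s): ", paste(missing, collapse = ", "))
  flags <- matrix(FALSE, nrow = length(regions), ncol = length(factor_order),
                  dimnames = list(NULL, factor_order))
  for (f in factor_order) {
    sc <- score_region_positivity(regions, libraries[[f]], chrom_sizes,
                                  cutoff = cutoff)
    S4Vectors::mcols(regions)[[paste0("count_", f)]] <- sc$count
    S4Vectors::mcols(regions)[[paste0("p_", f)]] <- sc$pvalue
    S4Vectors::mcols(regions)[[paste0("flag_", f)]] <- sc$positive
    flags[, f] <- sc$positive
  }
  S4Vectors::mcols(regions)$signature <- if (nrow(flags) == 0) character(0)
    else apply(flags, 1L, function(row)
      signature_label(stats::setNames(row, factor_order)))
  attr(regions, "factor_order") <- factor_order
  regions
}

#' Tabulate signature labels over scored regions
#'
#' @param regions Output of [build_signature_matrix()].
#' @return `data.frame` (`signature`, `n_regions`) sorted by decreasing
#'   count.
#' @export
signature_summary <- function(regions) {
  sig <- S4Vectors::mcols(regions)$signature
  if (is.null(sig)) stop("regions carry no signature column; score them first")
  if (length(sig) == 0)
    return(data.frame(signature = character(0), n_regions = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(sig)
  out <- data.frame(signature = names(tab), n_regions = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_regions, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned fragment-density matrix around anchor midpoints
#'
#' Rows are anchors, columns are `bin_bp` bins spanning the anchor midpoint
#' plus/minus `half_window`; each cell is the fragment overlap count scaled
#' to a library of `scale_to` fragments (signal "normalized to 10 million
#' reads" with the default).
#'
#' @param anchors `GRanges` of anchor regions (midpoints used).
#' @param frags A [fragment_set()].
#' @param half_window Half window in bp (default 1000, i.e. a 2 kb window).
#' @param bin_bp Bin width; must divide `2 * half_window` (default 25).
#' @param scale_to Library size to scale to (default 1e7).
#' @return Numeric matrix, anchors by bins; bin labels are the 0-based
#'   offsets of bin starts from the midpoint.
#' @export
read_density_matrix <- function(anchors, frags, half_window = 1000L,
                                bin_bp = 25L, scale_to = 1e7) {
  if (bin_bp <= 0 || (2L * half_window) %% bin_bp != 0)
    stop("bin_bp must be positive and divide 2 * half_window")
  nbin <- (2L * half_window) %/% bin_bp
  offsets <- seq(-half_window, half_window - bin_bp, by = bin_bp)
  m <- mid0(anchors)
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  bin_start <- rep(m, each = nbin) + rep(offsets, times = length(anchors))
  bin_end <- bin_start + bin_bp
  # bins running off the chromosome start are truncated at 0
  bin_start <- pmax(bin_start, 0)
  bin_end <- pmax(bin_end, bin_start + 1L)
  bins <- gr0(rep(chrom, each = nbin), bin_start, bin_end)
  counts <- count_overlapping(bins, frags)
  mat <- matrix(counts * (scale_to / frags$total_count),
                nrow = length(anchors), ncol = nbin, byrow = TRUE,
                dimnames = list(S4Vectors::mcols(anchors)$name %||% NULL,
                                offsets))
  mat
}
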