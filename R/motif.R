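#' Construct a position weight matrix
#'
#' @param matrix 4 x L numeric matrix of per-position base probabilities,
#'   rows named A, C, G, T; each column must sum to 1 (tolerance 1e-9).
#'   Counts are accepted and normalized with `pseudocount`.
#' @param name Motif name.
#' @param background Named base frequencies (default uniform 0.25).
#' @param threshold_frac Score threshold as a fraction of the maximal
#'   log-odds score (default 0.8); overridden by `score_threshold`.
#' @param score_threshold Absolute log2-odds threshold in bits (optional).
#' @param pseudocount Added per cell when normalizing count input.
#' @return A `pwm` object with fields `name`, `matrix`, `background`,
#'   `score_threshold`, `max_score`.
#' @export
pwm <- function(matrix, name = "motif",
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                threshold_frac = 0.8, score_threshold = NULL,
                pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stop("PWM must have length >= 4")
  if (is.null(rownames(matrix))) rownames(matrix) <- bases
  matrix <- matrix[bases, , drop = FALSE]
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-9)) {
    # treat as counts
    matrix <- sweep(matrix + pseudocount, 2, cs + 4 * pseudocount, "/")
  }
  background <- background[bases]
  if (any(background <= 0) && any(matrix[background <= 0, ] > 0))
    stop("zero background frequency with nonzero matrix probability")
  lodds <- log2(matrix / background)
  max_score <- sum(apply(lodds, 2, max))
  if (is.null(score_threshold)) score_threshold <- threshold_frac * max_score
  structure(list(name = name, matrix = matrix, background = background,
                 lodds = lodds, score_threshold = score_threshold,
                 max_score = max_score),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "': length ", ncol(x$matrix), ", max score ",
      round(x$max_score, 2), " bits, threshold ",
      round(x$score_threshold, 2), "\n", sep = "")
  invisible(x)
}

#' Read JASPAR-style PWMs
#'
#' Accepts the JASPAR text layout: a `>name` header followed by four lines
#' `A [ counts... ]` (brackets optional). Count matrices are normalized to
#' probabilities.
#'
#' @param path PWM text file (may contain several motifs).
#' @inheritParams pwm
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        threshold_frac = 0.8) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' header in PWM file")
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) stop("PWM block with fewer than 4 base rows")
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- if (length(nm) > 1) nm[2] else nm[1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("\\[|\\]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      list(base = toupper(parts[1]), vals = as.numeric(parts[-1]))
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- vapply(rows, `[[`, "", "base")
    out[[nm]] <- pwm(mat, name = nm, background = background,
                     threshold_frac = threshold_frac)
  }
  out
}

base_code <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  x  # NA for N and anything else
}

# Parse "chrom:start-end" genomic offsets from sequence names.
parse_seq_offset <- function(nm) {
  m <- regmatches(nm, regexec("^(\\S+):(\\d+)-(\\d+)$", nm))[[1]]
  if (length(m) == 4)
    list(chrom = m[2], offset = as.numeric(m[3]))
  else
    list(chrom = nm, offset = 0)
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every window on both strands as the summed log2-odds of the
#' observed bases against the background; windows containing N are
#' skipped. Hits at or above the motif's score threshold are reported with
#' genomic coordinates when sequence names look like `chrom:start-end`
#' (0-based half-open), else sequence-local coordinates.
#'
#' @param sequences Named character vector, or a `Biostrings::DNAStringSet`
#'   (e.g. from `Biostrings::readDNAStringSet()`).
#' @param motif A [pwm()].
#' @return `GRanges` of hits with metadata `motif`, `score`, and strand of
#'   the match; opposite-strand hits at the same position are both kept.
#' @export
scan_pwm <- function(sequences, motif) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  L <- ncol(motif$matrix)
  lod <- motif$lodds
  # log-odds of the reverse complement motif in forward-strand coordinates
  lod_rc <- lod[4:1, rev(seq_len(L)), drop = FALSE]
  hits <- list()
  for (nm in names(sequences)) {
    code <- base_code(sequences[[nm]])
    n <- length(code)
    if (n < L) next
    npos <- n - L + 1L
    score_f <- numeric(npos); score_r <- numeric(npos)
    for (j in seq_len(L)) {
      b <- code[j:(npos + j - 1L)]
      score_f <- score_f + lod[cbind(b, j)]
      score_r <- score_r + lod_rc[cbind(b, j)]
    }
    off <- parse_seq_offset(nm)
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") score_f else score_r
      # NA propagates from windows containing N: hard misses
      at <- which(!is.na(sc) & sc >= motif$score_threshold)
      if (length(at)) {
        g <- gr0(off$chrom, off$offset + at - 1, off$offset + at - 1 + L,
                 strand)
        S4Vectors::mcols(g)$motif <- motif$name
        S4Vectors::mcols(g)$score <- sc[at]
        hits[[length(hits) + 1L]] <- g
      }
    }
  }
  if (length(hits) == 0) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$motif <- character(0)
    S4Vectors::mcols(g)$score <- numeric(0)
    return(g)
  }
  do.call(c, hits)
}

#' Motif enrichment near anchors versus background regions
#'
#' An anchor (or background region) contains a motif when a hit midpoint
#' lies within `window_bp` of the region midpoint. Per motif, the upper-
#' tail hypergeometric p-value tests whether hit-containing regions
#' concentrate among the anchors given the pooled margin; BH across motifs.
#'
#' @param anchors,background `GRanges` region sets (warned if overlapping).
#' @param hits Motif hits from [scan_pwm()] (several motifs allowed).
#' @param window_bp Containment window around region midpoints (default 100).
#' @return `data.frame` per motif: `motif`, `n_anchor_hit`, `n_anchor`,
#'   `n_background_hit`, `n_background`, `pvalue`, `padj`.
#' @export
motif_enrichment_near_anchors <- function(anchors, background, hits,
                                          window_bp = 100L) {
  if (length(background) == 0) stop("empty background region set")
  if (length(GenomicRanges::findOverlaps(anchors, background)) > 0)
    warning("anchors and background regions overlap")
  contains <- function(regions, h) {
    if (length(h) == 0) return(rep(FALSE, length(regions)))
    rm0 <- mid0(regions)
    win <- gr0(as.character(GenomeInfoDb::seqnames(regions)),
               pmax(rm0 - window_bp, 0), rm0 + window_bp + 1L)
    suppressWarnings(GenomicRanges::countOverlaps(win, midpoint_gr(h),
                                                  ignore.strand = TRUE)) > 0
  }
  motifs <- unique(S4Vectors::mcols(hits)$motif)
  if (length(motifs) == 0)
    return(data.frame(motif = character(0), n_anchor_hit = integer(0),
                      n_anchor = integer(0), n_background_hit = integer(0),
                      n_background = integer(0), pvalue = numeric(0),
                      padj = numeric(0)))
  rows <- lapply(motifs, function(mo) {
    h <- hits[S4Vectors::mcols(hits)$motif == mo]
    a <- sum(contains(anchors, h))
    b <- sum(contains(background, h))
    p <- hyper_upper_tail(a, a + b,
                          length(anchors) + length(background) - a - b,
                          length(anchors))
    data.frame(motif = mo, n_anchor_hit = a, n_anchor = length(anchors),
               n_background_hit = b, n_background = length(background),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out
}

#' Histogram of signed motif-to-anchor distances
#'
#' Signed distance from anchor midpoint to hit midpoint (positive when the
#' hit lies 3'-ward on the reference), binned at `bin_bp` over plus/minus
#' `max_dist`.
#'
#' @param anchors `GRanges` anchors.
#' @param hits Motif hits from [scan_pwm()].
#' @param max_dist Maximum absolute distance (default 500).
#' @param bin_bp Bin width (default 10).
#' @return `data.frame` (`bin_start`, `bin_end`, `count`); empty when no
#'   pair is within range.
#' @export
spacing_profile <- function(anchors, hits, max_dist = 500L, bin_bp = 10L) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  breaks <- seq(-max_dist, max_dist, by = bin_bp)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  if (length(anchors) == 0 || length(hits) == 0)
    return(data.frame(bin_start = breaks[-length(breaks)],
                      bin_end = breaks[-1],
                      count = integer(length(breaks) - 1L)))
  am <- mid0(anchors)
  win <- gr0(as.character(GenomeInfoDb::seqnames(anchors)),
             pmax(am - max_dist, 0), am + max_dist + 1L)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(midpoint_gr(hits), win,
                                                     ignore.strand = TRUE))
  d <- mid0(hits)[S4Vectors::queryHits(ov)] - am[S4Vectors::subjectHits(ov)]
  d <- d[abs(d) <= max_dist]
  idx <- findInterval(d, breaks)
  idx[idx == length(breaks)] <- length(breaks) - 1L  # right edge closed
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             count = tabulate(idx, nbins = length(breaks) - 1L))
}
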