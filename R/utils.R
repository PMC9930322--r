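# Internal helpers shared across modules.

# 0-based <-> GRanges (1-based closed) conversion. All spec-facing
# arithmetic (BED I/O, midpoints, windows) is done in 0-based half-open
# coordinates; these keep the conversion in one place.

gr0 <- function(chrom, start0, end0, strand = "*") {
  stopifnot(all(end0 > start0), all(start0 >= 0))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand)
}

start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0   <- function(gr) GenomicRanges::end(gr)

# Midpoint in 0-based coordinates: floor((start0 + end0) / 2).
mid0 <- function(gr) (start0(gr) + end0(gr)) %/% 2L

# A point interval [m, m+1) at each 0-based midpoint.
midpoint_gr <- function(gr) gr0(as.character(GenomeInfoDb::seqnames(gr)), mid0(gr), mid0(gr) + 1L)

# Sort with deterministic (natural) chromosome order regardless of the
# order chromosomes first appeared in.
sort_gr <- function(gr) GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))

# Upper-tail Poisson probability P(X >= count | lambda), computed via the
# survival function in log-capable form; exact for count = 0.
poisson_upper_tail <- function(count, lambda) {
  ifelse(count <= 0, 1, stats::ppois(count - 1, lambda, lower.tail = FALSE))
}

# Upper-tail hypergeometric P(X >= q) of drawing q marked items.
hyper_upper_tail <- function(q, n_marked, n_unmarked, n_drawn) {
  ifelse(q <= 0, 1,
         stats::phyper(q - 1, n_marked, n_unmarked, n_drawn, lower.tail = FALSE))
}

check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  invisible(chrom_sizes)
}

genome_size <- function(chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  sum(as.numeric(chrom_sizes))
}

# Deterministic per-stage RNG streams derived from a master seed; offsets
# keep derived seeds well below 2^31.
stage_seed <- function(seed, stage, k = 0L) {
  offs <- c(annotation = 11L, sites = 23L, fragments = 37L, expression = 53L,
            sequence = 71L, generic = 97L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(seed) + offs[[stage]] * (1L + as.integer(k))) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
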