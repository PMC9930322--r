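# Independent oracles and tiny fixture builders used across tests.

# Upper-tail Poisson probability by direct pmf summation over the upper
# side (no survival-function call).
poisson_tail_oracle <- function(count, lambda) {
  if (count <= 0) return(1)
  hi <- max(count + 200, ceiling(lambda + 60 * sqrt(lambda + 1)))
  sum(stats::dpois(count:hi, lambda))
}

# Upper-tail hypergeometric by pmf summation.
hyper_tail_oracle <- function(q, m, n, k) {
  if (q <= 0) return(1)
  sum(stats::dhyper(q:min(k, m), m, n, k))
}

# Fixed-point interval merger (0-based half-open chrom/start/end):
# repeated passes over the sorted intervals, merging any adjacent pair with
# gap <= gap_bp, until a pass makes no change.
brute_merge_oracle <- function(df, gap_bp) {
  chrom <- as.character(df$chrom); s <- df$start; e <- df$end
  repeat {
    o <- order(chrom, s, e)
    chrom <- chrom[o]; s <- s[o]; e <- e[o]
    n <- length(s)
    keep_c <- character(n); keep_s <- numeric(n); keep_e <- numeric(n)
    k <- 0L; merged <- FALSE
    for (i in seq_len(n)) {
      if (k > 0L && chrom[i] == keep_c[k] && s[i] - keep_e[k] <= gap_bp) {
        keep_e[k] <- max(keep_e[k], e[i])
        merged <- TRUE
      } else {
        k <- k + 1L
        keep_c[k] <- chrom[i]; keep_s[k] <- s[i]; keep_e[k] <- e[i]
      }
    }
    chrom <- keep_c[seq_len(k)]; s <- keep_s[seq_len(k)]; e <- keep_e[seq_len(k)]
    if (!merged) break
  }
  data.frame(chrom = chrom, start = s, end = e, stringsAsFactors = FALSE)
}

# Pairwise overlap counter (0-based half-open).
brute_count_oracle <- function(qs, qe, fs, fe) {
  vapply(seq_along(qs), function(i) sum(fs < qe[i] & fe > qs[i]), 0L)
}

# Tukey summary from first principles: manual type-7 quantiles on the
# sorted vector, 1.5*IQR whiskers.
tukey_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  qq <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    if (lo >= n) return(v[n])
    v[lo] + (h - floor(h)) * (v[lo + 1] - v[lo])
  }
  q1 <- qq(0.25); q3 <- qq(0.75); iqr <- q3 - q1
  inside <- v[v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr]
  list(median = qq(0.5), q1 = q1, q3 = q3,
       whisker_low = min(inside), whisker_high = max(inside),
       n_outliers = n - length(inside))
}

# GRanges from 0-based half-open vectors.
make_gr <- function(chrom, start0, end0, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}

# Fragment set from 0-based fragment coordinates (already "extended").
make_frags <- function(chrom, start0, end0, label = "lib", fraglen = 150L) {
  fragment_set(make_gr(chrom, start0, end0), label = label,
               fragment_length = fraglen)
}

# Uniform random fragment library of n fragments of length fl on a genome.
random_frags <- function(n, chrom_sizes, fl = 150L, seed = 1) {
  set.seed(seed)
  ci <- sample.int(length(chrom_sizes), n, replace = TRUE,
                   prob = chrom_sizes / sum(chrom_sizes))
  chrom <- names(chrom_sizes)[ci]
  s <- floor(runif(n, 0, chrom_sizes[ci] - fl))
  make_frags(chrom, s, s + fl, fraglen = fl)
}

# Two-gene annotation used by context/assignment tests.
toy_annotation <- function() {
  genome_annotation(
    c(chr1 = 100000, chr2 = 50000),
    data.frame(gene_id = c("gplus", "gminus"),
               chrom = c("chr1", "chr1"),
               strand = c("+", "-"),
               tss = c(10000, 20000) + c(0, 60000),
               tes = c(20000, 10000) + c(0, 60000)))
}

# Small fast simulation profile for pipeline-level tests; any argument
# can be overridden through ...
small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chroms = 1, chrom_length_bp = 1e6,
               n_genes = 40, site_offset_bp = 1000,
               n_fragments_per_library = 2e4, input_library_size = 2e4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}
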