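#' Read a BED3/BED6 file of genomic intervals
#'
#' Coordinates in the file are 0-based half-open (BED convention) and are
#' converted to a 1-based closed `GRanges`. Strand is taken from column 6
#' when present, otherwise all intervals are unstranded (`*`).
#'
#' @param path Path to a tab-separated BED file (no header).
#' @return A `GRanges` in file order; column 4, when present, is kept as
#'   metadata column `name`, column 5 as `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop("invalid interval at BED line ", bad[1], ": end <= start or start < 0")
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  if (any(has6)) {
    st <- vapply(fields[has6], `[[`, "", 6L)
    if (any(!st %in% c("+", "-", ".")))
      stop("unknown strand symbol in BED column 6: ", st[!st %in% c("+", "-", ".")][1])
    strand[has6] <- ifelse(st == ".", "*", st)
  }
  gr <- gr0(chrom, s, e, strand)
  if (any(nf >= 4))
    S4Vectors::mcols(gr)$name <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", ""), ".")
  if (any(nf >= 5))
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(
      ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "0", ""), "0")))
  gr
}

#' Write genomic intervals to a BED file
#'
#' Written 0-based half-open; round-trips through [read_bed()] exactly.
#' A `name` metadata column becomes BED column 4; intervals with strand
#' are written as BED6 with score 0 (or the `score` column when present).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  st <- as.character(GenomicRanges::strand(gr))
  nm <- S4Vectors::mcols(gr)$name
  sc <- S4Vectors::mcols(gr)$score
  need6 <- any(st != "*") || !is.null(nm) || !is.null(sc)
  if (need6) {
    lines <- paste(chrom, format(start0(gr), scientific = FALSE, trim = TRUE),
                   format(end0(gr), scientific = FALSE, trim = TRUE),
                   nm %||% rep(".", length(gr)),
                   sc %||% rep(0, length(gr)),
                   ifelse(st == "*", ".", st), sep = "\t")
  } else {
    lines <- paste(chrom, format(start0(gr), scientific = FALSE, trim = TRUE),
                   format(end0(gr), scientific = FALSE, trim = TRUE), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a genome annotation
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `tes` (0-based). The TSS is the 5' end in the
#'   direction of transcription, so `tss < tes` on `+` and `tss > tes`
#'   on `-`.
#' @return A `genome_annotation` object (list with `chrom_sizes`, `genes`).
#' @export
genome_annotation <- function(chrom_sizes, genes) {
  check_chrom_sizes(chrom_sizes)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(genes)))
    stop("genes must have columns: ", paste(need, collapse = ", "))
  if (nrow(genes)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup))
      stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
    if (any(!genes$strand %in% c("+", "-")))
      stop("unknown strand symbol in gene annotation")
    if (any(genes$tss == genes$tes)) stop("gene with tss == tes")
    bad <- (genes$strand == "+" & genes$tss >= genes$tes) |
           (genes$strand == "-" & genes$tss <= genes$tes)
    if (any(bad))
      stop("tss/tes inconsistent with strand for: ",
           paste(genes$gene_id[bad], collapse = ", "))
    if (any(!genes$chrom %in% names(chrom_sizes)))
      stop("gene on unknown chromosome")
    hi <- pmax(genes$tss, genes$tes)
    if (any(hi > chrom_sizes[genes$chrom]))
      stop("gene outside chromosome bounds: ",
           paste(genes$gene_id[hi > chrom_sizes[genes$chrom]], collapse = ", "))
  }
  structure(list(chrom_sizes = chrom_sizes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_sizes), "chromosome(s),",
      format(genome_size(x$chrom_sizes), big.mark = ","), "bp,",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Read a gene annotation from refFlat-like TSV or GTF
#'
#' For `refflat_tsv` the file has columns `gene_id`, `chrom`, `strand`,
#' `txStart`, `txEnd` (0-based half-open, with or without a header). TSS and
#' TES are derived strand-aware: on `+`, tss = txStart and tes = txEnd; on
#' `-`, tss = txEnd and tes = txStart. For `gtf`, gene-level records
#' (1-based closed, converted on read) with a `gene_id` attribute are used.
#'
#' @param path Annotation file.
#' @param format `"refflat_tsv"` or `"gtf"`.
#' @param chrom_sizes_path Optional companion UCSC chrom.sizes file
#'   (two-column TSV); when absent, sizes are inferred as the maximum gene
#'   coordinate per chromosome.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("refflat_tsv", "gtf"),
                            chrom_sizes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "refflat_tsv") {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "chrom", "strand", "txStart", "txEnd") %in% names(tab))) {
      tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(tab) < 5) stop("refflat_tsv needs 5 columns")
      names(tab)[1:5] <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
    }
    txs <- as.numeric(tab$txStart); txe <- as.numeric(tab$txEnd)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9)) stop("malformed GTF line")
    keep <- vapply(f, `[[`, "", 3L) == "gene"
    f <- f[keep]
    if (!length(f)) stop("no gene-level records in GTF")
    gid <- vapply(f, function(x) {
      m <- regmatches(x[[9]], regexec('gene_id "([^"]+)"', x[[9]]))[[1]]
      if (length(m) < 2) stop("GTF gene record without gene_id attribute")
      m[[2]]
    }, "")
    tab <- data.frame(gene_id = gid,
                      chrom = vapply(f, `[[`, "", 1L),
                      strand = vapply(f, `[[`, "", 7L),
                      stringsAsFactors = FALSE)
    # GTF is 1-based closed: convert to 0-based half-open.
    txs <- as.numeric(vapply(f, `[[`, "", 4L)) - 1
    txe <- as.numeric(vapply(f, `[[`, "", 5L))
  }
  if (any(!tab$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(tab$strand[!tab$strand %in% c("+", "-")]), collapse = ", "))
  genes <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                      strand = tab$strand,
                      tss = ifelse(tab$strand == "+", txs, txe),
                      tes = ifelse(tab$strand == "+", txe, txs),
                      stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes_path)) {
    cs <- utils::read.delim(chrom_sizes_path, header = FALSE,
                            stringsAsFactors = FALSE)
    chrom_sizes <- stats::setNames(as.numeric(cs[[2]]), cs[[1]])
  } else {
    chrom_sizes <- tapply(pmax(txs, txe), tab$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
    message("chrom_sizes inferred from maximum gene coordinates; ",
            "supply a chrom.sizes file for exact genome size")
  }
  genome_annotation(chrom_sizes, genes)
}

#' Construct a fragment set
#'
#' A labelled library of extended sequencing fragments, the unit of all
#' count-based statistics.
#'
#' @param fragments `GRanges` of fragments.
#' @param label Library name (e.g. `"GLIS3-ChIP"`, `"input"`).
#' @param fragment_length Nominal extended fragment length (bp).
#' @return A `fragment_set` object.
#' @export
fragment_set <- function(fragments, label = "library", fragment_length = 150L) {
  stopifnot(methods::is(fragments, "GRanges"))
  structure(list(label = label, fragments = fragments,
                 total_count = length(fragments),
                 fragment_length = as.integer(fragment_length)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set '", x$label, "': ", format(x$total_count, big.mark = ","),
      " fragments of ", x$fragment_length, " bp\n", sep = "")
  invisible(x)
}

#' Extend reads to fixed-length fragments
#'
#' Each read is replaced by the interval of exactly `length` bp starting at
#' its 5' end and extending in strand direction (the standard ChIP-seq
#' fragment-length extension), clipped to chromosome bounds. Unstranded
#' reads are treated as `+` and counted in a warning.
#'
#' @param reads `GRanges` of mapped reads.
#' @param length Fragment length in bp (default 150).
#' @param chrom_sizes Named chromosome lengths.
#' @param label Library label for the resulting [fragment_set()].
#' @return A [fragment_set()] with `total_count == length(reads)`.
#' @export
extend_fragments <- function(reads, length = 150L, chrom_sizes,
                             label = "library") {
  stopifnot(length >= 1)
  check_chrom_sizes(chrom_sizes)
  chrom <- as.character(GenomeInfoDb::seqnames(reads))
  if (any(!chrom %in% names(chrom_sizes)))
    stop("read on chromosome absent from chrom_sizes: ",
         unique(chrom[!chrom %in% names(chrom_sizes)])[1])
  clen <- unname(chrom_sizes[chrom])
  s0 <- start0(reads); e0 <- end0(reads)
  if (any(s0 >= clen | e0 <= 0))
    stop("read entirely outside chromosome bounds")
  st <- as.character(GenomicRanges::strand(reads))
  n_unstranded <- sum(st == "*")
  if (n_unstranded > 0)
    warning(n_unstranded, " unstranded read(s) treated as + strand")
  plus <- st != "-"
  # 5' end: start for +, last base (end0 - 1) for -.
  new_s <- ifelse(plus, s0, e0 - length)
  new_e <- ifelse(plus, s0 + length, e0)
  new_s <- pmax(new_s, 0)
  new_e <- pmin(new_e, clen)
  gr <- gr0(chrom, new_s, new_e, ifelse(plus, "+", "-"))
  fragment_set(gr, label = label, fragment_length = length)
}

#' Count fragments overlapping a query
#'
#' Number of fragments sharing at least one base with each query interval
#' (strand-blind), via the interval index.
#'
#' @param query `GRanges` of query regions.
#' @param frags A [fragment_set()] or `GRanges`.
#' @return Integer vector, one count per query.
#' @export
count_overlapping <- function(query, frags) {
  gr <- if (methods::is(frags, "fragment_set")) frags$fragments else frags
  if (length(gr) == 0) return(integer(length(query)))
  GenomicRanges::countOverlaps(query, gr, ignore.strand = TRUE)
}
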