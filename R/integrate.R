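#' Classify peaks by genomic context
#'
#' Classifies each peak's 0-based midpoint against all genes with
#' precedence TSS_proximal > Upstream > Genebody > Intergenic. Windows are
#' strand-aware (0-based, half-open):
#' \itemize{
#'   \item TSS_proximal: the 1 kb immediately upstream of the TSS
#'     (`[tss-1000, tss)` on `+`; `[tss, tss+1000)` on `-`);
#'   \item Upstream: 5 kb to 1 kb upstream of the TSS;
#'   \item Genebody: the transcript span TSS..TES;
#'   \item Intergenic: everything else.
#' }
#' The assigned gene is the one justifying the winning category; ties are
#' broken by nearest TSS, then lexicographic gene id.
#'
#' @param peaks `GRanges` of peaks (or regions).
#' @param annotation A [genome_annotation()].
#' @param proximal_bp,upstream_bp Window extents (defaults 1000 and 5000).
#' @return `data.frame` with one row per peak: `category` (factor with
#'   levels TSS_proximal, Upstream, Genebody, Intergenic) and `gene_id`
#'   (`NA` for Intergenic).
#' @export
classify_genomic_context <- function(peaks, annotation,
                                     proximal_bp = 1000L, upstream_bp = 5000L) {
  genes <- annotation$genes
  m <- mid0(peaks)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  lv <- c("TSS_proximal", "Upstream", "Genebody", "Intergenic")
  n <- length(peaks)
  category <- rep("Intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (nrow(genes) > 0 && n > 0) {
    plus <- genes$strand == "+"
    win <- function(s0, e0) {
      s0 <- pmax(s0, 0)
      keep <- e0 > s0
      g <- gr0(genes$chrom[keep], s0[keep], e0[keep])
      S4Vectors::mcols(g)$gene <- which(keep)
      g
    }
    windows <- list(
      TSS_proximal = win(ifelse(plus, genes$tss - proximal_bp, genes$tss),
                         ifelse(plus, genes$tss, genes$tss + proximal_bp)),
      Upstream = win(ifelse(plus, genes$tss - upstream_bp, genes$tss + proximal_bp),
                     ifelse(plus, genes$tss - proximal_bp, genes$tss + upstream_bp)),
      Genebody = win(pmin(genes$tss, genes$tes), pmax(genes$tss, genes$tes)))
    pts <- gr0(chrom, m, m + 1L)
    unassigned <- rep(TRUE, n)
    for (cat_name in names(windows)) {
      w <- windows[[cat_name]]
      ov <- suppressWarnings(GenomicRanges::findOverlaps(pts, w))
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      sel <- unassigned[qh]
      qh <- qh[sel]; sh <- sh[sel]
      if (length(qh)) {
        gidx <- S4Vectors::mcols(w)$gene[sh]
        d <- abs(m[qh] - genes$tss[gidx])
        ord <- order(qh, d, genes$gene_id[gidx])
        first <- ord[!duplicated(qh[ord])]
        category[qh[first]] <- cat_name
        gene_id[qh[first]] <- genes$gene_id[gidx[first]]
        unassigned[qh[first]] <- FALSE
      }
    }
  }
  data.frame(category = factor(category, levels = lv), gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Summarize genomic-context categories
#'
#' @param peaks `GRanges` (or [peak_set()]).
#' @param annotation A [genome_annotation()].
#' @return `data.frame` (`category`, `count`, `fraction`); counts sum to
#'   the number of peaks, fractions to 1.
#' @export
summarize_contexts <- function(peaks, annotation) {
  gr <- if (methods::is(peaks, "peak_set")) peaks$peaks else peaks
  ctx <- classify_genomic_context(gr, annotation)
  tab <- table(ctx$category)
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = if (length(gr)) as.integer(tab) / length(gr) else rep(0, 4),
             stringsAsFactors = FALSE)
}

#' Assign scored regions to genes within a TSS window
#'
#' A region is linked to a gene when the region midpoint lies within
#' `window_bp` of the gene TSS (inclusive at both ends, strand-agnostic:
#' "5 kb up- or downstream"). Per-gene factor flags use union semantics: a
#' gene is positive for a factor when at least one linked region is
#' positive for that factor. Genes with no linked region are omitted.
#'
#' @param regions Scored regions from [build_signature_matrix()].
#' @param annotation A [genome_annotation()].
#' @param window_bp TSS window half-width (default 5000).
#' @param factor_order Factor display order; defaults to the order stored
#'   on `regions`.
#' @return `data.frame`, one row per bound gene: `gene_id`, one logical
#'   `flag_<factor>` column per factor, `signature`, and
#'   `supporting_regions` (comma-separated `chrom:start-end` ids, 0-based).
#' @export
assign_regions_to_genes <- function(regions, annotation, window_bp = 5000L,
                                    factor_order = attr(regions, "factor_order")) {
  if (is.null(factor_order))
    stop("factor_order not given and not stored on regions")
  flag_cols <- paste0("flag_", factor_order)
  if (!all(flag_cols %in% names(S4Vectors::mcols(regions))))
    stop("regions are not scored; run build_signature_matrix() first")
  genes <- annotation$genes
  empty <- data.frame(gene_id = character(0), stringsAsFactors = FALSE)
  for (fc in flag_cols) empty[[fc]] <- logical(0)
  empty$signature <- character(0)
  empty$supporting_regions <- character(0)
  if (nrow(genes) == 0 || length(regions) == 0) return(empty)
  m <- mid0(regions)
  rchrom <- as.character(GenomeInfoDb::seqnames(regions))
  region_id <- paste0(rchrom, ":", start0(regions), "-", end0(regions))
  tss_win <- gr0(genes$chrom, pmax(genes$tss - window_bp, 0),
                 genes$tss + window_bp + 1L)  # inclusive both ends
  pts <- gr0(rchrom, m, m + 1L)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pts, tss_win))
  if (length(ov) == 0) return(empty)
  ridx <- S4Vectors::queryHits(ov); gidx <- S4Vectors::subjectHits(ov)
  flags <- as.matrix(as.data.frame(S4Vectors::mcols(regions)[flag_cols]))
  ord <- order(gidx, ridx)
  ridx <- ridx[ord]; gidx <- gidx[ord]
  split_r <- split(ridx, gidx)
  gene_rows <- as.integer(names(split_r))
  out <- data.frame(gene_id = genes$gene_id[gene_rows],
                    stringsAsFactors = FALSE)
  for (j in seq_along(factor_order))
    out[[flag_cols[j]]] <- vapply(split_r, function(r) any(flags[r, j]), TRUE)
  out$signature <- vapply(seq_len(nrow(out)), function(i)
    signature_label(stats::setNames(
      as.logical(out[i, flag_cols]), factor_order)), "")
  out$supporting_regions <- vapply(split_r, function(r)
    paste(region_id[r], collapse = ","), "")
  rownames(out) <- NULL
  attr(out, "factor_order") <- factor_order
  out
}

#' Tabulate gene-level co-binding signatures
#'
#' Counts genes per signature label, plus per-factor totals (genes bound by
#' that factor under any signature) and, for every signature, its
#' percentage within each factor's bound genes (1-decimal rounding).
#'
#' @param records Gene records from [assign_regions_to_genes()], or a
#'   `data.frame` with columns `signature` and `n` giving pre-tabulated
#'   label counts.
#' @param factor_order Factor display order.
#' @return List with `counts` (`signature`, `n_genes`), `factor_totals`
#'   (named vector), and `percent_of_factor` (matrix signature x factor,
#'   NA where the factor is negative in that signature).
#' @export
tabulate_gene_signatures <- function(records, factor_order = attr(records, "factor_order")) {
  if (is.null(factor_order)) stop("factor_order required")
  if (all(c("signature", "n") %in% names(records)) && !"gene_id" %in% names(records)) {
    counts <- data.frame(signature = records$signature,
                         n_genes = as.integer(records$n),
                         stringsAsFactors = FALSE)
  } else {
    tab <- table(records$signature)
    counts <- data.frame(signature = names(tab), n_genes = as.integer(tab),
                         stringsAsFactors = FALSE)
  }
  counts <- counts[order(-counts$n_genes, counts$signature), , drop = FALSE]
  rownames(counts) <- NULL
  flag_mat <- t(vapply(counts$signature, parse_signature_label,
                       logical(length(factor_order)), factor_order = factor_order))
  colnames(flag_mat) <- factor_order
  factor_totals <- stats::setNames(
    as.integer(colSums(flag_mat * counts$n_genes)), factor_order)
  pct <- matrix(NA_real_, nrow = nrow(counts), ncol = length(factor_order),
                dimnames = list(counts$signature, factor_order))
  for (f in factor_order) {
    pos <- flag_mat[, f]
    if (factor_totals[[f]] > 0)
      pct[pos, f] <- round(counts$n_genes[pos] / factor_totals[[f]] * 100, 1)
  }
  list(counts = counts, factor_totals = factor_totals,
       percent_of_factor = pct)
}

#' Threshold a differential-expression table
#'
#' Fold changes are signed linear folds (magnitude at least 1; the sign is
#' the direction), or log2 fold changes converted on read with
#' `log2_input = TRUE`. A gene is `up` when `FC >= fc_min` with
#' `fdr < fdr_max` (inclusive fold boundary, strict FDR), `down` when
#' `FC <= -fc_min` with `fdr < fdr_max`, otherwise `NS`.
#'
#' @param de_table `data.frame` with columns `gene`, `fc`, `fdr` (or a TSV
#'   path with that header).
#' @param fc_min Minimum linear fold (default 1.5).
#' @param fdr_max FDR ceiling, strict (default 0.05).
#' @param log2_input `fc` column is log2 fold change.
#' @return `data.frame` (`gene_id`, `fold_change`, `fdr`, `status`) with
#'   `status` in up/down/NS.
#' @export
filter_de_genes <- function(de_table, fc_min = 1.5, fdr_max = 0.05,
                            log2_input = FALSE) {
  if (is.character(de_table) && length(de_table) == 1)
    de_table <- utils::read.delim(de_table, stringsAsFactors = FALSE)
  need <- c("gene", "fc", "fdr")
  if (!all(need %in% names(de_table)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  fc <- as.numeric(de_table$fc)
  if (log2_input) {
    fc <- ifelse(fc >= 0, 2^fc, -(2^(-fc)))
  } else if (any(abs(fc) < 1, na.rm = TRUE)) {
    stop("signed linear fold changes must have magnitude >= 1 ",
         "(use log2_input = TRUE for log2 values)")
  }
  fdr <- as.numeric(de_table$fdr)
  status <- ifelse(fc >= fc_min & fdr < fdr_max, "up",
            ifelse(fc <= -fc_min & fdr < fdr_max, "down", "NS"))
  data.frame(gene_id = as.character(de_table$gene), fold_change = fc,
             fdr = fdr, status = status, stringsAsFactors = FALSE)
}

#' Cross-tabulate a co-binding signature against expression calls
#'
#' Restricts gene records to one signature label and partitions those genes
#' into up / down / NS per contrast (genes absent from a contrast's call
#' table count as NS).
#'
#' @param records Gene records from [assign_regions_to_genes()].
#' @param calls_by_contrast Named list of [filter_de_genes()] outputs.
#' @param signature_filter Signature label, e.g. `"G+N+P+"`.
#' @param factor_order Factor display order (validates the label).
#' @return List with `counts` (`data.frame`: contrast, up, down, NS) and
#'   `genes` (named list of per-contrast lists `up`/`down`/`ns`).
#' @export
crosstab_binding_expression <- function(records, calls_by_contrast,
                                        signature_filter,
                                        factor_order = attr(records, "factor_order")) {
  if (!is.null(factor_order))
    parse_signature_label(signature_filter, factor_order)  # validates label
  sel <- records$gene_id[records$signature == signature_filter]
  counts <- data.frame(contrast = names(calls_by_contrast),
                       up = 0L, down = 0L, NS = 0L, stringsAsFactors = FALSE)
  genes <- list()
  for (i in seq_along(calls_by_contrast)) {
    calls <- calls_by_contrast[[i]]
    st <- calls$status[match(sel, calls$gene_id)]
    st[is.na(st)] <- "NS"
    counts$up[i] <- sum(st == "up")
    counts$down[i] <- sum(st == "down")
    counts$NS[i] <- sum(st == "NS")
    genes[[names(calls_by_contrast)[i]]] <-
      list(up = sel[st == "up"], down = sel[st == "down"], ns = sel[st == "NS"])
  }
  list(counts = counts, genes = genes, n_filtered = length(sel))
}

#' Build the per-gene binding/expression report
#'
#' One row per gene: fold change and FDR per contrast (`NS` where not
#' significant), then one `+`/`-` column per factor. Rows follow
#' `gene_subset` order when given, else lexicographic gene order over the
#' union of bound and called genes.
#'
#' @param records Gene records from [assign_regions_to_genes()].
#' @param calls_by_contrast Named list of [filter_de_genes()] outputs.
#' @param gene_subset Optional character vector of gene ids.
#' @param factor_order Factor display order.
#' @return `data.frame` report; attribute `warnings` lists subset genes
#'   found in neither records nor calls.
#' @export
build_gene_binding_report <- function(records, calls_by_contrast,
                                      gene_subset = NULL,
                                      factor_order = attr(records, "factor_order")) {
  if (is.null(factor_order)) stop("factor_order required")
  known <- unique(c(records$gene_id,
                    unlist(lapply(calls_by_contrast, `[[`, "gene_id"))))
  warn <- character(0)
  if (is.null(gene_subset)) {
    genes <- sort(known)
  } else {
    warn <- setdiff(gene_subset, known)
    genes <- gene_subset[gene_subset %in% known]
  }
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cn in names(calls_by_contrast)) {
    calls <- calls_by_contrast[[cn]]
    idx <- match(genes, calls$gene_id)
    sig <- !is.na(idx) & calls$status[idx] != "NS"
    out[[paste0("fc_", cn)]] <-
      ifelse(sig, as.character(calls$fold_change[idx]), "NS")
    out[[paste0("fdr_", cn)]] <-
      ifelse(sig, as.character(calls$fdr[idx]), "NS")
  }
  ridx <- match(genes, records$gene_id)
  for (f in factor_order) {
    fl <- records[[paste0("flag_", f)]][ridx]
    fl[is.na(fl)] <- FALSE
    out[[f]] <- ifelse(fl, "+", "-")
  }
  attr(out, "warnings") <- warn
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>genes...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) stop("malformed GMT line (need name, desc, genes)")
  stats::setNames(lapply(f, function(x) unique(x[-(1:2)])),
                  vapply(f, `[[`, "", 1L))
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by drawing `|query|` genes from the universe without
#' replacement: upper-tail hypergeometric p-value of the overlap, BH
#' adjusted across sets. Sets are intersected with the universe first; the
#' query must be a subset of the universe.
#'
#' @param query_genes Character vector of genes of interest.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @return `data.frame` per set: `set`, `set_size`, `overlap`, `pvalue`,
#'   `padj`, sorted by p-value.
#' @export
overrepresentation_test <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query_genes <- unique(query_genes)
  if (any(!query_genes %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query_genes, universe), 3), collapse = ", "))
  k <- length(query_genes)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(s, query_genes))
    p <- hyper_upper_tail(ov, length(s), length(universe) - length(s), k)
    data.frame(set = nm, set_size = length(s), overlap = ov, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$pvalue, out$set), , drop = FALSE]
}
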