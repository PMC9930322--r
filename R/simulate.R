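#' Simulation configuration
#'
#' Defines the synthetic co-binding study: a multi-chromosome genome,
#' TSS-spaced genes, planted per-gene co-binding signatures with one
#' binding site near each bound TSS, ChIP and input fragment libraries at
#' a fixed site-over-background enrichment, expression contrasts in which
#' subsets of co-bound genes respond, and optional sequences with planted
#' motif consensus strings. Every artifact is deterministic for a fixed
#' seed; each component (annotation, sites, per-factor fragments,
#' expression) draws from its own seed stream derived from the master seed.
#'
#' @param seed Master seed (integer).
#' @param n_chroms,chrom_length_bp Genome shape (default 2 x 50 Mb).
#' @param n_genes Number of genes (default 2000).
#' @param factor_order Factor names in display order (default G, N, P).
#' @param category_proportions Named fractions per signature label; must
#'   sum to at most 1, the remainder being unbound genes.
#' @param site_offset_bp Maximum |site center - TSS| (default 4000).
#' @param site_width_bp Planted site window width (default 300).
#' @param enrichment_fold Site-window over background fragment rate
#'   (default 20; 1 gives a null library).
#' @param n_fragments_per_library,input_library_size Library sizes
#'   (default 1e6 each).
#' @param fragment_length_bp Extended fragment length (default 150).
#' @param frag_sd_bp SD of the fragment 5' position around the site
#'   (default 40).
#' @param de_effects Per contrast, per category, named fractions `up` /
#'   `down` of genes affected.
#' @param fold_range Magnitude range of affected linear folds, drawn
#'   log-uniform (default 2-20).
#' @param motif_specs Named per-factor consensus strings planted at
#'   occupied sites when sequences are generated.
#' @param emit_fasta Generate genome sequence (keep the genome small when
#'   TRUE).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 2L,
                              chrom_length_bp = 5e7,
                              n_genes = 2000L,
                              factor_order = c("G", "N", "P"),
                              category_proportions = c(
                                "G+N+P+" = 0.25, "G+N+P-" = 0.05,
                                "G+N-P+" = 0.02, "G+N-P-" = 0.02,
                                "G-N+P+" = 0.10, "G-N+P-" = 0.10,
                                "G-N-P+" = 0.10),
                              site_offset_bp = 4000L,
                              site_width_bp = 300L,
                              enrichment_fold = 20,
                              n_fragments_per_library = 1e6,
                              input_library_size = 1e6,
                              fragment_length_bp = 150L,
                              frag_sd_bp = 40,
                              de_effects = list(
                                LID_vs_ND = list("G+N+P+" = c(up = 0.10, down = 0.02)),
                                KO_vs_WT = list("G+N+P+" = c(down = 0.077, up = 0.044))),
                              fold_range = c(2, 20),
                              motif_specs = NULL,
                              emit_fasta = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp, n_genes = as.integer(n_genes),
              factor_order = factor_order,
              category_proportions = category_proportions,
              site_offset_bp = as.integer(site_offset_bp),
              site_width_bp = as.integer(site_width_bp),
              enrichment_fold = enrichment_fold,
              n_fragments_per_library = n_fragments_per_library,
              input_library_size = input_library_size,
              fragment_length_bp = as.integer(fragment_length_bp),
              frag_sd_bp = frag_sd_bp, de_effects = de_effects,
              fold_range = fold_range, motif_specs = motif_specs,
              emit_fasta = isTRUE(emit_fasta))
  if (sum(category_proportions) > 1 + 1e-12)
    stop("category proportions must sum to at most 1")
  if (any(category_proportions < 0)) stop("negative category proportion")
  for (lab in names(category_proportions))
    parse_signature_label(lab, factor_order)  # validates labels
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (any(c(cfg$n_chroms, cfg$chrom_length_bp, cfg$fragment_length_bp,
            cfg$n_fragments_per_library, cfg$input_library_size) <= 0))
    stop("all sizes and counts must be positive")
  for (contrast in names(de_effects))
    for (cat in names(de_effects[[contrast]]))
      if (cat != "unbound")
        parse_signature_label(cat, factor_order)
  if (!is.null(motif_specs)) {
    bad <- setdiff(names(motif_specs), factor_order)
    if (length(bad)) stop("motif_specs for unknown factor: ", bad[1])
  }
  structure(cfg, class = "simulation_config")
}

# Minimum spacing keeping each gene's site window and TSS window private.
min_tss_spacing <- function(config, gene_window_bp = 5000L) {
  2L * (config$site_offset_bp + gene_window_bp)
}

#' Simulate a genome annotation (and optionally its sequence)
#'
#' Genes are laid out on alternating strands with enforced minimum
#' inter-TSS spacing so each gene's planted site and TSS window stay
#' unambiguous; gene lengths are drawn uniformly between 5 and 20 kb.
#'
#' @param config A [simulation_config()].
#' @return List: `annotation` ([genome_annotation()]) and `sequences`
#'   (a `Biostrings::DNAStringSet`, or `NULL` unless `emit_fasta`).
#' @export
simulate_genome_annotation <- function(config) {
  cs <- stats::setNames(rep(config$chrom_length_bp, config$n_chroms),
                        paste0("chr", seq_len(config$n_chroms)))
  spacing <- min_tss_spacing(config)
  margin <- max(spacing, 21000)
  genes <- NULL
  if (config$n_genes > 0) {
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chroms + 1L)))
    slot <- (config$chrom_length_bp - 2 * margin) / max(per_chrom)
    if (slot < spacing)
      stop("genome too small for ", config$n_genes, " genes at spacing ",
           spacing, " bp; need chromosome length >= ",
           ceiling(max(per_chrom) * spacing + 2 * margin), " bp")
    genes <- with_seed(stage_seed(config$seed, "annotation"), {
      rows <- lapply(seq_len(config$n_chroms), function(ci) {
        n <- per_chrom[ci]
        if (n == 0) return(NULL)
        jitter <- stats::runif(n, 0, slot - spacing)
        tss <- floor(margin + (seq_len(n) - 1) * slot + jitter)
        strand <- rep(c("+", "-"), length.out = n)
        len <- floor(stats::runif(n, 5000, 20000))
        tes <- ifelse(strand == "+", tss + len, tss - len)
        data.frame(chrom = names(cs)[ci], strand = strand, tss = tss,
                   tes = tes, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "strand", "tss", "tes")]
  } else {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), tss = numeric(0),
                        tes = numeric(0), stringsAsFactors = FALSE)
  }
  sequences <- NULL
  if (config$emit_fasta) {
    sequences <- with_seed(stage_seed(config$seed, "sequence"), {
      seqs <- vapply(names(cs), function(ch)
        paste(sample(c("A", "C", "G", "T"), cs[[ch]], replace = TRUE),
              collapse = ""), "")
      Biostrings::DNAStringSet(stats::setNames(seqs, names(cs)))
    })
  }
  list(annotation = genome_annotation(cs, genes), sequences = sequences)
}

#' Plant co-binding sites and motifs
#'
#' Assigns every gene a signature label by the configured proportions
#' (remainder all-negative/unbound), places one site uniformly within
#' TSS plus/minus `site_offset_bp` for bound genes, and (when sequences
#' are provided) writes each occupying factor's motif consensus into the
#' site at a recorded offset.
#'
#' @param genome Output of [simulate_genome_annotation()].
#' @param config A [simulation_config()].
#' @return List: `truth` (`data.frame`: gene_id, label, site_start,
#'   site_end, site_center, `occ_<factor>` logicals, and
#'   `motifpos_<factor>` 0-based offsets when motifs were planted) and
#'   `sequences` (possibly modified).
#' @export
plant_sites <- function(genome, config) {
  ann <- genome$annotation
  genes <- ann$genes
  fo <- config$factor_order
  labels_cfg <- names(config$category_proportions)
  neg_label <- signature_label(stats::setNames(rep(FALSE, length(fo)), fo))
  truth <- with_seed(stage_seed(config$seed, "sites"), {
    prob <- c(config$category_proportions,
              1 - sum(config$category_proportions))
    lab <- sample(c(labels_cfg, neg_label), nrow(genes), replace = TRUE,
                  prob = prob)
    offset <- floor(stats::runif(nrow(genes), -config$site_offset_bp,
                                 config$site_offset_bp + 1))
    data.frame(gene_id = genes$gene_id, label = lab,
               site_center = genes$tss + offset, stringsAsFactors = FALSE)
  })
  bound <- truth$label != neg_label
  truth$site_center[!bound] <- NA
  half <- config$site_width_bp %/% 2L
  truth$site_start <- truth$site_center - half
  truth$site_end <- truth$site_start + config$site_width_bp
  truth$chrom <- genes$chrom
  occ <- t(vapply(truth$label, parse_signature_label,
                  logical(length(fo)), factor_order = fo))
  for (j in seq_along(fo)) truth[[paste0("occ_", fo[j])]] <- occ[, j]
  sequences <- genome$sequences
  if (!is.null(sequences) && !is.null(config$motif_specs)) {
    for (j in seq_along(fo)) {
      f <- fo[j]
      cons <- config$motif_specs[[f]]
      if (is.null(cons)) next
      pos_col <- paste0("motifpos_", f)
      truth[[pos_col]] <- NA_real_
      idx <- which(truth[[paste0("occ_", f)]])
      for (i in idx) {
        # deterministic per-factor lane inside the site
        at0 <- truth$site_start[i] + (j - 1L) * (nchar(cons) + 2L)
        Biostrings::subseq(sequences[[truth$chrom[i]]],
                           start = at0 + 1L,
                           end = at0 + nchar(cons)) <- Biostrings::DNAString(cons)
        truth[[pos_col]][i] <- at0
      }
    }
  }
  list(truth = truth, sequences = sequences)
}

#' Simulate a ChIP fragment library for one factor
#'
#' Each fragment is independently a site fragment (probability calibrated
#' so the site-window fragment rate exceeds background by
#' `enrichment_fold`) or a background fragment placed uniformly on the
#' genome. Site fragments pick an occupied site uniformly; the 5' position
#' is Normal(site center -/+ fragment_length/2, `frag_sd_bp`) for +/-
#' strand reads, so extended fragments cover the site from both sides.
#'
#' @param truth Truth table from [plant_sites()].
#' @param annotation A [genome_annotation()].
#' @param factor Factor name, or `"input"` for a pure-background library.
#' @param config A [simulation_config()].
#' @return A [fragment_set()] of extended fragments.
#' @export
simulate_chip_fragments <- function(truth, annotation, factor, config) {
  cs <- annotation$chrom_sizes
  G <- genome_size(cs)
  fl <- config$fragment_length_bp
  is_input <- identical(factor, "input")
  n <- if (is_input) config$input_library_size else config$n_fragments_per_library
  k <- if (is_input) 0L else match(factor, config$factor_order)
  if (!is_input && is.na(k)) stop("unknown factor: ", factor)
  sites <- if (is_input) truth[0, ] else truth[which(truth[[paste0("occ_", factor)]]), ]
  S <- nrow(sites)
  pi_site <- 0
  if (!is_input && S > 0 && config$enrichment_fold > 1) {
    sw <- S * config$site_width_bp
    pi_site <- (config$enrichment_fold - 1) * sw /
      (G + (config$enrichment_fold - 1) * sw)
  }
  if (!is_input && S == 0 && config$enrichment_fold > 1)
    warning("factor ", factor, " has no occupied site; all-background library")
  reads <- with_seed(stage_seed(config$seed, "fragments", k), {
    from_site <- stats::runif(n) < pi_site
    n_site <- sum(from_site)
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    chrom <- character(n); pos5 <- numeric(n)
    if (n_site > 0) {
      si <- sample.int(S, n_site, replace = TRUE)
      center <- sites$site_center[si]
      shift <- ifelse(strand[from_site] == "+", -fl / 2, fl / 2)
      pos5[from_site] <- round(stats::rnorm(n_site, center + shift,
                                            config$frag_sd_bp))
      chrom[from_site] <- sites$chrom[si]
    }
    n_bg <- n - n_site
    if (n_bg > 0) {
      ci <- sample.int(length(cs), n_bg, replace = TRUE,
                       prob = as.numeric(cs) / G)
      chrom[!from_site] <- names(cs)[ci]
      pos5[!from_site] <- floor(stats::runif(n_bg, 0, cs[ci]))
    }
    pos5 <- pmin(pmax(pos5, 0), cs[chrom] - 1)
    gr0(chrom, pos5, pos5 + 1, strand)
  })
  label <- if (is_input) "input" else paste0(factor, "-ChIP")
  extend_fragments(reads, length = fl, chrom_sizes = cs, label = label)
}

#' Simulate a differential-expression table for one contrast
#'
#' Affected genes are drawn per (category, fraction) from `de_effects`;
#' their linear fold magnitudes are log-uniform over `fold_range` with the
#' configured sign and FDR Uniform(0, 0.01), so all pass the 1.5-fold /
#' FDR 0.05 filter by construction. Unaffected genes get magnitudes
#' Uniform(1, 1.2) with random sign and FDR Uniform(0.1, 1).
#'
#' @param truth Truth table from [plant_sites()].
#' @param config A [simulation_config()].
#' @param contrast Contrast name (must be in `config$de_effects`).
#' @return List: `table` (`data.frame` gene, fc, fdr) and `truth`
#'   (`data.frame` gene_id, status in up/down/NS).
#' @export
simulate_expression_table <- function(truth, config, contrast) {
  if (!contrast %in% names(config$de_effects))
    stop("unknown contrast: ", contrast)
  eff <- config$de_effects[[contrast]]
  fo <- config$factor_order
  neg_label <- signature_label(stats::setNames(rep(FALSE, length(fo)), fo))
  k <- match(contrast, names(config$de_effects))
  with_seed(stage_seed(config$seed, "expression", k), {
    n <- nrow(truth)
    status <- rep("NS", n)
    for (cat in names(eff)) {
      in_cat <- if (cat == "unbound") truth$label == neg_label else truth$label == cat
      idx <- which(in_cat)
      fr <- eff[[cat]]
      if (!all(names(fr) %in% c("up", "down")))
        stop("de_effects fractions must be named up/down")
      if (sum(fr) > 1) stop("affected fractions exceed 1 for ", cat)
      n_up <- round(.frac(fr["up"]) * length(idx))
      n_dn <- round(.frac(fr["down"]) * length(idx))
      pick <- idx[sample.int(length(idx), min(length(idx), n_up + n_dn))]
      if (n_up > 0) status[pick[seq_len(min(n_up, length(pick)))]] <- "up"
      if (n_dn > 0 && length(pick) > n_up)
        status[pick[(n_up + 1):length(pick)]] <- "down"
    }
    aff <- status != "NS"
    mag <- numeric(n)
    mag[aff] <- exp(stats::runif(sum(aff), log(config$fold_range[1]),
                                 log(config$fold_range[2])))
    mag[!aff] <- stats::runif(sum(!aff), 1, 1.2)
    sign <- ifelse(status == "up", 1,
            ifelse(status == "down", -1,
                   ifelse(stats::runif(n) < 0.5, 1, -1)))
    fdr <- ifelse(aff, stats::runif(n, 0, 0.01), stats::runif(n, 0.1, 1))
    list(table = data.frame(gene = truth$gene_id, fc = sign * mag, fdr = fdr,
                            stringsAsFactors = FALSE),
         truth = data.frame(gene_id = truth$gene_id, status = status,
                            stringsAsFactors = FALSE))
  })
}

# NA-tolerant fraction lookup (missing name in a named vector gives NA)
.frac <- function(x) if (length(x) == 0 || is.na(x)) 0 else unname(x)

#' Simulate a complete co-binding study
#'
#' Runs all generator stages: genome/annotation, planted sites, one ChIP
#' library per factor plus an input library, and one DE table per
#' configured contrast.
#'
#' @param config A [simulation_config()].
#' @return List: `config`, `annotation`, `sequences`, `truth`,
#'   `libraries` (named list of [fragment_set()] per factor), `input`,
#'   `de` (per contrast: `table`, `truth`).
#' @export
simulate_cobinding_study <- function(config = simulation_config()) {
  genome <- simulate_genome_annotation(config)
  planted <- plant_sites(genome, config)
  libraries <- stats::setNames(lapply(config$factor_order, function(f)
    simulate_chip_fragments(planted$truth, genome$annotation, f, config)),
    config$factor_order)
  input <- simulate_chip_fragments(planted$truth, genome$annotation,
                                   "input", config)
  de <- stats::setNames(lapply(names(config$de_effects), function(ct)
    simulate_expression_table(planted$truth, config, ct)),
    names(config$de_effects))
  list(config = config, annotation = genome$annotation,
       sequences = planted$sequences, truth = planted$truth,
       libraries = libraries, input = input, de = de)
}

#' Write a simulated study to plain-text files
#'
#' Emits the refFlat-like annotation TSV, chrom.sizes, per-library
#' fragment BED6, DE TSVs, truth TSVs, optional FASTA, and the resolved
#' configuration as a text echo.
#'
#' @param study Output of [simulate_cobinding_study()].
#' @param outdir Output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- study$annotation
  genes <- ann$genes
  refflat <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        strand = genes$strand,
                        txStart = pmin(genes$tss, genes$tes),
                        txEnd = pmax(genes$tss, genes$tes))
  utils::write.table(refflat, file.path(outdir, "annotation.refflat.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(names(ann$chrom_sizes),
               format(ann$chrom_sizes, scientific = FALSE, trim = TRUE)),
    file.path(outdir, "genome.chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (f in names(study$libraries))
    write_bed(study$libraries[[f]]$fragments,
              file.path(outdir, paste0(f, ".fragments.bed")))
  write_bed(study$input$fragments, file.path(outdir, "input.fragments.bed"))
  utils::write.table(study$truth, file.path(outdir, "truth.sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ct in names(study$de)) {
    utils::write.table(study$de[[ct]]$table,
                       file.path(outdir, paste0("de.", ct, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(study$de[[ct]]$truth,
                       file.path(outdir, paste0("truth.de.", ct, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(study$sequences))
    Biostrings::writeXStringSet(study$sequences,
                                file.path(outdir, "genome.fa"))
  writeLines(utils::capture.output(utils::str(unclass(study$config))),
             file.path(outdir, "config.echo.txt"))
  invisible(outdir)
}
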