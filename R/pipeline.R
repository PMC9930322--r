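#' Pipeline run configuration
#'
#' Collects inputs and stage parameters for [run_cobinding_pipeline()].
#' Inputs may be in-memory objects ([fragment_set()], [genome_annotation()],
#' `data.frame`s) or file paths (fragment BED6 of reads, refFlat TSV, DE
#' TSV with header gene/fc/fdr). Peak-calling profiles: `"factor-stringent"`
#' (min_fold 8, FDR 1e-5) and `"factor-permissive"` (min_fold 4, FDR 1e-3).
#'
#' @param chip Named list (factor -> [fragment_set()] or BED path of reads).
#' @param input A [fragment_set()], BED path, or `NULL` (uniform
#'   pseudo-input).
#' @param annotation [genome_annotation()] or refFlat TSV path.
#' @param chrom_sizes Named lengths, chrom.sizes path, or `NULL` to use the
#'   annotation's.
#' @param de_tables Named list (contrast -> `data.frame` or TSV path); may
#'   be empty.
#' @param outdir Output directory.
#' @param factor_order Factor display order (default `names(chip)`).
#' @param profile Peak-calling profile name (sets `min_fold`/`fdr` unless
#'   given explicitly).
#' @param min_fold,fdr Peak-caller thresholds (override the profile).
#' @param window_bp,step_bp Caller window geometry (300/75).
#' @param resize_width Peak resize width (300).
#' @param gap_bp Collapse gap (50).
#' @param cutoff Positivity p-value cutoff (1e-6).
#' @param tss_window_bp Gene-assignment TSS window (5000).
#' @param fc_min,fdr_max DE thresholds (1.5, 0.05).
#' @param log2_input DE tables carry log2 folds.
#' @param signature_filter Signature label for the expression crosstab
#'   (default: all factors positive).
#' @param fragment_length Extension length applied to BED read input (150).
#' @return A validated `run_config` list.
#' @export
run_config <- function(chip, input = NULL, annotation, chrom_sizes = NULL,
                       de_tables = list(), outdir = tempfile("cobind_run_"),
                       factor_order = names(chip),
                       profile = c("factor-stringent", "factor-permissive"),
                       min_fold = NULL, fdr = NULL,
                       window_bp = 300L, step_bp = 75L, resize_width = 300L,
                       gap_bp = 50L, cutoff = 1e-6, tss_window_bp = 5000L,
                       fc_min = 1.5, fdr_max = 0.05, log2_input = FALSE,
                       signature_filter = NULL, fragment_length = 150L) {
  profile <- match.arg(profile)
  prof <- switch(profile,
                 "factor-stringent" = list(min_fold = 8, fdr = 1e-5),
                 "factor-permissive" = list(min_fold = 4, fdr = 1e-3))
  if (is.null(names(chip)) || any(!nzchar(names(chip))))
    stop("chip must be a named list (factor -> library)")
  if (!all(factor_order %in% names(chip)))
    stop("factor_order names a factor with no chip library")
  for (x in chip)
    if (is.character(x) && !file.exists(x)) stop("missing chip input: ", x)
  if (is.character(input) && !file.exists(input))
    stop("missing input library: ", input)
  if (is.character(annotation) && !file.exists(annotation))
    stop("missing annotation: ", annotation)
  for (nm in names(de_tables)) {
    x <- de_tables[[nm]]
    if (is.character(x) && !file.exists(x))
      stop("missing DE table for contrast ", nm, ": ", x)
  }
  if (is.null(signature_filter))
    signature_filter <- signature_label(
      stats::setNames(rep(TRUE, length(factor_order)), factor_order))
  parse_signature_label(signature_filter, factor_order)
  structure(list(chip = chip, input = input, annotation = annotation,
                 chrom_sizes = chrom_sizes, de_tables = de_tables,
                 outdir = outdir, factor_order = factor_order,
                 profile = profile,
                 min_fold = min_fold %||% prof$min_fold,
                 fdr = fdr %||% prof$fdr,
                 window_bp = window_bp, step_bp = step_bp,
                 resize_width = resize_width, gap_bp = gap_bp,
                 cutoff = cutoff, tss_window_bp = tss_window_bp,
                 fc_min = fc_min, fdr_max = fdr_max,
                 log2_input = log2_input,
                 signature_filter = signature_filter,
                 fragment_length = fragment_length),
            class = "run_config")
}

resolve_fragments <- function(x, chrom_sizes, fragment_length, label) {
  if (methods::is(x, "fragment_set")) return(x)
  reads <- read_bed(x)
  extend_fragments(reads, length = fragment_length,
                   chrom_sizes = chrom_sizes, label = label)
}

provenance_header <- function(config_hash) {
  c(paste0("# cobindseq ", as.character(utils::packageVersion("cobindseq"))),
    paste0("# config_hash ", config_hash),
    paste0("# timestamp ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

write_tsv_prov <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the co-binding analysis end-to-end
#'
#' Stages: per-factor peak calling against the input, resizing to fixed
#' width, gap-tolerant collapsing into multi-factor regions, per-factor
#' positivity scoring, genomic-context summaries, TSS-window gene
#' assignment, and (when DE tables are configured) expression integration.
#' All outputs carry a provenance header; re-running on identical inputs
#' is byte-identical except for the timestamp lines.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`peaksets`, `regions`, `records`, `contexts`, `calls`, `crosstab`,
#'   `report`) and `outdir`.
#' @export
run_cobinding_pipeline <- function(config) {
  stopifnot(methods::is(config, "run_config"))
  ann <- if (is.character(config$annotation))
    read_annotation(config$annotation, "refflat_tsv",
                    chrom_sizes_path = if (is.character(config$chrom_sizes))
                      config$chrom_sizes else NULL)
  else config$annotation
  chrom_sizes <- if (is.numeric(config$chrom_sizes)) config$chrom_sizes
                 else ann$chrom_sizes
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_txt <- tempfile(); on.exit(unlink(cfg_txt), add = TRUE)
  # hash the analysis parameters only, not input/output paths
  params <- c("factor_order", "profile", "min_fold", "fdr", "window_bp",
              "step_bp", "resize_width", "gap_bp", "cutoff", "tss_window_bp",
              "fc_min", "fdr_max", "log2_input", "signature_filter",
              "fragment_length")
  writeLines(deparse(unclass(config)[params]), cfg_txt)
  hdr <- provenance_header(unname(tools::md5sum(cfg_txt)))
  log_msg <- function(stage, ...)
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  libs <- stage("load", {
    input <- if (is.null(config$input)) NULL else
      resolve_fragments(config$input, chrom_sizes, config$fragment_length,
                        "input")
    chip <- stats::setNames(lapply(config$factor_order, function(f)
      resolve_fragments(config$chip[[f]], chrom_sizes,
                        config$fragment_length, paste0(f, "-ChIP"))),
      config$factor_order)
    list(chip = chip, input = input)
  })

  peaksets <- stage("callpeaks", {
    lapply(config$factor_order, function(f) {
      log_msg("callpeaks", f)
      call_peaks_factor(libs$chip[[f]], libs$input, chrom_sizes, factor = f,
                        window_bp = config$window_bp,
                        step_bp = config$step_bp,
                        min_fold = config$min_fold, fdr = config$fdr)
    })
  })
  names(peaksets) <- config$factor_order

  resized <- stage("resize", lapply(peaksets, resize_peaks,
                                    width = config$resize_width,
                                    chrom_sizes = chrom_sizes))
  regions <- stage("collapse",
                   collapse_peaksets(resized, gap_bp = config$gap_bp))
  regions <- stage("score",
                   build_signature_matrix(regions, libs$chip, chrom_sizes,
                                          cutoff = config$cutoff,
                                          factor_order = config$factor_order))
  contexts <- stage("annotate", {
    ctx <- lapply(resized, summarize_contexts, annotation = ann)
    do.call(rbind, lapply(names(ctx), function(f)
      cbind(factor = f, ctx[[f]])))
  })
  records <- stage("annotate",
                   assign_regions_to_genes(regions, ann,
                                           window_bp = config$tss_window_bp,
                                           factor_order = config$factor_order))
  calls <- crosstab <- report <- NULL
  if (length(config$de_tables) > 0) {
    calls <- stage("integrate", lapply(config$de_tables, filter_de_genes,
                                       fc_min = config$fc_min,
                                       fdr_max = config$fdr_max,
                                       log2_input = config$log2_input))
    crosstab <- stage("integrate",
                      crosstab_binding_expression(records, calls,
                                                  config$signature_filter,
                                                  config$factor_order))
    report <- stage("integrate",
                    build_gene_binding_report(records, calls,
                                              factor_order = config$factor_order))
  }

  # outputs
  sig_bed <- regions
  S4Vectors::mcols(sig_bed) <- NULL
  S4Vectors::mcols(sig_bed)$name <- S4Vectors::mcols(regions)$signature
  write_bed(sig_bed, file.path(config$outdir, "collapsed_regions.bed"))
  write_tsv_prov(signature_summary(regions),
                 file.path(config$outdir, "signature_summary.tsv"), hdr)
  write_tsv_prov(contexts, file.path(config$outdir, "context_summary.tsv"),
                 hdr)
  rec_out <- records
  rec_flags <- paste0("flag_", config$factor_order)
  for (fc in rec_flags) rec_out[[fc]] <- ifelse(rec_out[[fc]], "+", "-")
  write_tsv_prov(rec_out, file.path(config$outdir, "gene_binding_records.tsv"),
                 hdr)
  if (!is.null(crosstab)) {
    write_tsv_prov(crosstab$counts,
                   file.path(config$outdir, "expression_crosstab.tsv"), hdr)
    write_tsv_prov(report, file.path(config$outdir, "gene_report.tsv"), hdr)
  }
  manifest <- data.frame(
    key = c("package", "n_factors", "profile", "n_regions", "n_bound_genes"),
    value = c(as.character(utils::packageVersion("cobindseq")),
              length(config$factor_order), config$profile,
              length(regions), nrow(records)))
  write_tsv_prov(manifest, file.path(config$outdir, "run_manifest.tsv"), hdr)
  invisible(list(peaksets = peaksets, resized = resized, regions = regions,
                 records = records, contexts = contexts, calls = calls,
                 crosstab = crosstab, report = report,
                 outdir = config$outdir, annotation = ann))
}

#' Benchmark signature recovery on simulated truth
#'
#' Simulates a study, runs the pipeline on it, and compares results to the
#' generator's ground truth: per-factor site sensitivity (occupied sites
#' whose overlapping region is flagged positive), per-factor gene
#' specificity, gene-level signature accuracy, the gene-level
#' false-positive rate among truly unbound genes, and per-contrast
#' agreement of the signature-filtered down/up gene sets with truth.
#'
#' @param sim_config A [simulation_config()].
#' @param outdir Optional pipeline output directory.
#' @return `data.frame` (`metric`, `value`); the pipeline result is
#'   attached as attribute `run`.
#' @export
run_recovery_benchmark <- function(sim_config = simulation_config(),
                                   outdir = tempfile("cobind_bench_")) {
  study <- simulate_cobinding_study(sim_config)
  fo <- sim_config$factor_order
  rc <- run_config(chip = study$libraries, input = study$input,
                   annotation = study$annotation,
                   de_tables = stats::setNames(
                     lapply(study$de, `[[`, "table"), names(study$de)),
                   outdir = outdir, factor_order = fo)
  run <- run_cobinding_pipeline(rc)
  truth <- study$truth
  neg_label <- signature_label(stats::setNames(rep(FALSE, length(fo)), fo))
  metrics <- list()
  add <- function(metric, value)
    metrics[[length(metrics) + 1L]] <<- data.frame(metric = metric,
                                                   value = value)
  # per-factor site sensitivity / gene specificity
  for (f in fo) {
    occ <- which(truth[[paste0("occ_", f)]])
    flag_col <- paste0("flag_", f)
    if (length(occ)) {
      sites <- gr0(truth$chrom[occ], truth$site_start[occ],
                   truth$site_end[occ])
      pos_regions <- run$regions[S4Vectors::mcols(run$regions)[[flag_col]]]
      sens <- mean(suppressWarnings(
        GenomicRanges::countOverlaps(sites, pos_regions,
                                     ignore.strand = TRUE)) > 0)
      add(paste0("site_sensitivity_", f), sens)
    }
    neg_genes <- truth$gene_id[!truth[[paste0("occ_", f)]]]
    called_pos <- run$records$gene_id[run$records[[flag_col]]]
    add(paste0("gene_specificity_", f),
        1 - mean(neg_genes %in% called_pos))
  }
  # gene-level signature accuracy over all genes
  pipe_label <- run$records$signature[match(truth$gene_id,
                                            run$records$gene_id)]
  pipe_label[is.na(pipe_label)] <- neg_label
  add("signature_accuracy", mean(pipe_label == truth$label))
  unbound <- truth$label == neg_label
  add("gene_false_positive_rate",
      if (any(unbound)) mean(pipe_label[unbound] != neg_label) else 0)
  # DE crosstab agreement against truth, within the all-positive signature
  pos_label <- signature_label(stats::setNames(rep(TRUE, length(fo)), fo))
  if (!is.null(run$crosstab)) {
    for (ct in names(study$de)) {
      de_truth <- study$de[[ct]]$truth
      for (dir in c("down", "up")) {
        truth_set <- intersect(truth$gene_id[truth$label == pos_label],
                               de_truth$gene_id[de_truth$status == dir])
        pipe_set <- run$crosstab$genes[[ct]][[dir]]
        denom <- max(length(truth_set), length(pipe_set), 1L)
        add(paste0("de_", dir, "_agreement_", ct),
            length(intersect(truth_set, pipe_set)) / denom)
        add(paste0("de_", dir, "_n_", ct), length(pipe_set))
      }
    }
  }
  out <- do.call(rbind, metrics)
  utils::write.table(out, file.path(outdir, "benchmark_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attr(out, "run") <- run
  out
}
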