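test_that("simulation configs validate proportions, labels, and sizes", {
  expect_error(simulation_config(category_proportions = c("G+N+P+" = 1.2)),
               "at most 1")
  expect_error(simulation_config(category_proportions = c("X+Y+" = 0.2)),
               "factor order")
  expect_error(simulation_config(enrichment_fold = 0.5), "enrichment_fold")
  cfg <- small_sim_config()
  expect_s3_class(cfg, "simulation_config")
})

test_that("generated annotations honor TSS spacing and are deterministic", {
  for (seed in c(1, 7, 23)) {
    cfg <- small_sim_config(seed = seed)
    g1 <- simulate_genome_annotation(cfg)
    g2 <- simulate_genome_annotation(cfg)
    expect_identical(g1$annotation$genes, g2$annotation$genes)
    genes <- g1$annotation$genes
    spacing <- cobindseq:::min_tss_spacing(cfg)
    for (ch in unique(genes$chrom)) {
      tss <- sort(genes$tss[genes$chrom == ch])
      if (length(tss) > 1) expect_gte(min(diff(tss)), spacing)
    }
    hi <- pmax(genes$tss, genes$tes)
    expect_true(all(hi <= g1$annotation$chrom_sizes[genes$chrom]))
  }
  # genome too small for the requested gene count
  expect_error(simulate_genome_annotation(
    simulation_config(n_chroms = 1, chrom_length_bp = 1e5, n_genes = 100)),
    "too small")
  # zero genes: annotation with chrom sizes only
  g0 <- simulate_genome_annotation(small_sim_config(n_genes = 0))
  expect_equal(nrow(g0$annotation$genes), 0L)
})

test_that("plant_sites assigns labels by proportion and records consistent truth", {
  cfg <- small_sim_config(
    category_proportions = c("G+N+P+" = 1.0))
  planted <- plant_sites(simulate_genome_annotation(cfg), cfg)
  expect_true(all(planted$truth$label == "G+N+P+"))
  expect_true(all(planted$truth$occ_G & planted$truth$occ_N &
                    planted$truth$occ_P))
  # site centers stay within the configured TSS offset
  ann <- simulate_genome_annotation(cfg)$annotation
  off <- abs(planted$truth$site_center - ann$genes$tss)
  expect_true(all(off <= cfg$site_offset_bp))

  cfg2 <- small_sim_config(seed = 2)
  planted2 <- plant_sites(simulate_genome_annotation(cfg2), cfg2)
  neg <- planted2$truth$label == "G-N-P-"
  expect_true(all(is.na(planted2$truth$site_center[neg])))
  expect_true(all(!is.na(planted2$truth$site_center[!neg])))
  # occupancy columns agree with the label string
  occ <- as.matrix(planted2$truth[, c("occ_G", "occ_N", "occ_P")])
  relabel <- apply(occ, 1, function(r)
    signature_label(stats::setNames(as.logical(r), c("G", "N", "P"))))
  expect_equal(unname(relabel), planted2$truth$label)
})

test_that("motif consensus strings are written at the recorded offsets", {
  cfg <- simulation_config(seed = 3, n_chroms = 1, chrom_length_bp = 6e5,
                           n_genes = 20, site_offset_bp = 1000,
                           n_fragments_per_library = 1000,
                           input_library_size = 1000,
                           category_proportions = c("G+N+P+" = 0.8),
                           motif_specs = list(G = "GACCTTGCAT",
                                              N = "CACTTGAAGT"),
                           emit_fasta = TRUE)
  planted <- plant_sites(simulate_genome_annotation(cfg), cfg)
  truth <- planted$truth
  seqs <- planted$sequences
  idx <- which(truth$occ_G)
  expect_gt(length(idx), 0)
  for (i in idx) {
    at <- truth$motifpos_G[i]
    got <- as.character(Biostrings::subseq(seqs[[truth$chrom[i]]],
                                           at + 1, at + 10))
    expect_equal(got, "GACCTTGCAT")
    atN <- truth$motifpos_N[i]
    gotN <- as.character(Biostrings::subseq(seqs[[truth$chrom[i]]],
                                            atN + 1, atN + 10))
    expect_equal(gotN, "CACTTGAAGT")
  }
})

test_that("fragment libraries honor size, length, and the null construction", {
  cfg <- small_sim_config()
  genome <- simulate_genome_annotation(cfg)
  planted <- plant_sites(genome, cfg)
  lib <- simulate_chip_fragments(planted$truth, genome$annotation, "G", cfg)
  expect_equal(lib$total_count, cfg$n_fragments_per_library)
  w <- GenomicRanges::width(lib$fragments)
  expect_true(mean(w == cfg$fragment_length_bp) > 0.99)  # clipped at edges only
  # same seed -> byte-identical library
  lib2 <- simulate_chip_fragments(planted$truth, genome$annotation, "G", cfg)
  expect_identical(as.data.frame(lib$fragments), as.data.frame(lib2$fragments))
  # input library start positions are uniform (KS test)
  inp <- simulate_chip_fragments(planted$truth, genome$annotation, "input", cfg)
  u <- (GenomicRanges::start(inp$fragments) - 1) / cfg$chrom_length_bp
  expect_gt(suppressWarnings(stats::ks.test(u, "punif")$p.value), 0.01)
  # enrichment_fold 1 gives a background-only ChIP library
  cfg_null <- small_sim_config(enrichment_fold = 1)
  null_lib <- simulate_chip_fragments(planted$truth, genome$annotation, "G",
                                      cfg_null)
  occ <- planted$truth[which(planted$truth$occ_G), ]
  sites <- make_gr(occ$chrom, occ$site_start, occ$site_end)
  sc <- score_region_positivity(sites, null_lib,
                                genome$annotation$chrom_sizes)
  expect_equal(sum(sc$positive), 0L)
})

test_that("planted sites score positive for their occupying factors", {
  cfg <- small_sim_config()
  genome <- simulate_genome_annotation(cfg)
  planted <- plant_sites(genome, cfg)
  for (f in c("G", "N", "P")) {
    lib <- simulate_chip_fragments(planted$truth, genome$annotation, f, cfg)
    occ <- planted$truth[which(planted$truth[[paste0("occ_", f)]]), ]
    sites <- make_gr(occ$chrom, occ$site_start, occ$site_end)
    sc <- score_region_positivity(sites, lib, genome$annotation$chrom_sizes)
    expect_gte(mean(sc$positive), 0.9)
  }
})

test_that("expression tables embed recoverable DE truth", {
  cfg <- small_sim_config(
    n_genes = 200, n_chroms = 1, chrom_length_bp = 4e6,
    de_effects = list(KO = list("G+N+P+" = c(down = 0.5, up = 0.2))))
  genome <- simulate_genome_annotation(cfg)
  planted <- plant_sites(genome, cfg)
  de <- simulate_expression_table(planted$truth, cfg, "KO")
  calls <- filter_de_genes(de$table)
  # every affected gene passes the 1.5-fold / FDR 0.05 filter by construction
  expect_equal(calls$status, de$truth$status)
  trip <- planted$truth$gene_id[planted$truth$label == "G+N+P+"]
  n_dn <- sum(de$truth$status == "down" & de$truth$gene_id %in% trip)
  expect_equal(n_dn, round(0.5 * length(trip)))
  # all affected genes are in the planted category
  expect_true(all(de$truth$gene_id[de$truth$status != "NS"] %in% trip))
  expect_error(simulate_expression_table(planted$truth, cfg, "nope"),
               "contrast")
})

test_that("the full study is deterministic and writes plain-text artifacts", {
  cfg <- small_sim_config(n_fragments_per_library = 5000,
                          input_library_size = 5000)
  s1 <- simulate_cobinding_study(cfg)
  s2 <- simulate_cobinding_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$libraries$G$fragments),
                   as.data.frame(s2$libraries$G$fragments))
  expect_identical(s1$de$KO_vs_WT$table, s2$de$KO_vs_WT$table)
  out <- withr::local_tempdir()
  write_simulation(s1, out)
  expect_true(all(file.exists(file.path(out,
    c("annotation.refflat.tsv", "genome.chrom.sizes", "G.fragments.bed",
      "input.fragments.bed", "truth.sites.tsv", "de.KO_vs_WT.tsv")))))
  back <- read_annotation(file.path(out, "annotation.refflat.tsv"),
                          "refflat_tsv",
                          chrom_sizes_path = file.path(out, "genome.chrom.sizes"))
  expect_equal(back$genes$tss, s1$annotation$genes$tss)
  expect_equal(unname(back$chrom_sizes),
               unname(s1$annotation$chrom_sizes))
})
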