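test_that("genomic context classification follows window definitions and precedence", {
  ann <- toy_annotation()
  # gplus: + strand, tss 10000, tes 20000; gminus: - strand, tss 80000
  pt <- function(m) make_gr("chr1", m, m + 1)
  expect_equal(as.character(classify_genomic_context(pt(9500), ann)$category),
               "TSS_proximal")
  expect_equal(as.character(classify_genomic_context(pt(7000), ann)$category),
               "Upstream")
  expect_equal(as.character(classify_genomic_context(pt(15000), ann)$category),
               "Genebody")
  expect_equal(as.character(classify_genomic_context(pt(50000), ann)$category),
               "Intergenic")
  expect_true(is.na(classify_genomic_context(pt(50000), ann)$gene_id))
  # minus strand: proximal window sits above the TSS coordinate
  ctx <- classify_genomic_context(pt(80500), ann)
  expect_equal(as.character(ctx$category), "TSS_proximal")
  expect_equal(ctx$gene_id, "gminus")
})

test_that("context categories partition the peak set", {
  ann <- toy_annotation()
  set.seed(3)
  m <- sample(0:99000, 500)
  peaks <- make_gr("chr1", m, m + 300)
  tab <- summarize_contexts(peaks, ann)
  expect_equal(sum(tab$count), 500L)
  expect_equal(sum(tab$fraction), 1)
  # gene-free chromosome: everything intergenic
  tab2 <- summarize_contexts(make_gr("chr2", c(100, 5000), c(400, 5300)), ann)
  expect_equal(tab2$fraction[tab2$category == "Intergenic"], 1)
})

test_that("strand mirror symmetry leaves classification invariant", {
  C <- 200000
  set.seed(17)
  for (rep in 1:20) {
    tss <- sample(30000:170000, 1)
    len <- sample(5000:20000, 1)
    st <- sample(c("+", "-"), 1)
    genes <- data.frame(gene_id = "g", chrom = "chr1", strand = st,
                        tss = tss,
                        tes = if (st == "+") tss + len else tss - len)
    ann <- genome_annotation(c(chr1 = C), genes)
    # mirrored annotation: strand flipped; boundary coordinates map as
    # x -> C - x (half-open convention), point positions as m -> C - 1 - m
    genes_m <- data.frame(gene_id = "g", chrom = "chr1",
                          strand = if (st == "+") "-" else "+",
                          tss = C - tss,
                          tes = C - genes$tes)
    ann_m <- genome_annotation(c(chr1 = C), genes_m)
    m <- sample(0:(C - 2), 50)
    fwd <- classify_genomic_context(make_gr("chr1", m, m + 1), ann)
    rev <- classify_genomic_context(make_gr("chr1", C - 1 - m, C - m), ann_m)
    expect_equal(as.character(fwd$category), as.character(rev$category))
  }
})

# scored-region builder for assignment tests: one region per row
scored_regions <- function(chrom, s, e, flags_list, factor_order = c("G", "N", "P")) {
  gr <- make_gr(chrom, s, e)
  for (i in seq_along(factor_order)) {
    f <- factor_order[i]
    S4Vectors::mcols(gr)[[paste0("flag_", f)]] <-
      vapply(flags_list, `[[`, TRUE, i)
  }
  S4Vectors::mcols(gr)$signature <- vapply(flags_list, function(fl)
    signature_label(stats::setNames(fl, factor_order)), "")
  attr(gr, "factor_order") <- factor_order
  gr
}

test_that("gene assignment respects the inclusive 5 kb midpoint rule", {
  ann <- toy_annotation()   # gplus tss 10000
  # region midpoints exactly 5000 and 5001 bp from the TSS
  at <- function(mid) scored_regions("chr1", mid - 150, mid + 150,
                                     list(c(TRUE, FALSE, FALSE)))
  rec_in <- assign_regions_to_genes(at(15000), ann)
  expect_true("gplus" %in% rec_in$gene_id)
  rec_out <- assign_regions_to_genes(at(15001), ann)
  expect_false("gplus" %in% rec_out$gene_id)
  rec_in2 <- assign_regions_to_genes(at(5000), ann)
  expect_true("gplus" %in% rec_in2$gene_id)
})

test_that("gene flags use union semantics over supporting regions", {
  ann <- toy_annotation()
  regions <- scored_regions("chr1", c(8000, 11000), c(8300, 11300),
                            list(c(TRUE, FALSE, FALSE),
                                 c(FALSE, TRUE, TRUE)))
  rec <- assign_regions_to_genes(regions, ann)
  row <- rec[rec$gene_id == "gplus", ]
  expect_equal(row$signature, "G+N+P+")
  expect_equal(length(strsplit(row$supporting_regions, ",")[[1]]), 2L)
})

test_that("signature tabulation reproduces within-factor percentages", {
  # label counts chosen to mimic a 3-factor study: shares within the
  # G-bound genes must come out to one decimal
  counts <- data.frame(signature = c("G+N+P+", "G+N+P-", "G+N-P+", "G+N-P-"),
                       n = c(4502, 519, 126, 93))
  tab <- tabulate_gene_signatures(counts, factor_order = c("G", "N", "P"))
  expect_equal(unname(tab$factor_totals["G"]), 5240L)
  expect_equal(tab$percent_of_factor["G+N+P+", "G"], 85.9)
  expect_equal(sum(tab$counts$n_genes), 5240L)
  # degenerate case: one label only
  one <- tabulate_gene_signatures(
    data.frame(signature = "G+N+P+", n = 7), factor_order = c("G", "N", "P"))
  expect_equal(unname(one$percent_of_factor["G+N+P+", ]), c(100, 100, 100))
})

test_that("tabulation is invariant to record order and partitions records", {
  set.seed(5)
  labs <- sample(c("G+N+P+", "G+N-P-", "G-N+P-"), 200, replace = TRUE)
  rec <- data.frame(gene_id = paste0("g", 1:200), signature = labs)
  attr(rec, "factor_order") <- c("G", "N", "P")
  t1 <- tabulate_gene_signatures(rec)
  rec2 <- rec[sample(200), ]
  attr(rec2, "factor_order") <- c("G", "N", "P")
  t2 <- tabulate_gene_signatures(rec2)
  expect_equal(t1$counts, t2$counts)
  expect_equal(sum(t1$counts$n_genes), 200L)
})

test_that("DE filtering applies inclusive fold and strict FDR boundaries", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                   fc = c(12.50, 1.5, 2.0, -15.73, -1.49),
                   fdr = c(3.01e-60, 0.01, 0.05, 3.81e-28, 0.001))
  calls <- filter_de_genes(de)
  expect_equal(calls$status, c("up", "up", "NS", "down", "NS"))
  # |FC| < 1 is an ambiguous encoding in signed-linear mode
  expect_error(filter_de_genes(data.frame(gene = "g", fc = 0.5, fdr = 0.01)),
               "magnitude")
  # log2 input converted on read: log2 FC of 1 is a 2-fold change
  lg <- filter_de_genes(data.frame(gene = "g", fc = 1, fdr = 0.01),
                        log2_input = TRUE)
  expect_equal(lg$fold_change, 2)
  expect_equal(lg$status, "up")
})

test_that("DE filtering equals a brute-force row filter on random tables", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 100
    sign <- sample(c(-1, 1), n, replace = TRUE)
    mag <- exp(runif(n, 0, log(30)))
    de <- data.frame(gene = paste0("g", 1:n), fc = sign * pmax(mag, 1),
                     fdr = runif(n))
    calls <- filter_de_genes(de, fc_min = 1.5, fdr_max = 0.05)
    brute <- ifelse(de$fc >= 1.5 & de$fdr < 0.05, "up",
             ifelse(de$fc <= -1.5 & de$fdr < 0.05, "down", "NS"))
    expect_equal(calls$status, brute)
  }
})

test_that("binding-expression crosstab partitions the filtered genes", {
  rec <- data.frame(gene_id = paste0("g", 1:10),
                    signature = rep(c("G+N+P+", "G-N-P-"), each = 5))
  attr(rec, "factor_order") <- c("G", "N", "P")
  calls <- list(
    c1 = data.frame(gene_id = paste0("g", 1:10),
                    fold_change = c(2, -3, 1.1, 2, -2, rep(1.1, 5)),
                    fdr = c(0.001, 0.001, 0.5, 0.01, 0.04, rep(0.9, 5)),
                    status = c("up", "down", "NS", "up", "down", rep("NS", 5))))
  ct <- crosstab_binding_expression(rec, calls, "G+N+P+")
  expect_equal(ct$counts$up + ct$counts$down + ct$counts$NS, 5L)
  expect_equal(ct$counts$up, 2L)
  expect_equal(ct$counts$down, 2L)
  expect_setequal(ct$genes$c1$down, c("g2", "g5"))
  # no DE genes -> everything NS
  none <- crosstab_binding_expression(
    rec, list(c1 = data.frame(gene_id = "g1", fold_change = 1.1,
                              fdr = 0.9, status = "NS")), "G+N+P+")
  expect_equal(none$counts$NS, 5L)
  expect_error(crosstab_binding_expression(rec, calls, "bogus"), "label")
})

test_that("gene binding report renders NS rows and default flags", {
  rec <- data.frame(gene_id = "tg", signature = "G+N+P+",
                    flag_G = TRUE, flag_N = TRUE, flag_P = TRUE)
  attr(rec, "factor_order") <- c("G", "N", "P")
  calls <- list(
    lid = data.frame(gene_id = c("tg", "other"), fold_change = c(1.1, 3),
                     fdr = c(0.9, 0.001), status = c("NS", "up")),
    ko = data.frame(gene_id = c("tg", "other"), fold_change = c(-1.05, 2),
                    fdr = c(0.7, 0.01), status = c("NS", "up")))
  rep_tab <- build_gene_binding_report(rec, calls)
  tg <- rep_tab[rep_tab$gene_id == "tg", ]
  # the "NS NS + + +" pattern: bound but unchanged in both contrasts
  expect_equal(unname(unlist(tg[, c("fc_lid", "fc_ko", "G", "N", "P")])),
               c("NS", "NS", "+", "+", "+"))
  other <- rep_tab[rep_tab$gene_id == "other", ]
  expect_equal(unname(unlist(other[, c("G", "N", "P")])), c("-", "-", "-"))
  # absent subset genes land in the warnings attribute, not the table
  sub <- build_gene_binding_report(rec, calls, gene_subset = c("tg", "ghost"))
  expect_equal(sub$gene_id, "tg")
  expect_equal(attr(sub, "warnings"), "ghost")
  empty <- build_gene_binding_report(rec, calls, gene_subset = character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("over-representation test matches the hypergeometric oracle", {
  universe <- paste0("g", 1:1000)
  query <- paste0("g", 1:50)
  sets <- list(hit = c(paste0("g", 1:30), paste0("g", 500:569)),
               miss = paste0("g", 600:699),
               all = universe)
  res <- overrepresentation_test(query, sets, universe)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$overlap, 30L)
  expect_equal(hit$pvalue, hyper_tail_oracle(30, 100, 900, 50))
  expect_equal(res$pvalue[res$set == "miss"], 1)
  expect_equal(res$pvalue[res$set == "all"], 1)  # P(X >= |query|) = 1
  expect_error(overrepresentation_test(query, sets, character(0)), "universe")
  expect_error(overrepresentation_test("zz", sets, universe), "outside")
})

test_that("GMT parsing returns named gene lists", {
  tf <- withr::local_tempfile()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg9"), tf)
  sets <- read_gmt(tf)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g9")
  writeLines("bad\tonlydesc", tf)
  expect_error(read_gmt(tf), "malformed")
})
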