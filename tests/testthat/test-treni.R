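test_that("novelty is decided by the intron chain and exon containment", {
  ref <- make_tx("ref1", "g1", cbind(c(100, 500, 900), c(200, 600, 1000)), "+", 510)
  same <- make_tx("cand1", "gX", cbind(c(100, 500, 900), c(200, 600, 1000)), "+")
  expect_equal(nrow(find_novel(same, ref)$transcripts), 0)

  extra5 <- make_tx("cand2", "gX", cbind(c(10, 100, 500, 900), c(60, 200, 600, 1000)), "+")
  nov <- find_novel(extra5, ref)
  expect_equal(nov$transcripts$transcript_id, "cand2")
  expect_equal(nov$transcripts$gene_id, "g1")  # attributed by exonic overlap

  mono_in <- make_tx("cand3", "gX", cbind(520, 580), "+")
  expect_equal(nrow(find_novel(mono_in, ref)$transcripts), 0)
  mono_out <- make_tx("cand4", "gX", cbind(700, 800), "+")
  expect_equal(find_novel(mono_out, ref)$transcripts$transcript_id, "cand4")
})

test_that("TRENI calling needs exonic repeat overlap of min_overlap bases", {
  nov <- make_tx("n1", "g1", cbind(c(100, 500), c(200, 600)), "+", is_novel = TRUE)
  rep_in_exon <- data.frame(chrom = "chr1", start = 120L, end = 180L, strand = "+",
                            repeat_name = "r1", family = "Alu", repclass = "SINE")
  expect_equal(call_treni(nov, rep_in_exon)$transcript_id, "n1")

  rep_intron <- transform(rep_in_exon, start = 250L, end = 450L)
  expect_equal(nrow(call_treni(nov, rep_intron)), 0)

  rep_9bp <- transform(rep_in_exon, start = 191L, end = 300L)  # 9 bp in exon
  expect_equal(nrow(call_treni(nov, rep_9bp)), 0)
  rep_10bp <- transform(rep_in_exon, start = 190L, end = 300L)
  expect_equal(call_treni(nov, rep_10bp)$transcript_id, "n1")
  expect_equal(call_treni(nov, rep_10bp)$overlap_bp, 10L)
})

test_that("placement is strand-aware around the start codon", {
  place <- function(rep_start, rep_end, strand) {
    sc <- if (strand == "+") 200L else 200L
    ref <- make_tx("r1", "g1", cbind(c(50, 400), c(300, 500)), strand, sc)
    nov <- make_tx("n1", "g1", cbind(c(50, 400), c(300, 500)), strand, is_novel = TRUE)
    hits <- data.frame(transcript_id = "n1", gene_id = "g1", chrom = "chr1",
                       rep_start = rep_start, rep_end = rep_end,
                       repeat_name = "x", family = "Alu", overlap_bp = 10L,
                       stringsAsFactors = FALSE)
    out <- classify_placement(hits, nov, ref)
    c(utr = out$five_prime_utr, down = out$downstream_of_start)
  }
  expect_equal(place(100, 150, "+"), c(utr = TRUE, down = FALSE))
  expect_equal(place(100, 150, "-"), c(utr = FALSE, down = TRUE))
  expect_equal(place(180, 220, "+"), c(utr = TRUE, down = TRUE))
  expect_equal(place(220, 280, "-"), c(utr = TRUE, down = FALSE))
})

test_that("junction ratio counts spliced support into the nearest exon", {
  ref_ex <- data.frame(start = c(100, 1000), end = c(200, 1100))
  reads <- function(n_junction, n_contained, n_elsewhere = 0) {
    rows <- list()
    for (i in seq_len(n_junction))
      rows[[length(rows) + 1]] <- data.frame(
        read_id = paste0("j", i), chrom = "chr1",
        start = c(150, 500), end = c(200, 550))
    for (i in seq_len(n_contained))
      rows[[length(rows) + 1]] <- data.frame(
        read_id = paste0("c", i), chrom = "chr1", start = 510, end = 560)
    for (i in seq_len(n_elsewhere))
      rows[[length(rows) + 1]] <- data.frame(
        read_id = paste0("e", i), chrom = "chr1", start = 2000, end = 2050)
    do.call(rbind, rows)
  }
  # repeat at [500, 600); nearest exon is [100,200) (gap 300 vs 400)
  expect_equal(junction_ratio(500, 600, ref_ex, "+", reads(20, 0)), 1.0)
  expect_equal(junction_ratio(500, 600, ref_ex, "+", reads(10, 10)), 0.5)
  expect_true(is.na(junction_ratio(500, 600, ref_ex, "+", reads(0, 0, 5))))
  # spliced into the far exon does not count
  far <- data.frame(read_id = "f", chrom = "chr1",
                    start = c(510, 1010), end = c(560, 1060))
  expect_equal(junction_ratio(500, 600, ref_ex, "+", rbind(reads(1, 0), far)), 0.5)
})

test_that("nearest-exon ties break 3'-ward by strand", {
  ref_ex <- data.frame(start = c(100, 900), end = c(200, 1000))
  # repeat [500,600) is 300 bp from both exons
  jplus <- data.frame(read_id = "p", chrom = "chr1",
                      start = c(510, 910), end = c(560, 960))
  expect_equal(junction_ratio(500, 600, ref_ex, "+", jplus), 1.0)
  expect_equal(junction_ratio(500, 600, ref_ex, "-", jplus), 0.0)
  jminus <- data.frame(read_id = "m", chrom = "chr1",
                       start = c(110, 510), end = c(160, 560))
  expect_equal(junction_ratio(500, 600, ref_ex, "-", jminus), 1.0)
})

test_that("JR filter is inclusive at the threshold and drops undefined", {
  hits <- data.frame(transcript_id = c("a", "b", "c"),
                     jr = c(0.9, 0.8999, NA))
  kept <- jr_filter(hits)
  expect_equal(kept$transcript_id, "a")
  expect_true(all(kept$transcript_id %in% hits$transcript_id))
})

test_that("family enrichment reproduces the cross-product odds ratio", {
  # family "F": 30 in TRENIs, 70 out; others: 100 in, 900 out
  reps <- data.frame(
    chrom = "chr1",
    start = seq_len(1100) * 10L, end = seq_len(1100) * 10L + 5L,
    strand = "+", repeat_name = paste0("r", seq_len(1100)),
    family = rep(c("F", "Other"), c(100, 1000)),
    repclass = "x", stringsAsFactors = FALSE)
  in_idx <- c(1:30, 101:200)
  hits <- data.frame(transcript_id = paste0("t", seq_along(in_idx)),
                     gene_id = "g", chrom = "chr1",
                     rep_start = reps$start[in_idx], rep_end = reps$end[in_idx],
                     repeat_name = reps$repeat_name[in_idx],
                     family = reps$family[in_idx], overlap_bp = 5L,
                     stringsAsFactors = FALSE)
  fam <- family_enrichment(reps, hits, min_copies = 20)
  f <- fam[fam$family == "F", ]
  expect_equal(f$in_treni, 30)
  expect_equal(f$odds_ratio, 27 / 7, tolerance = 1e-12)
  expect_true(f$ci_low < 27 / 7 & 27 / 7 < f$ci_high)
  expect_lt(f$chi2_p, 0.001)

  # fewer than min_copies suppresses the OR but keeps the counts
  fam19 <- family_enrichment(reps, hits[c(1:19, 31:130), ], min_copies = 20)
  expect_true(is.na(fam19$odds_ratio[fam19$family == "F"]))
  expect_equal(fam19$in_treni[fam19$family == "F"], 19)

  # independence gives OR = 1
  fam_ind <- family_enrichment(reps, hits[c(1:10, 31:130), ], min_copies = 10)
  expect_equal(fam_ind$odds_ratio[fam_ind$family == "F"], 1)
})

test_that("every repeat copy lands in exactly one family table cell", {
  ann <- simulate_annotation_and_reads(synthetic_config(seed = 12, n_transcripts = 30))
  nov <- find_novel(ann$transcripts, ref_of(ann))
  hits <- call_treni(nov, ann$repeats)
  fam <- family_enrichment(ann$repeats, hits, min_copies = 1)
  per_family <- fam$in_treni + fam$out_treni
  expect_equal(sum(per_family), nrow(ann$repeats))
  expect_true(all(fam$in_treni + fam$out_treni + fam$other_in + fam$other_out ==
                    nrow(ann$repeats)))
})

test_that("synthetic TRENI truth is recovered exactly with junction ratios", {
  cfg <- synthetic_config(seed = 13, n_transcripts = 40)
  ann <- simulate_annotation_and_reads(cfg)
  ref <- ref_of(ann)
  nov <- find_novel(ann$transcripts, ref)
  expect_setequal(nov$transcripts$transcript_id, ann$truth$novel)
  hits <- add_junction_ratios(
    classify_placement(call_treni(nov, ann$repeats), nov, ref), ref, ann$reads)
  truth <- ann$truth$treni
  expect_setequal(hits$transcript_id, truth$transcript_id)
  m <- merge(hits, truth, by = "transcript_id")
  got <- ifelse(m$five_prime_utr & !m$downstream_of_start, "five_prime_utr",
                "downstream_of_start")
  expect_equal(got, m$placement)
  expect_true(all(abs(m$jr - m$true_jr) <= 1 / cfg$reads_per_repeat))
  # JR numerator never exceeds the denominator
  expect_true(all(m$jr >= 0 & m$jr <= 1))
})

test_that("5' UTR enrichment restricts the in-TRENI set", {
  ann <- simulate_annotation_and_reads(synthetic_config(seed = 14, n_transcripts = 40))
  ref <- ref_of(ann)
  nov <- find_novel(ann$transcripts, ref)
  hits <- classify_placement(call_treni(nov, ann$repeats), nov, ref)
  fam_all <- family_enrichment(ann$repeats, hits, min_copies = 1)
  fam_utr <- utr_family_enrichment(ann$repeats, hits, min_copies = 1)
  expect_equal(sum(fam_utr$in_treni), sum(hits$five_prime_utr))
  expect_lte(sum(fam_utr$in_treni), sum(fam_all$in_treni))
})

test_that("TRENI lineage testing delegates to the gene-level machinery", {
  cfg <- synthetic_config(seed = 15, n_genes = 200)
  sim <- simulate_cells_and_expression(cfg)
  renamed <- sim$fpkm
  rownames(renamed) <- sprintf("TRENI_%04d", seq_len(nrow(renamed)))
  out <- treni_lineage_tests(renamed, sim$cells, "four_cell", seed = 3)
  direct <- lineage_tests(sim$fpkm, sim$cells, "four_cell")
  expect_equal(out$tests$q, direct$q)
  expect_equal(out$tests$p, direct$p)
  expect_error(treni_lineage_tests(sim$fpkm[0, ], sim$cells, "four_cell"),
               "empty")
})

test_that("planted TRENI effects separate from the shuffled background", {
  wins <- 0
  for (s in 1:5) {
    cfg <- synthetic_config(seed = 50 + s, n_genes = 300,
                            frac_lineage_genes = 0.1, lineage_effect = 2)
    sim <- simulate_cells_and_expression(cfg)
    out <- treni_lineage_tests(sim$fpkm, sim$cells, "four_cell", seed = s)
    if (out$comparison$n_real_below > 0 && out$comparison$n_shuffled_below == 0)
      wins <- wins + 1
  }
  expect_gte(wins, 4)
})
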