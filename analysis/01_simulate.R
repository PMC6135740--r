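#!/usr/bin/env Rscript
# Generate every input the workflow consumes: blastomere metadata and FPKM,
# blastocyst imaging counts, and the transcript/repeat/read fixtures for
# isoform calling. All downstream steps read only the files written here.
suppressMessages(library(lineageseq))

seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L
dir.create("results/synthetic", showWarnings = FALSE, recursive = TRUE)
cfg <- synthetic_config(seed = seed)

sim <- simulate_cells_and_expression(cfg)
write_cells(sim$cells, "results/synthetic/cells_truth.tsv")
write_matrix(sim$fpkm, "results/synthetic/fpkm.tsv")
write.table(sim$truth, "results/synthetic/planted_genes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cells: %d (%d four-cell, %d eight-cell embryos); genes: %d (%d planted)\n",
            nrow(sim$cells), cfg$n_embryos_4cell, cfg$n_embryos_8cell,
            nrow(sim$fpkm), sum(sim$truth$planted)))

img <- simulate_image_counts(cfg)
write_image_counts(img$counts, "results/synthetic/image_counts.tsv")
write.table(img$truth, "results/synthetic/image_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("imaged blastocysts: %d (%d generated pole-biased)\n",
            nrow(img$counts), sum(img$truth$unbalanced)))

ann <- simulate_annotation_and_reads(cfg)
tx <- ann$transcripts$transcripts
ref <- transcript_set(tx[!tx$is_novel, , drop = FALSE],
                      ann$transcripts$exons[ann$transcripts$exons$transcript_id %in%
                                              tx$transcript_id[!tx$is_novel], ])
write_gtf(ref, "results/synthetic/annotation.gtf")
write_gtf(ann$transcripts, "results/synthetic/assembled.gtf")
rep_bed <- sprintf("%s\t%d\t%d\t%s#%s/%s\t0\t%s",
                   ann$repeats$chrom, ann$repeats$start, ann$repeats$end,
                   ann$repeats$repeat_name, ann$repeats$family,
                   ann$repeats$repclass, ann$repeats$strand)
writeLines(rep_bed, "results/synthetic/repeats.bed")
write_read_blocks(ann$reads, "results/synthetic/reads.bed")
write.table(ann$truth$treni, "results/synthetic/treni_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(ann$truth$novel, "results/synthetic/novel_truth.txt")
cat(sprintf("transcripts: %d reference + %d novel; repeats: %d; spliced/contained reads: %d\n",
            sum(!tx$is_novel), sum(tx$is_novel), nrow(ann$repeats),
            length(unique(ann$reads$read_id))))
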