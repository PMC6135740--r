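# Small in-code fixture builders shared across test files.

# one embryo's worth of cells with explicit marker counts
make_embryo_cells <- function(embryo = "E1", stage = "four_cell",
                              markers = list(c(GFP = 50), c(GFP = 50),
                                             c(RFP = 50), c(RFP = 50)),
                              pairs = 5e6) {
  n <- length(markers)
  counts <- t(vapply(markers, function(m) {
    v <- c(GFP = 0, CFP = 0, RFP = 0, YFP = 0)
    v[names(m)] <- m
    v
  }, numeric(4)))
  cell_table(cell_id = paste0(embryo, "_c", seq_len(n)),
             embryo_id = embryo, stage = stage,
             GFP = counts[, "GFP"], CFP = counts[, "CFP"],
             RFP = counts[, "RFP"], YFP = counts[, "YFP"],
             uniquely_mapped_pairs = pairs)
}

# balanced nested design: E embryos x 2 lineages x n_per cells
make_design <- function(E = 4, n_per = 2) {
  embryo <- rep(sprintf("E%02d", seq_len(E)), each = 2 * n_per)
  lineage <- rep(rep(c("A", "B"), each = n_per), times = E)
  list(embryo = embryo, lineage = lineage, n = E * 2 * n_per)
}

# one imaging-count row from explicit per-marker 2x2 tables
make_image_row <- function(id = "IMG_1",
                           gfp = c(5, 5, 5, 5), rfp = c(5, 5, 5, 5)) {
  validate_image_counts(data.frame(
    embryo_id = id, total_cells = sum(gfp),
    gfp_pos_emb = gfp[1], gfp_neg_emb = gfp[2],
    gfp_pos_abem = gfp[3], gfp_neg_abem = gfp[4],
    rfp_pos_emb = rfp[1], rfp_neg_emb = rfp[2],
    rfp_pos_abem = rfp[3], rfp_neg_abem = rfp[4],
    stringsAsFactors = FALSE))
}

# minimal transcript set: one transcript from an exon matrix
make_tx <- function(id, gene, exons, strand = "+", start_codon = NA,
                    chrom = "chr1", is_novel = FALSE) {
  transcript_set(
    data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
               strand = strand, start_codon = start_codon, is_novel = is_novel,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = id, start = exons[, 1], end = exons[, 2]))
}

# combine transcript sets
bind_tx <- function(...) {
  sets <- list(...)
  transcript_set(do.call(rbind, lapply(sets, `[[`, "transcripts")),
                 do.call(rbind, lapply(sets, `[[`, "exons")))
}

# reference subset of a simulated annotation
ref_of <- function(ann) {
  tx <- ann$transcripts$transcripts
  transcript_set(tx[!tx$is_novel, , drop = FALSE],
                 ann$transcripts$exons[ann$transcripts$exons$transcript_id %in%
                                         tx$transcript_id[!tx$is_novel], , drop = FALSE])
}
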