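test_that("GTF reading converts 1-based closed to 0-based half-open and groups exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tstart_codon\t311\t313\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  ts <- read_gtf(gtf)
  expect_equal(nrow(ts$transcripts), 1)
  ex <- ts$exons
  expect_equal(ex$start, c(100L, 300L))
  expect_equal(ex$end, c(200L, 400L))
  expect_equal(ts$transcripts$start_codon, 310L)
})

test_that("GTF reader handles minus-strand start codons, empty files and errors", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t300\t.\t-\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tstart_codon\t198\t200\t.\t-\t.\tgene_id "g1"; transcript_id "t1";'),
    gtf)
  ts <- read_gtf(gtf)
  # first transcribed base of the codon is its highest coordinate on "-"
  expect_equal(ts$transcripts$start_codon, 199L)

  writeLines(character(0), gtf)
  expect_equal(nrow(read_gtf(gtf)$transcripts), 0)

  writeLines("chr1 only three fields", gtf)
  expect_error(read_gtf(gtf), "line 1")

  writeLines('chr1\tsrc\tstart_codon\t198\t200\t.\t-\t.\tgene_id "g"; transcript_id "t";',
             gtf)
  expect_error(read_gtf(gtf), "zero exons")
})

test_that("GTF write -> read round-trip preserves genomic spans", {
  ts <- bind_tx(
    make_tx("t1", "g1", cbind(c(100, 500), c(250, 800)), "+", start_codon = 510),
    make_tx("t2", "g2", cbind(2000, 2500), "-"))
  path <- tempfile(fileext = ".gtf")
  write_gtf(ts, path)
  back <- read_gtf(path)
  expect_equal(back$exons[c("transcript_id", "start", "end")],
               ts$exons[c("transcript_id", "start", "end")])
  expect_equal(back$transcripts$start_codon, ts$transcripts$start_codon)
})

test_that("RepeatMasker .out records convert coordinates and parse families", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat  class/family",
    "",
    "  463   1.3  0.6  1.7  chr1      101   200  (1000) +  B1_Mus   SINE/Alu    1 100 (5) 1",
    "  463   1.3  0.6  1.7  chr1      301   350  (1000) C  MIR3     SINE/MIR    1  50 (5) 2"),
    out)
  reps <- read_repeatmasker(out)
  expect_equal(reps$start, c(100L, 300L))
  expect_equal(reps$end, c(200L, 350L))
  expect_equal(reps$family, c("Alu", "MIR"))
  expect_equal(reps$repclass, c("SINE", "SINE"))
  expect_equal(reps$strand, c("+", "-"))
})

test_that("RepeatMasker BED input parses name#family/class; header-only gives empty", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tB1_Mus#Alu/SINE\t0\t+", bed)
  reps <- read_repeatmasker(bed)
  expect_equal(reps$family, "Alu")
  expect_equal(reps$repeat_name, "B1_Mus")
  expect_equal(reps$repclass, "SINE")

  out <- tempfile(fileext = ".out")
  writeLines(c("   SW   perc ...", "score   div. ..."), out)
  expect_equal(nrow(read_repeatmasker(out)), 0)
})

test_that("matrix, cell and image-count TSVs round-trip and reject bad input", {
  m <- matrix(runif(9), 3, dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  p <- tempfile(fileext = ".tsv")
  write_matrix(m, p)
  expect_equal(read_matrix(p), m)

  bad <- rbind(m, m[1, , drop = FALSE])
  expect_error(write_matrix(bad, p), "duplicate")
  m2 <- m; m2[1, 1] <- -1
  expect_error(write_matrix(m2, p), "negative")

  cells <- make_embryo_cells()
  write_cells(cells, p)
  back <- read_cells(p)
  expect_equal(back$cell_id, cells$cell_id)
  expect_equal(back$GFP, cells$GFP)

  img <- make_image_row()
  write_image_counts(img, p)
  expect_equal(read_image_counts(p), img)
  img$gfp_pos_emb <- img$gfp_pos_emb + 1
  expect_error(validate_image_counts(img), "sum")
})

test_that("BED12 blocks become read blocks", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t1200\tread1\t0\t+\t100\t1200\t0\t2\t50,50,\t0,1050,", bed)
  rb <- read_read_blocks(bed)
  expect_equal(nrow(rb), 2)
  expect_equal(rb$start, c(100L, 1150L))
  expect_equal(rb$end, c(150L, 1200L))
  # round-trip through the BED12 writer
  p2 <- tempfile(fileext = ".bed")
  write_read_blocks(rb, p2)
  expect_equal(read_read_blocks(p2), rb)
})

test_that("BAM N-gapped CIGAR splits into blocks", {
  # CIGAR 50M1000N50M at 0-based position 100 -> blocks [100,150), [1150,1200)
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:2000000",
    paste("r1", 0, "chr1", 101, 255, "50M1000N50M", "*", 0, 0,
          paste(rep("A", 100), collapse = ""),
          paste(rep("I", 100), collapse = ""), sep = "\t")),
    sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  rb <- read_read_blocks(bam)
  expect_equal(rb$read_id, c("r1", "r1"))
  expect_equal(rb$start, c(100L, 1150L))
  expect_equal(rb$end, c(150L, 1200L))
})

test_that("no degenerate interval survives any reader or validator", {
  expect_error(validate_read_blocks(
    data.frame(read_id = "r", chrom = "chr1", start = 10L, end = 10L)), "empty")
  expect_error(validate_repeats(
    data.frame(chrom = "chr1", start = 5L, end = 5L, strand = "+",
               repeat_name = "x", family = "f", repclass = "c")), "empty")
  expect_error(make_tx("t", "g", cbind(100, 100)), "empty|inverted")
  # generated fixtures all carry strictly positive widths
  ann <- simulate_annotation_and_reads(synthetic_config(seed = 3, n_transcripts = 20))
  expect_true(all(ann$transcripts$exons$end > ann$transcripts$exons$start))
  expect_true(all(ann$repeats$end > ann$repeats$start))
  expect_true(all(ann$reads$end > ann$reads$start))
})
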