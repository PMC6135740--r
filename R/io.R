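#' @title Readers and writers for the external formats
#' @description GTF and RepeatMasker .out are 1-based closed on disk and are
#' converted to 0-based half-open at read time; this is the single conversion
#' point in the package. TSV is the canonical exchange format for matrices
#' and metadata; BED12 or BAM carries spliced-read blocks.
#' @name io
NULL

#' Read transcript models from a GTF file
#'
#' Parses \code{exon} and \code{start_codon} features, groups them by
#' \code{transcript_id}, converts coordinates to 0-based half-open and sorts
#' exons by start. The start codon is stored as the genomic coordinate of its
#' first transcribed base (its highest coordinate on the minus strand).
#'
#' @param path GTF file with 1-based closed coordinates and
#'   \code{transcript_id}/\code{gene_id} attributes.
#' @return a [transcript_set()] with \code{is_novel = FALSE}.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  tx_id <- ge_id <- chrom <- strand <- character(0)
  feat <- character(0); start <- end <- integer(0)
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GTF record at line ", i, ": expected 9 tab-separated fields")
    if (!f[3] %in% c("exon", "start_codon")) next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("malformed GTF coordinates at line ", i)
    tid <- sub('.*transcript_id "([^"]+)".*', "\\1", f[9])
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", f[9])
    if (identical(tid, f[9]))
      stop("missing transcript_id attribute at line ", i)
    if (identical(gid, f[9])) gid <- NA_character_
    tx_id <- c(tx_id, tid); ge_id <- c(ge_id, gid)
    chrom <- c(chrom, f[1]); strand <- c(strand, f[7]); feat <- c(feat, f[3])
    start <- c(start, s - 1L); end <- c(end, e)  # 1-based closed -> 0-based half-open
  }
  if (!length(tx_id))
    return(transcript_set(
      data.frame(transcript_id = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 start_codon = integer(0), is_novel = logical(0)),
      data.frame(transcript_id = character(0), start = integer(0), end = integer(0))))
  recs <- data.frame(tx_id, ge_id, chrom, strand, feat, start, end,
                     stringsAsFactors = FALSE)
  ids <- unique(recs$tx_id)
  tx <- do.call(rbind, lapply(ids, function(tid) {
    r <- recs[recs$tx_id == tid, , drop = FALSE]
    ex <- r[r$feat == "exon", , drop = FALSE]
    if (nrow(ex) == 0) stop("transcript with zero exons: ", tid)
    sc <- r[r$feat == "start_codon", , drop = FALSE]
    sc_pos <- if (nrow(sc) == 0) NA_integer_ else
      if (sc$strand[1] == "-") sc$end[1] - 1L else sc$start[1]
    gid <- ex$ge_id[1]
    data.frame(transcript_id = tid,
               gene_id = if (is.na(gid)) tid else gid,
               chrom = ex$chrom[1], strand = ex$strand[1],
               start_codon = sc_pos, is_novel = FALSE,
               stringsAsFactors = FALSE)
  }))
  exons <- recs[recs$feat == "exon", c("tx_id", "start", "end")]
  names(exons)[1] <- "transcript_id"
  transcript_set(tx, exons)
}

#' Write a transcript set as GTF (exon and start_codon features)
#' @param ts a [transcript_set()].
#' @param path output file.
#' @export
write_gtf <- function(ts, path) {
  out <- character(0)
  for (i in seq_len(nrow(ts$transcripts))) {
    t <- ts$transcripts[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene_id, t$transcript_id)
    ex <- ts$exons[ts$exons$transcript_id == t$transcript_id, , drop = FALSE]
    out <- c(out, sprintf("%s\tlineageseq\texon\t%d\t%d\t.\t%s\t.\t%s",
                          t$chrom, ex$start + 1L, ex$end, t$strand, attrs))
    if (!is.na(t$start_codon)) {
      sc0 <- if (t$strand == "-") t$start_codon - 2L else t$start_codon
      out <- c(out, sprintf("%s\tlineageseq\tstart_codon\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, sc0 + 1L, sc0 + 3L, t$strand, attrs))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read repeat annotations (RepeatMasker .out or BED6)
#'
#' The RepeatMasker \code{.out} layout is header lines followed by
#' whitespace-delimited records whose repeat class/family field reads
#' \code{class/family} (e.g. \code{SINE/Alu}); families without a class keep
#' the whole token as both. BED6 input expects the name field as
#' \code{name#family/class}.
#'
#' @param path input file; format detected from content unless given.
#' @param format \code{"auto"}, \code{"out"} or \code{"bed"}.
#' @return data.frame as validated by [validate_repeats()].
#' @export
read_repeatmasker <- function(path, format = c("auto", "out", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (is.na(first)) "out"
      else if (grepl("^\\s*(SW|score)", first) || grepl("^\\s*\\d+\\s+\\d+\\.", first)) "out"
      else "bed"
  }
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), repeat_name = character(0),
                      family = character(0), repclass = character(0))
  if (format == "out") {
    body <- which(grepl("^\\s*\\d+\\s", lines))
    if (!length(body)) return(empty)
    recs <- lapply(body, function(i) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 11)
        stop("unparseable RepeatMasker record at line ", i)
      s <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
      if (is.na(s) || is.na(e))
        stop("unparseable RepeatMasker coordinates at line ", i)
      cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
      data.frame(chrom = f[5], start = s - 1L, end = e,
                 strand = if (f[9] == "C") "-" else "+",
                 repeat_name = f[10],
                 family = if (length(cf) > 1) cf[2] else cf[1],
                 repclass = cf[1], stringsAsFactors = FALSE)
    })
    return(validate_repeats(do.call(rbind, recs)))
  }
  body <- which(!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines)))
  if (!length(body)) return(empty)
  recs <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) stop("unparseable BED record at line ", i)
    nm <- strsplit(f[4], "#", fixed = TRUE)[[1]]
    fc <- if (length(nm) > 1) strsplit(nm[2], "/", fixed = TRUE)[[1]] else c(NA, NA)
    data.frame(chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
               strand = if (length(f) >= 6) f[6] else "+",
               repeat_name = nm[1],
               family = fc[1],
               repclass = if (length(fc) > 1) fc[2] else fc[1],
               stringsAsFactors = FALSE)
  })
  validate_repeats(do.call(rbind, recs))
}

#' Read / write a gene-by-cell matrix as TSV
#'
#' First column holds gene ids; remaining columns are cells. Write followed by
#' read is the identity.
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  validate_matrix(mat)
  mat
}

#' @rdname read_matrix
#' @param mat numeric matrix with dimnames.
#' @export
write_matrix <- function(mat, path) {
  validate_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the cell metadata table as TSV
#' @param path TSV file with the columns of [cell_table()].
#' @export
read_cells <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cells(df)
}

#' @rdname read_cells
#' @param cells a validated cell table.
#' @export
write_cells <- function(cells, path) {
  validate_cells(cells)
  utils::write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write per-embryo imaging counts as TSV
#' @param path TSV file with the columns of [validate_image_counts()].
#' @export
read_image_counts <- function(path) {
  validate_image_counts(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_image_counts
#' @param counts validated imaging-count table.
#' @export
write_image_counts <- function(counts, path) {
  validate_image_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spliced-alignment blocks from BED12 or BAM
#'
#' BED12 block fields define the blocks directly; for BAM, \code{N} CIGAR
#' operations split the alignment into blocks (via
#' \code{GenomicAlignments::grglist}).
#'
#' @param path a \code{.bed} or \code{.bam} file.
#' @return long-format block table as validated by [validate_read_blocks()].
#' @export
read_read_blocks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") {
    ga <- GenomicAlignments::readGAlignments(path, use.names = TRUE)
    grl <- GenomicAlignments::grglist(ga)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(gr$blocks)) {
      grl <- rtracklayer::blocks(gr)
    } else {
      grl <- GenomicRanges::split(gr, seq_along(gr))
      names(grl) <- gr$name
    }
    if (!is.null(gr$name)) names(grl) <- gr$name
  }
  flat <- unlist(grl, use.names = FALSE)
  reads <- data.frame(
    read_id = rep(names(grl), lengths(grl)),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    stringsAsFactors = FALSE)
  validate_read_blocks(reads)
}

#' Write read blocks as BED12
#' @param reads validated block table.
#' @param path output \code{.bed} file.
#' @export
write_read_blocks <- function(reads, path) {
  validate_read_blocks(reads)
  ids <- unique(reads$read_id)
  out <- vapply(ids, function(id) {
    b <- reads[reads$read_id == id, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    chromStart <- b$start[1]; chromEnd <- b$end[nrow(b)]
    sizes <- paste(b$end - b$start, collapse = ",")
    starts <- paste(b$start - chromStart, collapse = ",")
    sprintf("%s\t%d\t%d\t%s\t0\t+\t%d\t%d\t0\t%d\t%s,\t%s,",
            b$chrom[1], chromStart, chromEnd, id, chromStart, chromEnd,
            nrow(b), sizes, starts)
  }, character(1))
  writeLines(out, path)
  invisible(path)
}
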