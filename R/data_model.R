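#' @title Domain containers and validators
#' @description
#' All tabular objects in this package are plain data frames with fixed column
#' sets, validated on construction and on read. Genomic intervals are 0-based
#' half-open everywhere inside the package; conversion from 1-based closed
#' formats (GTF, RepeatMasker .out) happens exactly once, in the readers.
#' @name data_model
NULL

#' The four Brainbow lineage markers, in the alphabetical order used to break
#' the A/B labelling tie.
#' @export
BRAINBOW_MARKERS <- c("CFP", "GFP", "RFP", "YFP")

CELL_COLUMNS <- c("cell_id", "embryo_id", "stage",
                  "GFP", "CFP", "RFP", "YFP",
                  "uniquely_mapped_pairs", "lineage")

STAGES <- c("four_cell", "eight_cell")
LINEAGES <- c("A", "B", "unresolved")

#' Build a validated table of blastomere records
#'
#' One row per cell: embryo membership, developmental stage, read counts
#' mapped to each of the four Brainbow marker genes, the uniquely mapped
#' read-pair total used for QC, and the lineage call (initially
#' \code{"unresolved"}).
#'
#' @param cell_id,embryo_id character vectors.
#' @param stage \code{"four_cell"} or \code{"eight_cell"}.
#' @param GFP,CFP,RFP,YFP non-negative integer marker read counts.
#' @param uniquely_mapped_pairs non-negative integers.
#' @param lineage \code{"A"}, \code{"B"} or \code{"unresolved"}.
#' @return data.frame of class \code{cell_table}.
#' @export
cell_table <- function(cell_id, embryo_id, stage,
                       GFP = 0L, CFP = 0L, RFP = 0L, YFP = 0L,
                       uniquely_mapped_pairs = 0,
                       lineage = "unresolved") {
  df <- data.frame(cell_id = as.character(cell_id),
                   embryo_id = as.character(embryo_id),
                   stage = as.character(stage),
                   GFP = GFP, CFP = CFP, RFP = RFP, YFP = YFP,
                   uniquely_mapped_pairs = as.numeric(uniquely_mapped_pairs),
                   lineage = as.character(lineage),
                   stringsAsFactors = FALSE)
  validate_cells(df)
}

#' Validate a cell table
#' @param cells data.frame with the columns of [cell_table()].
#' @return the validated data.frame (invisibly classed \code{cell_table}).
#' @export
validate_cells <- function(cells) {
  missing <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing))
    stop("cell table missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id in cell table")
  if (!all(cells$stage %in% STAGES))
    stop("stage must be one of: ", paste(STAGES, collapse = ", "))
  if (!all(cells$lineage %in% LINEAGES))
    stop("lineage must be one of: ", paste(LINEAGES, collapse = ", "))
  for (m in BRAINBOW_MARKERS) {
    v <- cells[[m]]
    if (any(is.na(v)) || any(v < 0)) stop("negative or missing ", m, " counts")
  }
  if (any(cells$uniquely_mapped_pairs < 0))
    stop("negative uniquely_mapped_pairs")
  class(cells) <- unique(c("cell_table", class(cells)))
  cells
}

#' Validate a gene-by-cell FPKM matrix
#'
#' @param mat numeric matrix, genes in rows, cells in columns, with unique
#'   dimnames and no negative entries.
#' @param cells optional cell table; column names must be a subset of its
#'   \code{cell_id}s.
#' @return the matrix, invisibly.
#' @export
validate_matrix <- function(mat, cells = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene and cell dimnames")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate cell ids")
  if (any(mat < 0)) stop("negative FPKM values")
  if (!is.null(cells) && !all(colnames(mat) %in% cells$cell_id))
    stop("matrix columns not present in cell table")
  invisible(mat)
}

IMAGE_COUNT_COLUMNS <- c("embryo_id", "total_cells",
                         "gfp_pos_emb", "gfp_neg_emb", "gfp_pos_abem", "gfp_neg_abem",
                         "rfp_pos_emb", "rfp_neg_emb", "rfp_pos_abem", "rfp_neg_abem")

#' Validate per-embryo imaging counts
#'
#' One row per blastocyst: marker-positive and marker-negative cell counts in
#' the embryonic and abembryonic poles, for GFP and RFP (the two imageable
#' channels). For each marker the four cells must sum to \code{total_cells}.
#'
#' @param counts data.frame with columns \code{embryo_id}, \code{total_cells}
#'   and, per marker \code{gfp}/\code{rfp}:
#'   \code{<m>_pos_emb}, \code{<m>_neg_emb}, \code{<m>_pos_abem},
#'   \code{<m>_neg_abem}.
#' @return the validated data.frame.
#' @export
validate_image_counts <- function(counts) {
  missing <- setdiff(IMAGE_COUNT_COLUMNS, names(counts))
  if (length(missing))
    stop("image counts missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(counts$embryo_id)) stop("duplicate embryo_id")
  num <- counts[setdiff(IMAGE_COUNT_COLUMNS, "embryo_id")]
  if (any(as.matrix(num) < 0)) stop("negative counts")
  for (m in c("gfp", "rfp")) {
    tot <- counts[[paste0(m, "_pos_emb")]] + counts[[paste0(m, "_neg_emb")]] +
      counts[[paste0(m, "_pos_abem")]] + counts[[paste0(m, "_neg_abem")]]
    if (any(tot != counts$total_cells))
      stop(m, " counts do not sum to total_cells for embryo(s): ",
           paste(counts$embryo_id[tot != counts$total_cells], collapse = ", "))
  }
  counts
}

#' Construct an exon-structured transcript set
#'
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{start_codon} (0-based genomic coordinate of the first transcribed
#'   base of the start codon, \code{NA} if unknown) and \code{is_novel}.
#' @param exons data.frame with columns \code{transcript_id}, \code{start},
#'   \code{end}; intervals 0-based half-open, sorted and non-overlapping
#'   within each transcript.
#' @return list of class \code{transcript_set} with elements
#'   \code{transcripts} and \code{exons}.
#' @export
transcript_set <- function(transcripts, exons) {
  need_t <- c("transcript_id", "gene_id", "chrom", "strand", "start_codon", "is_novel")
  need_e <- c("transcript_id", "start", "end")
  if (!all(need_t %in% names(transcripts)))
    stop("transcripts needs columns: ", paste(need_t, collapse = ", "))
  if (!all(need_e %in% names(exons)))
    stop("exons needs columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript_id")
  if (!all(transcripts$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan)) stop("exons for unknown transcript(s): ", paste(orphan, collapse = ", "))
  bare <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(bare)) stop("transcript(s) with zero exons: ", paste(bare, collapse = ", "))
  # sort exons within transcript, check non-overlap and start-codon containment
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$transcript_id[i]
    idx <- by_tx[[tx]]
    s <- exons$start[idx]; e <- exons$end[idx]
    if (length(idx) > 1 && any(s[-1] < e[-length(e)]))
      stop("overlapping exons in transcript ", tx)
    sc <- transcripts$start_codon[i]
    if (!is.na(sc) && !any(sc >= s & sc < e))
      stop("start_codon outside exons in transcript ", tx)
  }
  structure(list(transcripts = transcripts, exons = exons),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$is_novel), "novel ),", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Validate a repeat annotation table
#'
#' @param repeats data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{repeat_name},
#'   \code{family}, \code{repclass}. Strand is recorded but ignored by all
#'   overlap computations.
#' @return the validated data.frame.
#' @export
validate_repeats <- function(repeats) {
  need <- c("chrom", "start", "end", "strand", "repeat_name", "family", "repclass")
  if (!all(need %in% names(repeats)))
    stop("repeat table needs columns: ", paste(need, collapse = ", "))
  if (nrow(repeats) && any(repeats$end <= repeats$start))
    stop("empty repeat interval")
  repeats
}

#' Validate spliced-read alignment blocks
#'
#' Long format: one row per aligned block, grouped by \code{read_id}. A read
#' with two or more blocks is a spliced (junction-capable) alignment.
#'
#' @param reads data.frame with columns \code{read_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open; sorted and disjoint within
#'   a read).
#' @return the validated data.frame.
#' @export
validate_read_blocks <- function(reads) {
  need <- c("read_id", "chrom", "start", "end")
  if (!all(need %in% names(reads)))
    stop("read blocks need columns: ", paste(need, collapse = ", "))
  if (nrow(reads) == 0) return(reads)
  if (any(reads$end <= reads$start)) stop("empty read block interval")
  ord <- order(reads$read_id, reads$start)
  r <- reads[ord, , drop = FALSE]
  same <- r$read_id[-1] == r$read_id[-nrow(r)]
  if (any(same & r$start[-1] < r$end[-nrow(r)]))
    stop("overlapping blocks within a read")
  chroms <- tapply(reads$chrom, reads$read_id, function(x) length(unique(x)))
  if (any(chroms > 1)) stop("read with blocks on multiple chromosomes")
  reads
}
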