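#' @title Marker calling, lineage assignment and QC
#' @description
#' Reads mapped to the Brainbow marker genes identify which lineage marker a
#' blastomere expresses; cells of each embryo are then partitioned into the
#' two cell-division lineages A and B. Standard quality filters: cells need 3
#' million uniquely mapped read pairs, and genes count as expressed at
#' FPKM > 1.
#' @name lineage_assignment
NULL

#' Call the expressed Brainbow marker of one cell
#'
#' A marker is called when its read count reaches \code{min_reads} and
#' dominates every other marker at least five-fold; otherwise the cell is
#' uncallable. The dominance rule guards against ambient reads and index
#' hopping.
#'
#' @param marker_reads named non-negative counts for GFP, CFP, RFP, YFP.
#' @param min_reads minimum reads on the winning marker.
#' @return marker name, or \code{NA_character_} when no unique marker
#'   qualifies.
#' @export
call_marker <- function(marker_reads, min_reads = 10) {
  if (!all(BRAINBOW_MARKERS %in% names(marker_reads)))
    stop("marker_reads must be named with the four markers")
  v <- as.numeric(marker_reads[BRAINBOW_MARKERS])
  if (any(is.na(v)) || any(v < 0)) stop("negative or missing marker counts")
  ok <- vapply(seq_along(v), function(i)
    v[i] >= min_reads && v[i] >= 5 * max(v[-i]), logical(1))
  if (sum(ok) == 1) BRAINBOW_MARKERS[ok] else NA_character_
}

#' Partition one embryo's cells into lineages A and B
#'
#' Markers are called per cell; when exactly two distinct markers are seen in
#' the embryo, cells carrying the alphabetically smaller marker become
#' lineage A and the other marker lineage B (a fixed convention — the labels
#' are arbitrary per embryo). Cells with no marker call stay unresolved, and
#' if fewer or more than two markers are seen the whole embryo is
#' unresolved.
#'
#' @param cells cell table rows sharing one \code{embryo_id}.
#' @param min_reads passed to [call_marker()].
#' @return the cells with the \code{lineage} column set.
#' @export
assign_lineages <- function(cells, min_reads = 10) {
  if (nrow(cells) == 0) stop("assign_lineages: empty input")
  if (length(unique(cells$embryo_id)) != 1)
    stop("assign_lineages expects the cells of a single embryo")
  calls <- vapply(seq_len(nrow(cells)), function(i)
    call_marker(unlist(cells[i, BRAINBOW_MARKERS]), min_reads), character(1))
  seen <- sort(unique(calls[!is.na(calls)]))
  if (length(seen) == 2) {
    cells$lineage <- ifelse(is.na(calls), "unresolved",
                            ifelse(calls == seen[1], "A", "B"))
  } else {
    cells$lineage <- "unresolved"
  }
  cells
}

#' @rdname assign_lineages
#' @param all_cells a cell table possibly spanning many embryos.
#' @export
assign_lineages_all <- function(all_cells, min_reads = 10) {
  validate_cells(all_cells)
  parts <- lapply(split(seq_len(nrow(all_cells)), all_cells$embryo_id),
                  function(idx) assign_lineages(all_cells[idx, , drop = FALSE], min_reads))
  out <- do.call(rbind, parts)
  out <- out[match(all_cells$cell_id, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  validate_cells(out)
}

#' Quality-control filter on uniquely mapped read pairs
#'
#' Cells producing fewer than \code{min_pairs} uniquely mapped read pairs are
#' dropped; exactly \code{min_pairs} is kept.
#'
#' @param cells cell table.
#' @param min_pairs inclusive threshold, default 3 million.
#' @return list with elements \code{kept} and \code{dropped}.
#' @export
qc_filter <- function(cells, min_pairs = 3e6) {
  keep <- cells$uniquely_mapped_pairs >= min_pairs
  list(kept = cells[keep, , drop = FALSE],
       dropped = cells[!keep, , drop = FALSE])
}

#' Count expressed genes per cell and their per-stage union
#'
#' A gene is expressed in a cell iff its FPKM strictly exceeds
#' \code{threshold}.
#'
#' @param mat gene-by-cell FPKM matrix (already subset to one stage).
#' @param threshold FPKM cutoff, default 1 (strict).
#' @return list with \code{per_cell} (named expressed-gene counts) and
#'   \code{n_union} (genes expressed in at least one cell).
#' @export
call_expressed_genes <- function(mat, threshold = 1.0) {
  validate_matrix(mat)
  expressed <- mat > threshold
  list(per_cell = colSums(expressed), n_union = sum(rowSums(expressed) > 0))
}
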