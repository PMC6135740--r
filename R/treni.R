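#' @title Transposon-related novel isoform (TRENI) calling
#' @description
#' A novel isoform is a transcript whose ordered intron chain is absent from
#' the reference annotation (monoexonic transcripts are novel when not
#' contained in any reference exon). A TRENI is a novel isoform with at least
#' one exon overlapping a RepeatMasker repeat by a minimum number of bases.
#' Each carried repeat is placed relative to the host gene's annotated start
#' codon (5' UTR versus downstream, strand-aware), supported by its junction
#' ratio — the fraction of repeat-overlapping reads spliced into the nearest
#' reference exon — and summarized by per-family enrichment odds ratios that
#' account for genome-wide copy numbers.
#' @name treni
NULL

# 0-based half-open data.frame columns -> GRanges
.gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

.chain_key <- function(ts) {
  tx <- ts$transcripts
  idx <- split(seq_len(nrow(ts$exons)), ts$exons$transcript_id)
  vapply(seq_len(nrow(tx)), function(i) {
    j <- idx[[tx$transcript_id[i]]]
    if (length(j) < 2) return(NA_character_)
    s <- ts$exons$start[j]; e <- ts$exons$end[j]
    paste(tx$chrom[i], tx$strand[i],
          paste(e[-length(e)], s[-1], sep = "-", collapse = ";"), sep = "|")
  }, character(1))
}

#' Identify novel transcripts against a reference annotation
#'
#' Multiexonic transcripts are novel iff their intron chain (the ordered
#' junction set, with chromosome and strand) matches no reference
#' transcript; monoexonic transcripts are novel iff their exon is not
#' contained within any reference exon. Each novel isoform is attributed to
#' the reference gene with maximal exonic overlap (its own gene id is kept
#' when nothing overlaps).
#'
#' @param transcripts candidate [transcript_set()].
#' @param reference annotated [transcript_set()].
#' @return a [transcript_set()] of the novel transcripts, with
#'   \code{is_novel = TRUE} and reattributed \code{gene_id}.
#' @export
find_novel <- function(transcripts, reference) {
  ref_chains <- stats::na.omit(.chain_key(reference))
  keys <- .chain_key(transcripts)
  tx <- transcripts$transcripts
  ref_ex <- merge(reference$exons, reference$transcripts[, c("transcript_id", "gene_id", "chrom")],
                  by = "transcript_id")
  ref_gr <- .gr(ref_ex$chrom, ref_ex$start, ref_ex$end)
  idx <- split(seq_len(nrow(transcripts$exons)), transcripts$exons$transcript_id)
  novel <- logical(nrow(tx))
  multi <- !is.na(keys)
  novel[multi] <- !(keys[multi] %in% ref_chains)
  for (i in which(!multi)) {
    j <- idx[[tx$transcript_id[i]]]
    g <- .gr(tx$chrom[i], transcripts$exons$start[j], transcripts$exons$end[j])
    novel[i] <- length(GenomicRanges::findOverlaps(g, ref_gr, type = "within")) == 0
  }
  if (!any(novel)) {
    empty <- tx[0, , drop = FALSE]
    return(transcript_set(empty, transcripts$exons[0, , drop = FALSE]))
  }
  nov_tx <- tx[novel, , drop = FALSE]
  nov_ex <- transcripts$exons[transcripts$exons$transcript_id %in% nov_tx$transcript_id, ,
                              drop = FALSE]
  # gene attribution by maximal exonic overlap, one overlap query for all
  ex_chrom <- nov_tx$chrom[match(nov_ex$transcript_id, nov_tx$transcript_id)]
  g <- .gr(ex_chrom, nov_ex$start, nov_ex$end)
  hit <- GenomicRanges::findOverlaps(g, ref_gr)
  if (length(hit)) {
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(g[qh], ref_gr[sh]))
    by_pair <- rowsum(ov, paste(nov_ex$transcript_id[qh], ref_ex$gene_id[sh],
                                sep = "\r"))
    pair <- strsplit(rownames(by_pair), "\r", fixed = TRUE)
    best <- tapply(seq_along(pair), vapply(pair, `[`, character(1), 1),
                   function(k) vapply(pair, `[`, character(1), 2)[k[which.max(by_pair[k])]])
    found <- match(nov_tx$transcript_id, names(best))
    nov_tx$gene_id[!is.na(found)] <- unlist(best)[found[!is.na(found)]]
  }
  nov_tx$is_novel <- TRUE
  transcript_set(nov_tx, nov_ex)
}

#' Call TRENIs: novel isoforms with exonic repeat overlap
#'
#' A transcript is a TRENI iff at least one repeat interval overlaps at
#' least one of its exons by \code{min_overlap} bases on the same
#' chromosome. All overlapping repeats are recorded, one row per
#' transcript-repeat pair. Repeat strand is ignored.
#'
#' @param novel a [transcript_set()] of novel isoforms.
#' @param repeats repeat table as from [read_repeatmasker()].
#' @param min_overlap minimum single-exon overlap in bp (default 10).
#' @return data.frame with \code{transcript_id}, \code{gene_id},
#'   \code{chrom}, \code{rep_start}, \code{rep_end}, \code{repeat_name},
#'   \code{family}, \code{overlap_bp}.
#' @export
call_treni <- function(novel, repeats, min_overlap = 10) {
  empty <- data.frame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), rep_start = integer(0),
                      rep_end = integer(0), repeat_name = character(0),
                      family = character(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(novel$transcripts) == 0 || nrow(repeats) == 0) return(empty)
  ex <- merge(novel$exons, novel$transcripts[, c("transcript_id", "gene_id", "chrom")],
              by = "transcript_id")
  ex_gr <- .gr(ex$chrom, ex$start, ex$end)
  rep_gr <- .gr(repeats$chrom, repeats$start, repeats$end)
  hit <- GenomicRanges::findOverlaps(ex_gr, rep_gr, minoverlap = min_overlap)
  if (length(hit) == 0) return(empty)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ex_gr[qh], rep_gr[sh]))
  pair <- paste(ex$transcript_id[qh], sh)
  agg <- rowsum(ov, pair)
  first <- !duplicated(pair)
  out <- data.frame(transcript_id = ex$transcript_id[qh][first],
                    gene_id = ex$gene_id[qh][first],
                    chrom = ex$chrom[qh][first],
                    rep_start = repeats$start[sh][first],
                    rep_end = repeats$end[sh][first],
                    repeat_name = repeats$repeat_name[sh][first],
                    family = repeats$family[sh][first],
                    overlap_bp = as.integer(agg[match(pair[first], rownames(agg))]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$rep_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# placement of overlap pieces (0-based half-open) relative to a start codon
# position, in transcript orientation
.placement_one <- function(ov_start, ov_end, sc, strand) {
  if (is.na(sc)) return(c(five_prime_utr = NA, downstream_of_start = NA))
  if (strand == "+") {
    five <- any(ov_start < sc)
    down <- any(ov_end > sc)
  } else {
    five <- any(ov_end > sc + 1)
    down <- any(ov_start <= sc)
  }
  c(five_prime_utr = five, downstream_of_start = down)
}

#' Classify repeat placement relative to the host start codon
#'
#' The exonic overlap of each carried repeat is compared with the host
#' gene's annotated start codon in transcript orientation: overlap strictly
#' 5' of the codon is \code{five_prime_utr}, overlap at or 3' of it is
#' \code{downstream_of_start}, and a straddling repeat contributes both. On
#' the minus strand "5' of" means greater genomic coordinate. The start
#' codon is taken from the first reference transcript of the host gene that
#' carries one.
#'
#' @param hits TRENI hit table from [call_treni()].
#' @param novel the novel [transcript_set()] (for exon structures).
#' @param reference annotated [transcript_set()] (for start codons and
#'   strand).
#' @return \code{hits} with logical columns \code{five_prime_utr} and
#'   \code{downstream_of_start} added (\code{NA} when the host has no
#'   annotated start codon).
#' @export
classify_placement <- function(hits, novel, reference) {
  ref_tx <- reference$transcripts
  five <- down <- rep(NA, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cand <- ref_tx[ref_tx$gene_id == hits$gene_id[i] & !is.na(ref_tx$start_codon), ,
                   drop = FALSE]
    if (nrow(cand) == 0) next
    sc <- cand$start_codon[1]; strand <- cand$strand[1]
    ex <- novel$exons[novel$exons$transcript_id == hits$transcript_id[i], , drop = FALSE]
    os <- pmax(ex$start, hits$rep_start[i]); oe <- pmin(ex$end, hits$rep_end[i])
    keep <- oe > os
    if (!any(keep)) next
    pl <- .placement_one(os[keep], oe[keep], sc, strand)
    five[i] <- pl[["five_prime_utr"]]; down[i] <- pl[["downstream_of_start"]]
  }
  hits$five_prime_utr <- five
  hits$downstream_of_start <- down
  hits
}

# gap between two 0-based half-open intervals (0 when they overlap)
.gap <- function(a_start, a_end, b_start, b_end) {
  pmax(pmax(b_start - a_end, a_start - b_end), 0L)
}

#' Junction ratio of one repeat
#'
#' Denominator: reads with at least 1 bp overlapping the repeat interval.
#' Numerator: the subset with two or more blocks in which one block overlaps
#' the repeat and a different block overlaps the nearest reference exon of
#' the host gene (nearest by genomic gap; ties go to the 3'-ward exon in
#' transcript orientation).
#'
#' @param rep_start,rep_end repeat interval (0-based half-open).
#' @param ref_exons data.frame of the host gene's reference exons
#'   (\code{start}, \code{end}).
#' @param strand host transcript strand (for the tie-break).
#' @param reads block table on the repeat's chromosome
#'   ([validate_read_blocks()] format).
#' @return junction ratio in [0, 1], or \code{NA} when no read overlaps the
#'   repeat.
#' @export
junction_ratio <- function(rep_start, rep_end, ref_exons, strand, reads) {
  if (nrow(ref_exons) == 0) stop("host gene has no reference exons")
  gaps <- .gap(ref_exons$start, ref_exons$end, rep_start, rep_end)
  best <- which(gaps == min(gaps))
  if (length(best) > 1)  # 3'-ward: larger coordinate on +, smaller on -
    best <- if (strand == "+") best[which.max(ref_exons$start[best])]
            else best[which.min(ref_exons$start[best])]
  ne_s <- ref_exons$start[best]; ne_e <- ref_exons$end[best]
  in_rep <- reads$end > rep_start & reads$start < rep_end
  den_ids <- unique(reads$read_id[in_rep])
  if (length(den_ids) == 0) return(NA_real_)
  in_ex <- reads$end > ne_s & reads$start < ne_e
  num <- vapply(den_ids, function(id) {
    b <- which(reads$read_id == id)
    if (length(b) < 2) return(FALSE)
    A <- in_rep[b]; B <- in_ex[b]  # need distinct blocks i, j with A[i], B[j]
    any(A) && any(B) &&
      !(sum(A) == 1 && sum(B) == 1 && which(A) == which(B))
  }, logical(1))
  sum(num) / length(den_ids)
}

#' Add per-repeat junction ratios to a TRENI hit table
#'
#' @param hits TRENI hit table ([call_treni()]).
#' @param reference annotated [transcript_set()].
#' @param reads spliced-read block table.
#' @return \code{hits} with a \code{jr} column.
#' @export
add_junction_ratios <- function(hits, reference, reads) {
  ref_ex <- merge(reference$exons,
                  reference$transcripts[, c("transcript_id", "gene_id", "strand")],
                  by = "transcript_id")
  hits$jr <- vapply(seq_len(nrow(hits)), function(i) {
    ex <- ref_ex[ref_ex$gene_id == hits$gene_id[i], , drop = FALSE]
    if (nrow(ex) == 0) return(NA_real_)
    rr <- reads[reads$chrom == hits$chrom[i], , drop = FALSE]
    junction_ratio(hits$rep_start[i], hits$rep_end[i],
                   ex[, c("start", "end")], ex$strand[1], rr)
  }, numeric(1))
  hits
}

#' Keep repeats with high-confidence junction support
#' @param hits hit table with a \code{jr} column.
#' @param threshold inclusive JR cutoff, default 0.9; undefined JR is
#'   dropped.
#' @return the filtered hit table.
#' @export
jr_filter <- function(hits, threshold = 0.9) {
  hits[!is.na(hits$jr) & hits$jr >= threshold, , drop = FALSE]
}

# 2x2 odds ratio with Haldane-Anscombe correction, Woolf CI and chi-square p
.or_table <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  corr <- if (any(cells == 0)) cells + 0.5 else cells
  or <- (corr[1] * corr[4]) / (corr[2] * corr[3])
  se <- sqrt(sum(1 / corr))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- tryCatch(
    suppressWarnings(stats::chisq.test(matrix(cells, 2), correct = FALSE)$p.value),
    error = function(e) NA_real_)
  list(or = or, ci_low = ci[1], ci_high = ci[2],
       p = if (is.na(p)) NA_real_ else max(p, 2.2e-16))
}

#' Repeat-family enrichment in TRENIs
#'
#' For each family f, the 2x2 table of genomic repeat copies
#' \{f vs not-f\} x \{contained in a TRENI vs not\} gives an odds ratio
#' (0.5 correction when a cell is zero), a 95\% Woolf confidence interval,
#' and a chi-square p-value (reported at the 2.2e-16 floor when
#' underflowed). The OR and CI are suppressed for families with fewer than
#' \code{min_copies} copies in TRENIs; every genomic copy is counted in
#' exactly one family's table.
#'
#' @param repeats genome-wide repeat table.
#' @param hits TRENI hit table; copies are matched to hits by chromosome,
#'   interval and repeat name.
#' @param min_copies minimum in-TRENI copies for a reported OR (default 20).
#' @return data.frame with one row per family, sorted by odds ratio
#'   (suppressed ORs last): \code{family}, \code{in_treni}, \code{out_treni},
#'   \code{other_in}, \code{other_out}, \code{odds_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{chi2_p}.
#' @export
family_enrichment <- function(repeats, hits, min_copies = 20) {
  key <- function(ch, s, e, n) paste(ch, s, e, n, sep = ":")
  in_treni <- key(repeats$chrom, repeats$start, repeats$end, repeats$repeat_name) %in%
    key(hits$chrom, hits$rep_start, hits$rep_end, hits$repeat_name)
  fams <- sort(unique(repeats$family))
  rows <- lapply(fams, function(f) {
    is_f <- repeats$family == f
    a <- sum(is_f & in_treni); b <- sum(is_f & !in_treni)
    c_ <- sum(!is_f & in_treni); d <- sum(!is_f & !in_treni)
    t <- .or_table(a, b, c_, d)
    sup <- a < min_copies
    data.frame(family = f, in_treni = a, out_treni = b, other_in = c_, other_out = d,
               odds_ratio = if (sup) NA_real_ else t$or,
               ci_low = if (sup) NA_real_ else t$ci_low,
               ci_high = if (sup) NA_real_ else t$ci_high,
               chi2_p = t$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$odds_ratio, na.last = TRUE), , drop = FALSE]
}

#' Repeat-family enrichment restricted to 5' UTR placements
#'
#' Same machinery as [family_enrichment()], with the in-TRENI set restricted
#' to repeats whose placement includes the 5' UTR.
#'
#' @inheritParams family_enrichment
#' @param hits hit table carrying the placement columns from
#'   [classify_placement()].
#' @export
utr_family_enrichment <- function(repeats, hits, min_copies = 20) {
  utr <- hits[!is.na(hits$five_prime_utr) & hits$five_prime_utr, , drop = FALSE]
  family_enrichment(repeats, utr, min_copies)
}

#' Between-lineage tests over TRENI expression
#'
#' Delegates wholesale to the lineage difference test with isoform-level
#' expression rows, and reports the real-versus-shuffled comparison at
#' \code{q_star}.
#'
#' @param treni_fpkm isoform-by-cell FPKM matrix of TRENIs.
#' @inheritParams shuffle_background
#' @param q_star reporting threshold, default 0.01.
#' @return list with \code{tests} (per-isoform F/p/q), \code{background}
#'   (pooled shuffled q-values) and \code{comparison}
#'   ([compare_distributions()] output).
#' @export
treni_lineage_tests <- function(treni_fpkm, cells, stage, n_shuffles = 1,
                                seed = 1, q_star = 0.01, threshold = 1.0) {
  if (is.null(dim(treni_fpkm)) || nrow(treni_fpkm) == 0)
    stop("empty TRENI expression matrix")
  tests <- lineage_tests(treni_fpkm, cells, stage, threshold)
  bg <- shuffle_background(treni_fpkm, cells, stage, n_shuffles, seed, threshold)
  list(tests = tests, background = bg,
       comparison = compare_distributions(tests$q, bg, q_star))
}
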