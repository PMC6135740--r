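#' @title Synthetic-data generators
#' @description
#' Every input the workflow consumes can be generated here with the
#' statistical structure the analysis assumes: embryos split into two equal
#' cell-division lineages, log-normal-style FPKM with embryo and lineage
#' effects, stochastic Brainbow marker recombination with dropout, imaging
#' counts in balanced and pole-biased regimes, and transcript/repeat/read
#' fixtures with planted transposon-bearing novel isoforms. All generators are
#' bit-reproducible under a fixed seed.
#' @name synthetic_data
NULL

#' Configuration for the synthetic-data generators
#'
#' Defaults mirror the study design the workflow targets: nine 4-cell and
#' four 8-cell embryos, two lineages of equal size per embryo, ~2/3 of imaged
#' blastocysts pole-biased.
#'
#' @param seed integer RNG seed.
#' @param n_embryos_4cell,n_embryos_8cell embryos per stage.
#' @param n_genes genes in the expression matrix.
#' @param frac_lineage_genes fraction of genes given a planted lineage effect.
#' @param lineage_effect log2-FPKM mean shift between lineages for planted
#'   genes (sign drawn per embryo).
#' @param embryo_sd,cell_sd embryo-effect and cell-level noise SDs on the
#'   log2-FPKM scale.
#' @param marker_mean_reads Poisson mean of reads on the recombined marker.
#' @param marker_dropout probability a cell's marker count is zeroed.
#' @param n_image_embryos imaged blastocysts.
#' @param unbalanced_frac fraction of imaged embryos with pole-biased marker
#'   allocation (target odds ratio at least 3; the rest sit near OR = 1).
#' @param n_transcripts reference transcripts (one per gene).
#' @param frac_novel novel isoforms generated, as a fraction of
#'   \code{n_transcripts}.
#' @param frac_repeat_bearing fraction of novel isoforms carrying one
#'   repeat-derived exon.
#' @param frac_utr among repeat-bearing isoforms, fraction with the repeat
#'   upstream of the host start codon (5' UTR placement).
#' @param family_weights named sampling weights for repeat families of
#'   planted repeats; genome background copies are drawn uniformly, so the
#'   top-weighted family is the planted enrichment.
#' @param n_background_per_family genome-wide repeat copies per family not in
#'   any transcript.
#' @param reads_per_repeat reads generated over each planted repeat.
#' @param junction_frac_range range of the per-repeat true junction fraction.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_embryos_4cell = 9L, n_embryos_8cell = 4L,
                             n_genes = 2000L,
                             frac_lineage_genes = 0.1,
                             lineage_effect = 2.0,
                             embryo_sd = 0.5, cell_sd = 0.5,
                             marker_mean_reads = 50,
                             marker_dropout = 0.1,
                             n_image_embryos = 18L,
                             unbalanced_frac = 2 / 3,
                             n_transcripts = 60L,
                             frac_novel = 0.5,
                             frac_repeat_bearing = 0.5,
                             frac_utr = 0.25,
                             family_weights = c(Alu = 4, B2 = 2, B4 = 2, L1 = 1, ERVK = 1),
                             n_background_per_family = 60L,
                             reads_per_repeat = 20L,
                             junction_frac_range = c(0.7, 1)) {
  cfg <- list(seed = as.integer(seed),
              n_embryos_4cell = as.integer(n_embryos_4cell),
              n_embryos_8cell = as.integer(n_embryos_8cell),
              n_genes = as.integer(n_genes),
              frac_lineage_genes = frac_lineage_genes,
              lineage_effect = lineage_effect,
              embryo_sd = embryo_sd, cell_sd = cell_sd,
              marker_mean_reads = marker_mean_reads,
              marker_dropout = marker_dropout,
              n_image_embryos = as.integer(n_image_embryos),
              unbalanced_frac = unbalanced_frac,
              n_transcripts = as.integer(n_transcripts),
              frac_novel = frac_novel,
              frac_repeat_bearing = frac_repeat_bearing,
              frac_utr = frac_utr,
              family_weights = family_weights,
              n_background_per_family = as.integer(n_background_per_family),
              reads_per_repeat = as.integer(reads_per_repeat),
              junction_frac_range = junction_frac_range)
  fr <- c(cfg$frac_lineage_genes, cfg$marker_dropout, cfg$unbalanced_frac,
          cfg$frac_novel, cfg$frac_repeat_bearing, cfg$frac_utr,
          cfg$junction_frac_range)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$embryo_sd <= 0 || cfg$cell_sd <= 0) stop("sds must be positive")
  if (cfg$n_genes < 1) stop("n_genes must be at least 1")
  structure(cfg, class = "synthetic_config")
}

#' Simulate blastomeres and their FPKM matrix
#'
#' Each embryo contributes 4 or 8 cells split equally between lineages A and
#' B. For gene g in cell c,
#' \code{log2(FPKM+1) = baseline_g + embryo effect + lineage shift + noise},
#' with the lineage shift \code{+/- lineage_effect/2} applied to planted genes
#' only (sign drawn per gene-embryo pair) and \code{FPKM = 2^x - 1} clipped at
#' zero. Each lineage of each embryo independently recombines one of the four
#' Brainbow markers, so about a quarter of embryos are colour-unresolvable by
#' design; marker reads are Poisson with dropout.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{cells} (truth lineage labels filled in),
#'   \code{fpkm} (gene-by-cell matrix) and \code{truth} (per-gene
#'   \code{planted} flag).
#' @export
simulate_cells_and_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  emb4 <- sprintf("E4_%02d", seq_len(config$n_embryos_4cell))
  emb8 <- sprintf("E8_%02d", seq_len(config$n_embryos_8cell))
  sizes <- c(rep(4L, length(emb4)), rep(8L, length(emb8)))
  embryos <- c(emb4, emb8)
  stage <- rep(c(rep("four_cell", length(emb4)), rep("eight_cell", length(emb8))),
               times = sizes)
  embryo_id <- rep(embryos, times = sizes)
  lineage <- unlist(lapply(sizes, function(n) rep(c("A", "B"), each = n / 2)))
  cell_id <- paste0(embryo_id, "_c", unlist(lapply(sizes, seq_len)))
  n_cells <- length(cell_id)
  E <- length(embryos)

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  n_planted <- round(config$frac_lineage_genes * config$n_genes)
  planted <- rep(FALSE, config$n_genes)
  if (n_planted > 0) planted[sample.int(config$n_genes, n_planted)] <- TRUE

  baseline <- stats::runif(config$n_genes, 2, 8)
  emb_eff <- matrix(stats::rnorm(config$n_genes * E, 0, config$embryo_sd),
                    nrow = config$n_genes, dimnames = list(genes, embryos))
  sign_ge <- matrix(sample(c(-1, 1), config$n_genes * E, replace = TRUE),
                    nrow = config$n_genes, dimnames = list(genes, embryos))
  ei <- match(embryo_id, embryos)
  shift <- sign_ge[, ei, drop = FALSE] *
    ifelse(lineage == "A", 1, -1)[col(sign_ge[, ei, drop = FALSE])] *
    (config$lineage_effect / 2) * planted
  x <- baseline + emb_eff[, ei, drop = FALSE] + shift +
    matrix(stats::rnorm(config$n_genes * n_cells, 0, config$cell_sd),
           nrow = config$n_genes)
  fpkm <- pmax(2^x - 1, 0)
  dimnames(fpkm) <- list(genes, cell_id)

  # markers: one recombination event per lineage per embryo
  marker_of <- matrix(sample(BRAINBOW_MARKERS, 2 * E, replace = TRUE),
                      nrow = E, dimnames = list(embryos, c("A", "B")))
  my_marker <- marker_of[cbind(ei, match(lineage, c("A", "B")))]
  reads <- stats::rpois(n_cells, config$marker_mean_reads)
  reads[stats::runif(n_cells) < config$marker_dropout] <- 0L
  mk <- matrix(0L, nrow = n_cells, ncol = 4,
               dimnames = list(NULL, BRAINBOW_MARKERS))
  mk[cbind(seq_len(n_cells), match(my_marker, BRAINBOW_MARKERS))] <- reads

  cells <- cell_table(cell_id, embryo_id, stage,
                      GFP = mk[, "GFP"], CFP = mk[, "CFP"],
                      RFP = mk[, "RFP"], YFP = mk[, "YFP"],
                      uniquely_mapped_pairs = round(stats::runif(n_cells, 5e6, 3e7)),
                      lineage = lineage)
  validate_matrix(fpkm, cells)
  list(cells = cells, fpkm = fpkm,
       truth = data.frame(gene_id = genes, planted = planted,
                          stringsAsFactors = FALSE))
}

# pick the marker-positive count in the embryonic pole that brings the
# Haldane-Anscombe-corrected OR closest to `target` on the log scale
.alloc_pos <- function(P, ne, na, target) {
  lo <- max(0L, P - na); hi <- min(P, ne)
  pe <- lo:hi
  or <- vapply(pe, function(x) odds_ratio(x, ne - x, P - x, na - (P - x)),
               numeric(1))
  pe[which.min(abs(log(or) - log(target)))]
}

#' Simulate blastocyst imaging counts
#'
#' A fraction \code{unbalanced_frac} of embryos gets pole-biased marker
#' allocation (target odds ratio drawn in [4, 9], GFP biased toward one pole
#' and RFP toward the other); the remainder is allocated proportionally to
#' pole size with a one-cell jitter, i.e. near OR = 1. Totals are 32-64 cells
#' and each marker labels roughly 30% of cells, so embryos pass the 1/3 and
#' 1/2 inclusion rules.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{counts} (imaging-count table) and \code{truth}
#'   (per-embryo \code{unbalanced} flag).
#' @export
simulate_image_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_image_embryos
  n_unb <- round(config$unbalanced_frac * n)
  unbalanced <- rep(FALSE, n)
  if (n_unb > 0) unbalanced[sample.int(n, n_unb)] <- TRUE
  rows <- lapply(seq_len(n), function(i) {
    total <- sample(32:64, 1)
    ne <- round(total / 2) + sample(-2:2, 1)
    na <- total - ne
    out <- list(embryo_id = sprintf("IMG_%02d", i), total_cells = total)
    flip <- sample(c(TRUE, FALSE), 1)  # which pole GFP is biased toward
    for (m in c("gfp", "rfp")) {
      P <- round(stats::runif(1, 0.25, 0.35) * total)
      if (unbalanced[i]) {
        target <- exp(stats::runif(1, log(4), log(9)))
        biased_emb <- if (m == "gfp") flip else !flip
        pe <- .alloc_pos(P, ne, na, if (biased_emb) target else 1 / target)
      } else {
        pe <- round(P * ne / total) + sample(-1:1, 1)
        pe <- min(max(pe, max(0L, P - na)), min(P, ne))
      }
      out[[paste0(m, "_pos_emb")]] <- pe
      out[[paste0(m, "_neg_emb")]] <- ne - pe
      out[[paste0(m, "_pos_abem")]] <- P - pe
      out[[paste0(m, "_neg_abem")]] <- na - (P - pe)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  counts <- validate_image_counts(do.call(rbind, rows))
  list(counts = counts,
       truth = data.frame(embryo_id = counts$embryo_id, unbalanced = unbalanced,
                          stringsAsFactors = FALSE))
}

#' Simulate transcript models, repeats and spliced reads
#'
#' Builds one reference transcript per gene (3-5 exons, start codon in the
#' second exon so the first exon is 5' UTR), then novel isoforms that copy a
#' host's exon chain and insert one extra exon into an intron, creating a new
#' junction. A fraction of novel isoforms carries a repeat exactly covering
#' the extra exon, placed in the first intron (5' UTR side of the start
#' codon) or further downstream; repeat families follow
#' \code{family_weights}, while background copies (uniform over families) are
#' scattered in intergenic space. For every planted repeat,
#' \code{reads_per_repeat} reads are generated: a true junction fraction f is
#' drawn from \code{junction_frac_range}, \code{round(f * reads)} reads are
#' spliced from the repeat into the nearest reference exon of the host gene,
#' and the rest lie wholly inside the repeat.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{transcripts} ([transcript_set()], novel flags set
#'   to truth), \code{repeats}, \code{reads}, and \code{truth} — a list with
#'   \code{novel} (novel transcript ids) and \code{treni} (one row per
#'   planted repeat: host transcript, interval, family, placement, true
#'   junction fraction).
#' @export
simulate_annotation_and_reads <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  n_ref <- config$n_transcripts
  cursor <- 10000L
  tx_rows <- list(); exon_rows <- list()
  ref_exons <- vector("list", n_ref)  # per-ref matrix of exon intervals
  for (i in seq_len(n_ref)) {
    nex <- sample(3:5, 1)
    lens <- sample(150:300, nex, replace = TRUE)
    gaps <- sample(400:1000, nex - 1, replace = TRUE)
    starts <- cursor + cumsum(c(0L, lens[-nex] + gaps))
    ends <- starts + lens
    strand <- sample(c("+", "-"), 1)
    # start codon 10 bp into the second exon in transcript orientation
    sc <- if (strand == "+") starts[2] + 10L else ends[nex - 1] - 1L - 10L
    tid <- sprintf("tx%03d.ref", i)
    tx_rows[[i]] <- data.frame(transcript_id = tid,
                               gene_id = sprintf("gene%03d", i),
                               chrom = "chr1", strand = strand,
                               start_codon = sc, is_novel = FALSE,
                               stringsAsFactors = FALSE)
    exon_rows[[i]] <- data.frame(transcript_id = tid, start = starts, end = ends,
                                 stringsAsFactors = FALSE)
    ref_exons[[i]] <- cbind(starts, ends)
    cursor <- ends[nex] + 5000L
  }

  n_novel <- round(config$frac_novel * n_ref)
  n_rep <- round(config$frac_repeat_bearing * n_novel)
  hosts <- sample.int(n_ref, n_novel, replace = FALSE)
  fams <- names(config$family_weights)
  treni_truth <- list(); reads_rows <- list(); rep_rows <- list()
  for (j in seq_len(n_novel)) {
    h <- hosts[j]
    host <- tx_rows[[h]]
    ex <- ref_exons[[h]]
    nex <- nrow(ex)
    bearing <- j <= n_rep
    # choose intron in transcript orientation: intron 1 is 5'UTR side
    utr <- bearing && stats::runif(1) < config$frac_utr
    down_introns <- 2:(nex - 1)
    k_tx <- if (utr) 1L else if (length(down_introns) == 1) down_introns else
      sample(down_introns, 1)  # intron index, transcript order
    k <- if (host$strand == "+") k_tx else nex - k_tx  # genomic intron index
    gap_l <- ex[k + 1, 1] - ex[k, 2]
    elen <- 100L
    # uneven offset so the nearest reference exon is unambiguous
    off <- sample(setdiff(seq(20L, gap_l - elen - 20L), (gap_l - elen) %/% 2), 1)
    nstart <- ex[k, 2] + off
    nend <- nstart + elen
    tid <- sprintf("tx%03d.nov%d", h, j)
    tx_rows[[n_ref + j]] <- data.frame(transcript_id = tid, gene_id = host$gene_id,
                                       chrom = "chr1", strand = host$strand,
                                       start_codon = NA_integer_, is_novel = TRUE,
                                       stringsAsFactors = FALSE)
    nov_ex <- rbind(data.frame(transcript_id = tid, start = ex[, 1], end = ex[, 2]),
                    data.frame(transcript_id = tid, start = nstart, end = nend))
    exon_rows[[n_ref + j]] <- nov_ex
    if (!bearing) next
    fam <- sample(fams, 1, prob = config$family_weights)
    rep_rows[[length(rep_rows) + 1]] <-
      data.frame(chrom = "chr1", start = nstart, end = nend,
                 strand = host$strand, repeat_name = paste0(fam, "_syn", j),
                 family = fam, repclass = "synthetic", stringsAsFactors = FALSE)
    # nearest reference exon by genomic gap (no ties by construction)
    near <- if (off < gap_l - elen - off) k else k + 1L
    jf <- stats::runif(1, config$junction_frac_range[1], config$junction_frac_range[2])
    R <- config$reads_per_repeat
    nj <- round(jf * R)
    for (r in seq_len(R)) {
      rid <- sprintf("%s_rep_r%02d", tid, r)
      b1s <- nstart + sample(0:(elen - 50L), 1)
      if (r <= nj) {
        e <- ex[near, ]
        b2s <- if (near == k) e[2] - 50L else e[1]
        reads_rows[[length(reads_rows) + 1]] <-
          data.frame(read_id = rid, chrom = "chr1",
                     start = c(b1s, b2s), end = c(b1s + 50L, b2s + 50L),
                     stringsAsFactors = FALSE)
      } else {
        reads_rows[[length(reads_rows) + 1]] <-
          data.frame(read_id = rid, chrom = "chr1",
                     start = b1s, end = b1s + 50L, stringsAsFactors = FALSE)
      }
    }
    treni_truth[[length(treni_truth) + 1]] <-
      data.frame(transcript_id = tid, gene_id = host$gene_id,
                 rep_start = nstart, rep_end = nend, family = fam,
                 placement = if (utr) "five_prime_utr" else "downstream_of_start",
                 true_jr = nj / R, stringsAsFactors = FALSE)
  }

  # intergenic background repeats, uniform over families
  bg_start <- cursor + 10000L
  n_bg <- config$n_background_per_family * length(fams)
  if (n_bg > 0) {
    bg <- data.frame(chrom = "chr1",
                     start = bg_start + (seq_len(n_bg) - 1L) * 500L,
                     end = bg_start + (seq_len(n_bg) - 1L) * 500L + 150L,
                     strand = "+",
                     repeat_name = paste0("bg", seq_len(n_bg)),
                     family = rep(fams, each = config$n_background_per_family),
                     repclass = "synthetic", stringsAsFactors = FALSE)
    rep_rows[[length(rep_rows) + 1]] <- bg
  }

  ts <- transcript_set(do.call(rbind, tx_rows), do.call(rbind, exon_rows))
  repeats <- validate_repeats(do.call(rbind, rep_rows))
  reads <- if (length(reads_rows)) validate_read_blocks(do.call(rbind, reads_rows))
           else data.frame(read_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0))
  treni <- if (length(treni_truth)) do.call(rbind, treni_truth)
           else data.frame(transcript_id = character(0), gene_id = character(0),
                           rep_start = integer(0), rep_end = integer(0),
                           family = character(0), placement = character(0),
                           true_jr = numeric(0))
  list(transcripts = ts, repeats = repeats, reads = reads,
       truth = list(novel = ts$transcripts$transcript_id[ts$transcripts$is_novel],
                    treni = treni))
}
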