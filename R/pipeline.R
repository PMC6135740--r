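#' @title End-to-end workflow orchestration
#' @description
#' Runs simulate -> lineage assignment -> balance -> variance partition ->
#' lineage difference test -> TRENI calling on one configuration, writing
#' every intermediate table as TSV (re-readable by this package's own
#' readers) plus a markdown summary. Deterministic given the seed.
#' @name pipeline
NULL

#' Percentage helpers
#'
#' \code{pct()} reports a rounded percentage of a numerator over a
#' denominator; \code{pct_trunc()} truncates to an integer (the convention
#' used for the balance summaries).
#'
#' @param num,den numerator and denominator.
#' @param digits decimal places for \code{pct()}.
#' @return numeric percentage.
#' @export
pct <- function(num, den, digits = 2) round(100 * num / den, digits)

#' @rdname pct
#' @export
pct_trunc <- function(num, den) as.integer(100 * num / den)

#' Default analysis settings
#'
#' All thresholds used along the workflow, overridable via a YAML file or a
#' named list: marker-calling reads, QC read pairs, expressed-gene FPKM
#' cutoff, balance band, JR cutoff, minimum family copies, reporting q*,
#' Beta reference parameters and shuffle count.
#'
#' @param overrides named list (or path to a YAML file) of settings to
#'   replace.
#' @return named list of settings, including a \code{synthetic} element of
#'   generator arguments.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    stage = "four_cell",
    min_reads = 10,
    min_pairs = 3e6,
    fpkm_threshold = 1.0,
    jr_threshold = 0.9,
    min_copies = 20,
    min_overlap = 10,
    q_star = 0.01,
    n_shuffles = 1,
    betas = list(c(1, 3), c(2, 2), c(5, 5)),
    synthetic = list())
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) {
    if ("betas" %in% names(overrides))
      overrides$betas <- lapply(overrides$betas, as.numeric)
    cfg[names(overrides)] <- overrides
  }
  cfg
}

.stage_run <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full workflow on synthetic data
#'
#' @param config settings from [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main results (balance summary, r
#'   values, beta comparisons, difference-test comparison, TRENI tables).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "results") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- do.call(synthetic_config,
                 c(list(seed = config$seed), config$synthetic))

  sim <- .stage_run("simulate", simulate_cells_and_expression(syn))
  img <- .stage_run("simulate-imaging", simulate_image_counts(syn))
  ann <- .stage_run("simulate-annotation", simulate_annotation_and_reads(syn))
  write_cells(sim$cells, file.path(out_dir, "cells_truth.tsv"))
  write_matrix(sim$fpkm, file.path(out_dir, "fpkm.tsv"))
  write_image_counts(img$counts, file.path(out_dir, "image_counts.tsv"))

  cells <- .stage_run("assign-lineage", {
    blank <- sim$cells; blank$lineage <- "unresolved"
    qc <- qc_filter(blank, config$min_pairs)
    assign_lineages_all(qc$kept, config$min_reads)
  })
  write_cells(cells, file.path(out_dir, "cells_lineage.tsv"))

  balance <- .stage_run("balance", {
    res <- do.call(rbind, lapply(c("one_third", "half", "all"), function(m)
      balance_classify(img$counts, m)))
    summ <- summarize_balance(res)
    utils::write.table(res, file.path(out_dir, "balance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "balance_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summ
  })

  stage <- config$stage
  r <- .stage_run("variance", {
    r <- empirical_R(sim$fpkm, cells, stage, config$fpkm_threshold)
    utils::write.table(data.frame(gene_id = names(r), r = r),
                       file.path(out_dir, "r_values.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })
  betas <- .stage_run("beta-comparison", {
    cmp <- compare_to_beta(r, config$betas)
    tails <- do.call(rbind, lapply(cmp, function(x)
      cbind(alpha = x$alpha, beta = x$beta, ks_distance = x$ks_distance, x$tails)))
    utils::write.table(tails, file.path(out_dir, "beta_tails.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    qq <- do.call(rbind, lapply(cmp, function(x)
      cbind(alpha = x$alpha, beta = x$beta, x$qq)))
    utils::write.table(qq, file.path(out_dir, "beta_qq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cmp
  })

  diff <- .stage_run("difftest", {
    tests <- lineage_tests(sim$fpkm, cells, stage, config$fpkm_threshold)
    bg <- shuffle_background(sim$fpkm, cells, stage, config$n_shuffles,
                             config$seed, config$fpkm_threshold)
    cmp <- compare_distributions(tests$q, bg, config$q_star)
    utils::write.table(tests[order(tests$q), ], file.path(out_dir, "tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(q = bg), file.path(out_dir, "background.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(tests = tests, comparison = cmp)
  })

  top <- .stage_run("top-genes", {
    tg <- top_gene_report(sim$fpkm, cells, diff$tests, stage, n_top = 10)
    utils::write.table(tg, file.path(out_dir, "top_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tg
  })

  treni <- .stage_run("treni", {
    ref <- transcript_set(
      ann$transcripts$transcripts[!ann$transcripts$transcripts$is_novel, ],
      ann$transcripts$exons[ann$transcripts$exons$transcript_id %in%
        ann$transcripts$transcripts$transcript_id[!ann$transcripts$transcripts$is_novel], ])
    nov <- find_novel(ann$transcripts, ref)
    hits <- call_treni(nov, ann$repeats, config$min_overlap)
    hits <- classify_placement(hits, nov, ref)
    hits <- add_junction_ratios(hits, ref, ann$reads)
    fam <- family_enrichment(ann$repeats, hits, config$min_copies)
    utr <- utr_family_enrichment(ann$repeats, hits, config$min_copies)
    utils::write.table(hits, file.path(out_dir, "treni.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fam, file.path(out_dir, "families.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(utr, file.path(out_dir, "utr_families.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(novel = nov, hits = hits, families = fam, utr_families = utr)
  })

  summary_md <- c(
    "# Workflow summary", "",
    sprintf("Seed: %d; stage: %s", config$seed, stage), "",
    "## Blastocyst balance",
    sprintf("- %s: %d/%d unbalanced (%d%%)", balance$method,
            balance$n_unbalanced, balance$n_included, balance$percent_unbalanced),
    "",
    "## Lineage-variation ratio",
    sprintf("- %d expressed genes with defined r; mean r = %.3f", length(r), mean(r)),
    sprintf("- KS distance vs Beta(%g,%g): %.4f",
            vapply(betas, `[[`, numeric(1), "alpha"),
            vapply(betas, `[[`, numeric(1), "beta"),
            vapply(betas, `[[`, numeric(1), "ks_distance")),
    "",
    "## Lineage difference test",
    sprintf("- real vs shuffled q: KS = %.4f, p = %.3g; %d real / %d shuffled below q* = %g",
            diff$comparison$ks_stat, diff$comparison$ks_p,
            diff$comparison$n_real_below, diff$comparison$n_shuffled_below,
            diff$comparison$q_star),
    "",
    "## TRENIs",
    sprintf("- %d novel isoforms, %d TRENI repeat hits, %d passing JR >= %g",
            nrow(treni$novel$transcripts), nrow(treni$hits),
            nrow(jr_filter(treni$hits, config$jr_threshold)), config$jr_threshold),
    sprintf("- top enriched family: %s", treni$families$family[1]))
  writeLines(summary_md, file.path(out_dir, "summary.md"))

  invisible(list(balance = balance, r = r, betas = betas, diff = diff,
                 top_genes = top, treni = treni))
}

#' Rank top differential genes with per-embryo lineage means
#'
#' Thin reporting step: the \code{n_top} features with the smallest
#' q-values, each with its mean log2(FPKM+1) per embryo and lineage.
#'
#' @param fpkm gene-by-cell FPKM matrix.
#' @param cells cell table with lineage calls.
#' @param tests output of [lineage_tests()].
#' @param stage stage to report.
#' @param n_top number of features.
#' @return data.frame, one row per feature-embryo-lineage combination with
#'   the group mean, ordered by q.
#' @export
top_gene_report <- function(fpkm, cells, tests, stage, n_top = 10) {
  keep <- cells$stage == stage & cells$lineage %in% c("A", "B")
  cc <- cells[keep, , drop = FALSE]
  ord <- tests[order(tests$q, tests$p), , drop = FALSE]
  top <- utils::head(ord, n_top)
  y <- log2(fpkm[top$feature_id, cc$cell_id, drop = FALSE] + 1)
  grp <- interaction(cc$embryo_id, cc$lineage, drop = TRUE)
  means <- t(apply(y, 1, function(v) tapply(v, grp, mean)))
  long <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    parts <- strsplit(colnames(means), ".", fixed = TRUE)
    data.frame(feature_id = top$feature_id[i], q = top$q[i],
               embryo_id = vapply(parts, `[`, character(1), 1),
               lineage = vapply(parts, `[`, character(1), 2),
               mean_log2_fpkm = means[i, ], stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
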