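#' @title Blastocyst lineage-balance classification
#' @description
#' From imaging counts of marker-positive and marker-negative cells in the
#' embryonic and abembryonic poles, each blastocyst is classified as balanced
#' or unbalanced in its lineage contribution to the two poles, under three
#' counting methods: odds-ratio classification with a 1/3-of-cells inclusion
#' rule, the same with a 1/2 inclusion rule, and a pole-ratio classification
#' that includes every embryo. An embryo is balanced when the statistic lies
#' strictly inside (1/3, 3); it is unbalanced when any evaluated marker is
#' unbalanced.
#' @name embryo_balance
NULL

#' Inclusion rule for the odds-ratio methods
#'
#' An embryo is included when the fraction of its cells expressing either
#' imageable marker (GFP or RFP, both poles) reaches \code{min_frac}
#' (inclusive). With \code{denominator = "embryonic"} the rule instead uses
#' marker-positive cells in the embryonic pole over embryonic-pole cells.
#'
#' @param counts one row of an imaging-count table.
#' @param min_frac 1/3 or 1/2.
#' @param denominator \code{"all"} (default) or \code{"embryonic"}.
#' @return logical.
#' @export
inclusion <- function(counts, min_frac, denominator = c("all", "embryonic")) {
  denominator <- match.arg(denominator)
  pos_emb <- counts$gfp_pos_emb + counts$rfp_pos_emb
  if (denominator == "all") {
    pos <- pos_emb + counts$gfp_pos_abem + counts$rfp_pos_abem
    pos / counts$total_cells >= min_frac
  } else {
    ne <- counts$gfp_pos_emb + counts$gfp_neg_emb
    pos_emb / ne >= min_frac
  }
}

#' Odds ratio of a marker's 2x2 pole table
#'
#' \code{OR = (pos_emb * neg_abem) / (neg_emb * pos_abem)}. If any cell of the
#' table is zero, 0.5 is added to all four cells (Haldane-Anscombe) before
#' computing, keeping the OR finite. An all-zero table is undefined
#' (\code{NA}).
#'
#' @param pos_emb,neg_emb,pos_abem,neg_abem non-negative counts.
#' @return positive real, or \code{NA} for the all-zero table.
#' @export
odds_ratio <- function(pos_emb, neg_emb, pos_abem, neg_abem) {
  cells <- c(pos_emb, neg_emb, pos_abem, neg_abem)
  if (any(cells < 0)) stop("negative counts")
  if (all(cells == 0)) return(NA_real_)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Classify an odds ratio (or pole ratio) against the (1/3, 3) band
#' @param x positive statistic or \code{NA}.
#' @return \code{"balanced"}, \code{"unbalanced"}, or \code{NA}.
#' @export
classify_band <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x > 1 / 3 & x < 3, "balanced", "unbalanced"))
}

#' Pole-ratio statistic for one marker
#'
#' Ratio of marker-positive cells in the embryonic pole (n1) to
#' marker-positive cells in the abembryonic pole (n2), with 0.5 added to both
#' when either is zero; undefined when both are zero.
#'
#' @param n1,n2 non-negative counts.
#' @return positive real or \code{NA}.
#' @export
pole_ratio <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stop("negative counts")
  if (n1 == 0 && n2 == 0) return(NA_real_)
  if (n1 == 0 || n2 == 0) { n1 <- n1 + 0.5; n2 <- n2 + 0.5 }
  n1 / n2
}

#' Balance classification of imaged embryos under one counting method
#'
#' Methods: \code{"one_third"} and \code{"half"} apply the corresponding
#' inclusion rule and classify each marker's pole odds ratio;
#' \code{"all"} includes every embryo and classifies each marker's pole
#' ratio. The embryo is unbalanced if any evaluated marker is unbalanced;
#' markers with an undefined statistic are skipped, and an embryo with no
#' evaluable marker is not included.
#'
#' @param counts imaging-count table.
#' @param method \code{"one_third"}, \code{"half"} or \code{"all"}.
#' @param denominator passed to [inclusion()].
#' @return data.frame with one row per embryo: \code{embryo_id},
#'   \code{method}, \code{included}, per-marker statistics \code{gfp_stat}
#'   and \code{rfp_stat}, and \code{classification} (\code{"balanced"},
#'   \code{"unbalanced"} or \code{"not_included"}).
#' @export
balance_classify <- function(counts, method = c("one_third", "half", "all"),
                             denominator = "all") {
  method <- match.arg(method)
  validate_image_counts(counts)
  min_frac <- switch(method, one_third = 1 / 3, half = 1 / 2, all = 0)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, , drop = FALSE]
    inc <- method == "all" || inclusion(row, min_frac, denominator)
    stat <- c(gfp = NA_real_, rfp = NA_real_)
    cls <- "not_included"
    if (inc) {
      for (m in c("gfp", "rfp")) {
        stat[m] <- if (method == "all")
          pole_ratio(row[[paste0(m, "_pos_emb")]], row[[paste0(m, "_pos_abem")]])
        else
          odds_ratio(row[[paste0(m, "_pos_emb")]], row[[paste0(m, "_neg_emb")]],
                     row[[paste0(m, "_pos_abem")]], row[[paste0(m, "_neg_abem")]])
      }
      calls <- classify_band(stat)
      if (all(is.na(calls))) {
        inc <- FALSE
      } else {
        cls <- if (any(calls == "unbalanced", na.rm = TRUE)) "unbalanced" else "balanced"
      }
    }
    data.frame(embryo_id = row$embryo_id, method = method, included = inc,
               gfp_stat = stat[["gfp"]], rfp_stat = stat[["rfp"]],
               classification = if (inc) cls else "not_included",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize balance calls per method
#'
#' Percent unbalanced is truncated to an integer (8/12 -> 66). Methods with
#' no included embryo are omitted.
#'
#' @param results rows from [balance_classify()], possibly several methods.
#' @return data.frame with \code{method}, \code{n_included},
#'   \code{n_unbalanced}, \code{percent_unbalanced}.
#' @export
summarize_balance <- function(results) {
  out <- lapply(split(results, results$method), function(r) {
    inc <- r[r$included, , drop = FALSE]
    if (nrow(inc) == 0) return(NULL)
    u <- sum(inc$classification == "unbalanced")
    data.frame(method = r$method[1], n_included = nrow(inc), n_unbalanced = u,
               percent_unbalanced = as.integer(100 * u / nrow(inc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(method = character(0), n_included = integer(0),
                      n_unbalanced = integer(0), percent_unbalanced = integer(0))
  rownames(out) <- NULL
  out
}
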