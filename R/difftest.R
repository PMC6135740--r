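#' @title Per-feature lineage ANOVA, q-values and the shuffled background
#' @description
#' The second transcriptome-wide test: every feature gets an F test of the
#' null hypothesis of no between-lineage expression difference, from the
#' nested model of the variance-partition module
#' (\eqn{F = (SS_{lineage}/d_1)/(SS_{res}/d_{res})}). P-values are adjusted
#' to q-values (Benjamini-Hochberg by default). A background ensemble is
#' built by shuffling the lineage labels on every blastomere within its
#' embryo and re-running the identical test; real and background q-value
#' distributions are compared with a two-sample Kolmogorov-Smirnov test.
#' @name lineage_difference_test
NULL

#' Lineage ANOVA for one feature
#'
#' @inheritParams decompose_gene
#' @return list with \code{f_stat}, \code{p}, and the degrees of freedom
#'   \code{d1}, \code{d_res}; \code{NULL} when the feature must be skipped
#'   (no residual replication, or zero residual variance).
#' @export
anova_lineage <- function(y, embryo, lineage) {
  vp <- variance_partition_matrix(matrix(y, nrow = 1, dimnames = list("y", NULL)),
                                  embryo, lineage)
  d1 <- attr(vp, "d1"); d_res <- attr(vp, "d_res")
  if (d_res <= 0 || vp$ss_residual <= 0) return(NULL)
  f <- (vp$ss_lineage / d1) / (vp$ss_residual / d_res)
  list(f_stat = f, p = stats::pf(f, d1, d_res, lower.tail = FALSE),
       d1 = d1, d_res = d_res)
}

#' Multiple-testing adjustment of a p-value ensemble
#'
#' \code{"BH"} is the Benjamini-Hochberg step-up procedure; \code{"storey"}
#' additionally scales by the estimated null proportion
#' \eqn{\hat\pi_0 = \min(1, 2\,\overline{1\{p > 0.5\}})}.
#'
#' @param p_values numeric vector in [0, 1].
#' @param method \code{"BH"} (default) or \code{"storey"}.
#' @return q-values, monotone in p.
#' @export
compute_q <- function(p_values, method = c("BH", "storey")) {
  method <- match.arg(method)
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, 2 * mean(p_values > 0.5))
    q <- pmin(q * pi0, 1)
  }
  q
}

# internal: vectorized ANOVA + q over a log-scale matrix with given labels
.lineage_tests_labels <- function(Ylog, embryo, lineage, q_method = "BH") {
  vp <- variance_partition_matrix(Ylog, embryo, lineage)
  d1 <- attr(vp, "d1"); d_res <- attr(vp, "d_res")
  if (d_res <= 0) stop("no residual degrees of freedom: cannot test")
  ok <- vp$ss_residual > 0
  f <- ifelse(ok, (vp$ss_lineage / d1) / (vp$ss_residual / d_res), NA_real_)
  p <- stats::pf(f, d1, d_res, lower.tail = FALSE)
  out <- data.frame(feature_id = vp$feature_id, f_stat = f, p = p,
                    q = NA_real_, stringsAsFactors = FALSE)
  out$q[ok] <- compute_q(p[ok], method = q_method)
  out[ok, , drop = FALSE]
}

#' Per-feature lineage tests over an FPKM matrix
#'
#' Restricts to resolved cells of one stage, applies the expressed-feature
#' filter, transforms to log2(FPKM+1), and returns F, p and q per feature.
#' Features with zero residual variance are skipped.
#'
#' @inheritParams empirical_R
#' @param q_method passed to [compute_q()].
#' @return data.frame with \code{feature_id}, \code{f_stat}, \code{p},
#'   \code{q}.
#' @export
lineage_tests <- function(fpkm, cells, stage, threshold = 1.0, q_method = "BH") {
  keep <- cells$stage == stage & cells$lineage %in% c("A", "B")
  cc <- cells[keep, , drop = FALSE]
  if (nrow(cc) == 0) stop("no resolved cells at stage ", stage)
  m <- fpkm[, cc$cell_id, drop = FALSE]
  m <- m[rowSums(m > threshold) > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("no expressed features at stage ", stage)
  .lineage_tests_labels(log2(m + 1), cc$embryo_id, cc$lineage, q_method)
}

#' Shuffled-label background q-values
#'
#' For each shuffle the lineage labels are permuted within every embryo,
#' preserving the 2/2 (or 4/4) group sizes, and the full ANOVA + q pipeline
#' is re-run; q ensembles are pooled across shuffles. Shuffles are drawn with
#' replacement from the within-embryo permutation group, so a draw identical
#' to the real labels is permitted.
#'
#' @inheritParams lineage_tests
#' @param n_shuffles number of label shuffles pooled (default 1).
#' @param seed RNG seed for the permutations.
#' @param value \code{"q"} (default) pools adjusted values; \code{"p"} pools
#'   the raw permutation p-values, which is the right scale for calibration
#'   checks under a global null (q-values collapse onto near-degenerate
#'   atoms there).
#' @return numeric vector of pooled background values.
#' @export
shuffle_background <- function(fpkm, cells, stage, n_shuffles = 1, seed = 1,
                               threshold = 1.0, q_method = "BH",
                               value = c("q", "p")) {
  value <- match.arg(value)
  if (n_shuffles < 1) stop("n_shuffles must be at least 1")
  keep <- cells$stage == stage & cells$lineage %in% c("A", "B")
  cc <- cells[keep, , drop = FALSE]
  if (nrow(cc) == 0) stop("no resolved cells at stage ", stage)
  m <- fpkm[, cc$cell_id, drop = FALSE]
  m <- m[rowSums(m > threshold) > 0, , drop = FALSE]
  if (nrow(m) == 0) stop("no expressed features at stage ", stage)
  Ylog <- log2(m + 1)
  set.seed(seed)
  qs <- lapply(seq_len(n_shuffles), function(s) {
    shuffled <- cc$lineage
    for (e in unique(cc$embryo_id)) {
      idx <- which(cc$embryo_id == e)
      shuffled[idx] <- sample(cc$lineage[idx])
    }
    .lineage_tests_labels(Ylog, cc$embryo_id, shuffled, q_method)[[value]]
  })
  unlist(qs, use.names = FALSE)
}

#' Compare real and background q-value distributions
#'
#' Two-sample Kolmogorov-Smirnov test, plus counts of features below a
#' reference threshold \code{q_star} in each ensemble. P-values below the
#' double-precision floor are reported at the floor (2.2e-16).
#'
#' @param real_q,shuffled_q numeric q-value ensembles.
#' @param q_star reporting threshold, default 0.01.
#' @return list with \code{ks_stat}, \code{ks_p}, \code{n_real},
#'   \code{n_shuffled}, \code{n_real_below}, \code{n_shuffled_below},
#'   \code{q_star}.
#' @export
compare_distributions <- function(real_q, shuffled_q, q_star = 0.01) {
  if (length(real_q) == 0 || length(shuffled_q) == 0)
    stop("empty q-value ensemble")
  ks <- suppressWarnings(stats::ks.test(real_q, shuffled_q))
  list(ks_stat = unname(ks$statistic),
       ks_p = max(ks$p.value, 2.2e-16),
       n_real = length(real_q), n_shuffled = length(shuffled_q),
       n_real_below = sum(real_q < q_star),
       n_shuffled_below = sum(shuffled_q < q_star),
       q_star = q_star)
}
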