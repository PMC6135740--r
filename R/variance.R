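#' @title Nested variance partitioning and the lineage-variation ratio
#' @description
#' For every gene a Gaussian linear model with embryo as a factor and lineage
#' nested within embryo is decomposed by sequential (type-I) sums of squares,
#' embryo entered first:
#' \deqn{SS_{embryo} = \sum_i n_i(\bar y_i - \bar y)^2,\quad
#'       SS_{lineage} = \sum_i \sum_j n_{ij}(\bar y_{ij} - \bar y_i)^2,\quad
#'       SS_{res} = \sum (y - \bar y_{ij})^2}
#' with i indexing embryos and j the lineage within embryo. The per-gene
#' ratio \eqn{r_g = SS_{lineage}/(SS_{lineage}+SS_{embryo})} measures how much
#' of the structured variation is between lineages rather than between
#' embryos; under a balanced Gaussian null with E embryos,
#' \eqn{r_g \sim Beta(E/2, (E-1)/2)}. Lineage is nested because the A/B
#' labels are not comparable across embryos. Expression enters as
#' \code{log2(FPKM + 1)}.
#' @name variance_partition
NULL

.check_nested_design <- function(embryo, lineage) {
  embryo <- factor(embryo)
  lineage <- factor(lineage)
  if (nlevels(embryo) < 2) stop("need at least 2 embryos")
  tab <- table(embryo, lineage)
  if (any(tab == 0)) stop("every embryo needs cells of both lineages")
  list(embryo = embryo, lineage = lineage)
}

#' Nested sums of squares for one gene
#'
#' @param y per-cell values on the log2(FPKM+1) scale.
#' @param embryo,lineage per-cell labels; every embryo must contain both
#'   lineages and there must be at least two embryos.
#' @return list with \code{ss_embryo}, \code{ss_lineage}, \code{ss_residual}
#'   and \code{r} (\code{NA} when \code{ss_lineage + ss_embryo} is zero).
#' @export
decompose_gene <- function(y, embryo, lineage) {
  d <- .check_nested_design(embryo, lineage)
  vp <- variance_partition_matrix(matrix(y, nrow = 1, dimnames = list("y", NULL)),
                                  d$embryo, d$lineage)
  list(ss_embryo = vp$ss_embryo, ss_lineage = vp$ss_lineage,
       ss_residual = vp$ss_residual, r = vp$r)
}

#' Vectorized nested decomposition over a matrix of features
#'
#' @param Y numeric matrix, features in rows, cells in columns, on the
#'   analysis (log) scale.
#' @param embryo,lineage per-cell labels.
#' @return data.frame with one row per feature: sums of squares, \code{r},
#'   and the design degrees of freedom as attributes \code{d1} (lineage
#'   within embryo), \code{d2} (embryo) and \code{d_res}.
#' @export
variance_partition_matrix <- function(Y, embryo, lineage) {
  d <- .check_nested_design(embryo, lineage)
  e <- d$embryo; l <- d$lineage
  grp <- interaction(e, l, drop = TRUE)
  n_e <- as.numeric(table(e)); n_g <- as.numeric(table(grp))
  C <- ncol(Y)
  ind_e <- stats::model.matrix(~ 0 + e)
  ind_g <- stats::model.matrix(~ 0 + grp)
  grand <- rowSums(Y) / C
  M_e <- sweep(Y %*% ind_e, 2, n_e, "/")
  M_g <- sweep(Y %*% ind_g, 2, n_g, "/")
  ss_embryo <- rowSums(sweep((M_e - grand)^2, 2, n_e, "*"))
  emb_of_grp <- match(as.character(tapply(as.character(e), grp, `[`, 1)),
                      levels(e))
  M_e_g <- M_e[, emb_of_grp, drop = FALSE]
  ss_lineage <- rowSums(sweep((M_g - M_e_g)^2, 2, n_g, "*"))
  ss_total <- rowSums((Y - grand)^2)
  ss_residual <- pmax(ss_total - ss_embryo - ss_lineage, 0)
  denom <- ss_lineage + ss_embryo
  r <- ifelse(denom > 0, ss_lineage / denom, NA_real_)
  out <- data.frame(feature_id = rownames(Y), ss_embryo = ss_embryo,
                    ss_lineage = ss_lineage, ss_residual = ss_residual, r = r,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d1") <- nlevels(grp) - nlevels(e)
  attr(out, "d2") <- nlevels(e) - 1L
  attr(out, "d_res") <- C - nlevels(grp)
  out
}

#' Empirical distribution R of the ratio across expressed genes
#'
#' Restricts to resolved cells of one stage, applies the expressed-gene
#' filter (FPKM > threshold in at least one cell of the stage), transforms to
#' log2(FPKM+1) and returns one r per gene with a defined ratio, in gene
#' order.
#'
#' @param fpkm gene-by-cell FPKM matrix.
#' @param cells cell table with lineage calls.
#' @param stage \code{"four_cell"} or \code{"eight_cell"}.
#' @param threshold expressed-gene FPKM cutoff.
#' @return named numeric vector of r values.
#' @export
empirical_R <- function(fpkm, cells, stage, threshold = 1.0) {
  keep <- cells$stage == stage & cells$lineage %in% c("A", "B")
  cc <- cells[keep, , drop = FALSE]
  if (nrow(cc) == 0) stop("no resolved cells at stage ", stage)
  m <- fpkm[, cc$cell_id, drop = FALSE]
  expressed <- rowSums(m > threshold) > 0
  m <- m[expressed, , drop = FALSE]
  if (nrow(m) == 0) return(stats::setNames(numeric(0), character(0)))
  vp <- variance_partition_matrix(log2(m + 1), cc$embryo_id, cc$lineage)
  r <- stats::setNames(vp$r, vp$feature_id)
  r[!is.na(r)]
}

#' Compare the empirical R distribution against Beta references
#'
#' For each (a, b): the one-sample Kolmogorov-Smirnov distance between the r
#' values and Beta(a, b); empirical versus analytic upper-tail probabilities
#' \eqn{P(R \ge 1-\delta)} for each delta; and Q-Q points at percentiles
#' 1..99.
#'
#' @param r_values numeric vector in [0, 1].
#' @param params list of \code{c(a, b)} Beta parameter pairs.
#' @param deltas tail offsets.
#' @return list of \code{beta_comparison} entries, each with \code{alpha},
#'   \code{beta}, \code{ks_distance}, \code{tails} (data.frame delta /
#'   empirical / analytic) and \code{qq} (data.frame of Beta and empirical
#'   quantiles).
#' @export
compare_to_beta <- function(r_values,
                            params = list(c(1, 3), c(2, 2), c(5, 5)),
                            deltas = c(0.05, 0.1, 0.2)) {
  if (length(r_values) == 0) stop("empty r_values")
  probs <- seq(0.01, 0.99, by = 0.01)
  emp_q <- stats::quantile(r_values, probs, names = FALSE, type = 7)
  lapply(params, function(ab) {
    a <- ab[1]; b <- ab[2]
    ks <- suppressWarnings(stats::ks.test(r_values, stats::pbeta,
                                          shape1 = a, shape2 = b))
    tails <- data.frame(
      delta = deltas,
      empirical = vapply(deltas, function(d) mean(r_values >= 1 - d), numeric(1)),
      analytic = stats::pbeta(1 - deltas, a, b, lower.tail = FALSE))
    structure(list(alpha = a, beta = b,
                   ks_distance = unname(ks$statistic),
                   tails = tails,
                   qq = data.frame(beta_quantile = stats::qbeta(probs, a, b),
                                   empirical_quantile = emp_q)),
              class = "beta_comparison")
  })
}
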