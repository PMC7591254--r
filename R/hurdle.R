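# Two-part hurdle differential expression.
#
# Single-cell log-normalised expression is modelled in two parts: a
# detection component (is the gene expressed at all, Bernoulli with a group
# term, logistic-regression likelihood) and a continuous component (the
# positive log-expression values, Gaussian with a group term and a shared
# variance). Each component contributes a likelihood-ratio statistic; the
# two are summed and referred to a chi-square whose degrees of freedom is
# the number of informative components. With a single two-level factor both
# component MLEs have closed forms, which is what the vectorised core below
# evaluates.

# binomial log-likelihood at the MLE, with 0*log(0) = 0
.bin_ll <- function(k, n) {
  n <- rep_len(n, length(k))
  ll <- numeric(length(k))
  i <- k > 0
  ll[i] <- ll[i] + k[i] * log(k[i] / n[i])
  i <- k < n
  ll[i] <- ll[i] + (n[i] - k[i]) * log(1 - k[i] / n[i])
  ll
}

# Vectorised hurdle LRT over the rows of a genes x cells matrix.
# Returns per-gene statistic, df, p and detection bookkeeping.
hurdle_stats <- function(X, cells_a, cells_b) {
  Xa <- X[, cells_a, drop = FALSE]
  Xb <- X[, cells_b, drop = FALSE]
  na <- ncol(Xa); nb <- ncol(Xb)
  ka <- Matrix::rowSums(Xa > 0); kb <- Matrix::rowSums(Xb > 0)
  sxa <- Matrix::rowSums(Xa); sxb <- Matrix::rowSums(Xb)
  s2a <- Matrix::rowSums(Xa^2); s2b <- Matrix::rowSums(Xb^2)

  # detection component: group-wise vs pooled binomial likelihood
  K <- ka + kb; N <- na + nb
  det_stat <- 2 * (.bin_ll(ka, na) + .bin_ll(kb, nb) - .bin_ll(K, N))
  det_df <- as.numeric(K > 0 & K < N)
  det_stat[det_df == 0] <- 0

  # continuous component: equal-variance Gaussian LRT on positive values
  m <- ka + kb
  ss1 <- pmax(s2a - ifelse(ka > 0, sxa^2 / ka, 0), 0) +
    pmax(s2b - ifelse(kb > 0, sxb^2 / kb, 0), 0)
  ss0 <- pmax((s2a + s2b) - (sxa + sxb)^2 / pmax(m, 1), 0)
  cont_df <- as.numeric(ka > 0 & kb > 0 & m >= 3)
  cont_stat <- numeric(nrow(X))
  ok <- cont_df == 1 & ss1 > 1e-12
  cont_stat[ok] <- m[ok] * log(ss0[ok] / ss1[ok])
  sep <- cont_df == 1 & ss1 <= 1e-12 & ss0 > 1e-12
  cont_stat[sep] <- Inf # positive values perfectly separated by group
  cont_stat[cont_df == 1 & ss0 <= 1e-12] <- 0
  cont_stat <- pmax(cont_stat, 0)

  stat <- det_stat + cont_stat
  df <- det_df + cont_df
  p <- ifelse(df > 0, pchisq(stat, df, lower.tail = FALSE), 1)
  data.frame(statistic = stat, df = df, p_value = p,
             pct_a = ka / na, pct_b = kb / nb,
             untestable = K == 0, row.names = rownames(X))
}

#' Hurdle-model test for one gene
#'
#' Tests whether a gene's expression differs between two cell groups with a
#' two-part model: a logistic (detection) component and an equal-variance
#' Gaussian component on the positive log-expression values. The two
#' likelihood-ratio statistics are summed and referred to a chi-square with
#' one degree of freedom per informative component (a component with no
#' information - e.g. the gene is never, or always, detected - contributes
#' zero df). A gene at zero in both groups is untestable and reported with
#' p = 1.
#'
#' @param expr_a,expr_b numeric vectors of log-normalised expression in the
#'   two groups (zeros = undetected).
#' @return List with `statistic`, `df`, `p_value` and `untestable`.
#' @examples
#' hurdle_test(c(0, 0, 1.2, 2, 1.8), c(0, 0, 0, 0, 0.1))
#' @export
hurdle_test <- function(expr_a, expr_b) {
  if (length(expr_a) == 0 || length(expr_b) == 0) {
    stop("both groups must be non-empty")
  }
  X <- matrix(c(expr_a, expr_b), nrow = 1)
  res <- hurdle_stats(X, seq_along(expr_a),
                      length(expr_a) + seq_along(expr_b))
  list(statistic = res$statistic, df = res$df, p_value = res$p_value,
       untestable = res$untestable)
}

# log fold change on the log-normalised scale:
# ln(mean(expm1(x_a)) + 1) - ln(mean(expm1(x_b)) + 1)
log_fc_groups <- function(X, cells_a, cells_b) {
  ma <- Matrix::rowSums(expm1(X[, cells_a, drop = FALSE])) / length(cells_a)
  mb <- Matrix::rowSums(expm1(X[, cells_b, drop = FALSE])) / length(cells_b)
  log(ma + 1) - log(mb + 1)
}

de_table <- function(X, cells_a, cells_b, logfc_min, min_pct, adjust) {
  lfc <- log_fc_groups(X, cells_a, cells_b)
  stats <- hurdle_stats(X, cells_a, cells_b)
  tested <- (stats$pct_a >= min_pct | stats$pct_b >= min_pct) &
    abs(lfc) >= logfc_min & !stats$untestable
  out <- data.frame(gene = rownames(X), log_fc = lfc,
                    p_value = stats$p_value,
                    pct_a = stats$pct_a, pct_b = stats$pct_b,
                    row.names = NULL)[tested, , drop = FALSE]
  out$p_adj <- p.adjust(out$p_value, method = adjust)
  out$direction <- ifelse(out$log_fc > 0, "up", "down")
  out <- out[order(out$p_value, -abs(out$log_fc)), ]
  rownames(out) <- NULL
  out[, c("gene", "log_fc", "p_value", "p_adj", "pct_a", "pct_b",
          "direction")]
}

#' Cluster markers by hurdle-model DE
#'
#' Compares one cluster against all other cells. Genes are pre-filtered by
#' a minimum absolute log fold change (default 0.25 natural-log units, the
#' conventional marker threshold) and a minimum detection fraction in
#' either group, then hurdle-tested and multiple-testing adjusted
#' (Bonferroni by default; `"BH"` available).
#'
#' The log fold change is `ln(mean(expm1(x)) + 1)` in the cluster minus the
#' same in the rest, computed on log-normalised values.
#'
#' @param sce a count object with a `"lognorm"` assay, or a genes x cells
#'   log-expression matrix.
#' @param labels per-cell cluster labels (vector, length = cells).
#' @param group the cluster id to profile.
#' @param logfc_min minimum |log fold change| (natural log), default 0.25.
#' @param min_pct minimum detection fraction in at least one group,
#'   default 0.10.
#' @param adjust multiple-testing method for `p_adj` (default
#'   `"bonferroni"`).
#' @return A DE table: data.frame with columns gene, log_fc, p_value,
#'   p_adj, pct_a (group), pct_b (rest), direction.
#' @export
find_markers <- function(sce, labels, group, logfc_min = 0.25,
                         min_pct = 0.10, adjust = "bonferroni") {
  X <- if (is(sce, "SingleCellExperiment")) assay(sce, "lognorm") else sce
  stopifnot(length(labels) == ncol(X))
  cells_a <- which(labels == group)
  if (length(cells_a) < 3) {
    stop("cluster ", group, " has fewer than 3 cells")
  }
  cells_b <- which(labels != group)
  if (length(cells_b) == 0) stop("no comparison cells outside the group")
  de_table(X, cells_a, cells_b, logfc_min, min_pct, adjust)
}

#' Hurdle-model DE between two arbitrary cell sets
#'
#' Like [find_markers()] but for any two disjoint cell sets, e.g. the
#' MAC2+ cells against the homeostatic cluster, at the stricter default
#' threshold |logFC| >= 0.5 used for that contrast.
#'
#' @param sce count object with `"lognorm"` assay, or matrix.
#' @param cells_a,cells_b disjoint cell index or cell-id vectors.
#' @inheritParams find_markers
#' @return A DE table (see [find_markers()]).
#' @export
contrast_de <- function(sce, cells_a, cells_b, logfc_min = 0.5,
                        min_pct = 0.10, adjust = "bonferroni") {
  X <- if (is(sce, "SingleCellExperiment")) assay(sce, "lognorm") else sce
  if (is.character(cells_a)) cells_a <- match(cells_a, colnames(X))
  if (is.character(cells_b)) cells_b <- match(cells_b, colnames(X))
  if (anyNA(cells_a) || anyNA(cells_b)) stop("unknown cell id(s)")
  if (length(intersect(cells_a, cells_b)) > 0) {
    stop("cell sets overlap")
  }
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stop("both cell sets must be non-empty")
  }
  de_table(X, cells_a, cells_b, logfc_min, min_pct, adjust)
}

#' Write a DE table as CSV
#'
#' @param de a DE table from [find_markers()] or [contrast_de()].
#' @param file output CSV path (fixed column order).
#' @export
write_de_table <- function(de, file) {
  utils::write.csv(de[, c("gene", "log_fc", "p_value", "p_adj", "pct_a",
                          "pct_b", "direction")], file, row.names = FALSE)
  invisible(file)
}
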