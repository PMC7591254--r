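#' Gate cells positive for a marker by the mean + k SD rule
#'
#' Classifies a cell as marker-positive when its log-normalised expression
#' exceeds (strictly) the mean plus `k_sd` standard deviations of the
#' marker across all cells, zeros included - the rule used to call MAC2+
#' cells from Lgals3 log UMI. The threshold is computed once over the
#' pooled object, not per condition. The sample (n - 1) standard deviation
#' is the default; set `sd_type = "population"` for the n denominator.
#'
#' @param expr named numeric vector: one gene's log-normalised expression
#'   per cell, or a count object plus `gene` to pull it from.
#' @param k_sd number of standard deviations above the mean (default 1).
#' @param gene gene id when `expr` is a count object.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return A `gate_result`: list with `threshold`, `k_sd`, logical
#'   `labels` per cell, and `n_positive`.
#' @examples
#' g <- gate_positive(c(a = 0, b = 0, c = 0, d = 4))
#' g$threshold # 1 + 1 * 2 = 3; only cell d is positive
#' @export
gate_positive <- function(expr, k_sd = 1, gene = NULL, sd_type = "sample") {
  if (is(expr, "SingleCellExperiment")) {
    if (is.null(gene)) stop("supply `gene` when gating a count object")
    if (!"lognorm" %in% assayNames(expr)) stop("run log_normalize() first")
    expr <- setNames(as.numeric(assay(expr, "lognorm")[gene, ]),
                     colnames(expr))
  }
  if (length(expr) == 0) stop("expression vector is empty")
  mu <- mean(expr)
  s <- stats::sd(expr)
  if (sd_type == "population") s <- s * sqrt((length(expr) - 1) / length(expr))
  if (is.na(s) || s == 0) {
    warning("zero expression variance; no cells gated positive")
    s <- 0
  }
  threshold <- mu + k_sd * s
  labels <- expr > threshold
  structure(list(threshold = threshold, k_sd = k_sd, labels = labels,
                 n_positive = sum(labels)), class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("gate: threshold", format(x$threshold, digits = 4), "(mean +",
      x$k_sd, "SD);", x$n_positive, "of", length(x$labels),
      "cells positive\n")
  invisible(x)
}

#' Positive-cell frequency per condition
#'
#' Tabulates, for each experimental condition, the number of gated-positive
#' cells, the condition total, and the percentage (reported to one
#' decimal), e.g. 300 of 10,103 Ctrl cells -> 3.0%.
#'
#' @param gate a `gate_result` (or a logical per-cell vector).
#' @param conditions per-cell condition labels, same length/order as the
#'   gated cells.
#' @return data.frame with columns condition, n_positive, n_total, pct.
#' @export
condition_frequencies <- function(gate, conditions) {
  labels <- if (is(gate, "gate_result")) gate$labels else gate
  stopifnot(length(labels) == length(conditions))
  conditions <- as.character(conditions)
  lv <- if (all(unique(conditions) %in% condition_levels())) {
    condition_levels()
  } else sort(unique(conditions))
  present <- lv %in% conditions
  if (!all(present)) {
    warning("condition(s) with zero cells omitted: ",
            paste(lv[!present], collapse = ", "))
    lv <- lv[present]
  }
  n_total <- vapply(lv, function(cd) sum(conditions == cd), numeric(1))
  n_positive <- vapply(lv, function(cd) sum(labels[conditions == cd]),
                       numeric(1))
  data.frame(condition = lv, n_positive = n_positive, n_total = n_total,
             pct = round(100 * n_positive / n_total, 1), row.names = NULL)
}

#' Cluster composition of gated-positive cells
#'
#' Counts positive cells per cluster; the counts sum to the total number of
#' positives.
#'
#' @param gate a `gate_result` (or logical per-cell vector).
#' @param clusters per-cell cluster labels.
#' @return data.frame with columns cluster, n_positive, pct_of_positives.
#' @export
cluster_composition <- function(gate, clusters) {
  labels <- if (is(gate, "gate_result")) gate$labels else gate
  stopifnot(length(labels) == length(clusters))
  tab <- table(cluster = clusters[labels])
  pos <- sum(labels)
  data.frame(cluster = names(tab), n_positive = as.numeric(tab),
             pct_of_positives = if (pos > 0) {
               round(100 * as.numeric(tab) / pos, 1)
             } else numeric(length(tab)),
             row.names = NULL)
}
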