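#' Quality-control thresholds
#'
#' Defaults are the study's stated filters: cells with a total UMI count
#' below 500 or above 20,000, fewer than 200 detected genes, or more than
#' 10% mitochondrial counts are removed; genes detected in fewer than 10 of
#' the surviving cells are then removed. All boundaries are read literally
#' ("below", "above", "less than", "greater than" are strict), so a cell at
#' exactly 500 UMI or exactly 10% mito survives.
#'
#' @param umi_min,umi_max,genes_min,mito_max,gene_min_cells rule thresholds.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(umi_min = 500, umi_max = 20000, genes_min = 200,
                          mito_max = 0.10, gene_min_cells = 10) {
  stopifnot(umi_min < umi_max, mito_max > 0, mito_max <= 1,
            genes_min >= 0, gene_min_cells >= 0)
  structure(list(umi_min = umi_min, umi_max = umi_max, genes_min = genes_min,
                 mito_max = mito_max, gene_min_cells = gene_min_cells),
            class = "qc_thresholds")
}

#' Apply cell- and gene-level quality filters
#'
#' All cell rules are evaluated jointly on the input matrix (so their order
#' cannot matter); the gene rule is then applied to the surviving cells.
#' The percent-mito of a cell is the share of its total counts on genes
#' flagged `is_mito`, computed before any gene removal.
#'
#' @param sce a count object (see [count_matrix()]).
#' @param thresholds a [qc_thresholds()] object.
#' @param cell_blacklist optional character vector of cell ids to drop in
#'   addition to the rule-based filters (hook for manual outlier removal;
#'   no automatic outlier rule is applied).
#' @return A list with `sce` (the filtered object) and `report`, a
#'   `qc_report` holding input/output dimensions, per-rule removal counts
#'   (a cell failing several rules is counted under each) and the per-cell
#'   QC statistics table.
#' @examples
#' sce <- generate_counts(gen_params(n_genes = 300, n_cells_per_sample = 40,
#'   samples_per_condition = c(Ctrl = 1, D0 = 1, D2 = 1)))
#' res <- apply_qc(sce, qc_thresholds())
#' res$report$n_cells_out
#' @export
apply_qc <- function(sce, thresholds = qc_thresholds(),
                     cell_blacklist = NULL) {
  stopifnot(is(thresholds, "qc_thresholds"))
  counts <- assay(sce, "counts")
  th <- thresholds
  total <- Matrix::colSums(counts)
  n_detected <- Matrix::colSums(counts > 0)
  mito_flag <- rowData(sce)$is_mito
  if (!any(mito_flag)) {
    warning("no mitochondrial genes flagged; percent-mito rule passes vacuously")
    pct_mito <- rep(0, ncol(counts))
  } else {
    mito_counts <- Matrix::colSums(counts[mito_flag, , drop = FALSE])
    pct_mito <- ifelse(total > 0, mito_counts / total, 0)
  }

  fail_umi_low <- total < th$umi_min
  fail_umi_high <- total > th$umi_max
  fail_genes <- n_detected < th$genes_min
  fail_mito <- pct_mito > th$mito_max
  fail_blacklist <- colnames(counts) %in% (cell_blacklist %||% character())
  keep_cell <- !(fail_umi_low | fail_umi_high | fail_genes | fail_mito |
                   fail_blacklist)

  kept <- sce[, keep_cell]
  detected_in <- Matrix::rowSums(assay(kept, "counts") > 0)
  keep_gene <- detected_in >= th$gene_min_cells
  out <- kept[keep_gene, ]
  if (ncol(out) == 0 && ncol(sce) > 0) {
    warning("all cells removed by QC")
  }

  report <- structure(list(
    n_cells_in = ncol(sce), n_cells_out = ncol(out),
    n_genes_in = nrow(sce), n_genes_out = nrow(out),
    removals = c(umi_low = sum(fail_umi_low), umi_high = sum(fail_umi_high),
                 few_genes = sum(fail_genes), high_mito = sum(fail_mito),
                 blacklist = sum(fail_blacklist),
                 genes_low_detection = sum(!keep_gene)),
    thresholds = th,
    cell_stats = data.frame(cell_id = colnames(counts), total_umi = total,
                            n_genes = n_detected, pct_mito = pct_mito,
                            kept = keep_cell, row.names = NULL)
  ), class = "qc_report")
  list(sce = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_cells_in, "cells /", x$n_genes_in, "genes in;",
      x$n_cells_out, "cells /", x$n_genes_out, "genes out\n")
  cat("removals (cells may fail several rules):\n")
  print(x$removals)
  invisible(x)
}

#' Write a QC report to disk
#'
#' Writes the summary as JSON and the per-cell statistics as TSV.
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path directory to write `qc_report.json` and `qc_cells.tsv` into.
#' @export
write_qc_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_cells_in = report$n_cells_in, n_cells_out = report$n_cells_out,
         n_genes_in = report$n_genes_in, n_genes_out = report$n_genes_out,
         removals = as.list(report$removals),
         thresholds = unclass(report$thresholds)),
    file.path(path, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  write.table(report$cell_stats, file.path(path, "qc_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
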