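#' Build a single-cell count object
#'
#' Wraps a sparse genes x cells integer count matrix plus per-cell and
#' per-gene annotation into a [SingleCellExperiment::SingleCellExperiment],
#' the container used by every downstream step. Cell metadata carries the
#' sample of origin, the experimental condition (`Ctrl` untreated, `D0` end
#' of CSF1R-inhibitor treatment, `D2` two days of repopulation) and - for
#' synthetic data - the planted ground truth. Gene metadata carries the
#' mitochondrial flag used by QC and the marker-panel membership used by
#' annotation.
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense
#'   or any `Matrix` sparse class; stored as `dgCMatrix`).
#' @param cell_meta data.frame with one row per cell: `cell_id`, `sample_id`,
#'   `condition` (levels `Ctrl`, `D0`, `D2`), optionally `true_population`
#'   and `true_mac2`.
#' @param gene_meta data.frame with one row per gene: `gene_id`, logical
#'   `is_mito`, and `panels` (comma-separated panel names, may be empty).
#' @return A `SingleCellExperiment` with assay `"counts"`.
#' @examples
#' m <- Matrix::rsparsematrix(5, 4, 0.5, rand.x = function(n) rpois(n, 3))
#' m@x <- abs(m@x)
#' sce <- count_matrix(m,
#'   cell_meta = data.frame(
#'     cell_id = paste0("c", 1:4), sample_id = "s1", condition = "Ctrl"),
#'   gene_meta = data.frame(
#'     gene_id = paste0("g", 1:5), is_mito = FALSE, panels = ""))
#' @export
count_matrix <- function(counts, cell_meta, gene_meta) {
  counts <- as(as(as(counts, "dMatrix"), "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta rows (", nrow(cell_meta), ") != matrix columns (",
         ncol(counts), ")")
  }
  if (nrow(gene_meta) != nrow(counts)) {
    stop("gene_meta rows (", nrow(gene_meta), ") != matrix rows (",
         nrow(counts), ")")
  }
  stopifnot(all(c("cell_id", "sample_id", "condition") %in% names(cell_meta)),
            all(c("gene_id", "is_mito") %in% names(gene_meta)))
  bad <- setdiff(unique(as.character(cell_meta$condition)), condition_levels())
  if (length(bad)) {
    stop("unknown condition level(s): ", paste(bad, collapse = ", "))
  }
  cell_meta$condition <- factor(as.character(cell_meta$condition),
                                levels = condition_levels())
  if (is.null(gene_meta$panels)) gene_meta$panels <- ""
  rownames(counts) <- gene_meta$gene_id
  colnames(counts) <- cell_meta$cell_id
  SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_meta, row.names = cell_meta$cell_id),
    rowData = DataFrame(gene_meta, row.names = gene_meta$gene_id)
  )
}

#' @rdname count_matrix
#' @export
condition_levels <- function() c("Ctrl", "D0", "D2")

#' Write / read a count object as 10x-style plain-text files
#'
#' `write_tenx()` writes `matrix.mtx` (Matrix Market, 1-based coordinates),
#' `features.tsv` (gene_id, gene_symbol, mito flag, panel membership),
#' `barcodes.tsv` and `cell_metadata.tsv` under `path`. `read_tenx()`
#' reads them back; the pair round-trips counts and metadata exactly.
#'
#' @param sce a count object from [count_matrix()] or [generate_counts()].
#' @param path directory to write into (created if absent).
#' @return `write_tenx()` the path, invisibly; `read_tenx()` a
#'   `SingleCellExperiment`.
#' @export
write_tenx <- function(sce, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  Matrix::writeMM(assay(sce, "counts"), file.path(path, "matrix.mtx"))
  gm <- as.data.frame(rowData(sce))
  feat <- data.frame(gene_id = gm$gene_id, gene_symbol = gm$gene_id,
                     is_mito = gm$is_mito,
                     panels = gm$panels %||% "")
  write.table(feat, file.path(path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(colnames(sce), file.path(path, "barcodes.tsv"))
  cm <- as.data.frame(colData(sce))
  write.table(cm, file.path(path, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tenx
#' @export
read_tenx <- function(path) {
  counts <- as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
  feat <- read.delim(file.path(path, "features.tsv"),
                     colClasses = c(panels = "character"))
  feat$panels[is.na(feat$panels)] <- ""
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  cm_path <- file.path(path, "cell_metadata.tsv")
  if (file.exists(cm_path) && ncol(counts) > 0) {
    cm <- read.delim(cm_path)
    cm <- cm[match(barcodes, cm$cell_id), , drop = FALSE]
  } else {
    cm <- data.frame(cell_id = barcodes,
                     sample_id = rep("unknown", length(barcodes)),
                     condition = rep("Ctrl", length(barcodes)))
  }
  count_matrix(counts, cm, feat[c("gene_id", "is_mito", "panels")])
}

#' Genes belonging to a named panel
#'
#' Looks up panel membership recorded in `rowData(sce)$panels`
#' (comma-separated panel names per gene).
#'
#' @param sce a count object.
#' @param panel panel name, e.g. `"myeloid"` or `"stage_YS"`.
#' @return Character vector of gene ids.
#' @export
panel_genes <- function(sce, panel) {
  p <- strsplit(rowData(sce)$panels %||% rep("", nrow(sce)), ",", fixed = TRUE)
  rownames(sce)[vapply(p, function(x) panel %in% x, logical(1))]
}
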