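#' Cluster cells on PCA scores via a shared-nearest-neighbour graph
#'
#' Builds a k-nearest-neighbour graph on the PC scores (Euclidean), weights
#' each edge by the Jaccard overlap of the two cells' neighbour sets, prunes
#' weak edges, and runs Louvain modularity optimisation. Clusters are
#' relabelled in decreasing size order, so labels are stable for a given
#' seed.
#'
#' @param scores cells x k numeric matrix (see [reduce_pca()]).
#' @param resolution Louvain resolution (default 0.8; higher gives more
#'   clusters).
#' @param seed RNG seed for the community search.
#' @param snn_k neighbours per cell for the SNN graph (default 20).
#' @param prune minimum Jaccard weight kept as an edge (default 1/15).
#' @param pcs_use columns of `scores` to use (default all, i.e. the leading
#'   components kept at the PCA step).
#' @return A `cluster_assignment`: list with integer `labels` (one per
#'   cell, 1 = largest cluster), `n_clusters`, `params`, and an
#'   `annotations` map (filled by [annotate_and_strip()]).
#' @export
cluster_cells <- function(scores, resolution = 0.8, seed = 42L,
                          snn_k = 20, prune = 1 / 15, pcs_use = NULL) {
  if (!is.null(pcs_use)) scores <- scores[, pcs_use, drop = FALSE]
  n <- nrow(scores)
  if (n < snn_k + 1) {
    stop("fewer cells (", n, ") than the neighbour count (", snn_k + 1, ")")
  }
  nn <- RANN::nn2(scores, k = snn_k + 1)$nn.idx # includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  k1 <- ncol(nn)
  snn <- shared
  snn@x <- snn@x / (2 * k1 - snn@x) # Jaccard for equal-size sets
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  # relabel by decreasing cluster size (ties: first-seen order)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  labels <- unname(relab[as.character(memb)])
  names(labels) <- rownames(scores)
  structure(list(
    labels = labels,
    n_clusters = length(sizes),
    params = list(resolution = resolution, seed = seed, snn_k = snn_k,
                  prune = prune, n_pcs = ncol(scores)),
    annotations = setNames(rep("unknown", length(sizes)), seq_along(sizes))
  ), class = "cluster_assignment")
}

#' Choose a clustering resolution by sweeping towards a target cluster count
#'
#' The cluster count, not the resolution, is the reproducible quantity of
#' the original analysis (nine clusters before contaminant removal, five
#' after). This helper clusters the same scores at a grid of resolutions
#' and returns the assignment whose cluster count is closest to
#' `target_k` (ties favour the lower resolution, i.e. the coarser
#' solution).
#'
#' @inheritParams cluster_cells
#' @param target_k desired number of clusters.
#' @param resolutions grid to sweep.
#' @return The selected `cluster_assignment` (its `params$resolution`
#'   records the choice).
#' @export
sweep_resolution <- function(scores, target_k, resolutions = seq(0.2, 1.2,
                                                                 by = 0.2),
                             seed = 42L, snn_k = 20) {
  fits <- lapply(resolutions, function(r) {
    cluster_cells(scores, resolution = r, seed = seed, snn_k = snn_k)
  })
  ks <- vapply(fits, function(f) f$n_clusters, numeric(1))
  fits[[which.min(abs(ks - target_k))]]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster assignment:", length(x$labels), "cells in", x$n_clusters,
      "clusters (resolution ", x$params$resolution, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Annotate clusters by marker panels and remove contaminants
#'
#' Computes, for every cluster, the detection fraction of the core myeloid
#' panel (Itgam, Aif1, Cx3cr1, Csf1r) and of each contaminant panel
#' (neutrophil, lymphoid, endothelial, astroglial). Clusters whose myeloid
#' score falls below `myeloid_threshold` are labelled with their
#' best-scoring contaminant panel and their cells are removed, leaving the
#' myeloid object used by all downstream stages; remaining clusters are
#' labelled `"myeloid"`.
#'
#' @param sce a count object.
#' @param assignment a `cluster_assignment` for the cells of `sce`.
#' @param marker_panels named list of gene vectors; must contain `myeloid`
#'   plus at least one contaminant panel. Defaults to the panels recorded in
#'   `rowData(sce)$panels`.
#' @param myeloid_threshold detection-fraction threshold below which a
#'   cluster is called non-myeloid (default 0.25).
#' @return List with the stripped `sce`, the updated `assignment`
#'   (annotations filled, labels subset to retained cells) and the
#'   cluster x panel `scores` matrix.
#' @export
annotate_and_strip <- function(sce, assignment, marker_panels = NULL,
                               myeloid_threshold = 0.25) {
  stopifnot(is(assignment, "cluster_assignment"),
            length(assignment$labels) == ncol(sce))
  if (is.null(marker_panels)) {
    marker_panels <- c(
      list(myeloid = panel_genes(sce, "myeloid")),
      setNames(lapply(contaminant_populations(), panel_genes, sce = sce),
               contaminant_populations()))
    marker_panels <- marker_panels[vapply(marker_panels, length,
                                          integer(1)) > 0]
  }
  if (!"myeloid" %in% names(marker_panels) ||
      length(marker_panels$myeloid) == 0) {
    stop("marker_panels must include a non-empty 'myeloid' panel")
  }
  counts <- assay(sce, "counts")
  labels <- assignment$labels
  clusters <- sort(unique(labels))
  panel_det <- function(pn, cells) {
    genes <- intersect(marker_panels[[pn]], rownames(counts))
    if (length(genes) == 0) return(NA_real_)
    mean(Matrix::rowMeans(counts[genes, cells, drop = FALSE] > 0))
  }
  scores <- sapply(names(marker_panels), function(pn) {
    vapply(clusters, function(cl) panel_det(pn, labels == cl), numeric(1))
  })
  scores <- matrix(scores, nrow = length(clusters),
                   dimnames = list(clusters, names(marker_panels)))
  contam_panels <- setdiff(colnames(scores), "myeloid")
  is_contam <- setNames(scores[, "myeloid"] < myeloid_threshold,
                        rownames(scores))
  if (all(is_contam)) stop("all clusters scored non-myeloid")
  ann <- setNames(rep("myeloid", length(clusters)), clusters)
  if (any(is_contam) && length(contam_panels)) {
    # identity call: detection enrichment over the rest of the data, so
    # ubiquitously detected panel genes do not dominate the label
    enrich <- sapply(contam_panels, function(pn) {
      vapply(clusters[is_contam], function(cl) {
        panel_det(pn, labels == cl) - panel_det(pn, labels != cl)
      }, numeric(1))
    })
    enrich <- matrix(enrich, nrow = sum(is_contam),
                     dimnames = list(clusters[is_contam], contam_panels))
    best <- contam_panels[apply(enrich, 1, which.max)]
    best[apply(enrich, 1, function(x) all(is.na(x) | x <= 0))] <- "unknown"
    ann[is_contam] <- best
  } else if (any(is_contam)) {
    ann[is_contam] <- "unknown"
  }
  keep <- unname(!is_contam[as.character(labels)])
  out <- assignment
  out$labels <- labels[keep]
  out$annotations <- ann
  out$n_clusters <- length(unique(out$labels))
  list(sce = sce[, keep], assignment = out, scores = scores)
}

#' Write a cluster assignment as TSV
#'
#' @param assignment a `cluster_assignment`.
#' @param file output path; columns barcode, cluster, annotation.
#' @export
write_cluster_assignment <- function(assignment, file) {
  df <- data.frame(barcode = names(assignment$labels),
                   cluster = unname(assignment$labels),
                   annotation = unname(
                     assignment$annotations[as.character(assignment$labels)]))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
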