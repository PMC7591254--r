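#' Tabulate cells per cluster and sample
#'
#' Builds the samples x clusters cell-count table used by the differential
#' abundance model, together with each sample's total captured cells (the
#' normalising offset) and condition.
#'
#' @param cells a count object whose `colData` has `sample_id` and
#'   `condition`, or a data.frame with those columns; cluster labels are
#'   taken from `clusters` (or a `cluster` column).
#' @param clusters per-cell cluster labels (optional if `cells` has a
#'   `cluster` column).
#' @return A `cluster_counts`: list with `counts` (samples x clusters
#'   integer matrix), `total_cells` (per sample) and `condition` (factor
#'   per sample).
#' @export
tabulate_counts <- function(cells, clusters = NULL) {
  meta <- if (is(cells, "SingleCellExperiment")) {
    as.data.frame(colData(cells))
  } else as.data.frame(cells)
  if (is.null(clusters)) clusters <- meta$cluster
  stopifnot(!is.null(clusters), length(clusters) == nrow(meta),
            all(c("sample_id", "condition") %in% names(meta)))
  tab <- table(sample = meta$sample_id, cluster = clusters)
  counts <- matrix(as.numeric(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  cond <- vapply(rownames(counts), function(s) {
    as.character(meta$condition[match(s, meta$sample_id)])
  }, character(1))
  structure(list(counts = counts,
                 total_cells = rowSums(counts),
                 condition = factor(cond, levels = intersect(
                   condition_levels(), unique(cond)))),
            class = "cluster_counts")
}

#' Negative-binomial GLM for one cluster's counts
#'
#' Log-link NB regression of per-sample cell counts on condition with a
#' per-sample log-total offset. Coefficients come from iteratively
#' reweighted least squares at fixed dispersion; the dispersion (1/size)
#' is chosen by profile maximum likelihood over a log grid. As the data
#' approach Poisson the profiled dispersion goes to zero and the
#' coefficients converge to a Poisson GLM's.
#'
#' @param y per-sample counts for one cluster.
#' @param condition per-sample condition factor.
#' @param offset_log per-sample log of total cells captured.
#' @return List with `coefficients`, `dispersion` (1/size), `theta`
#'   (NB size), `fitted`, `loglik`, and `flagged` (TRUE when the counts
#'   are all zero and no model is fit). A condition level with all-zero
#'   counts triggers a small continuity correction with a warning.
#' @export
fit_nb_glm <- function(y, condition, offset_log) {
  stopifnot(length(y) == length(condition),
            length(y) == length(offset_log))
  condition <- droplevels(as.factor(condition))
  if (all(y == 0)) {
    warning("all counts are zero; no model fit")
    return(list(coefficients = NULL, dispersion = NA_real_,
                theta = NA_real_, fitted = rep(0, length(y)),
                loglik = NA_real_, flagged = TRUE))
  }
  zero_level <- vapply(levels(condition),
                       function(l) all(y[condition == l] == 0), logical(1))
  if (any(zero_level)) {
    warning("condition level(s) with all-zero counts (",
            paste(levels(condition)[zero_level], collapse = ", "),
            "); applying a 0.25 continuity correction")
    y <- y + 0.25
  }
  fit_at <- function(theta) {
    suppressWarnings(stats::glm(
      y ~ condition + offset(offset_log),
      family = MASS::negative.binomial(theta = theta)))
  }
  prof <- function(log_theta) {
    fit <- fit_at(exp(log_theta))
    sum(dnbinom(round(y), size = exp(log_theta), mu = fitted(fit),
                log = TRUE))
  }
  opt <- stats::optimize(prof, c(log(1e-3), log(1e8)), maximum = TRUE,
                         tol = 1e-6)
  theta <- exp(opt$maximum)
  # flat profiles at the Poisson end: snap to the boundary
  if (opt$maximum > log(1e8) - 1) theta <- 1e8
  fit <- fit_at(theta)
  list(coefficients = coef(fit), dispersion = 1 / theta, theta = theta,
       fitted = unname(fitted(fit)), loglik = opt$objective,
       flagged = FALSE)
}

#' Differential cluster abundance across conditions
#'
#' Tests, per cluster and condition contrast, whether the cluster's cell
#' frequency differs, with a negative-binomial GLM on cells-per-cluster
#' counts offset by each sample's log total (edgeR's quasi-likelihood
#' machinery: common dispersion across clusters, then a QL F-test per
#' contrast). With fewer than one residual degree of freedom (one sample
#' per level) the test falls back to a likelihood-ratio chi-square with a
#' warning. No multiple-testing correction is applied by default (set
#' `adjust = "BH"` to add one).
#'
#' @param counts a `cluster_counts` from [tabulate_counts()].
#' @param contrasts list of condition pairs `c(level, reference)`;
#'   defaults to D0 vs Ctrl and D2 vs Ctrl.
#' @param adjust p-value adjustment across clusters (default `"none"`).
#' @return data.frame with cluster, contrast, log_fold_change (natural
#'   log), p_value, p_adj, dispersion_estimate.
#' @export
test_abundance <- function(counts, contrasts = NULL, adjust = "none") {
  stopifnot(is(counts, "cluster_counts"))
  cond <- counts$condition
  lev <- levels(cond)
  if (is.null(contrasts)) {
    contrasts <- lapply(setdiff(lev, "Ctrl"), function(l) c(l, "Ctrl"))
  }
  for (ct in contrasts) {
    if (!all(ct %in% lev)) {
      stop("contrast references absent level(s): ",
           paste(setdiff(ct, lev), collapse = ", "))
    }
  }
  y <- t(counts$counts) # clusters x samples, edgeR orientation
  if (is.null(rownames(y))) rownames(y) <- paste0("cluster", seq_len(nrow(y)))
  dge <- edgeR::DGEList(counts = y, lib.size = counts$total_cells)
  design <- model.matrix(~ 0 + cond)
  colnames(design) <- lev
  resid_df <- ncol(y) - ncol(design)
  use_ql <- resid_df >= 1
  if (use_ql) {
    dge <- edgeR::estimateDisp(dge, design)
    fit <- edgeR::glmQLFit(dge, design)
    disp <- dge$common.dispersion
  } else {
    warning("no residual degrees of freedom; ",
            "falling back to a Poisson likelihood-ratio chi-square test")
    fit <- edgeR::glmFit(dge, design, dispersion = 0)
    disp <- 0
  }
  rows <- lapply(contrasts, function(ct) {
    cvec <- as.numeric(lev == ct[1]) - as.numeric(lev == ct[2])
    res <- if (use_ql) {
      edgeR::glmQLFTest(fit, contrast = cvec)
    } else {
      edgeR::glmLRT(fit, contrast = cvec)
    }
    tab <- res$table
    data.frame(cluster = rownames(y),
               contrast = paste(ct[1], "vs", ct[2]),
               log_fold_change = tab$logFC * log(2),
               p_value = tab$PValue,
               dispersion_estimate = disp,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::ave(out$p_value, out$contrast,
                          FUN = function(p) p.adjust(p, method = adjust))
  out
}

#' Write cluster counts / abundance results as CSV
#'
#' @param counts a `cluster_counts`.
#' @param file output path.
#' @export
write_cluster_counts <- function(counts, file) {
  df <- data.frame(sample = rownames(counts$counts),
                   condition = as.character(counts$condition),
                   total_cells = counts$total_cells,
                   as.data.frame(counts$counts), check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
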