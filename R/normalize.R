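#' Log-normalise counts
#'
#' Scales each cell to a common target total and log-transforms:
#' `value(g, c) = ln(1 + count(g, c) * scale_total / total(c))`. Zeros map
#' to zero, so the result stays sparse. The result is stored as assay
#' `"lognorm"`; this (pre-regression) scale is the one the marker gate and
#' the hurdle tests operate on.
#'
#' @param sce a count object.
#' @param scale_total per-cell target total (default 10,000).
#' @return `sce` with an added `"lognorm"` assay and
#'   `metadata(sce)$scale_total` set.
#' @export
log_normalize <- function(sce, scale_total = 1e4) {
  counts <- assay(sce, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(counts)[total == 0], 5), collapse = ", "))
  }
  m <- as(counts, "CsparseMatrix")
  m@x <- log1p(m@x * scale_total / rep.int(total, diff(m@p)))
  assay(sce, "lognorm") <- m
  metadata(sce)$scale_total <- scale_total
  sce
}

#' Regress technical covariates out of the log-normalised matrix
#'
#' Fits, for every gene, an ordinary least-squares model of log-normalised
#' expression on an intercept, the per-cell total UMI count and the per-cell
#' mitochondrial fraction, and keeps the residuals (assay `"corrected"`).
#' Constant covariate columns are dropped with a warning.
#'
#' @param sce a count object with a `"lognorm"` assay (see
#'   [log_normalize()]).
#' @param covariates optional data.frame with columns `total_umi` and
#'   `pct_mito` (one row per cell); computed from the counts when omitted.
#' @return `sce` with an added dense `"corrected"` assay and
#'   `metadata(sce)$covariates_regressed` recording which covariates were
#'   used.
#' @export
regress_covariates <- function(sce, covariates = NULL) {
  if (!"lognorm" %in% assayNames(sce)) stop("run log_normalize() first")
  Y <- as.matrix(assay(sce, "lognorm"))
  if (is.null(covariates)) {
    counts <- assay(sce, "counts")
    total <- Matrix::colSums(counts)
    mito_flag <- rowData(sce)$is_mito
    mito <- if (any(mito_flag)) {
      Matrix::colSums(counts[mito_flag, , drop = FALSE]) / total
    } else rep(0, ncol(counts))
    covariates <- data.frame(total_umi = total, pct_mito = mito)
  }
  if (nrow(covariates) != ncol(sce)) {
    stop("covariate rows must match cell count")
  }
  X <- as.matrix(covariates[, intersect(c("total_umi", "pct_mito"),
                                        names(covariates)), drop = FALSE])
  keep <- apply(X, 2, function(x) stats::var(x) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  used <- colnames(X)
  X <- cbind(intercept = 1, X)
  Q <- qr.Q(qr(X))
  resid <- Y - (Y %*% Q) %*% t(Q)
  dimnames(resid) <- dimnames(Y)
  assay(sce, "corrected") <- resid
  metadata(sce)$covariates_regressed <- used
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalised expression
#' standardised against a loess mean-variance trend (fit on log10 scale),
#' so "most variable" is comparable across expression magnitudes, and
#' returns the top `n`. Ties break by gene order, so the result is
#' deterministic.
#'
#' @param sce a count object with a `"lognorm"` assay.
#' @param n number of genes to return (default 3,000).
#' @param span loess span of the mean-variance trend.
#' @return Character vector of gene ids, highest standardised variance
#'   first.
#' @export
select_hvgs <- function(sce, n = 3000, span = 0.3) {
  stopifnot(n >= 1)
  m <- assay(sce, "lognorm")
  mu <- Matrix::rowMeans(m)
  ex2 <- Matrix::rowMeans(m^2)
  nc <- ncol(m)
  v <- (ex2 - mu^2) * nc / max(nc - 1, 1)
  std <- rep(0, length(v))
  fit_idx <- which(v > 0 & mu > 0)
  if (length(fit_idx) >= 10) {
    fit <- stats::loess(log10(v[fit_idx]) ~ log10(mu[fit_idx]), span = span,
                        degree = 2)
    std[fit_idx] <- v[fit_idx] / 10^stats::fitted(fit)
  } else {
    std[fit_idx] <- v[fit_idx]
  }
  if (n > nrow(m)) {
    warning("n exceeds gene count; returning all genes")
    n <- nrow(m)
  }
  ord <- order(-std, seq_along(std))
  rownames(m)[ord[seq_len(n)]]
}

#' Principal-component scores of cells
#'
#' Standardises each highly-variable gene (zero mean, unit variance over
#' cells), then computes the leading principal components over cells.
#' Component signs are fixed so the largest-magnitude gene loading of each
#' component is positive, making outputs reproducible. Uses a truncated SVD
#' (irlba) for large matrices and a full SVD otherwise.
#'
#' @param sce a count object with a `"lognorm"` (or `"corrected"`) assay,
#'   or a plain genes x cells matrix.
#' @param hvgs character vector of gene ids to use (see [select_hvgs()]).
#' @param n_pcs number of components (default 10).
#' @param assay_name which assay to use when `sce` is a
#'   `SingleCellExperiment`; defaults to `"corrected"` when present, else
#'   `"lognorm"`.
#' @return cells x n_pcs score matrix with attributes `sdev` (component
#'   standard deviations), `var_explained` and `rotation`.
#' @export
reduce_pca <- function(sce, hvgs = NULL, n_pcs = 10, assay_name = NULL) {
  if (is(sce, "SingleCellExperiment")) {
    assay_name <- assay_name %||%
      (if ("corrected" %in% assayNames(sce)) "corrected" else "lognorm")
    m <- assay(sce, assay_name)
  } else {
    m <- sce
  }
  if (!is.null(hvgs)) {
    if (length(hvgs) == 0) stop("hvgs must be non-empty")
    m <- m[intersect(hvgs, rownames(m)), , drop = FALSE]
  }
  X <- as.matrix(Matrix::t(m)) # cells x genes
  if (n_pcs > min(dim(X))) {
    stop("n_pcs (", n_pcs, ") exceeds matrix rank bound ", min(dim(X)))
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
  n <- nrow(X)
  if (min(dim(X)) > 300 && n_pcs < min(dim(X)) / 3) {
    sv <- irlba::irlba(X, nv = n_pcs)
  } else {
    sv <- svd(X, nu = n_pcs, nv = n_pcs)
    sv$d <- sv$d[seq_len(n_pcs)]
  }
  flip <- vapply(seq_len(n_pcs), function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d, n_pcs), 2, flip, `*`)
  rotation <- sweep(sv$v, 2, flip, `*`)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  total_var <- sum(apply(X, 2, stats::var))
  attr(scores, "sdev") <- sv$d / sqrt(n - 1)
  attr(scores, "var_explained") <- (sv$d^2 / (n - 1)) / total_var
  attr(scores, "rotation") <- rotation
  scores
}
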