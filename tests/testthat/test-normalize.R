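test_that("log-normalisation follows ln(1 + count * scale / total)", {
  m <- matrix(0L, 3, 2)
  m[1, 1] <- 10L; m[2, 1] <- 990L  # cell total 1000
  m[1, 2] <- 20L; m[2, 2] <- 1980L # doubled column
  sce <- log_normalize(tiny_sce(m), scale_total = 1e4)
  X <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  expect_equal(X[1, 1], log(101), tolerance = 1e-12) # ~4.6151
  expect_equal(X[3, 1], 0)
  # doubling every count in a cell leaves its normalised column unchanged
  expect_equal(X[, 1], X[, 2], tolerance = 1e-12, ignore_attr = TRUE)

  m0 <- m; m0[, 2] <- 0L
  expect_error(log_normalize(tiny_sce(m0)), "c002")
})

test_that("normalisation is independent of gene order", {
  sce <- small_synth()[1:100, 1:50]
  a <- as.matrix(SummarizedExperiment::assay(log_normalize(sce), "lognorm"))
  perm <- sample(nrow(sce))
  b <- as.matrix(SummarizedExperiment::assay(log_normalize(sce[perm, ]),
                                             "lognorm"))
  expect_equal(b[rownames(a), ], a)
})

test_that("covariate regression removes exactly the linear part", {
  set.seed(1)
  nc <- 60
  total <- rpois(nc, 2000)
  pct <- runif(nc, 0, 0.1)
  Y <- rbind(rep(2.5, nc),                 # constant gene
             0.003 * total,                # exact linear function
             rnorm(nc))                    # noise gene
  sce <- tiny_sce(matrix(1L, 3, nc))
  dimnames(Y) <- dimnames(sce)
  SummarizedExperiment::assay(sce, "lognorm") <- Y
  cov <- data.frame(total_umi = total, pct_mito = pct)
  out <- regress_covariates(sce, cov)
  R <- as.matrix(SummarizedExperiment::assay(out, "corrected"))
  expect_equal(max(abs(R[1, ])), 0, tolerance = 1e-8)
  expect_equal(max(abs(R[2, ])), 0, tolerance = 1e-8)
  # residuals are orthogonal to the covariates and centred
  expect_lt(abs(sum(R[3, ] * total)), 1e-6 * sd(total) * nc)
  expect_lt(abs(mean(R[3, ])), 1e-10)

  # covariates orthogonal to a centred gene leave it unchanged
  x <- rep(c(-1, 1), nc / 2)
  cov2 <- data.frame(total_umi = rep(c(10, 10, 20, 20), nc / 4),
                     pct_mito = rep(0.05, nc))
  sce2 <- tiny_sce(matrix(1L, 1, nc))
  x_m <- matrix(x, 1, dimnames = dimnames(sce2))
  SummarizedExperiment::assay(sce2, "lognorm") <- x_m
  out2 <- suppressWarnings(regress_covariates(sce2, cov2))
  expect_equal(as.numeric(SummarizedExperiment::assay(out2, "corrected")),
               x - mean(x), tolerance = 1e-10)
  expect_warning(regress_covariates(sce2, cov2), "constant")
})

test_that("HVG selection ranks by trend-standardised variance", {
  set.seed(2)
  nc <- 80
  vars <- c(5, 4, 3, 2, 1)
  Y <- t(sapply(vars, function(v) rnorm(nc, mean = 5, sd = sqrt(v))))
  sce <- tiny_sce(matrix(1L, 5, nc))
  dimnames(Y) <- dimnames(sce)
  SummarizedExperiment::assay(sce, "lognorm") <- Y
  top2 <- select_hvgs(sce, 2)
  expect_setequal(top2, c("g001", "g002"))

  # ties break deterministically by gene order
  Yt <- rbind(Y[1, ], Y[1, ], Y[1, ])
  sce_t <- tiny_sce(matrix(1L, 3, nc))
  dimnames(Yt) <- dimnames(sce_t)
  SummarizedExperiment::assay(sce_t, "lognorm") <- Yt
  expect_equal(select_hvgs(sce_t, 2), c("g001", "g002"))

  expect_warning(all_g <- select_hvgs(sce, 10), "exceeds")
  expect_setequal(all_g, rownames(sce))
})

test_that("PCA scores obey the standard identities", {
  set.seed(3)
  # 2-gene toy: eigenvalues of the correlation matrix are 1 +/- r
  n <- 200
  g1 <- rnorm(n)
  g2 <- 0.6 * g1 + sqrt(1 - 0.36) * rnorm(n)
  Y <- rbind(g1, g2)
  rownames(Y) <- c("a", "b")
  sc <- reduce_pca(Y, n_pcs = 2)
  r <- cor(g1, g2)
  expect_equal(sort(attr(sc, "sdev")^2, decreasing = TRUE),
               sort(c(1 + r, 1 - r), decreasing = TRUE), tolerance = 1e-8)
  # total score variance equals the sum of retained eigenvalues
  expect_equal(sum(apply(sc, 2, var)), sum(attr(sc, "sdev")^2),
               tolerance = 1e-8)

  # rank-1 data: PC1 explains essentially everything
  base <- rnorm(n)
  Y1 <- rbind(2 * base, -base, 0.5 * base) + 1
  rownames(Y1) <- c("a", "b", "c")
  sc1 <- reduce_pca(Y1, n_pcs = 2)
  ve <- attr(sc1, "var_explained")
  expect_gt(ve[1] / sum(ve), 0.999)

  expect_error(reduce_pca(Y, n_pcs = 50), "exceeds")
})

test_that("PCA scores are invariant to cell order up to nothing at all", {
  sce <- log_normalize(small_synth()[, 1:120])
  X <- as.matrix(SummarizedExperiment::assay(sce, "lognorm"))
  sc1 <- reduce_pca(X, n_pcs = 5)
  perm <- sample(ncol(X))
  sc2 <- reduce_pca(X[, perm], n_pcs = 5)
  expect_equal(sc2[match(rownames(sc1), rownames(sc2)), ], sc1,
               tolerance = 1e-6, ignore_attr = TRUE)
})
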