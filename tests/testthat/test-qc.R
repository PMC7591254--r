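# hand-built 6-cell fixture: one cell violates each cell rule exactly once
qc_fixture <- function() {
  ng <- 300
  m <- matrix(0L, ng, 6)
  mito <- c(TRUE, TRUE, rep(FALSE, ng - 2))
  fill <- function(genes, count) {
    v <- integer(ng); v[genes] <- count; v
  }
  m[, 1] <- fill(3:252, 4) + fill(1:2, 10)      # clean: 1020 UMI, 2% mito
  m[, 2] <- fill(3:262, 4) + fill(1:2, 5)       # clean: 1050 UMI, 1% mito
  m[, 3] <- fill(3:202, 2)                      # 400 UMI -> below minimum
  m[, 4] <- fill(3:252, 100)                    # 25,000 UMI -> above maximum
  m[, 5] <- fill(3:152, 5)                      # 150 genes -> too few
  m[, 6] <- fill(3:222, 4) + fill(1:2, 60)      # 1000 UMI, 12% mito
  tiny_sce(m, mito = mito)
}

test_that("each stated cell rule removes exactly its violating cell", {
  sce <- qc_fixture()
  th <- qc_thresholds(gene_min_cells = 1)
  res <- apply_qc(sce, th)
  expect_equal(colnames(res$sce), c("c001", "c002"))
  expect_equal(unname(res$report$removals[c("umi_low", "umi_high",
                                            "few_genes", "high_mito")]),
               c(1, 1, 1, 1))
  expect_equal(res$report$n_cells_in, 6)
  expect_equal(res$report$n_cells_out, 2)
  # boundary convention is strict: a 500-UMI cell survives
  m <- matrix(0L, 300, 1); m[3:252, 1] <- 2L # exactly 500 UMI, 250 genes
  ok <- apply_qc(tiny_sce(m, mito = c(TRUE, TRUE, rep(FALSE, 298))),
                 qc_thresholds(gene_min_cells = 1))
  expect_equal(ok$report$n_cells_out, 1)
})

test_that("empty input yields empty output and zero removals", {
  sce <- qc_fixture()[, integer(0)]
  res <- suppressWarnings(apply_qc(sce, qc_thresholds(gene_min_cells = 1)))
  expect_equal(res$report$n_cells_out, 0)
  expect_true(all(res$report$removals[c("umi_low", "umi_high", "few_genes",
                                        "high_mito")] == 0))
})

test_that("QC is idempotent and survivors match a per-cell re-check", {
  sce <- small_synth()
  res <- apply_qc(sce)
  again <- apply_qc(res$sce)
  expect_equal(dim(again$sce), dim(res$sce))
  expect_equal(colnames(again$sce), colnames(res$sce))

  # brute-force oracle: re-evaluate every rule cell by cell on the input
  counts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  mito <- SummarizedExperiment::rowData(sce)$is_mito
  keep <- vapply(seq_len(ncol(counts)), function(i) {
    x <- counts[, i]
    tot <- sum(x)
    tot >= 500 && tot <= 20000 && sum(x > 0) >= 200 &&
      sum(x[mito]) / tot <= 0.10
  }, logical(1))
  expect_setequal(colnames(res$sce), colnames(sce)[keep])
})

test_that("loosening any threshold never loses cells", {
  sce <- small_synth()
  base <- qc_thresholds()
  n0 <- apply_qc(sce, base)$report$n_cells_out
  looser <- list(qc_thresholds(umi_min = 200),
                 qc_thresholds(umi_max = 50000),
                 qc_thresholds(genes_min = 50),
                 qc_thresholds(mito_max = 0.30))
  for (th in looser) {
    expect_gte(apply_qc(sce, th)$report$n_cells_out, n0)
  }
})

test_that("missing mito flags and blacklists are handled", {
  m <- matrix(4L, 300, 3)
  sce <- tiny_sce(m)
  expect_warning(res <- apply_qc(sce, qc_thresholds(gene_min_cells = 1)),
                 "mito")
  expect_equal(res$report$n_cells_out, 3)
  res2 <- suppressWarnings(apply_qc(sce, qc_thresholds(gene_min_cells = 1),
                                    cell_blacklist = "c002"))
  expect_equal(colnames(res2$sce), c("c001", "c003"))
  expect_equal(unname(res2$report$removals["blacklist"]), 1)
})

test_that("the gene rule counts detection among surviving cells only", {
  ng <- 300
  m <- matrix(0L, ng, 4)
  m[1:250, 1:2] <- 4L                  # two clean cells
  m[251:260, 3] <- 100L                # gene block carried by a bad cell
  m[1:200, 3] <- 120L                  # 25,000+ UMI -> removed
  m[1:250, 4] <- 4L
  sce <- tiny_sce(m)
  res <- suppressWarnings(apply_qc(sce, qc_thresholds(gene_min_cells = 3)))
  # genes 251:260 were detected only in the removed cell
  expect_false(any(paste0("g", 251:260) %in% rownames(res$sce)))
})
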