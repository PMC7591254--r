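# shared test fixtures and small oracles, built in code

# adjusted Rand index (independent implementation for recovery checks)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# minimal count object from a dense matrix
tiny_sce <- function(counts, conditions = NULL, mito = NULL,
                     samples = NULL, panels = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  count_matrix(
    Matrix::Matrix(counts, sparse = TRUE),
    cell_meta = data.frame(
      cell_id = sprintf("c%03d", seq_len(nc)),
      sample_id = samples %||% rep("s1", nc),
      condition = conditions %||% rep("Ctrl", nc)),
    gene_meta = data.frame(
      gene_id = sprintf("g%03d", seq_len(ng)),
      is_mito = mito %||% rep(FALSE, ng),
      panels = panels %||% rep("", ng)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic object shared across tests (generated once per session)
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_counts(gen_params(
        n_genes = 600, n_cells_per_sample = 250,
        samples_per_condition = c(Ctrl = 2, D0 = 2, D2 = 1), seed = 42))
    }
    cache
  }
})
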