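#' Marker panels and populations of the synthetic study design
#'
#' `default_panels()` returns the named gene panels used by the generator and
#' the annotation step: one expression panel per population (five myeloid -
#' homeostatic, chemokine, ribosomal/translation, MHC/Cd74-high,
#' proliferative - and four contaminants - neutrophil, lymphoid, endothelial,
#' astroglial), the core myeloid identity panel (Itgam, Aif1, Cx3cr1, Csf1r),
#' the mitochondrial genes, the Lgals3-high ("MAC2+") transcriptional program
#' (up: Lgals3, Lyz2 and yolk-sac/early-embryonic genes; down: the
#' homeostatic regulators Tmem119, P2ry12, Cx3cr1, Csf1r, Mafb), and seven
#' pairwise-disjoint developmental stage sets (YS, E1, E2, P1, P2, A1, A2)
#' spanning the yolk-sac to adult microglia trajectory. Canonical mouse
#' marker symbols are used where they exist; stage sets are padded with
#' synthetic `Dev*` gene ids to a realistic size.
#'
#' @return Named list of character vectors of gene ids.
#' @export
default_panels <- function() {
  stage <- list(
    stage_YS = c("Timd4", "Mrc1", "F13a1", "Dab2", "Pf4",
                 sprintf("DevYS%02d", 1:15)),
    stage_E1 = c("Lyz2", "Fabp5", "Mest", "Crybb1", "Mcm5",
                 sprintf("DevE1%02d", 1:15)),
    stage_E2 = c("Cd36", "Hmox1", "Lgmn", "Ctsb",
                 sprintf("DevE2%02d", 1:16)),
    stage_P1 = c("Cd9", "Fn1", "Lpl",
                 sprintf("DevP1%02d", 1:17)),
    stage_P2 = c("Crybb1b", "Csf2rb", "Itgb5",
                 sprintf("DevP2%02d", 1:17)),
    stage_A1 = c("Mafb", "Cx3cr1", "Csf1r", "Pmepa1",
                 sprintf("DevA1%02d", 1:16)),
    stage_A2 = c("Tmem119", "P2ry12", "Selplg", "Sall1",
                 sprintf("DevA2%02d", 1:16))
  )
  c(list(
    homeostatic  = c("Tmem119", "P2ry12", "P2ry13", "Selplg", "Trem2",
                     "Hexb", "Siglech", "Olfml3", "Gpr34", "Sparc"),
    chemokine    = c("Ccl3", "Ccl4", "Ccl2", "Egr1", "Nfkbia", "Tnf",
                     "Il1b", "Atf3", "Jun", "Fos"),
    ribosomal    = c("Lars2", "Dst", "Macf1", "Rps26", "Rps8", "Rps24",
                     "Rpl35a", "Rps29", "Rpl37", "Rps21"),
    mhc          = c("Cd74", "H2-Ab1", "H2-Eb1", "H2-Aa", "H2-D1", "B2m",
                     "Cd52", "Ctss"),
    proliferative = c("Mki67", "Top2a", "Stmn1", "Ube2c", "Birc5", "Ccnb1",
                      "Cdk1", "Hmgb2", "Cenpa", "Tubb5"),
    neutrophil   = c("S100a8", "S100a9", "Ly6g", "Retnlg", "Camp", "Ngp"),
    lymphoid     = c("Cd3e", "Cd3d", "Nkg7", "Cd79a", "Cd79b", "Ms4a1"),
    endothelial  = c("Cldn5", "Pecam1", "Flt1", "Ly6c1", "Slco1a4", "Vtn"),
    astroglial   = c("Gfap", "Aqp4", "Slc1a3", "Aldoc", "Clu", "Plpp3"),
    myeloid      = c("Itgam", "Aif1", "Cx3cr1", "Csf1r"),
    mito         = c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Co3",
                     "mt-Atp6", "mt-Atp8", "mt-Cytb", "mt-Nd3", "mt-Nd4",
                     "mt-Nd4l", "mt-Nd5", "mt-Nd6"),
    lgals3_program_up = unique(c("Lgals3", "Lyz2",
                                 stage$stage_YS, stage$stage_E1)),
    lgals3_program_down = c("Tmem119", "P2ry12", "Cx3cr1", "Csf1r", "Mafb")
  ), stage)
}

#' @rdname default_panels
#' @export
myeloid_populations <- function() {
  c("homeostatic", "chemokine", "ribosomal", "mhc", "proliferative")
}

#' @rdname default_panels
#' @export
contaminant_populations <- function() {
  c("neutrophil", "lymphoid", "endothelial", "astroglial")
}

#' Parameters of the synthetic count generator
#'
#' Returns the generator parameter set, with defaults emulating the study
#' design: three conditions (Ctrl, D0 at the end of 14 days of CSF1R
#' inhibitor, D2 after 2 days of repopulation) with 3/3/2 samples, ~4,500
#' cells per sample, nine populations whose per-condition mixing proportions
#' mirror the observed composition shifts (homeostatic microglia dominate
#' Ctrl; chemokine-high and proliferative cells expand under treatment, the
#' proliferative population from 0.12% of Ctrl myeloid cells to ~10%), and a
#' rare Lgals3-high subpopulation carried by 3.0% / 9.8% / 11.2% of myeloid
#' cells in Ctrl / D0 / D2.
#'
#' Counts are negative binomial (mean/size parameterisation, variance
#' `mu + mu^2/size`) around per-cell means built from gamma-distributed
#' baseline gene weights, population-panel fold changes, the Lgals3-program
#' shift in program-carrying cells, a beta-distributed per-cell
#' mitochondrial fraction, and a lognormal library size.
#'
#' @param n_genes size of the gene universe (named marker genes plus
#'   synthetic filler ids).
#' @param panels named list of gene panels, see [default_panels()].
#' @param cluster_props conditions x populations matrix of mixing
#'   proportions; rows must sum to 1.
#' @param mac2_frac named per-condition probability that a myeloid cell
#'   carries the Lgals3-high program.
#' @param libsize_meanlog,libsize_sdlog lognormal library-size parameters
#'   (defaults give a mean of ~7,800 UMI/cell).
#' @param nb_dispersion NB size parameter (larger = closer to Poisson).
#' @param effect_logfc natural-log fold shift applied to Lgals3-program
#'   genes in program-carrying cells.
#' @param lgals3_mean_counts baseline Lgals3 abundance, as expected counts
#'   per typical library, in program-negative cells. Lgals3 is broadly
#'   detected at low-to-moderate level across the sorted myeloid
#'   compartment (program carriers sit `effect_logfc` above this), so the
#'   gene gets a fixed baseline rather than a random one.
#' @param panel_logfc natural-log fold elevation of a population's own
#'   marker panel.
#' @param myeloid_logfc natural-log fold elevation of the core myeloid
#'   panel in myeloid populations.
#' @param contaminant_myeloid_scale residual (ambient-like) fraction of
#'   myeloid-panel expression left in contaminant populations.
#' @param offtarget_lineage_scale residual fraction of a contaminant
#'   lineage panel (neutrophil, lymphoid, endothelial, astroglial genes)
#'   expressed outside its own population; these markers are
#'   lineage-restricted in real tissue.
#' @param mito_mean,mito_mean_high,high_mito_frac mean mitochondrial
#'   fraction of typical cells, of stressed cells, and the fraction of
#'   stressed cells (these exercise the percent-mito QC rule).
#' @param n_cells_per_sample cells drawn per sample (scalar or per-sample).
#' @param samples_per_condition named integer vector of samples per
#'   condition.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `gen_params`.
#' @export
gen_params <- function(n_genes = 2000,
                       panels = default_panels(),
                       cluster_props = default_cluster_props(),
                       mac2_frac = c(Ctrl = 0.030, D0 = 0.098, D2 = 0.112),
                       libsize_meanlog = log(7400),
                       libsize_sdlog = 0.35,
                       nb_dispersion = 15,
                       effect_logfc = 1.5,
                       lgals3_mean_counts = 8,
                       panel_logfc = 2.5,
                       myeloid_logfc = 1.5,
                       contaminant_myeloid_scale = 0.005,
                       offtarget_lineage_scale = 0.02,
                       mito_mean = 0.04,
                       mito_mean_high = 0.20,
                       high_mito_frac = 0.05,
                       n_cells_per_sample = 4500,
                       samples_per_condition = c(Ctrl = 3, D0 = 3, D2 = 2),
                       seed = 1L) {
  p <- structure(as.list(environment()), class = "gen_params")
  validate_gen_params(p)
  p
}

#' @rdname gen_params
#' @export
default_cluster_props <- function() {
  pops <- c(myeloid_populations(), contaminant_populations())
  props <- rbind(
    Ctrl = c(0.7148, 0.0600, 0.0600, 0.0700, 0.0012, rep(0.0235, 4)),
    D0   = c(0.1500, 0.3000, 0.1300, 0.2200, 0.1000, rep(0.0250, 4)),
    D2   = c(0.1500, 0.2500, 0.2500, 0.1500, 0.1000, rep(0.0250, 4))
  )
  colnames(props) <- pops
  props
}

validate_gen_params <- function(p) {
  stopifnot(p$n_genes >= 1, p$nb_dispersion > 0, p$libsize_sdlog >= 0)
  if (any(abs(rowSums(p$cluster_props) - 1) > 1e-9)) {
    stop("each cluster_props row must sum to 1")
  }
  if (!all(condition_levels() %in% rownames(p$cluster_props))) {
    stop("cluster_props must have rows Ctrl, D0, D2")
  }
  if (any(p$mac2_frac < 0 | p$mac2_frac > 1)) {
    stop("mac2_frac must lie in [0, 1]")
  }
  if (any(p$n_cells_per_sample <= 0)) {
    stop("n_cells_per_sample must be positive")
  }
  if (p$effect_logfc != 0 &&
      (length(p$panels$lgals3_program_up) == 0 ||
       length(p$panels$lgals3_program_down) == 0)) {
    stop("lgals3 program panels are empty but effect_logfc is non-zero")
  }
  used <- colnames(p$cluster_props)
  if (p$panel_logfc != 0) {
    empty <- used[vapply(p$panels[used], length, integer(1)) == 0]
    if (length(empty)) {
      stop("empty panel(s) referenced by a non-zero panel effect: ",
           paste(empty, collapse = ", "))
    }
  }
  universe <- gene_universe(p)
  extra <- setdiff(unique(unlist(p$panels)), universe)
  if (length(extra)) {
    stop("panel genes outside the gene universe: ",
         paste(head(extra, 5), collapse = ", "))
  }
  stage <- p$panels[grep("^stage_", names(p$panels))]
  if (length(stage) > 1) {
    for (i in seq_len(length(stage) - 1)) for (j in (i + 1):length(stage)) {
      ov <- intersect(stage[[i]], stage[[j]])
      if (length(ov)) {
        stop("stage sets ", names(stage)[i], " and ", names(stage)[j],
             " overlap: ", paste(head(ov, 5), collapse = ", "))
      }
    }
  }
  invisible(p)
}

# Full ordered gene universe: all named panel genes first, then filler ids.
gene_universe <- function(p) {
  named <- unique(unlist(p$panels, use.names = FALSE))
  if (length(named) > p$n_genes) {
    stop("n_genes (", p$n_genes, ") smaller than the number of panel genes (",
         length(named), ")")
  }
  c(named, sprintf("Gene%05d", seq_len(p$n_genes - length(named))))
}

#' Generate a synthetic three-condition count matrix with ground truth
#'
#' Draws, for every sample, each cell's population from that condition's
#' mixing proportions, marks myeloid cells as Lgals3-program carriers with
#' the condition's `mac2_frac`, builds per-cell expected expression
#' (baseline gamma weights x population-panel fold changes x program shift),
#' replaces the mitochondrial share of each cell's library with a
#' beta-distributed fraction, scales to a lognormal library size and samples
#' negative-binomial counts. Deterministic given `params$seed`.
#'
#' @param params a [gen_params()] object.
#' @return A `SingleCellExperiment` (see [count_matrix()]) whose `colData`
#'   records `sample_id`, `condition`, `true_population` and `true_mac2`,
#'   and whose `rowData` flags mitochondrial genes and panel membership.
#'   Generation parameters are kept in `metadata(sce)$gen_params`.
#' @examples
#' p <- gen_params(n_genes = 400, n_cells_per_sample = 50,
#'                 samples_per_condition = c(Ctrl = 1, D0 = 1, D2 = 1))
#' sce <- generate_counts(p)
#' table(sce$condition)
#' @export
generate_counts <- function(params) {
  validate_gen_params(params)
  p <- params
  genes <- gene_universe(p)
  n_genes <- length(genes)
  pops <- colnames(p$cluster_props)
  named_panel_genes <- unique(unlist(p$panels, use.names = FALSE))
  mito_idx <- match(p$panels$mito, genes)
  is_mito <- seq_len(n_genes) %in% mito_idx

  conds <- rep(names(p$samples_per_condition), p$samples_per_condition)
  n_samples <- length(conds)
  ncells <- rep_len(p$n_cells_per_sample, n_samples)

  with_seed(p$seed, {
    # heavy-tailed baseline: filler genes ~ Gamma(0.5), curated marker genes
    # ~ Gamma(3) so markers are reliably detectable (as real markers are)
    w <- rgamma(n_genes, shape = 0.5, scale = 1)
    curated <- genes %in% named_panel_genes
    w[curated] <- rgamma(sum(curated), shape = 3, scale = 1)
    w <- pmax(w, 1e-6)

    # population baseline matrices: genes x populations
    B <- matrix(w, n_genes, length(pops), dimnames = list(genes, pops))
    for (pop in pops) {
      # non-myeloid lineage markers are silent outside their lineage
      for (cp in intersect(contaminant_populations(), names(p$panels))) {
        if (cp != pop) {
          B[match(p$panels[[cp]], genes), pop] <-
            B[match(p$panels[[cp]], genes), pop] * p$offtarget_lineage_scale
        }
      }
      own <- match(p$panels[[pop]], genes)
      B[own, pop] <- B[own, pop] * exp(p$panel_logfc)
      my <- match(p$panels$myeloid, genes)
      if (pop %in% myeloid_populations()) {
        B[my, pop] <- B[my, pop] * exp(p$myeloid_logfc)
      } else {
        B[my, pop] <- B[my, pop] * p$contaminant_myeloid_scale
      }
    }
    # pin the gate marker's baseline share of each population's library to
    # the configured expected counts per typical library
    lg <- match("Lgals3", genes)
    if (!is.na(lg)) {
      share <- p$lgals3_mean_counts / exp(p$libsize_meanlog)
      other <- colSums(B) - B[lg, ]
      B[lg, ] <- share / (1 - share) * other
    }
    up_idx <- match(p$panels$lgals3_program_up, genes)
    down_idx <- match(p$panels$lgals3_program_down, genes)

    blocks <- vector("list", n_samples)
    meta <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      cond <- conds[s]
      nc <- ncells[s]
      pop_s <- sample(pops, nc, replace = TRUE,
                      prob = p$cluster_props[cond, ])
      myeloid <- pop_s %in% myeloid_populations()
      mac2 <- myeloid & (runif(nc) < p$mac2_frac[[cond]])

      mu <- B[, pop_s, drop = FALSE]
      if (any(mac2)) {
        mu[up_idx, mac2] <- mu[up_idx, mac2] * exp(p$effect_logfc)
        mu[down_idx, mac2] <- mu[down_idx, mac2] * exp(-p$effect_logfc)
      }
      # per-cell mitochondrial fraction (beta mixture with a stressed tail)
      hi <- runif(nc) < p$high_mito_frac
      m_frac <- ifelse(hi,
                       rbeta(nc, 8, 8 * (1 - p$mito_mean_high) / p$mito_mean_high),
                       rbeta(nc, 6, 6 * (1 - p$mito_mean) / p$mito_mean))
      mito_w <- w[mito_idx] / sum(w[mito_idx])
      nonmito_tot <- colSums(mu[!is_mito, , drop = FALSE])
      mu[!is_mito, ] <- sweep(mu[!is_mito, , drop = FALSE], 2,
                              (1 - m_frac) / nonmito_tot, `*`)
      mu[mito_idx, ] <- outer(mito_w, m_frac)
      lib <- rlnorm(nc, p$libsize_meanlog, p$libsize_sdlog)
      mu <- sweep(mu, 2, lib, `*`)

      cnt <- matrix(rnbinom(length(mu), mu = mu, size = p$nb_dispersion),
                    n_genes, nc)
      blocks[[s]] <- as(as(Matrix::Matrix(cnt, sparse = TRUE),
                           "CsparseMatrix"), "generalMatrix")
      sample_id <- sprintf("%s_s%d", cond, sum(conds[seq_len(s)] == cond))
      meta[[s]] <- data.frame(
        cell_id = sprintf("%s_c%04d", sample_id, seq_len(nc)),
        sample_id = sample_id, condition = cond,
        true_population = pop_s, true_mac2 = mac2,
        stringsAsFactors = FALSE)
    }
  })

  counts <- do.call(cbind, blocks)
  cell_meta <- do.call(rbind, meta)
  membership <- vapply(genes, function(g) {
    paste(names(p$panels)[vapply(p$panels, function(x) g %in% x, logical(1))],
          collapse = ",")
  }, character(1))
  gene_meta <- data.frame(gene_id = genes, is_mito = is_mito,
                          panels = unname(membership),
                          stringsAsFactors = FALSE)
  sce <- count_matrix(counts, cell_meta, gene_meta)
  metadata(sce)$gen_params <- p
  sce
}
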