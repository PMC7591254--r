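#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' exactly one input source (synthetic generator parameters, or a path to
#' 10x-style files), one parameter block per stage, a root seed from which
#' each stochastic stage's seed is derived deterministically, and an
#' optional output directory for stage artifacts. Any block can be
#' partially overridden; unspecified values keep the defaults shown here.
#'
#' @param input either `list(synthetic = list(...))` with [gen_params()]
#'   overrides, or `list(path = "dir")` pointing at [write_tenx()] output.
#' @param seed root integer seed.
#' @param qc,cluster,gate,de,signatures,abundance stage parameter blocks.
#' @param outdir optional directory; when set, each stage writes its
#'   artifact files there.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(input = list(synthetic = list()),
                            seed = 1L,
                            qc = list(),
                            cluster = list(),
                            gate = list(),
                            de = list(),
                            signatures = list(),
                            abundance = list(),
                            outdir = NULL) {
  if (sum(c("synthetic", "path") %in% names(input)) != 1) {
    stop("config must name exactly one input source: synthetic or path")
  }
  defaults <- list(
    qc = list(enabled = TRUE, umi_min = 500, umi_max = 20000,
              genes_min = 200, mito_max = 0.10, gene_min_cells = 10),
    cluster = list(n_hvgs = 3000, n_pcs = 10, resolution = 0.8,
                   snn_k = 20, regress = TRUE, myeloid_threshold = 0.25),
    gate = list(enabled = TRUE, gene = "Lgals3", k_sd = 1),
    de = list(logfc_min = 0.5, min_pct = 0.10, adjust = "bonferroni"),
    signatures = list(gmt = NULL),
    abundance = list(contrasts = NULL)
  )
  cfg <- list(input = input, seed = as.integer(seed),
              qc = modifyList(defaults$qc, qc),
              cluster = modifyList(defaults$cluster, cluster),
              gate = modifyList(defaults$gate, gate),
              de = modifyList(defaults$de, de),
              signatures = modifyList(defaults$signatures, signatures),
              abundance = modifyList(defaults$abundance, abundance),
              outdir = outdir)
  structure(cfg, class = "run_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same structure.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(
    pipeline_config)))])
}

# per-stage seeds derived from the root seed (kept inside 32-bit range)
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, cluster = 2L, gate = 3L, de = 4L,
            signatures = 5L, abundance = 6L, imaging = 7L)
  (as.integer(seed) + 7919L * offs[[stage]]) %% 2147483543L
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data synthesis (or ingestion), quality control,
#' normalisation / covariate regression / PCA / SNN clustering /
#' contaminant stripping, marker gating with condition frequencies,
#' hurdle-model DE of gated cells against the homeostatic cluster,
#' developmental-signature overlap of the up- and down-regulated DEGs, and
#' negative-binomial differential cluster abundance. Each stage's summary
#' goes into the returned report; with `outdir` set the stage artifacts
#' (TSV/CSV/JSON) are written as well. Fully deterministic given the
#' config's root seed. A stage failure aborts with the stage name; the
#' partial report up to that point is attached to the error condition.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return List of class `run_report` with per-stage summaries, a config
#'   echo and a version stamp.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is(config, "run_config"))
  report <- list(schema_version = 1L,
                 package_version = as.character(utils::packageVersion(
                   "microrepop")),
                 config = unclass(config), stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cond <- simpleError(paste0("stage '", name, "' failed: ",
                                 conditionMessage(e)))
      cond$partial_report <- report
      stop(cond)
    })
  }
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)

  # --- input ---------------------------------------------------------
  sce <- run_stage("input", {
    if ("synthetic" %in% names(config$input)) {
      ov <- config$input$synthetic
      ov$seed <- ov$seed %||% derive_seed(config$seed, "simulate")
      generate_counts(do.call(gen_params, ov))
    } else {
      read_tenx(config$input$path)
    }
  })
  report$stages$input <- list(n_cells = ncol(sce), n_genes = nrow(sce),
                              cells_per_condition = as.list(table(
                                sce$condition)))

  # --- qc ------------------------------------------------------------
  if (isTRUE(config$qc$enabled)) {
    qc <- run_stage("qc", {
      th <- qc_thresholds(config$qc$umi_min, config$qc$umi_max,
                          config$qc$genes_min, config$qc$mito_max,
                          config$qc$gene_min_cells)
      apply_qc(sce, th)
    })
    sce <- qc$sce
    report$stages$qc <- list(
      n_cells_in = qc$report$n_cells_in, n_cells_out = qc$report$n_cells_out,
      n_genes_in = qc$report$n_genes_in, n_genes_out = qc$report$n_genes_out,
      removals = as.list(qc$report$removals))
    if (!is.null(outdir)) write_qc_report(qc$report, outdir)
  }

  # --- cluster -------------------------------------------------------
  cl <- config$cluster
  strip <- run_stage("cluster", {
    sce <- log_normalize(sce)
    if (isTRUE(cl$regress)) sce <- regress_covariates(sce)
    hvgs <- select_hvgs(sce, n = min(cl$n_hvgs, nrow(sce)))
    scores <- reduce_pca(sce, hvgs, n_pcs = cl$n_pcs)
    assignment <- cluster_cells(scores, resolution = cl$resolution,
                                seed = derive_seed(config$seed, "cluster"),
                                snn_k = cl$snn_k)
    annotate_and_strip(sce, assignment,
                       myeloid_threshold = cl$myeloid_threshold)
  })
  sce <- strip$sce
  assignment <- strip$assignment
  report$stages$cluster <- list(
    n_clusters_total = length(strip$assignment$annotations),
    annotations = as.list(strip$assignment$annotations),
    n_cells_retained = ncol(sce),
    cluster_sizes = as.list(table(assignment$labels)),
    cluster_sizes_by_condition = lapply(
      split(as.character(sce$condition), assignment$labels), table))
  if (!is.null(outdir)) {
    write_cluster_assignment(assignment,
                             file.path(outdir, "clusters.tsv"))
  }

  # --- gate ----------------------------------------------------------
  mac2 <- NULL
  if (isTRUE(config$gate$enabled)) {
    gate_res <- run_stage("gate", {
      gate_positive(sce, k_sd = config$gate$k_sd, gene = config$gate$gene)
    })
    freq <- condition_frequencies(gate_res, sce$condition)
    comp <- cluster_composition(gate_res, assignment$labels)
    mac2 <- gate_res
    report$stages$gate <- list(threshold = gate_res$threshold,
                               k_sd = gate_res$k_sd,
                               n_positive = gate_res$n_positive,
                               n_total = length(gate_res$labels),
                               condition_frequencies = freq,
                               cluster_composition = comp)
    if (!is.null(outdir)) {
      utils::write.csv(freq, file.path(outdir, "gate_frequencies.csv"),
                       row.names = FALSE)
      utils::write.csv(comp, file.path(outdir, "gate_composition.csv"),
                       row.names = FALSE)
    }
  } else {
    report$stages$gate <- list(skipped = "gating disabled in config")
  }

  # --- de + signatures (need the gate) -------------------------------
  if (!is.null(mac2)) {
    de <- run_stage("de", {
      homeo <- homeostatic_cluster(sce, assignment)
      cells_a <- which(mac2$labels)
      cells_b <- which(assignment$labels == homeo & !mac2$labels)
      list(homeo = homeo,
           table = contrast_de(sce, cells_a, cells_b,
                               logfc_min = config$de$logfc_min,
                               min_pct = config$de$min_pct,
                               adjust = config$de$adjust))
    })
    det <- de$table[de$table$p_adj < 0.05, ]
    report$stages$de <- list(
      homeostatic_cluster = de$homeo,
      n_tested = nrow(de$table),
      n_up = sum(det$direction == "up"),
      n_down = sum(det$direction == "down"))
    if (!is.null(outdir)) {
      write_de_table(de$table, file.path(outdir, "mac2_vs_homeostatic.csv"))
    }

    sig <- run_stage("signatures", {
      sets <- if (!is.null(config$signatures$gmt)) {
        load_stage_sets(config$signatures$gmt)
      } else {
        stage_sets_from_rowdata(sce)
      }
      list(up = overlap_fractions(det$gene[det$direction == "up"], sets),
           down = overlap_fractions(det$gene[det$direction == "down"],
                                    sets))
    })
    report$stages$signatures <- list(up = as.data.frame(sig$up),
                                     down = as.data.frame(sig$down))
    if (!is.null(outdir)) {
      write_overlap_profile(sig$up, file.path(outdir, "overlap_up"))
      write_overlap_profile(sig$down, file.path(outdir, "overlap_down"))
    }
  } else {
    report$stages$de <- list(skipped = "requires the gate stage")
    report$stages$signatures <- list(skipped = "requires the gate stage")
  }

  # --- abundance -----------------------------------------------------
  ab <- run_stage("abundance", {
    cc <- tabulate_counts(sce, assignment$labels)
    list(counts = cc,
         result = test_abundance(cc, contrasts = config$abundance$contrasts))
  })
  report$stages$abundance <- list(result = ab$result)
  if (!is.null(outdir)) {
    write_cluster_counts(ab$counts, file.path(outdir, "cluster_counts.csv"))
    utils::write.csv(ab$result, file.path(outdir, "abundance.csv"),
                     row.names = FALSE)
  }

  class(report) <- "run_report"
  if (!is.null(outdir)) {
    write_run_report(report, file.path(outdir, "report.json"))
  }
  report
}

# cluster with the highest homeostatic-panel detection fraction
homeostatic_cluster <- function(sce, assignment) {
  genes <- intersect(panel_genes(sce, "homeostatic"), rownames(sce))
  if (length(genes) == 0) stop("no homeostatic panel genes present")
  det <- assay(sce, "counts")[genes, , drop = FALSE] > 0
  cl <- sort(unique(assignment$labels))
  score <- vapply(cl, function(k) {
    mean(Matrix::rowMeans(det[, assignment$labels == k, drop = FALSE]))
  }, numeric(1))
  cl[which.max(score)]
}

# seven stage sets recovered from rowData panel membership
stage_sets_from_rowdata <- function(sce) {
  sets <- lapply(paste0("stage_", stage_names()), panel_genes, sce = sce)
  names(sets) <- stage_names()
  if (all(vapply(sets, length, integer(1)) == 0)) {
    stop("no stage_* panels in rowData; supply a GMT file")
  }
  structure(sets, class = "stage_sets")
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report (schema", x$schema_version, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    if (!is.null(s$skipped)) {
      cat(" -", nm, ": skipped (", s$skipped, ")\n")
    } else {
      cat(" -", nm, ": done\n")
    }
  }
  invisible(x)
}
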