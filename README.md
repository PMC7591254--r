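# microrepop

Finding the CSF1R-inhibition-resistant, progenitor-like **MAC2+ (Lgals3-high)
microglial subpopulation** in single-cell RNA-seq — as a tested, reusable R
pipeline.

Microglia depend on CSF1R signalling: two weeks of a CSF1R inhibitor removes
~90% of them, and survivors repopulate the brain within days of withdrawal. A
small subpopulation marked by high Galectin-3 (*Lgals3* / MAC2) resists
inhibition, carries a transcriptional program resembling yolk-sac and
early-embryonic microglial progenitors, and proliferates during repopulation.
`microrepop` implements the computational analysis that identifies and
characterises this population across three conditions — untreated (`Ctrl`),
end of treatment (`D0`), and two days of repopulation (`D2`) — for anyone who
wants to reproduce the approach, apply it to their own 10x-style data, or
study its statistical behaviour on synthetic data with known ground truth.

## What it computes

| Stage | Function(s) | Model / rule |
|---|---|---|
| Quality control | `apply_qc()` | keep cells with 500 ≤ UMI ≤ 20,000, ≥ 200 genes, ≤ 10% mito counts; then genes detected in ≥ 10 cells |
| Normalisation | `log_normalize()`, `regress_covariates()` | `ln(1 + count·10⁴/total)`; per-gene OLS residuals on total UMI + %mito |
| Reduction + clustering | `select_hvgs()`, `reduce_pca()`, `cluster_cells()` | loess-standardised variance (top 3,000), 10 PCs, Louvain on a k=20 SNN graph |
| Contaminant removal | `annotate_and_strip()` | clusters with myeloid-panel (Itgam, Aif1, Cx3cr1, Csf1r) detection < 0.25 are labelled by lineage-panel enrichment and dropped |
| Differential expression | `hurdle_test()`, `find_markers()`, `contrast_de()` | two-part hurdle model: binomial detection LRT + Gaussian LRT on positive log-expression, summed, χ² with per-component df |
| MAC2+ gating | `gate_positive()`, `condition_frequencies()` | positive iff log-normalised *Lgals3* > mean + 1 SD over all cells (zeros included, pooled conditions) |
| Developmental signatures | `load_stage_sets()`, `overlap_fractions()`, `venn_compare()`, `hypergeom_enrich()` | % of DEGs in each of the seven disjoint stage sets YS, E1, E2, P1, P2, A1, A2 |
| Differential abundance | `tabulate_counts()`, `fit_nb_glm()`, `test_abundance()` | NB GLM on cells-per-cluster counts, offset = log total cells/sample, quasi-likelihood F-tests |
| Imaging | `adaptive_threshold()`, `segment_mask()`, `colocalize()`, `count_phenotypes()` | local-mean threshold, 8-connected components, pairing when mask overlap > 10% of the smaller mask |
| Synthesis | `generate_counts()`, `synth_image()` | NB counts for 9 populations × 3 conditions with a planted Lgals3-high program; rendered IF fields with ground truth |

The hurdle statistic for a gene with groups A, B is
`Λ = Λ_detection + Λ_continuous`, where `Λ_detection` is the binomial LRT on
detection counts (k_A/n_A vs k_B/n_B) and `Λ_continuous = m·log(SS₀/SS₁)` is
the equal-variance Gaussian LRT on the m positive values; `Λ ~ χ²(df)` with
one df per informative component. The abundance model for cluster j is
`y_sj ~ NB(μ_sj, φ)`, `log μ_sj = log T_s + x_sᵀβ_j`, with `T_s` the cells
captured in sample s.

## Worked example

The whole pipeline runs from one configuration on synthetic data emulating
the study design (no external data needed):

```r
library(microrepop)

cfg <- pipeline_config(
  input = list(synthetic = list(n_genes = 800, n_cells_per_sample = 700)),
  seed = 1,
  cluster = list(resolution = 0.4))
rep <- run_pipeline(cfg)

rep$stages$qc$n_cells_out          # cells surviving QC
unlist(rep$stages$cluster$annotations)
rep$stages$gate$condition_frequencies
head(rep$stages$signatures$up)
```

Output (abridged):

```
== QC ==                 5600 cells in; 5306 kept
== clusters ==           1-5, 10-14 "myeloid"; 6 "neutrophil"; 7 "lymphoid";
                         8 "astroglial"; 9 "endothelial"
retained:                4792 cells
== MAC2+ gate ==
  condition n_positive n_total  pct
1      Ctrl        119    1820  6.5
2        D0        247    1767 14.0
3        D2        187    1205 15.5
== DE (MAC2+ vs homeostatic) ==   69 up / 13 down DEGs
== up-DEG overlap with stage sets ==
  YS 28.99%   E1 28.99%   unassigned 42.03%
```

Reading this: QC removed the planted high-mito cells; clustering found the
five myeloid populations (several split further by the planted MAC2+
program) and exactly the four contaminant lineages, which were stripped; the
mean+1SD *Lgals3* gate calls 8–15% of cells per condition positive (the
planted carrier fractions are 3.0/9.8/11.2% — at the default moderate effect
size the gate over-calls a few percent of bulk cells, as quantified in the
methods vignette); the MAC2+-vs-homeostatic contrast recovers the planted
program, whose up-regulated genes concentrate in the yolk-sac (YS) and
early-embryonic (E1) stage sets, the hallmark of the progenitor-like state.

Real 10x-style data enter the same pipeline via
`input = list(path = "dir/")`, where the directory holds `matrix.mtx`,
`features.tsv`, `barcodes.tsv` and a per-barcode metadata TSV (see
`write_tenx()` for the exact layout).

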