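# bivalentscan

Integrative analysis of how an overexpressed transcription factor engages
**bivalent chromatin** — and whether its expression is prognostic in a
genomically defined patient subgroup.

## The problem

When a lineage-foreign transcription factor is switched on in a cancer
cell line (with a DNA-binding-dead mutant as control), four questions
recur:

1. Which genes does it *target* — i.e. which genes both carry a
   high-confidence binding peak near their TSS and respond
   transcriptionally?
2. What **chromatin context** does it bind? In particular, are activated
   targets enriched for bivalent (H3K4me3 + H3K27me3) and
   Polycomb-repressed (ReprPC) promoters — chromatin poised for
   activation?
3. Does binding **remodel** that chromatin: gain of H3K4me3, loss of
   H3K27me3 and of EZH2 (PRC2) occupancy around activating peaks?
4. Is the factor's expression associated with survival — not overall,
   but specifically in patients whose tumours are *RAS-driven* and carry
   *TP53 loss-of-function* alterations?

`bivalentscan` implements the full pipeline for these questions on
standard downstream files (narrowPeak, bedGraph, ChromHMM-style BED, a
DE table, GMT, a cohort TSV), with every statistic that matters —
hypergeometric overlap, preranked GSEA (ES/NES/permutation p),
Kaplan–Meier and the log-rank test — implemented from first principles
and cross-checked against independent references in the test suite.

Core definitions:

* **High-confidence peak:** −log10 p > 8 and fold enrichment > 4 (strict).
* **Target gene:** ≥ 1 high-confidence peak with summit within 100 kb of
  the TSS, significant, and |log2FC| > 2 (activated above +2, repressed
  below −2).
* **Bivalent/Polycomb group:** {TssBiv, BivFlnk, EnhBiv, ReprPC, ReprPCWk}
  of the 15-state Roadmap vocabulary.
* **RAS-driven / RAS-activated:** oncogenic alteration in
  {KRAS, NRAS, HRAS, RIT1, NF1} / that list plus
  {EGFR, ERBB2, MET, BRAF, MAP2K1}.
* **Upper-quartile stratification:** high iff expression ≥ Q3
  (type-7 interpolation, ties high).

Because the real inputs are consortium-scale, the package ships a seeded
synthetic-study generator (`simulate_study()`) that plants all of these
effects at desk scale and writes a ground-truth manifest, so the entire
pipeline is verifiable end to end. See the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter defaults and the
generator's scope.

## Worked example

```r
library(bivalentscan)

cfg <- simulation_config(seed = 7, n_chroms = 2, chrom_length = 22e6,
                         n_genes = 150, n_activated_targets = 30,
                         n_repressed_targets = 12, n_decoy_peaks = 60,
                         n_patients = 400)
truth <- simulate_study(cfg, "study")

genes <- read_gene_annotation("study/genes.gtf", "gtf")
peaks <- read_narrowpeak("study/peaks.narrowPeak")
expr  <- read_expression("study/expression.tsv")
tc <- call_targets(peaks, genes, expr)

seg <- read_segmentation("study/segmentation.bed")
grp <- anchor_groups(genes, tc$targets, tc$hc_peaks, tc$peak_labels)
f_act <- state_fractions(grp$activated_tss, seg)$group_fraction
f_bg  <- state_fractions(grp$nontarget_tss, seg)$group_fraction

layout <- genome_layout(c("chr1", "chr2"), rep(cfg$chrom_length, 2))
ratio <- log2_ratio_track(
  read_bedgraph("study/coverage_h3k4me3_oc2.bedGraph",  layout, 50),
  read_bedgraph("study/coverage_h3k4me3_ddbd.bedGraph", layout, 50),
  pseudocount = 0.1)
mp <- metaprofile(ratio, grp$activating_summits, flank = 5000)

sets <- read_gmt("study/gene_sets.gmt")
res <- gsea_permutation(rank_by_log2fc(expr), sets$PLANTED_ACTIVATED_TARGETS,
                        n_perm = 1000, seed = 1)

cohort <- read_cohort("study/cohort.tsv")
rs <- run_stratified_survival(cohort, "ras_driven", require_tp53_lof = TRUE)
```

Output of the summaries above (seed 7):

```
high-confidence peaks: 42 of 102
activated / repressed targets: 30 / 12
bivalent/Polycomb fraction: activated 40.0%, background 13.0%
mean H3K4me3 log2FC at activating summits (+/-500 bp): +0.97
planted-set GSEA: ES 1.000, NES 2.52, p 0.001252
log-rank in RAS-driven & TP53-LOF (n=44): chi2 6.18, p 0.01288
```

Reading it: the filter keeps exactly the 42 planted true peaks; target
calling recovers the 30 activated / 12 repressed planted genes; activated
TSSs sit in bivalent/Polycomb states three times as often as background;
the planted +1 log2 gain of H3K4me3 is recovered (+0.97) at activating
summits; the planted activated-target set is maximally enriched at 1,000
permutations; and the planted hazard ratio is detected inside the
RAS-driven ∧ TP53-LOF stratum.

The one-call equivalent is `run_all(default_run_config(seed, workdir))`,
which runs simulate → targets → chromstate → signal → enrich → survival,
writes every stage table plus `run_summary.json`, and is byte-identical
across reruns with the same seed.

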