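# lfqtime

Downstream analysis of **longitudinal label-free quantification (LFQ)
proteomics**: studies in which the same individuals are sampled repeatedly
over a timecourse (the motivating design is six fish sampled on days
0–84 after immunization, with ~278 plasma proteins quantified per sample)
and the question is which proteins respond to time at the population level,
how they co-vary, and how confidently highly similar duplicated proteins
can be told apart.

The package is aimed at proteomics analysts working downstream of a search
engine: it starts from a protein × sample abundance table (a generic TSV or
a MaxQuant `proteinGroups.txt`) and/or a protein FASTA, and implements:

* **Protein grouping** — in-silico tryptic digestion (K/R rule, proline
  exception, configurable missed cleavages) and *majority protein group*
  assembly: a protein joins a group when at least a fraction *t* (default
  0.5) of **its own** detected peptides are shared with the group's lead,
  so nested peptide sets always co-group.
* **Duplicated-protein diagnostics** — for genomes shaped by whole-genome
  duplication (salmonid Ss4R ohnologs): trimmed global-alignment percent
  identity, shared-peptide percentage (smaller set as denominator),
  duplicate screening at 70% identity/coverage, classification of groups
  into *scenario i* (duplicates co-grouped) vs *scenario ii* (duplicates
  split across groups), and identity–sharing correlations.
* **Preprocessing** — presence filtering (≥ 7 of 10 days in every
  individual), log2 transformation (zero intensity = non-detection),
  iterative random-forest imputation (missForest-style, deterministic),
  day-0 baseline normalisation, and log-scale averaging of designated IgM
  proteins.
* **Population statistics** — per-protein one-way ANOVA on sampling day
  with Benjamini–Hochberg control and its equivalent R² selection boundary

  R²\* = (k−1)F\* / ((k−1)F\* + k(r−1)),  F\* = F⁻¹₍ₖ₋₁,ₖ₍ᵣ₋₁₎₎(1 − Rq/m),

  which evaluates to **R² > 0.34** at m = 278 tests, R = 41 rejections,
  q = 0.05, df (9, 50); Tukey–Kramer compact letter displays;
  Anderson–Darling and Brown–Forsythe diagnostics; PCA; Spearman
  correlation.
* **Profile clustering** — Pearson dissimilarity (1 − r) of z-scored mean
  temporal profiles, complete-linkage trees, multiple-fragment seriation
  with exact optimal branch flipping, and cluster extraction labelled in
  heatmap order.
* **A synthetic cohort generator** — log2 model with protein baselines,
  per-(protein, individual) intercepts (partially shared across proteins),
  five archetypal temporal response shapes for a 15% responder subset, and
  calibrated low-abundance-biased (MNAR) missingness — so the whole
  pipeline is testable with known ground truth. See
  `vignettes/lfqtime-methods.Rmd` for the model and the rationale behind
  every default.

## Worked example

Simulate a cohort at the design geometry, hide values the way LFQ loses
them, and run the full analysis:

```r
library(lfqtime)

design <- cohort_design(seed = 7)           # 278 proteins, 6 fish, 10 days
sim    <- simulate_abundance(design)
masked <- apply_missingness(sim$tensor, design$missing_rate,
                            design$mnar_strength, seed = 7)
lfq    <- delog2_transform(masked)          # linear scale, as read from disk

res <- run_timecourse_analysis(lfq, q = 0.05, k_clusters = 5, seed = 7)
summary(res)
```

```
Longitudinal LFQ timecourse analysis
  retained proteins: 278 of 278 (presence filter)
  datapoints: 16680
  day-responsive proteins (BH q <= 0.05): 42 (15.1%)
  equivalent R2 selection boundary: 0.34
  profile clusters (k = 5): 9/9/8/8/8
  PC1/PC2 variance (raw): 35.7% / 9.8%
  PC1/PC2 variance (day-0 normalised): 15.4% / 9.5%
  strongest day effects:
    P0022  F = 15.10, R2 = 0.731, BH p = 2.6e-09
    P0030  F = 15.05, R2 = 0.730, BH p = 2.6e-09
    ...
```

Reading the output: all 278 proteins pass the presence filter at the
planted 0.78% missingness; 42 proteins (15.1%) show a sampling-day effect
after BH correction, and that cutoff is equivalent to R² > 0.34 — i.e. for
the selected proteins, sampling day explains over a third of the abundance
variance despite the dominant individual-to-individual differences visible
on PC1 of the raw PCA. The selected proteins fall into five temporal
clusters of 8–9 proteins. Against the generator's truth table, all 42
planted responders are recovered (`sensitivity: 1`).

A command-line interface wraps the same functions
(`exec/lfqtime <simulate|group|duplicates|preprocess|stats|cluster|report>`;
every stochastic subcommand takes `--seed`).

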