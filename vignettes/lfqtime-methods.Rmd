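---
title: "Methods: longitudinal LFQ proteomics with lfqtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal LFQ proteomics with lfqtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lfqtime` analyses label-free quantification (LFQ) proteomics timecourses in
which the same individuals are sampled repeatedly — the motivating design is
six fish sampled on days 0, 7, 14, 21, 28, 35, 42, 56, 70 and 84 after
immunization, with a few hundred plasma proteins quantified per sample. This
vignette documents the statistical model behind each stage, the defaults and
why they are what they are, and what the synthetic cohort generator does and
does not emulate.

## Protein groups from shared peptides

LC-MS proteomics cannot always distinguish proteins that yield the same
tryptic peptides, so quantification operates on *majority protein groups*
(MPGs). `tryptic_digest()` applies the classical trypsin rule (cleave
C-terminal to K or R unless followed by P) with up to two missed cleavages by
default and peptide length bounds of 7–35 residues, typical LC-MS
detectability limits. `assemble_groups()` seeds groups greedily from the
protein with the most detected peptides (ties broken by accession for
reproducibility) and admits a candidate protein P when

\[
  \frac{|pep(P) \cap pep(\mathrm{lead})|}{|pep(P)|} \;\ge\; t,
  \qquad t = 0.5 ,
\]

i.e. the candidate's **own** peptide count is the denominator. The phrase
"proteins sharing at least half of their peptides" is ambiguous between this
asymmetric reading and a symmetric one; the asymmetric rule was chosen
because it guarantees *subset absorption* — a protein whose peptides are
nested in another's always co-groups with it, which is how protein-inference
tools treat indistinguishable isoforms. Membership is evaluated against the
lead only, not transitively against later joiners; this gives deterministic
single-pass semantics and is a documented limitation. The threshold is a
parameter, and the suite verifies that the resulting partition is invariant
to the input order of proteins.

## Duplicated proteins and the whole-genome duplication

Salmonid genomes retain thousands of gene pairs from the salmonid-specific
fourth-round whole-genome duplication (Ss4R, ~88–103 Mya); their protein
products (ohnologs) are often 75–99% identical and stress the protein-group
concept. `pairwise_identity()` uses a global alignment (match 1, mismatch
−1, gap open 10, gap extend 0.5) trimmed to the aligned span of the shorter
protein; a built-in aligner replaces an external BLAST dependency because
the screening cutoffs used downstream (70% identity / 70% mutual length
coverage in `find_duplicates()`) are coarse enough to be insensitive to the
exact scoring. `shared_peptide_fraction()` divides the shared peptide count
by the **smaller** peptide set, so nested peptide sets score 100% — the
behaviour consistent with duplicate pairs reaching 100% sharing without
identical sequences; a Jaccard denominator is available behind a flag.
Groups are classified *scenario i* when a group contains a duplicate pair
from distinct genes, and *scenario ii* when a group's members have their
duplicates only in other groups. Ss4R labels come from generator metadata
for synthetic proteomes; for real data the caller must supply a
homeologous-chromosome pairing table — no genome lookup is attempted.

## Preprocessing

**Presence filter.** A protein is retained only if observed on at least 7 of
the 10 sampling days in *every* individual. This deliberately conservative
rule restricts inference to consistently measured proteins; at the design
geometry (278 retained proteins × 6 individuals × 10 days) the retained
matrix holds 16,680 datapoints, and 130 missing entries correspond to 0.78%
missingness.

**Zero handling.** An LFQ intensity of 0 in an input table is treated as a
non-detection (missing), never as a true zero, following the MaxQuant
convention; blank cells are equivalent.

**Imputation.** Missing log2 values are imputed by an iterative
random-forest scheme in the missForest style: initialise each hole with its
protein's same-day mean, then sweep proteins in increasing-missingness
order, regressing each protein's 60-sample vector on all other proteins
(100 trees, `mtry = floor(sqrt(p - 1))`) and replacing its holes with forest
predictions, stopping when the relative change in the imputed values rises
or after 10 sweeps. The forest backend is `ranger` with a fixed seed and one
thread, so imputation is deterministic. Per-day-mean and a correlation-based
k-nearest-protein method are provided as baselines; the suite requires the
forest to beat the day-mean baseline in held-out RMSE under the default
missingness model. Observed entries are never altered, and the returned
tensor records which entries were filled.

**Day-0 normalisation.** "Day 7 / day 0" ratios are computed as
subtractions on the log2 scale (exactly equivalent), so every individual's
day-0 entry becomes 0. **IgM aggregation** averages the designated
immunoglobulin proteins on the log2 scale (a geometric mean on the linear
scale), stated explicitly because the arithmetic/geometric distinction
matters when comparing to ELISA titres.

## Per-protein ANOVA, FDR and the R² boundary

Each protein is tested by one-way fixed-factor ANOVA on sampling day,
recording \(R^2 = SS_{day}/SS_{total}\), with Benjamini–Hochberg control
applied once across all retained proteins. In a balanced design the BH
decision is equivalent to an R² threshold: with \(R\) rejections among
\(m\) tests at FDR level \(q\), the raw-p boundary is \(Rq/m\), and
inverting the \(F(k-1,\,k(r-1))\) tail maps it to

\[
  R^{2*} = \frac{(k-1)F^*}{(k-1)F^* + k(r-1)} .
\]

At \(m = 278\), \(R = 41\), \(q = 0.05\), df \((9, 50)\) this gives 0.344,
i.e. a BH-corrected \(p \le 0.05\) corresponds to \(R^2 > 0.34\) — the
package recomputes this correspondence on every run and the selected set
always equals the set above the recomputed boundary. Proteins passing the
cutoff receive Tukey–Kramer compact letter displays (studentized-range
p-values, insert-and-absorb letter assignment). Anderson–Darling normality
(parameters estimated, case-3 statistic) and Brown–Forsythe Levene checks
are reported as diagnostics only; no protein is excluded on their basis.

An important caveat is inherited deliberately: the ANOVA treats the six
individuals as independent replicates within each day although they are
repeated measures of the same animals. Because the design is balanced, the
per-individual intercept cancels from the between-day sum of squares and
inflates the residual, making the test *conservative* — raw p-values are
stochastically larger than uniform whenever individual variance is present.
The package reproduces this historical choice rather than replacing it with
a mixed model, and the calibration checks below are constructed accordingly.

## Profile clustering and seriation

Mean-over-individuals temporal profiles of the selected proteins (optionally
with mean-IgM and titre rows appended) are row z-scored (display parity;
correlations are unaffected) and compared by Pearson dissimilarity
\(d = 1 - r\). Trees use complete linkage. For display order, the package
implements the multiple-fragment heuristic (greedy shortest-edge path
construction) and then chooses, among all \(2^{n-1}\) leaf orders obtainable
by flipping the tree's internal branches, the one minimising the sum of
adjacent-leaf dissimilarities — computed exactly by dynamic programming and
oriented to agree with the unconstrained multiple-fragment path. The exact
flipping objective used by the original PermutMatrix heatmap software is not
published; the minimal-adjacent-dissimilarity criterion is this package's
choice and is stated in its outputs. Cluster labels from `cut_clusters()`
are renumbered by first appearance along the seriated order, so cluster 1
is leftmost on a heatmap. `k = 5` is the default cluster count, mirroring
the five archetypal response shapes; the two-clade cut (`k = 2`) remains
available through the same interface.

## The synthetic cohort generator

Because raw study tables are not redistributable, every stage is exercised
against synthetic cohorts with known truth. The per-observation model on
the log2 scale is

\[
  y_{pfd} = \mu_p + a_{pf} + e\,g_p(d)\,\mathbb{1}\{p \text{ responder}\}
            + \varepsilon_{pfd},
\]

with protein baselines \(\mu_p \sim N(25, 1)\), residual noise
\(\varepsilon \sim N(0, \sigma_\text{noise}^2)\), and a per-(protein,
individual) intercept

\[
  a_{pf} = \sigma_\text{ind}\left(\sqrt{w}\,F_f + \sqrt{1-w}\,G_{pf}\right),
\]

whose component \(F_f\) is shared across proteins (a sample-level
individual signature, weight \(w = 0.5\) by default) while \(G_{pf}\) is
protein-specific. Both ingredients matter: the shared part makes samples
from one individual cohere in PCA and gives cross-protein imputation
something to learn from; the protein-specific part reflects genuine
genetic/physiological differences per protein. The realized \(F_f\) is
standardized across the cohort so the planted between-individual variance
is exact rather than subject to 5-degree-of-freedom sampling noise.

**Archetypes.** Fifteen percent of proteins are responders, assigned
round-robin to five piecewise-linear temporal shapes: a late single peak
(A1), a slow monotone rise (A2), an early spike with plateau (B1), a
mid-course peak with late trough (B2), and an early-high decaying shape
(B3). Each shape is centred and scaled to unit SD across the ten days, so
`effect_size` is the day-to-day SD of a planted effect in log2 units; the
peak excursion is roughly 1.4–2 × `effect_size`. Normalising to equal SD
(rather than equal peak) makes every archetype equally detectable by the
day-ANOVA, so recovery benchmarks measure the pipeline, not the shape
lottery. At the default `effect_size = 1.0` the peak fold change is
roughly 2.6–4, matching the 3–5-fold antibody rises typical of a primary
immunization response.

**Default variance components** were fixed by power analysis before any
benchmark was run: with unit-SD profiles the day-ANOVA noncentrality is
\(6 \cdot 9 \cdot e^2 / (\sigma_\text{ind}^2 + \sigma_\text{noise}^2)\);
at \(\sigma_\text{noise} = 0.5\), \(\sigma_\text{ind} = 0.75\) and the
stress effect \(e = 2\sigma_\text{noise} = 1\) this is ≈ 66, giving
per-protein power above 0.95 at the BH-implied per-test level (≈ 0.006–
0.0075 at df 9, 50) while the individual intercept (variance 0.5625) still
dominates the residual (0.25) — individual differences explain about 70% of
the stochastic variance of every protein, and far more of the global PCA
structure since only 15% of proteins carry any day effect.

**Missingness** is missing-not-at-random: each entry is masked with
probability \(\mathrm{logit}^{-1}(a - s\,z)\) where \(z\) is the entry's
abundance z-score, \(s\) (`mnar_strength`, default 1) tilts non-detection
toward low abundances as for intensities near the detection limit, and the
intercept \(a\) is calibrated by root finding so the expected masked
fraction equals the target (default 0.78%, the post-filter rate of the
motivating design). `mnar_strength = 0` recovers MCAR. The pre-filter
missingness rate of real data is not modelled — the generator plants the
post-filter rate directly, which is the quantity the imputation stage
actually faces.

**Null-calibration cohorts.** Uniformity of the raw ANOVA p-values is
checked on cohorts with `effect_size = 0` *and* `sigma_individual = 0`.
With an individual intercept present the test is conservative (see above),
so a Kolmogorov–Smirnov uniformity check would correctly reject — not
because the p-value computation is wrong but because the exchangeability
assumption is violated by design. The calibration therefore isolates the
exchangeable null; FDR control is checked on the same cohorts, and is only
strengthened by the conservativeness under individual structure.

**Randomness** flows from one master seed through counter-based substreams
(one per protein, family, or fish), so enlarging a simulation never
perturbs the units already generated, and every stochastic function is
reproducible from its `seed` argument alone.

**What the generator does not emulate:** peptide-level intensities and
their roll-up into protein LFQ values, between-run normalisation artefacts,
batch effects, heavy-tailed or correlated residuals, isoform-level
missingness, and real paralog sequence evolution (substitutions are placed
uniformly at random, with no indels or rate heterogeneity). Passing
recovery benchmarks on these cohorts therefore demonstrates correctness of
the pipeline's logic under its own assumptions, not performance guarantees
on any particular real dataset.

## Numerical choices and degenerate inputs

* All-identical values in an ANOVA raise an error rather than returning
  `F = 0/0`; groups with equal means but unequal values return `F = 0`,
  `p = 1`.
* Zero within-group variance in the Tukey step falls back to "any mean
  difference is significant", keeping the letter display defined for
  degenerate planted fixtures.
* Constant profile rows are rejected by name before z-scoring or
  correlation, since their dissimilarity is undefined.
* Identity targets for simulated paralogs are rounded to the nearest
  achievable substitution count, never refused, so a 100-residue template
  at 99.5% identity yields 99% or 100% — always within half a grid step.
* The imputation loop stops on the first increase of the relative change in
  imputed values (missForest's criterion) and returns the previous sweep.
* Problem sizes in the shipped benchmarks: full-geometry cohorts
  (278 × 60) for calibration, recovery and imputation; 60-protein cohorts
  for archetype recovery; 50 paralog pairs and 100 random peptide indices
  for the grouping and duplicate mechanisms. These sizes give stable
  statistics while keeping a complete run of the suite inside a few
  minutes on one CPU.

## Known limitations

Group membership is lead-anchored rather than transitive; the sharing
threshold's effect on group counts is monotone only empirically, not by
theorem. The identity of a duplicate pair is computed from one optimal
alignment; co-optimal alignments can differ by a fraction of a percentage
point. The repeated-measures caveat of the day-ANOVA is documented, not
fixed. Tie-breaking inside the complete-linkage agglomeration follows the
underlying `hclust` implementation; with continuous dissimilarities ties
have probability zero.
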