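---
title: "Methods: RPKM thresholds, two-group ANOVA, splicing indexes"
author: "rpkmsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RPKM thresholds, two-group ANOVA, splicing indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpkmsplice)
```

# The analysis

`rpkmsplice` implements a classical two-group bulk RNA-seq comparison of the
kind used to profile embryonic mouse heart valves from a transcription-factor
knockout (here generically "mutant") against wild-type littermates
("control"), three biological replicates per genotype. The pipeline starts
from an exon-level read-count matrix — alignment and read counting are
upstream of this package — and runs five stages:

1. **Quantification.** Abundances are Reads Per Kilobase per Million mapped
   reads, $\mathrm{RPKM} = c \cdot 10^9 / (L \cdot N)$ for count $c$, feature
   length $L$ in bases and library size $N$. Gene counts are the sum of the
   gene's exon counts, gene length is the union of its exon intervals, and
   $N$ is the per-sample column sum of gene counts — one normalization basis
   shared by the gene and exon levels.
2. **Reliability thresholds.** A gene is analyzed only if it reaches 50 reads
   in at least one sample (the *Reliable Quantification Threshold*: at ~50
   reads an RPKM is expected to be reproducible between technical
   replicates). To stop low counts from generating spurious large ratios,
   any cell with ≤ 10 reads/gene (≤ 1 read/exon at the exon level) is
   replaced by that feature's *replacement floor*: the RPKM equivalent of
   the threshold count averaged across all samples. Floored cells of a
   feature share one value, so a gene entirely at the floor has fold change
   exactly 1.
3. **Differential expression.** Per gene, a one-way fixed-effects ANOVA with
   df = (1, 4) across genotypes, plus the mutant/control ratio of group-mean
   post-replacement RPKM. The fold change is reported as `NA` when *both*
   group mean raw counts are below 50 reads. Genes with p < 0.05 form the DE
   set; the downstream focus list additionally requires a two-sided 1.5-fold
   change (≥ 1.5 or ≤ 1/1.5). A Venn-style detection classification
   (detected ⇔ count > 10 in a sample) labels each gene `common`,
   `unique_A`, `unique_B` or `excluded`.
4. **Clustering.** The DE genes are log2-transformed, median-centered per
   gene, and hierarchically clustered with centered (Pearson) correlation as
   similarity (distance $1-r$) and unweighted average linkage, on both the
   gene and sample margins; results are written as Cluster 3.0 / Java
   TreeView `.cdt`/`.gtr`/`.atr` files.
5. **Splicing indexes.** Per exon and sample,
   $\mathrm{SI}(e,s) = \mathrm{RPKM}_{\text{exon}} / \mathrm{RPKM}_{\text{gene}}$,
   after a two-step exon filter (gene reliable; exon has ≥ 1 read in ≥ 1
   sample) and the 1-read exon floor. The SI is `NA` wherever the gene has
   < 50 reads in that sample; an exon with any `NA` sample gets `NA`
   statistics. Retained exons are tested by the same two-group ANOVA plus a
   Tukey HSD contrast. Finally, over-representation of the focus list in
   user-supplied GMT gene sets is tested with the one-sided hypergeometric
   (Fisher) test against the universe of *detectable* (reliable) genes, with
   Benjamini–Hochberg adjustment and an adjusted-p < 0.05 call.

# Design choices where the protocol is open

Several details are not fixed by the conventions the pipeline follows; the
package makes these choices once and exposes them as configuration:

- **ANOVA scale.** The gene-level ANOVA runs on log2 post-replacement RPKM
  (`anova_scale = "log2"`), which stabilizes the strong mean–variance
  relation of count-derived abundances and matches the clustering transform.
  A linear-scale option is kept for comparison. The splicing-index ANOVA, by
  contrast, runs on the raw ratio: the SI is defined as a plain quotient and
  is already normalized by the gene's own abundance.
- **Venn detection threshold.** The per-sample detection cutoff is
  count > 10 (`k_det = 10`): a cell that escaped the 10-read replacement
  floor carries quantitative evidence of expression, a floored cell does
  not. It is configurable because the choice is a convention, not a
  consequence of the model.
- **Threshold orientation.** "A minimum of ~50 reads" is implemented
  inclusively (≥ 50), "≤ 10 reads" inclusively as printed; both boundaries
  are exercised explicitly by tests at 49/50/51 and 9/10/11 reads.
- **Library size.** With alignment out of scope, the total-mapped-read count
  is not available; the column sum of gene-level counts stands in. Since
  RPKM enters every downstream decision only through ratios and thresholds
  computed from the same basis, the substitution is consistent across
  stages.
- **Fold-change direction split.** `up`/`down` are defined by the reported
  fold change; genes whose fold change is `NA` (both groups under 50 mean
  reads) remain in the DE set when p < 0.05 but never pass the fold-change
  filter, so the run manifest records the three-way split
  `n_de = n_de_up + n_de_down + n_de_undirected` and, separately, the
  fold-change-filtered `n_fc_filtered = n_fc_up + n_fc_down`.
- **Multiple testing.** Gene-level calls use the raw p < 0.05 convention; a
  Benjamini–Hochberg column is emitted for information only. Enrichment
  *is* BH-adjusted (the usual over-representation convention), with
  Bonferroni as an option.
- **Tukey with two groups.** The Tukey-adjusted p equals the ANOVA p when
  only one pairwise contrast exists; the studentized-range computation
  (`ptukey` at $q = \sqrt{2F}$) is retained so the column matches a generic
  post-hoc report. R's `ptukey` agrees with the exact identity to about
  $10^{-6}$ relative — tests of the identity use a $10^{-5}$ tolerance while
  the algebraic oracles elsewhere hold at $10^{-10}$.

# Numerical and algorithmic notes

- **Row-wise ANOVA.** The two-group F statistic is computed vectorized over
  features ($F = \mathrm{SSB} / (\mathrm{SSW}/(n_A+n_B-2))$, upper tail of
  `pf`), so a genome-scale matrix needs one call rather than one model fit
  per feature. Tests pin it to `stats::oneway.test`, to
  `t.test(var.equal = TRUE)` via the $F = t^2$ identity (relative tolerance
  $10^{-10}$ over 1,000 random inputs), and to `aov`/`TukeyHSD` per exon.
  Degenerate rows are defined, not errors: both groups constant and equal
  gives $F = 0, p = 1$; constant but different gives $F = \infty, p = 0$.
- **Average linkage.** Implemented with the unweighted Lance–Williams
  update and cached nearest-neighbour arrays (valid because average linkage
  is reducible: a merged cluster is never closer to a third cluster than
  its nearer part), giving $O(n^2)$ typical behavior — about 5 s for 2,500
  genes against hours for a naive full-matrix re-scan. Ties are broken
  deterministically toward the lexicographically smallest pair of cluster
  ids (leaves numbered in input order, merge $k$ creating id $n+k$), and
  the leaf order places, at every internal node, the subtree containing the
  lowest original leaf index first, so output is reproducible across runs
  and platforms. Merge heights are verified against both a brute-force
  re-scan oracle and `stats::hclust(method = "average")`.
- **Zero-variance rows.** A gene whose cells are all floored is constant
  after preprocessing and has no defined correlation; its similarity to
  everything is taken as 0 (with a warning) instead of aborting, mirroring
  the tolerance of the classic clustering tools.
- **Exact identities used as tests.** Pre-replacement,
  $\sum_g \mathrm{RPKM}_{g,s} L_g = 10^9$ for every sample; for a gene with
  disjoint exons and no floored/`NA` cells,
  $\sum_e \mathrm{SI}(e,s) L_e / L_g = 1$ exactly. Both are asserted to
  $10^{-10}$.

# The synthetic-data generator

Real data for this design (GEO-scale mouse valve RNA-seq) cannot ship with
a package, so validation rests on `simulate_dataset()`, which emulates the
statistical structure the analysis assumes:

- two groups × 3 replicates; ~19,000 genes with 4–12 exons of 80–400 bases
  (≈ 8 exons/gene on average), disjoint within a gene;
- baseline gene means drawn log-normally ($\log_2$ mean 7, sd 2.5 — a wide
  dynamic range with a realistic low-expression tail), split across exons
  proportional to exon length (uniform coverage);
- counts $\sim \mathrm{NB}(\mu, \mathrm{size} = 1/\phi)$ with
  $\mu = \text{baseline} \times \text{group effect} \times \text{exon
  multiplier} \times \text{library factor}$ and a shared dispersion
  $\phi = 0.05$, typical of laboratory-animal bulk RNA-seq; library factors
  0.9–1.1;
- planted truth: 10% DE genes (log2 fold change magnitude 1–3, random
  sign), 5% differential-exon-usage genes (one random exon scaled 3× in the
  mutant group), and 5% of the null genes rescaled so their expected
  maximum sample count lies in [30, 70] reads — deliberately straddling the
  50-read threshold so the boundary rules are exercised on both sides.

Gene counts are exon sums by construction, which makes the length-weighted
SI identity exact rather than approximate. A DEU gene's total abundance
shifts slightly in the mutant group (its scaled exon contributes to the gene
sum); its truth record still says `is_de = FALSE`, and the false-discovery
proportion is reported against that strict truth.

What the generator does **not** emulate: positional/GC coverage bias,
overlapping or shared exons, isoform-level correlation between exons,
batch effects, outlier libraries, and >2-group designs. Passing tests
therefore demonstrate that the *rules and statistics* are implemented
correctly and behave as designed under the assumed model — not that the
thresholds are optimal for any particular real dataset.

`simulate_dataset()` seeds the global RNG via `set.seed(params$seed)` — the
convention of the widely used count simulators — so identical parameters
reproduce the dataset bit for bit.

# Validation summary

The test suite checks, among others (problem sizes chosen to keep the whole
suite in the minutes range while leaving no stage untested):

- oracle equivalence: $F = t^2$ (1,000 random inputs, $10^{-10}$);
  hypergeometric enrichment against exhaustive enumeration of all
  $\binom{N}{n}$ draws for $N \le 12$; average-linkage heights against a
  brute-force re-scan on 50 random 8-leaf instances;
- null calibration at 5,000 genes, dispersion 0.05: the gene-level
  p < 0.05 rate stays within 3 binomial standard errors of 0.05 and
  exon-level p-values pass a Kolmogorov–Smirnov uniformity check at
  $\alpha = 0.01$;
- planted-truth recovery at 2,000 genes: 4-fold DE genes with baseline
  ≥ 200 expected reads are recovered at sensitivity ≥ 0.9 by the
  p < 0.05 ∧ FC > 1.5 caller, and 3× DEU exons are enriched among
  significant exons (one-sided Fisher p < $10^{-6}$);
- the printed boundary rules at exactly 49/50/51, 9/10/11, 0/1 reads;
- a full-scale end-to-end run (19,000 genes, 6 samples) with a
  self-consistent run manifest.

# Known limitations

- Two groups only; no covariates, no moderated variance estimators (use
  limma/DESeq2 when you want those — this package reproduces a specific
  classical protocol, floors and all).
- RPKM normalization is compositionally sensitive: strongly asymmetric
  differential expression inflates one group's library size and shifts the
  fold changes of unchanged genes away from 1 (visible in synthetic runs as
  an excess of calls opposite to the dominant planted direction). This is a
  property of the protocol being reproduced, not corrected here; TMM-style
  normalization is deliberately out of scope.
- The replacement floor intentionally biases low-abundance fold changes
  toward 1; interpret fold changes near the floor accordingly.
- The Venn `excluded` class and the DE set are computed on the reliable
  gene set; genes failing the 50-read threshold appear in no downstream
  table except the unquantified attribute of `filter_reliable()`.
- Enrichment results are only as good as the supplied GMT collections; no
  curated knowledge base ships with the package.
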