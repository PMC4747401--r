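---
title: "Methods: extracting clinically relevant drug-resistance genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting clinically relevant drug-resistance genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resisig)
```

## The problem

Gene signatures of chemoresistance derived from drug-induced resistant
cancer cell lines rarely transfer to patients. A resistant line differs
from its parental line in several ways at once: genes that are *basally*
different between the lines (BD genes), genes that any drug exposure
*induces* in the parental line (IP genes), and genes whose *response to
the drug differs* between the two lines (ID genes — the contrast between
drug-treated resistant and drug-treated parental cells at the same
treatment time). Only the last kind is a plausible resistance mechanism;
the first two are dominated by sustained and transient drug-response
programs. `resisig` implements the full analysis needed to make that
argument quantitatively: ranking statistics suited to two-or-three
replicate designs, a directional concordance test between any two gene
lists, a rank-based differential-expression test for clinical cohorts,
and the regimen-intersection logic that attributes clinical
resistance genes to individual drugs.

## Ranking statistics for small-replicate designs

With two or three technical replicates per condition, variance-based
statistics are underpowered, so genes are ranked by plain effect
statistics computed on non-log group means: the fold change
$FC_i = \bar{x}^A_i / \bar{x}^B_i$ and the average difference
$AD_i = \bar{x}^A_i - \bar{x}^B_i$, with group A always the
resistant/treated member. A gene is up-regulated when $FC_i > 1$
(equivalently $AD_i > 0$) and down-regulated when $FC_i < 1$
($AD_i < 0$); for positive group means the two statistics always agree
in sign, but they rank genes very differently. FC favours genes at low
absolute expression (where small fluctuations produce large ratios)
while AD favours highly expressed genes (where modest ratios produce
large differences). `expression_bias_report()` quantifies this by
comparing the mean expression of genes found exclusively by each method.

Because sorting by the raw statistic cannot produce a mixed up/down top
list, `top_n()` ranks by the symmetric magnitude $\max(FC, 1/FC)$
(respectively $|AD|$), with ties broken by gene id for determinism.
Ranking by the signed statistic remains available via `signed = TRUE`.
The default list size is 3000, intended for genome-scale platforms
(~20,000 genes); analyses of the bundled 2000-gene simulations use 400
so that the list-to-genome ratio is comparable.

## Directional consistency and its null

Two directional gene lists sharing $k$ genes, $s$ of which agree in
direction, have consistency score $100\,s/k$. Under the null that
directions are assigned independently with chance agreement probability
$p_e$ (0.5 by default), the significance of the observed agreement is
the exact one-sided binomial tail

$$p \;=\; 1 - \sum_{i=0}^{s-1} \binom{k}{i} p_e^{\,i} (1-p_e)^{k-i},$$

computed in `binomial_tail()` by direct summation of log-space terms —
no normal approximation, which matters for the very small tails that
the strong comparisons produce. The test is one-sided by construction
(agreement above chance is the only alternative of interest); an empty
overlap ($k=0$) yields $p = 1$ and a degenerate flag rather than an
error, so batch table generation never aborts.

## Rank-product differential expression for clinical cohorts

Responder versus non-responder comparisons pool cohorts from different
studies, so the test must be immune to per-dataset location shifts.
`rank_product()` implements the unpaired pairwise rank product: every
class-A sample is compared with every class-B sample (restricted to
same-dataset pairs by default), genes are ranked within each pairwise
difference, and the statistic is the geometric mean of a gene's ranks
across pairs. Only within-pair orderings enter, so adding any constant
to a sample's log expression changes nothing — the testable form of
batch resistance, asserted by the test suite.

Significance is obtained by permutation. The gene labels are permuted
*within each sample column* and all pairwise rankings are recomputed;
each gene's one-sided p-value is $(1 + \#\{\text{null} \le
\text{obs}\})/(B+1)$ over $B$ rounds. Permuting within samples rather
than within each pairwise difference vector preserves the correlation
between pairs that share a sample; ignoring that correlation
understates the variance of the cross-pair mean and, in our
measurements on null cohorts, produced ~30% of genes at $p<0.05$.
With the sample-wise scheme the null fraction is ~5%.

Since both an up and a down tail are tested per gene, the combined
p-value is $\min(1,\, 2\min(p_{up}, p_{down}))$; the raw one-sided
values, Benjamini–Hochberg FDR within each direction, and
Breitling-style expected-false-positive rates (`pfp_up`, `pfp_down`)
are all reported, so either FDR convention can be applied downstream.
Permutation p-values are bounded below by $1/(B+1)$; with the default
$B = 1000$ and 2000 genes this resolution is sufficient for FDR
thresholds of 0.1–0.2.

## From clinical DEG lists to per-drug resistance genes

Patients receive drug combinations, so a responder/non-responder DEG
list implicates a regimen, not a drug. Under the assumption that
combined drugs do not antagonize each other, a gene differentially
expressed in the same direction in two regimens that share drugs is
attributable to the shared drug(s). `intersect_regimens()` implements
this conclusion as direction-consistent set intersection (conflicting
genes are excluded and reported); `tiered_crg()` implements the
two-tier selection used for a discovery cohort (FDR < 0.2) confirmed in
an independent cohort (p < 0.05, same direction). The orientation
convention everywhere is that "up" means higher in non-responders,
matching "higher in the resistant line" for cell-line lists, so
consistency scores across the two domains are meaningful. Genes
unmeasured on a platform are excluded from intersections
(complete-case): a direction cannot be confirmed where it was never
observed.

## Pathway enrichment

`hypergeom_enrich()` performs the standard over-representation test:
the upper-tail hypergeometric probability of at least the observed
overlap (observed count included), BH-adjusted across sets. The
universe defaults to all genes measured on the platform and must be
supplied explicitly — enrichment is universe-sensitive. Gene sets are
read from standard GMT files; no pathway database ships with the
package (a small synthetic GMT fixture is included for tests).

## The synthetic-data generator

`generator_config()` + `generate_cellline_experiment()` +
`generate_clinical_cohort()` emulate the study design the pipeline
assumes: a parental/resistant pair profiled untreated and at 6, 12 and
24 h of treatment with 3 replicates per condition, and clinical
pre/post-chemotherapy cohorts of responders and non-responders. Effects
are additive on log2 (multiplicative on the linear scale):

* **resistance genes** (default 100, effect 1.5 log2 units) ramp up
  linearly with treatment time in the treated-resistant arm only,
  reaching full size at 24 h — late divergence is the signature the ID
  contrast detects. A 15-gene stratum sits on a high baseline
  (log2 ≈ 13) with a small log effect (0.30, FC ≈ 1.23): large average
  differences, fold changes too small for FC lists. This stratum gives
  the expression-bias diagnostics known positives.
* **drug-response genes** (default 200, peak 2.0 at 12 h, decaying to
  30% of peak by 24 h) are induced by treatment in both cell types. The
  resistant line additionally retains 60% of the peak in *all* its
  samples, modelling the chronically drug-exposed line's persistent
  induction. This sustained component is what makes BD lists agree with
  IP lists far above chance — the confounding phenomenon the pipeline
  is designed to expose — and is a deliberate modelling choice: without
  it, basal and induced programs would be artificially disjoint.
* **basal-difference genes** (default 100, effect 1.5) separate the
  lines everywhere and are resistance-irrelevant.

Clinical non-responders carry each planted resistance effect scaled by
an attenuation factor (0.5) and a per-patient log-normal heterogeneity
multiplier (sd 0.3); sample noise is larger than in cell lines (sd 0.5
vs 0.2). Pre-chemotherapy discovery cohorts are 25 non-responders vs 19
responders split over two batches with gene-wise batch shifts (sd 0.5);
the confirmation cohort is 14 vs 23 in one batch; the post-chemotherapy
cohort (17 vs 13) additionally places *all* its samples in the
drug-exposed state, so the responder/non-responder contrast there is
the clinical analogue of the ID contrast. Defaults were chosen once to
represent a realistic effect hierarchy (induction > basal ≈ resistance
at 24 h ≫ stratum ratio effect) and are not tuned per analysis; the
simulation is desk-scale (2000 genes) and its consistency scores land
in the 70–95% range that motivates the method.

What the generator does *not* emulate: probe-level artefacts,
cross-hybridization, tumor cellular composition, correlated gene
modules (genes are independent given their class), survival outcomes,
and dose–response. Passing recovery tests therefore demonstrate that
the pipeline's logic is correct under its own assumptions, not that
those assumptions hold on any particular clinical dataset.

## Numerical and design choices

* Probe aggregation (`aggregate_probes()`) averages probe rows on the
  scale the matrix is currently in; the recommended order is
  normalize-then-aggregate, and FC/AD are always computed after
  `delog()` since both are defined on non-log values.
* Quantile normalization assigns tied entries the mean of the quantile
  values they span (the `limma::normalizeQuantiles(ties = TRUE)`
  convention); values ≤ 0 are floored to a configurable epsilon
  (default 1.0) before log2.
* Group means of zero are floored to epsilon before ratios; with
  epsilon 0 a zero denominator is an error naming the gene.
* Ties in pairwise rank differences receive average ranks; top-list
  ties break by gene id; all permutations and simulations require an
  explicit integer seed, and identical seeds give bit-identical output.
* `run_full_pipeline()` executes the whole graph on a two-drug
  simulation — BD/IP/ID lists at every time point by both methods,
  BD_two/ID_two overlaps, discovery/confirmation/post-chemotherapy
  rank-product tables, the tiered CRG set, ID_clinical, all consistency
  tables, the bias report, trajectories and enrichment — and writes
  every table as TSV with a parameter header plus a manifest, so a run
  is fully reproducible from its output directory.

## Known limitations

The binomial consistency test treats genes as independent; co-regulated
modules inflate both the score and its apparent significance. The
rank-product permutation null assumes genes are exchangeable within a
sample; strong mean–variance trends would violate this. The
regimen-intersection logic inherits the no-antagonism assumption and
cannot attribute genes to drugs that never appear in a shared-drug
pair. None of these caveats is resolved by the synthetic validation,
which satisfies the assumptions by construction.
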