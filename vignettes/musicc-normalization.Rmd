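---
title: "Marker-gene normalization of metagenomic functional profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene normalization of metagenomic functional profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musiccr)
```

## The problem

Shotgun metagenomic pipelines count, per sample, the reads that map to
each gene family (here KEGG Orthology groups, "KOs"). Read counts depend
on sequencing depth, so they are almost universally converted to
*relative abundances* by dividing each gene's count by the sample total
("compositional normalization"). That quantity is unitless and is
confounded by sample-specific properties: communities of large genomes
dilute the apparent share of any given gene, high species richness and
poor reference coverage ("mappability", one minus the Nearest Sequenced
Taxon Index averaged over the community) change the fraction of reads
that map at all. Genes that are genuinely invariant across communities —
universal single-copy genes (USiCGs), present once in essentially every
bacterial and archaeal genome — therefore show strong, purely artifactual
variation in their relative abundance across samples.

`musiccr` implements the MUSiCC approach to this problem: use the USiCGs
themselves as a yardstick.

## The estimator

**Inter-sample correction.** Let $a_{gs}$ be the length-normalized
abundance of gene $g$ in sample $s$ (read count divided by the mean
length of genes annotated to the KO). The corrected abundance is

$$\hat c_{gs} = \frac{a_{gs}}{\operatorname{median}_{m \in U} a_{ms}},$$

the division being by the median abundance of the marker set $U$ in that
sample. Because each marker occurs once per genome, $\hat c_{gs}$
estimates the *average genomic copy number* of $g$ across the cells of
the community — the gene content of a "typical microbe" of the sample.
Two properties follow immediately and are what the tests verify: the
marker median is 1 in every sample after correction, and the estimate is
invariant to any per-sample rescaling of the input, which removes depth
and compositional artifacts regardless of their origin. The median runs
over *all* markers in the set, counting undetected markers as zeros; a
guard (default: at least 10 markers with nonzero abundance) rejects
degenerate samples where a median over mostly-zero markers would be
meaningless.

**Intra-sample correction.** Even within one sample the measured
abundances of the markers scatter around 1 in a way that is consistent
across samples and predictable from gene-specific properties (GC
content, length variability of the orthology group, annotation recall,
and so on). `fit_intra_model()` regresses the marker fold-changes
$r_m = a_{ms} / \bar a_{Us}$ on standardized gene properties with an
elastic-net penalty, and `apply_intra_correction()` divides every gene
by its predicted fold-change. Division is the unique application rule
that maps a perfectly predicted marker back to its expected value of 1;
the model itself only ever sees markers, so all other genes are unseen
data.

Details of the fit, all of which matter at the scale of ~76 markers and
~35 properties:

* **Nested cross-validation.** Outer folds (default 5) produce the
  held-out $R^2$; the penalty is chosen inside each outer training set
  by inner cross-validation, and the reported model is refit on all
  markers at the median of the outer-fold penalties. Property imputation
  (medians) and standardization are computed from training data only
  within each fold.
* **Relaxed elastic net.** A plain penalized fit at this sample size
  shrinks true coefficients substantially; we use glmnet's relaxed fit
  (the debiasing blend chosen by the same inner cross-validation), which
  recovers noise-free synthetic weights to within a few percent.
* **Held-out $R^2$ definition.** Per outer fold,
  $1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ with the baseline mean taken
  from the *training* fold (an intercept-only model learned on training
  data), averaged over folds. With ~15 markers per held-out fold a
  test-mean baseline would be biased downward; the training-mean
  baseline keeps every compared quantity train-derived.
* **Mixing parameter.** Default $\alpha = 0.5$; $\alpha = 1$ gives the
  pure L1 model.
* **Clamping.** Predicted fold-changes are clamped below at 0.01 so
  genes far outside the marker property range cannot flip sign or
  explode; clamp events are logged. The clamp interacts with heavy
  response noise: if responses sit at the generator's 0.05 floor, a
  clamped prediction can overshoot, which is why "correction reduces
  marker dispersion" is only guaranteed for data genuinely generated
  under the linear model.
* **Scope.** `fit_intra_model()` learns per sample;
  `fit_generic_model()` pools (marker, response) observations across
  samples with fold assignment at the marker level, so a marker never
  straddles train and test. Models serialize to flat key-value text.

**Marker selection.** `select_markers()` reproduces the selection rule
on any genome content matrix: prevalence (fraction of genomes carrying
the KO) at least 91.5% and mean copy number below 1.1 *conditional on
presence* gives the universal set; the band [85%, 91.5%) gives the
"semi-universal" set, disjoint by construction because the band is
closed below and open above. The 91.5% cutoff is taken as a fixed
default rather than re-derived (its original derivation depends on a
specific reference database snapshot). The packaged marker lists are
synthetic stand-ins with the canonical cardinalities (76 and 72); on
real KEGG-annotated data supply a curated list or derive one from a
genome content matrix.

## Alternative normalizations, for comparison

* `compositional_normalize()` — the conventional scheme, kept as the
  baseline the package argues against.
* `raes_egs()` — the closed-form effective genome size
  $EGS = (a + b\,L^{-c})/x$ with the published calibration
  $a = 21.2$, $b = 4230$, $c = 0.733$, where $x$ is the per-sample
  marker gene density. We define $x$ as the sum over marker-hitting
  reads of matched bases over marker gene length, divided by the total
  bases sequenced; the source description is ambiguous about the
  denominator and the depth-invariant reading is adopted (a constant
  factor is irrelevant to the correlation-based evaluation). Note
  $EGS$ falls with read length $L$, since $L^{-c}$ does.
* `marker_egs_normalize()` — a panel-of-eight universal genes scheme:
  $G = (g + L - 2m)/f$ per marker (gene length $g$, read length $L$,
  minimum overlap $m$, relative abundance $f$), averaged and multiplied
  back onto relative abundances. The panel is a configurable input; no
  default panel is shipped.

## What the simulator emulates

`build_genome_pool()` + `simulate_dataset()` generate the ground-truth
world in which the estimator can be judged exactly:

* Mock genomes carry every marker at copy 1, an *invariant pathway*
  (all genomes share identical copy numbers) and accessory KOs drawn
  with per-genome presence probabilities evenly spaced over a range, so
  pool genome sizes span a wide, reproducible range (>3-fold at the
  defaults). Gene lengths are log-normal around 900 bp; 10% of each
  genome is unannotated padding.
* Communities draw 10 of 21 genomes per sample, with relative
  abundances log-uniform up to a 100-fold ratio (the bound holds for
  every draw, not just in expectation).
* Reads are *origin-tracked*, not sequence-simulated: a read picks a
  genome with probability proportional to abundance × genome length
  (longer genomes contribute more DNA — exactly what makes average
  genome size a confounder for compositional normalization), then a KO
  within the genome proportional to copies × gene length, or the
  padding. Per-KO annotation recall and a misassignment probability
  emulate annotation error; padding reads stay unassigned. Defaults are
  500,000 reads of 101 bp; the test-suite and acceptance replicas run
  at 100,000 reads to keep runtimes in seconds, which is stated here as
  the package's chosen evaluation scale.
* The truth is explicit: `true_average_copy_number()` is the
  abundance-weighted copy number, and the per-sample true average
  genome size is the abundance-weighted genome length.

What the simulator does **not** emulate: base-level sequence and
sequencing error, alignment ambiguity (annotation error is a per-KO
coin flip, not homology-driven), 16S/OTU profiling error, and real
taxonomic covariance structure. Passing the end-to-end tests therefore
shows the estimator's arithmetic and its robustness to depth,
composition and genome-size confounding — not robustness to real-world
annotation pathologies.

On this synthetic world the headline behaviors reproduce at reduced
scale: per-sample regressions of corrected abundance on true copy
number have slopes tightly around 1, the invariant pathway's
coefficient of variation is an order of magnitude smaller under marker
normalization than under compositional normalization, and the
closed-form genome size estimate correlates near-perfectly with the
true abundance-weighted size. The exact numbers are computed by
`scripts/acceptance.R` and by `tests/testthat/test-acceptance.R`, not
quoted here.

## Sample-property estimation and evaluation machinery

`average_genome_size()`, `species_richness()` and `mappability()`
compute the three confounders from PICRUSt-style OTU bundles (OTU
relative abundances, predicted per-OTU KO copies, per-OTU NSTI). All
weighted averages are convex combinations over present OTUs; OTUs with
zero abundance never contribute and their NSTI may be missing.
`partial_correlation()` (residual-on-residual Pearson, t-test with
$n - 2 - k$ degrees of freedom, two-sided) and `residual_correlation()`
(bisquare IRLS with the conventional 95%-efficiency constant 4.685)
support the confounder dissection.

The comparative layer mirrors standard practice: pathway abundance as
member-KO sums, two-sided Wilcoxon rank-sum tests (exact for groups of
at most 8 without ties, normal approximation with midrank-tie and
continuity corrections otherwise), Bonferroni or Benjamini–Hochberg
adjustment, the higher-median-in-disease filter for pathway calls, CoV
subsampling bootstraps (n−1 standard deviation), OTU-specific-gene
concordance (Pearson against the source OTU with a 5-sample presence
minimum; fold-change discrepancies as symmetric log-ratios over
consecutive samples in the OTU's abundance ordering, which avoids
transitive double-counting), genomic-vs-metagenomic correlation
structure (Jaccard against abundance correlation, self-comparisons
excluded), and cross-study recovery with the alternative's hit list
truncated to the reference's size (ties at the cut broken by feature
id, logged).

## Numerical and degenerate-input choices

* Even-count medians are the mean of the two central values; after
  marker normalization the marker median equals 1 to within one ulp
  (bit-exact for odd marker counts).
* Zero abundances stay exactly zero through every normalization — no
  pseudocounts.
* Readers reject malformed input (duplicate identifiers, negative or
  non-numeric cells) naming the offending row and column; an explicit
  opt-in reads empty cells as zeros with a counted warning.
* Zero-variance responses yield a null model (all weights 0, held-out
  $R^2$ reported as 0) with a warning; zero-variance residuals in the
  correlation utilities report r = 0 with a warning rather than NaN.
* Identifiers are opaque strings; nothing validates KEGG format beyond
  non-emptiness.
* All randomness flows from explicit integer seeds; the same seed
  reproduces byte-identical simulator output.

## Known limitations

The intra-sample model corrects bias only as far as gene properties
predict it, and transfer beyond the marker property range relies on the
clamp rather than on extrapolation guarantees. The packaged marker
lists are placeholders for curated sets. The simulator's annotation
model is deliberately simple; findings reported on real cohort data
(human gut and other body-site metagenomes) are outside what a
desk-scale synthetic evaluation can reproduce and are not asserted by
this package's tests.
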