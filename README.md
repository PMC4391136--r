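# musiccr

Marker-gene based normalization of metagenomic functional profiles.

## What problem this solves

Functional metagenomics reduces a shotgun sample to a table of read
counts per gene family (KEGG Orthology groups, "KOs"). The near-universal
next step — dividing each gene by the sample total to get *relative
abundances* — produces a unitless quantity that is confounded by the
average genome size, species richness and reference mappability of the
community: genes that are present once in every genome of every sample
(universal single-copy genes, USiCGs) still appear to vary severalfold
across samples. Any downstream comparison (differential genes,
disease-associated pathways, cross-study pooling) inherits that spurious
variation.

`musiccr` instead estimates the **average genomic copy number** of each
gene: the length-normalized abundance of every gene in a sample is
divided by the *median abundance of the USiCGs* in that sample
(inter-sample correction),

    c[g,s] = a[g,s] / median over markers m of a[m,s],

so the marker median is 1 in every sample by construction and the result
reads as the gene content of a "typical microbe". A second, optional step
(intra-sample correction) learns an elastic-net model of marker
fold-changes on gene-specific properties (GC content, length
variability, annotation recall, ...) and divides every gene by its
predicted bias. The package also ships the machinery used to validate
such a normalization: marker selection from genome content matrices,
sample-property estimators (average genome size, richness, mappability)
from PICRUSt-style OTU bundles, genome-size-based alternative
normalizations, a ground-truth mock-community read simulator, and a
comparative-analysis layer (rank-sum differential tests, CoV bootstraps,
OTU-specific-gene concordance, correlation-structure comparison,
cross-study recovery).

Audience: microbiome researchers processing KO-by-sample tables, and
method developers who need a ground-truth simulator for normalization
benchmarks.

## Worked example

Simulate a 20-sample mock dataset with known truth, normalize it, and
check the estimator against the truth:

```r
library(musiccr)

markers <- musicc_markers("usicg")          # packaged 76-marker list
pathway <- sprintf("K7%04d", 1:35)          # invariant pathway KOs
pool <- build_genome_pool(n_genomes = 21, n_kos = 800,
                          markers = markers, pathway_kos = pathway,
                          seed = 11)
ds <- simulate_dataset(pool, n_samples = 20, n_reads = 1e5, seed = 42)

ln  <- length_normalize(ds$counts, pool$ko_length)
mus <- inter_musicc(ln, markers)
mus
#> abundance_table: 800 KOs x 20 samples [stage: inter_corrected]

slope_vs_truth(mus, ds$truth)
#> slope_summary: 20 samples, mean slope 1.0024, CoV 0.0125

pa_mus  <- pathway_abundance(mus, list(flagellar = pathway))["flagellar", ]
pa_comp <- pathway_abundance(compositional_normalize(ds$counts),
                             list(flagellar = pathway))["flagellar", ]
cov <- function(x) sd(x) / mean(x)
sprintf("invariant-pathway CoV: musicc %.3f vs compositional %.3f",
        cov(pa_mus), cov(pa_comp))
#> "invariant-pathway CoV: musicc 0.019 vs compositional 0.203"
```

Reading the numbers: every sample's regression of corrected abundance on
true average copy number has slope ≈ 1 (the estimator is calibrated, not
just consistent), and a pathway built to be identical in every genome —
whose measured variation is therefore pure artifact — varies by ~2%
after marker normalization versus ~20% under compositional
normalization.

The elastic-net bias model works the same way on synthetic properties
with known weights:

```r
syn <- synth_property_table(markers, true_weights = c(prop01 = 0.5),
                            noise_sd = 0.41, seed = 201)
fit <- fit_intra_model(syn$true_foldchange[markers$ko_ids],
                       syn$properties, folds = 5, seed = 1)
fit
#> intra_model [per_sample]: 3/35 nonzero property weights, held-out R^2 = 0.550
```

A command-line front end for shell pipelines lives at
`inst/cli/musiccr.R` (`normalize`, `select-markers`, `simulate`,
`evaluate` subcommands); run it with `Rscript` and no arguments for
usage.

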