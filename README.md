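# SEhierarchy

Dissecting the internal hierarchy of super-enhancers (SEs) from chromatin
interaction data.

## The problem

Super-enhancers — clusters of H3K27ac-marked enhancer peaks with unusually
high aggregate signal — are not internally homogeneous: in many SEs the
long-range chromatin contacts are funnelled through one or a few 5 kb bins,
suggesting a hierarchical organisation in which a *hub enhancer* organises
the rest of the cluster. `SEhierarchy` is for computational genomicists who
have enhancer peak calls and intra-chromosomal contact data (Hi-C counts or
pre-called ChIA-PET pairs) and want to (i) call SEs, (ii) quantify each
SE's structural hierarchy, (iii) identify hub enhancers, and (iv) run the
standard downstream statistics (variant fold-enrichment, CTCF context,
enhancer–promoter mapping).

## The method

1. **SE calling (ROSE-style).** Peaks are filtered against blacklist
   regions and promoter windows (TSS ± 2 kb), stitched when within
   12.5 kb, ranked by total constituent H3K27ac signal, and cut at the
   point of the rescaled rank-vs-signal curve where the tangent slope
   exceeds 1; regions above the cutoff are SEs.
2. **Significant interactions.** Raw contact matrices are balanced by
   iterative correction (ICE); each intra-chromosomal bin pair with
   10 kb ≤ *d* ≤ 2 Mb receives an upper-tail binomial p-value against a
   monotone, distance-dependent expected contact probability
   (equal-occupancy strata + isotonic pooling), with Benjamini–Hochberg
   control at FDR 0.01.
3. **H-score.** Each SE is divided into 5 kb bins on the Hi-C grid. With
   *f<sub>i</sub>* the number of significant interactions touching bin
   *i*, the bin z-scores are
   *z<sub>i</sub>* = (*f<sub>i</sub>* − mean *f*) / sd(*f*)
   (population SD) and the SE's **H-score = max<sub>i</sub>
   z<sub>i</sub>**. SEs with H-score > 1.5 are *hierarchical*;
   constituents overlapping a bin with *z* > 1.5 are *hub enhancers*,
   the remaining constituents non-hub. With *n* bins, H ≤ √(n−1).
4. **Annotation statistics.** Variant fold-enrichment
   (*m*/*n*)/(*M*/*N*) against a shuffled regular-enhancer background
   with two-sided Fisher exact tests; CTCF peaks classified by context
   (hub / non-hub / TAD boundary / excluded / other); PWM log-odds motif
   scanning; mean signal profiles around anchors; enhancer–promoter
   edges restricted to pairs connected by a significant interaction
   within one TAD.

A seeded synthetic-data generator (`simulateFixture()`) produces complete
desk-scale fixtures — peak landscapes with planted SE clusters, contacts
with power-law distance decay and planted hub loops, TADs, CTCF peaks and
hub-enriched variants — together with a ground-truth table, so the whole
chain is testable end to end. See the methods vignette
(`vignettes/se-hierarchy-methods.Rmd`) for models, defaults and design
decisions.

## Worked example

Generate the packaged demo fixture (2 chromosomes × 2 Mb, 12 planted SEs,
60 regular enhancers) and run the full pipeline:

```r
library(SEhierarchy)
fixtureDir <- tempfile("sehier_demo")
sim <- goldenFixture(fixtureDir)      # seeded, fully reproducible

outDir <- tempfile("sehier_out")
res <- runPipeline(list(
    peaks      = file.path(fixtureDir, "peaks.narrowPeak"),
    contacts   = file.path(fixtureDir, "contacts.tsv"),
    chromSizes = file.path(fixtureDir, "chrom.sizes"),
    tss        = file.path(fixtureDir, "tss.bed"),
    variants   = file.path(fixtureDir, "variants.bed"),
    tads       = file.path(fixtureDir, "tads.bed"),
    ctcf       = file.path(fixtureDir, "ctcf.bed")), outDir)

res$se
#> SuperEnhancerSet with 72 stitched region(s)
#>   super-enhancers: 12; regular: 60
#>   constituents: 131 peak(s)
res$calls
#> HierarchyCallSet: 12 SE(s), threshold 1.5
#>   hierarchical: 5; non-hierarchical: 7
#>   hub enhancers: 5; non-hub: 26
res$enrichment$hub
#> EnrichmentResult [hub]: m/n = 2/5 vs M/N = 59/600; score 4.068; Fisher p 0.0819
head(read.delim(file.path(outDir, "hierarchy_calls.tsv")), 4)
#>   X..se_id chrom  start    end n_bins h_score            class
#> 1     SE_1  chr1 385200 424800      8 0.00000 non-hierarchical
#> 2     SE_2  chr1 540200 579800      8 0.00000 non-hierarchical
#> 3     SE_3  chr1 655200 694800      8 0.00000 non-hierarchical
#> 4     SE_4  chr1 955200 994800      8 2.64575 hierarchical
```

Reading the output: all 72 stitched regions are ranked, and the geometric
cutoff recovers exactly the 12 planted high-signal clusters as SEs. Five
of them carry a planted hub bin; each shows an H-score of 2.646 = √7,
exactly what a single dominant bin among eight zero-background bins
produces (the extremal bound √(n−1)), and is called hierarchical, while
the flat SEs score 0. The hub enhancers
(constituents overlapping the dominant bin) are 4.1-fold enriched for the
variants the generator concentrated at hub bins, against a 10× shuffled
regular-enhancer background.

Per-file outputs in `outDir`: `superenhancers.bed`, `constituents.bed`,
`significant.bedpe`, `bin_frequency.bedgraph`, `hierarchy_calls.tsv`,
`se_bins.tsv`, `hub_enhancers.bed`, `nonhub_enhancers.bed`,
`enrichment.tsv`, `ctcf_context.bed` and a `manifest.json` recording
inputs, parameters and result counts.

The same pipeline is available from a shell:

```sh
Rscript exec/sehier simulate --seed 1 --out fixture/
Rscript exec/sehier run-all --peaks fixture/peaks.narrowPeak \
    --contacts fixture/contacts.tsv --chrom-sizes fixture/chrom.sizes \
    --out results/
```

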