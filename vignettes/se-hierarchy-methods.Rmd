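---
title: "Dissecting super-enhancer hierarchy: models and methods"
author: "SEhierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting super-enhancer hierarchy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SEhierarchy)
```

# The question the package answers

Super-enhancers (SEs) are clusters of enhancer peaks carrying unusually high
H3K27ac signal. Not all constituents of an SE are equal: chromatin-contact
data show that in a subset of SEs most long-range interactions are funnelled
through one or a few 5 kb bins. `SEhierarchy` quantifies this internal
hierarchy. The workflow is:

1. **SE calling.** H3K27ac peaks are filtered against blacklist regions and
   promoter windows (TSS ± 2 kb), stitched when closer than 12.5 kb,
   ranked by total constituent signal, and split into SEs and regular
   enhancers (REs) by the geometric cutoff of the rank-vs-signal curve.
2. **Interaction calling.** Raw intra-chromosomal contact matrices are
   balanced by iterative correction (ICE); each bin pair at distance 10 kb
   to 2 Mb gets an upper-tail binomial p-value against a distance-dependent
   expected probability, with Benjamini–Hochberg control at FDR 0.01. The
   per-bin interaction frequency is the number of significant interactions
   whose anchor falls in the bin. Pre-called interaction pairs (e.g.
   ChIA-PET PET clusters) can replace this step via `pairsFrequency()`.
3. **H-score.** Within each SE the 5 kb-bin frequencies are standardized to
   z-scores; the maximum z is the H-score. SEs with H-score > 1.5 are
   *hierarchical*; constituents overlapping a bin with z > 1.5 are *hub
   enhancers*, the rest non-hub.
4. **Annotation statistics.** Variant fold-enrichment `(m/n)/(M/N)` with
   Fisher tests against a shuffled-RE background, CTCF context classes,
   PWM motif scanning, signal profiles around anchors, and TAD-constrained
   enhancer-promoter maps.

# Statistical model and numerical choices

## H-score

For an SE with bin frequencies $f_1,\dots,f_n$ the package uses the
*population* standard deviation ($\sigma = \sqrt{\tfrac1n\sum(f_i-\bar f)^2}$),
so $z_i = (f_i - \bar f)/\sigma$ and $H = \max_i z_i$. With this convention
$H \le \sqrt{n-1}$, the bound being attained exactly by one-outlier vectors
(e.g. `c(2, 2, 2, 14)` gives $H = \sqrt 3$). A practical corollary: an SE
spanning at most three 5 kb bins can never exceed the default threshold of
1.5, so short SEs are structurally non-hierarchical. Degenerate inputs
(constant frequencies, a single bin, all zeros) are defined to have $H = 0$.
Sample-SD standardization is available (`populationSD = FALSE`) but not the
default, because the extremal bound and the zero convention are cleanest in
the population form. All comparisons are strict (`>` threshold). The bins
are anchored to the genome grid (bin $k$ covers
$[k \cdot 5000, (k+1) \cdot 5000)$), not to the SE start, because the
contact matrix defines the grid; an SE that only partially covers a bin
still owns that bin's full frequency.

The 1.5 default corresponds roughly to the upper tail of the within-SE
z-score distribution; 1.25 and 1.75 are supported as sensitivity sweeps.
The package reports the empirical percentile of the chosen threshold over
all SE bins but does not calibrate the threshold from it.

## SE calling

Stitching merges two enhancers when the genomic gap between them is at most
12,500 bp (transitively); signal is the plain sum of constituent peak
scores, with no length normalization or input subtraction, so the caller is
reproducible from a peak file alone. The cutoff rescales the
ascending-sorted signal curve to the unit square and scans discrete first
differences for the first slope above 1; regions with signal strictly above
the signal at that point are SEs. On a perfectly linear or constant curve
the slope never exceeds 1 and no region is called super — the conservative
reading of a degenerate landscape. Because the flag depends only on signal,
the called set is always a prefix of the descending ranking. Filtering
(blacklist, promoters) happens before stitching.

## Contact significance

The caller is a deliberately simplified distance-corrected test, not a
reimplementation of the published spline-based two-pass refinement: pairs
at tested distances are grouped into (default 100) equal-occupancy distance
strata — consecutive distances are pooled only until the occupancy target
is met, so at desk scale most strata are a single distance and the step
function introduces no within-stratum decay bias; stratum probabilities are
made monotone non-increasing by weighted pool-adjacent-violators; the
p-value is the upper-tail binomial probability of the (rounded) balanced
count in $N$ trials, $N$ the rounded total balanced count in the tested
range. This preserves the contract that matters downstream —
distance-corrected, FDR-controlled calls — and can be bypassed entirely by
supplying pre-called pairs.

Two bins of one pair may coincide at coarse resolutions; a within-bin pair
then increments its bin twice (both interaction ends are "associated with
the bin"); `countSameBinTwice = FALSE` switches to once.

## Iterative correction and the edge-bin QC filter

`iceNormalize()` repeatedly divides entry $(i,j)$ by $b_i b_j$, with $b$
the row-sum vector rescaled to mean 1 over unmasked (non-empty) rows, until
the coefficient of variation of unmasked row sums falls below `tol` (1e-8
by default, capped at 300 iterations). The accumulated bias vector
satisfies `raw == norm * bias_i * bias_j` exactly, which the tests assert
to 1e-8 relative.

Balancing assumes every bin should have equal total contact weight. Bins
near a chromosome end violate this structurally: they are missing partners
on one side, so ICE scales them up, inflating their normalized counts
relative to the distance-expected model and creating spurious significant
pairs. On real genomes these bins are a vanishing fraction and usually
masked as low-mappability; at desk scale they are visible. The caller
therefore applies a standard low-coverage QC filter at the pair level: the
relative balancing-weight product of each pair (`bias` column) must be at
least `minPairBias` (default 0.9, i.e. tolerated inflation ≤ about 11%,
within counting noise at typical counts) for the pair to be tested. The
filter removes pairs from testing only; they still participate in
balancing.

# The synthetic-data generator

`simulateFixture()` produces the desk-scale study condition with full
ground truth: SE clusters of 4–8 non-overlapping peaks inside an 8-bin
(40 kb) grid-aligned span with log-normal scores centred well above the
isolated regular enhancers (so the geometric cutoff has a planted answer);
a TSS beyond promoter-filter range of each SE; TADs partitioning each
chromosome; CTCF peaks at TAD boundaries and hub bins; contact counts
drawn per pair as Poisson with mean
$\mu(d) = \texttt{backgroundContactMean} \cdot (50\,\mathrm{kb}/d)^{\alpha}$
($\alpha = 1$ by default); and variants sampled with hub bins oversampled
by `hubVariantFold`.

Hub structure is planted as *loops*: each hierarchical SE's hub bin is
connected to `nHubPartners` (default 12) partner bins at 20–200 kb whose
pair means are multiplied by `hubFold`. Two design points deserve emphasis:

* **Loops, not row multipliers.** Multiplying *all* contacts of the hub bin
  by a constant is exactly a multiplicative bias $DMD$, which iterative
  correction removes by construction — such a planted signal cannot survive
  the package's own normalize→test→count pipeline, and it is also not what
  a hub enhancer looks like in real data, where the excess contacts are
  concentrated on specific partner anchors. A modest loop set keeps the hub
  row's total mass close to background (the partner count is chosen so the
  residual ICE suppression of loop counts stays below ~25%), which is what
  lets the signal pass balancing, as in real Hi-C.
* **Partners avoid SE spans and chromosome edges.** Partner bins are drawn
  outside every SE span so planted loops of one SE cannot masquerade as hub
  bins of another, and planted elements keep a 250 kb margin from
  chromosome ends (`edgeMargin`), where balancing is unreliable (see the
  QC filter above) and where real enhancer clusters do not live.

What the generator does *not* emulate: GC/mappability bias, fragment-level
artifacts, translocations, copy-number effects, TAD-dependent contact
enrichment, and replicate structure. Passing the recovery tests therefore
demonstrates that the statistical chain is correctly wired and calibrated
under the stated model, not that it is robust to every artifact of real
Hi-C libraries.

Default problem sizes (2–4 Mb chromosomes, tens of SEs, 5 kb bins,
~10⁵–10⁶ tested pairs) were chosen so that a full pipeline run completes in
well under a minute while keeping ≥ 50 SEs and ≥ 5×10⁴ tested pairs in the
calibration checks — large enough for the binomial and FDR asymptotics to
be meaningful.

# Annotation statistics: conventions

* **Enrichment counting.** `m` counts group loci overlapping ≥ 1 variant
  (the convention matching per-enhancer bar labels); a per-variant mode is
  available (`countMode = "variants"`). The background is a size-matched
  shuffle of the regular enhancers (default ×10 size multiplier in the
  pipeline), placed uniformly per chromosome with probability proportional
  to eligible positions; whether the shuffle should avoid blacklist regions
  is left to the caller via `excluded` (default: no exclusion). The Fisher
  test is two-sided.
* **CTCF context.** Peaks overlapping both a hub enhancer and a TAD
  boundary are `excluded` from the hub/boundary comparison, then hub,
  TAD-boundary, non-hub and other classes are assigned in that priority
  order, producing a partition. Cell-type consensus uses any-overlap
  ("the same peak" is read as any overlapping peak). When only TAD spans
  are available, boundaries are ±(resolution/2) windows around TAD edges.
* **Motif scanning.** Log-odds base 2 against a background composition,
  pseudocount 1e-3 per PWM cell before column normalization, both strands,
  ambiguous bases scored at background odds (contribution 0).
* **ChIA-PET mode.** Pre-called PET clusters reuse the Hi-C definitions
  unchanged: every anchor increments every bin it overlaps. This is an
  interpretation — the original analysis mentions an undescribed
  modification for ChIA-PET — and is documented as such.
* **eQTL unit.** Whether the locus or the SNP is the counting unit is
  genuinely ambiguous; both modes exist and the locus mode is the default.

# Known limitations

* The significance caller is a simplified distance-corrected binomial, not
  the published spline-refined two-pass; with strong real-data biases the
  equal-occupancy step model will be coarser than a spline fit.
* SE signal is the sum of peak scores; without alignment files there is no
  input subtraction or per-bp signal, so rankings can differ from
  pipelines that recompute signal from BAMs.
* Headline counts from the original study (hundreds of SEs per cell line,
  specific fold-enrichments) depend on external ENCODE/Hi-C/GWAS resources
  and are out of scope; the package's claims are the property-based
  guarantees exercised in its test suite.
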