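---
title: "Designing SNP arrays and building sex-specific linkage maps from full-sib families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing SNP arrays and building sex-specific linkage maps from full-sib families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibmap)
```

## Scope and model

`sibmap` implements the computational core of a high-density SNP-array and
linkage-mapping workflow for an outbred aquaculture species with a
fragmented draft genome — the setting of channel and blue catfish genomics,
where hundreds of thousands of markers are selected from resequencing data,
genotyped on full-sib families, assembled into a sex-specific genetic map,
and used to anchor and error-check the assembly. Everything runs on
synthetic data with known ground truth, so every stage is testable without
any external download.

The genetic model throughout is classical two-point linkage in full-sib
families. For two markers, a meiosis of a parent is *informative* when the
parent is heterozygous and the transmitted allele can be resolved from the
offspring and other-parent genotypes. With `R` recombinant and `N` total
informative meioses the recombination fraction is `r = R/N` (capped at
0.5), and the LOD score is the base-10 likelihood ratio of linkage at the
estimate against independence; a fully linked pair over 100 meioses gives
`100*log10(2) = 30.103`. Distances come from the Kosambi mapping function
`d = 25 ln((1+2r)/(1-2r))` cM, whose inverse is `r = tanh(d/50)/2`.

## The synthetic-data generator

`simulate_genome()` draws a lognormal scaffold-size distribution and places
non-overlapping genic intervals plus independent repeat intervals; realised
genic and repeat base fractions land within about two percentage points of
the request at megabase scale. `simulate_variant_pool()` lays down Poisson
SNPs with per-population alternative-allele frequencies drawn from a
category model (channel-specific, blue-specific, interspecific fixed
differences, shared polymorphism, with strain- and wild-specific subsets),
emitting only variants that clear a discovery minor-allele-frequency floor
of 0.05 in some population or across the pooled panel — the threshold
upstream variant calling would have applied. Configurable fractions of
sites are tri-allelic or carry a neighbour within 35 bp, so the filter
cascade always has work to do. `simulate_pconvert()` draws per-probe
conversion scores from Beta(83.4, 36.6); that calibration makes the
retained probe set (best probe per SNP, threshold 0.6) average about 0.71
with roughly 97% of scores above 0.65.

`simulate_families()` is the heart of the generator. Parent haplotypes
carry alleles at frequency 0.5; gametes follow an interference-free
count-location crossover process whose adjacent-marker recombination
fractions are the *inverse Kosambi* transform of the true cM gaps. That
choice makes downstream Kosambi re-estimation exact in expectation, which
is what turns the generator into a parameter-recovery oracle. Sex
dimorphism is a per-chromosome multiplicative expansion of the female map,
default 1.4 — the genome-wide female:male ratio reported for catfish — with
per-chromosome overrides available to mimic the observed 0.96–2.06 spread.
Genotyping error replaces a call with one of the other two genotypes
(default 1%), and missingness blanks calls (default 2%). Ground truth
(parental haplotypes and gamete origins) is retained for tests. The
default pedigree is four full-sib families of 120/119/120/119 offspring
with one sire shared between two families; total family sizes are not
dictated by the genome-wide totals alone, so the 478-offspring split is a
configurable choice.

## Array design

The filter cascade evaluates every criterion for every candidate and
reports all applicable reason codes: multi-locus 71-mer flanks (exact
occurrence counting on both strands via a k-mer dictionary, not
alignment), neighbours within 35 bp, homopolymer or dinucleotide runs of
8 bp or more, non-biallelic sites, and flank GC outside 30–70%. Two
criteria are deliberately *soft*, mirroring their preferential wording:
minor allele frequency at or below 0.1 and A/T or C/G allele pairs
deprioritise a candidate (tier 2) instead of excluding it. Greedy spacing
selection then scans each scaffold left to right — genic SNPs first with a
200 bp gap, intergenic SNPs with 350 bp, then remaining strain- and
wild-specific SNPs — admitting tier-2 candidates only where tier 1 leaves
a hole wider than twice the stage gap; SNPs from unmapped sources are
exempt from spacing. Ties at one position prefer higher MAF, then marker
id, making the whole selection deterministic and order-independent.
Spacing gaps apply within a stage only; whether they should reach across
stages is left open by the protocol we mirror, and the within-stage rule
is the simpler of the two readings.

Probe thresholding keeps the better of the two probes when at least one
clears the conversion-score threshold (default tau = 0.6 — the upstream
pipeline never states its cut, only the score distribution of what
survived, so tau is a calibrated knob) and tiles both probes for a
configurable "cover anyway" set standing in for the less-unique flank
regions a vendor would still tile. QC probes are 71-mers from
non-polymorphic regions, half with A/T and half with G/C at base 31.
`build_manifest()` enforces the composition arithmetic (SNP total = genic
+ intergenic; probe total = single + 2 × dual; categories partition the
total).

## Genotype QC and pedigree verification

Sample QC applies strict dish-QC and call-rate cuts (evaluation uses
0.85/0.95, mapping 0.82/0.97; both are plain parameters). The SNP
conversion classifier is cluster-free: call rate below threshold, then
three genotype classes → PolyHighResolution, het plus one homozygote →
NoMinorHom, one class → MonoHighResolution; off-target-variant and Other
classes need signal intensities we do not model, so they are assigned only
from simulation flags.

Pedigree verification computes pairwise identity-by-state distances
(`1 - mean shared alleles / 2` over pairwise-complete markers, with a
minimum-overlap guard), complete-linkage clustering (`hclust`), classical
multidimensional scaling (`cmdscale`), and a nearest-neighbour Z score for
outliers: samples whose nearest-neighbour distance is more than 4 standard
deviations above the mean are flagged. The Z construction is ours — the
referenced diagnostics do not define one — and the threshold is exposed.
Complete linkage needs a few hundred markers before the three-cluster
structure (two sire-sharing families merging) becomes reliable; the tests
use about 600.

## The mapping engine

Marker filtering drops markers with more than 12 missing offspring calls
or a minor-allele count under 6 per family, requires at least two
informative families, and eliminates segregation distortion at Pearson
p < 0.005 (1:1 for backcross-type markers, 1:2:1 for intercross; a marker
fails if its worst informative family fails). All pairwise two-point
estimates are computed by matrix algebra over per-parent transmission
matrices; linkage phase is a per-parent nuisance folded out by taking the
smaller of the two phase readings. Double-heterozygous marker/offspring
combinations whose transmissions cannot be resolved are excluded rather
than EM-weighted; for two markers the exhaustive phase treatment and the
resolvable-meiosis count give the same maximum-likelihood estimate, and
counting keeps the closed forms exact.

Linkage groups are connected components of the LOD graph at limit 35 with
a minimum size of 10; singletons join a group when their best LOD reaches
10 and beats the second-best group by 3.

Ordering is where we deliberately replace the reference tool's hidden
Markov machinery with a desk-scale, verifiable optimizer. Each group is
ordered by multi-start seriation: a spectral start (Fiedler vector of the
LOD-weighted graph Laplacian — LOD decays monotonically with distance, so
the similarity matrix has Robinson structure), plus greedy chains grown
from high-LOD seed pairs and polished by 2-opt. Every start is refined by
an iterative one-dimensional weighted-least-squares placement that
positions each marker from its *mid-range* neighbours (recombination
0.05–0.4): closer pairs sit below the genotyping-error floor and carry no
left/right information, farther pairs are saturated. The winning order is
the medoid of the refined candidates by mean Kendall agreement — most
starts converge to the same basin, and consensus proved far more reliable
than any single objective value. Two rounds are run: round one on
exact-duplicate representatives, then markers inseparable at the
apparent-recombination floor (`stack_r = 0.05`) are stacked onto their
most informative member, and round two re-orders the stack
representatives. Duplicates and stacked markers are reinserted at their
representative's position afterwards, which is also why removing the
collapse step can only inflate the map on error-bearing data.

Positions are *not* accumulated from adjacent-pair counts, which are
noise-dominated at sub-cM spacing and inflate badly under local order
uncertainty. Instead, sex-average positions solve a multipoint weighted
least squares over all pairs within a fitted-distance window:
`d_ij ~ (x_j - x_i) + c`, where the common offset `c` absorbs the constant
apparent-distance inflation a fixed genotyping-error rate adds to every
pairwise estimate. Pairwise distances enter through the Haldane transform
`-50 log(1 - 2r)` because the simulated crossover process composes without
interference across intervals; on the small adjacent gaps where positions
are finally read off, Haldane and Kosambi agree to third order in `r`.
Weights and the pair window are re-derived from fitted distances over a
few iterations — weighting or selecting on the observed estimates
themselves correlates with their own noise and demonstrably shrinks the
map. Positions are gauge-fixed by a tiny ridge, oriented along the order,
and made monotone by isotonic regression.

Sex-specific lengths need one more safeguard. Resolving a double-het
marker conditions on the two parents' transmissions agreeing, which pulls
female and male recombination estimates toward each other; sex-specific
counting therefore uses only meioses whose *other* parent is homozygous at
the marker. Those clean markers are sparse per parent, so each parent
contributes span-level recombination fractions between its consecutive
clean markers, and the sex map length is the weighted regression slope of
those span distances on the pooled-map template gaps (intercept again
absorbing the error inflation), scaled to the template span. This assumes
sex dimorphism acts approximately as a length scale along the group — true
by construction in the generator, an approximation for real data. The
sex-dimorphism G test (`G = 2 * sum O log(O/E)`, df 1) is built from a
per-meiosis 2×2 table: a meiosis is recombinant when its error-filtered
clean chain shows at least one transition. Whether the original analysis
built its contingency tables this way is not stated anywhere we could
check; ours is documented, not asserted as theirs.

## Genome integration

Scaffolds are anchored by majority vote of their mapped markers and
oriented by the sign of the Spearman correlation between physical and
genetic position over unique positions (|rho| at or above 0.5, otherwise
unknown). Misassembly detection segments the bp-sorted unique positions
into maximal monotone runs: an opposite-direction run of at least 3
markers is an inverted segment; a contiguous block mapping to another
linkage group, or a same-direction interior run displaced by more than
10 cM from both flanks (and not adjacent to an inversion signal), is a
translocated segment. Stacked positions are dropped before segmentation —
they cannot order anything within a scaffold but still vote for its
chromosome. The thresholds (3 markers, 10 cM) have no published
quantitative counterpart; they are validated purely by plant-and-recover
(recall 1.0, false-call rate 0.0 over 100 replicates at the default
noise). Chromosome-level AGP 2.1 is emitted with scaffolds in genetic
order, fixed gaps, and accepted inversions split and flipped.

## Reporting layer

Transcriptions of the published array and map summary tables ship as
plain TSV fixtures. The recompute functions re-derive every derivable
cell — probe totals, polymorphic/converted sums, per-group marker
intervals (half-up rounding to the printed precision), sex-map length
differences and female:male ratios — and flag printed inconsistencies
instead of reconciling them. One such inconsistency is real: in the
hybrid panel the two polymorphic classes sum to 504,165 while the printed
total is 504,265; the report carries both numbers. Note also that the
printed strain-specific total (48,434) equals the four domestic strains
*plus* the wild population rows.

## Problem sizes, tolerances, known limitations

The simulation studies used by the test-suite run at desk scale, chosen so
each check finishes in seconds while keeping enough meioses for the
estimators to concentrate: genome fixtures of 0.2–1 Mb; candidate pools of
a few thousand SNPs; mapping studies of 3 chromosomes × 200 markers (or
5 × 120 for the sex-dimorphism study) with the full 478-offspring
pedigree; 100 plant-and-recover replicates for misassembly calls. At
those sizes the engine recovers linkage-group membership at purity 1.0,
marker order at Kendall tau ≈ 0.95 or better, sex-average lengths within
about ±10%, and a genome-wide female:male ratio within a few percent of
the simulated 1.4 — with per-group estimates noticeably noisier (single-LG
crossover sampling alone contributes ~4–8% CV). What passing these tests
shows is that the algorithms recover the generator's truth under its
assumptions: no interference, uniform sex scaling, exchangeable offspring,
error and missingness independent of genotype. Real array data violate
all of these mildly (intensity-driven error clusters, segregation
distortion hotspots, localized recombination suppression), so field
accuracy will be worse than these figures, and the stacked fraction of
markers will be far larger at real densities.

Numerical conventions: coordinates are 1-based inclusive internally, with
BED's 0-based half-open convention applied only at I/O; all randomness
flows from one integer seed per call through a local RNG that never
touches global state; ordering ties break by marker id; degenerate inputs
(zero-length scaffolds, empty call vectors, pairs without informative
meioses) raise errors or produce explicit NA results rather than silent
values.
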