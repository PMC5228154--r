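# sibmap

SNP array design and sex-specific genetic linkage mapping from outbred
full-sib families, with scaffold anchoring and misassembly detection for
draft genome assemblies.

## The problem

High-density SNP arrays for aquaculture species such as channel catfish
(*Ictalurus punctatus*) and blue catfish (*I. furcatus*) are built by
filtering millions of resequencing-derived variants down to a few hundred
thousand well-spaced, well-behaved probes; the array is then used to
genotype full-sib reference families, build a genetic linkage map with
sex-specific recombination distances, and anchor, orient and error-check
the scaffolds of a fragmented reference assembly. `sibmap` implements that
entire computational chain natively in R, together with a synthetic-data
generator that produces every input with known ground truth, so each stage
can be validated by parameter recovery instead of external data.

The statistical core is two-point linkage in full-sib families. For a
marker pair, a parent's meiosis is informative when the parent is
heterozygous and the transmitted allele is resolvable; with `R`
recombinants among `N` informative meioses, `r̂ = R/N` (phase folded per
parent), and the LOD score is
`LOD = R log10(r̂) + (N−R) log10(1−r̂) + N log10 2`.
Genetic distances use the Kosambi mapping function
`d = 25 ln((1+2r)/(1−2r))` cM. Linkage groups are connected components of
the LOD graph (limit 35, minimum size 10); marker order comes from
spectral seriation plus a mid-range weighted-least-squares refinement with
medoid consensus across starts; map positions solve a multipoint least
squares whose intercept absorbs the apparent-distance inflation caused by
genotyping error; sex dimorphism is tested per linkage group with a
likelihood-ratio G test on recombinant vs non-recombinant meioses.

## Worked example

Simulate four full-sib families (478 offspring, one shared sire) on a
three-chromosome genome with 1% genotyping error and 2% missing calls,
then fit the map:

```r
library(sibmap)

cfg <- true_map_config(n_chromosomes = 3, chrom_lengths_cM = c(100, 80, 120),
                       markers_per_chrom = 200, genotyping_error_rate = 0.01,
                       missing_rate = 0.02, seed = 11)
sim <- simulate_families(cfg, default_pedigree_spec(), seed = 12)
map <- build_linkage_map(sim$genotypes, sim$pedigree, seed = 17)
map
#> Genetic linkage map: 3 linkage groups, 555 markers (128 unique positions)
#>   sex-average length 354.1 cM; female 412.9 cM; male 324.3 cM (F:M 1.27)
summary(map)
#> Per-linkage-group map summary
#>  lg n_markers n_unique length_avg length_female length_male interval_avg
#>   1       188       38      105.7         124.9      116.05        2.782
#>   2       183       43      101.4         115.6       84.31        2.358
#>   3       184       47      147.0         172.4      123.98        3.128
#>  fm_ratio       g_p
#>     1.077 1.208e-19
#>     1.371 3.179e-10
#>     1.390 1.036e-01
```

The three simulated chromosomes (sex-average truths 119, 95 and 141 cM)
come back as three linkage groups with pure membership; estimated
sex-average lengths sit within about 10% of truth, markers that the data
cannot separate stack at shared positions (the `n_unique` column), and the
female maps run longer than the male maps, as simulated. `plot(map)` draws
the marker positions per linkage group.

Upstream of mapping, `simulate_genome()`, `simulate_variant_pool()` and
`simulate_pconvert()` generate a draft genome, a candidate SNP pool and
probe conversion scores; `design_array()` runs the filter cascade, greedy
spacing selection, probe thresholding and QC-probe pick, returning an
array manifest whose composition arithmetic is checked on construction.
`pedigree_check()` verifies family structure from genotypes alone
(identity-by-state distances, complete-linkage clustering, classical MDS,
nearest-neighbour Z outliers), and `anchor_scaffolds()` /
`detect_misassembly()` / `emit_agp()` place scaffolds on the map, flag
inverted or translocated segments, and write a chromosome-level AGP.
Packaged summary-table fixtures are recomputed by `recompute_table3()`,
`recompute_table4()` and `recompute_tables56()`.

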