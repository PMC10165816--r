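# endovirome

Viral catalog construction and spatial ecology for rock-dwelling
(endolithic) microbiome surveys.

Metagenomic surveys of extreme environments — here, microbial communities
living inside Antarctic rocks — recover thousands of predicted viral
contigs whose diversity, hosts and biogeography are unknown. `endovirome`
implements the analysis that turns those contigs plus read-mapping
coverage into a filtered viral catalog and its ecology, for
microbial-ecology researchers who have run the upstream prediction tools
and want a tested, reproducible downstream pipeline:

* **vOTU clustering** — greedy dereplication of contigs into viral
  operational taxonomic units at ≥95% nucleotide identity over ≥85% of the
  shorter sequence (CD-HIT `-c 0.95 -aS 0.85` semantics), with exact
  Smith–Waterman alignments and a deterministic k-mer prescreen.
* **Detection and abundance** — a vOTU is detected in a sample when ≥75%
  of its length is covered ≥1×; abundance is the trimmed mean of per-base
  depth (tpmean). Catalog filtering removes vOTUs under 10 kbp, of
  undetermined quality, or detected nowhere.
* **Host prediction** — BLAST hits filtered at ≥2000 bp, ≥70% identity,
  bitscore ≥50, e ≤ 0.001 (MAG hits must also cover <50% of the subject);
  per-rank consensus over the top 5 hits; RefSeq and MAG predictions
  merged with MAG priority on disagreement.
* **Viral clusters** — a gene-sharing network with hypergeometric edge
  significance, `w = -log10 P(X >= a)`, Markov clustering into genus-rank
  VCs, the singleton/overlap/outlier status vocabulary, and VC-membership
  taxonomy (`Unique VC` = no reference genomes, a putatively novel genus).
* **Ecology** — Hellinger distances (`h_ij = sqrt(x_ij / x_i·)`,
  Euclidean on the transform), PCoA, PERMANOVA
  (`Distance ~ Site + Rock type`, sequential and marginal modes, 9,999
  permutations), multivariate dispersion tests, haversine geographic
  distances, and Spearman Mantel tests of distance decay with and without
  zero-distance pairs — all implemented from first principles with
  permutation conventions stated explicitly.
* **Synthetic data** — generators that plant known cluster structure,
  occupancy, hosts and VCs, and spatially autocorrelated communities with
  a tunable exponential distance decay, so every stage is testable with
  ground truth and no downloads.

## Worked example

Simulate a small survey (5 ancestral phage genomes, descendants at 2% and
10% divergence, 4 sites × 3 metagenomes), cluster it, build the abundance
matrix and test for spatial structure:

```r
library(endovirome)

cfg <- simConfig(seed = 42, n_ancestors = 5,
                 genome_length_range = c(2000, 3000),
                 divergence_levels = c(0.02, 0.10),
                 descendants_per_level = 2,
                 n_sites = 4, samples_per_site = 3)
pop  <- generatePopulation(cfg)
cat_ <- clusterVOTUs(pop$sequences)
cat_
#> VOTUCatalog: 15 vOTUs from 25 sequences (identity >= 0.95, short coverage >= 0.85)

meta <- generateSampleMetadata(cfg)
reps <- pop$sequences[representatives(cat_)]
covr <- generateCoverage(cfg, reps, meta)
am   <- buildAbundanceMatrix(covr$coverage, reps, samples = meta$sample_id)
am
#> AbundanceMatrix: 12 samples x 15 vOTUs (tpmean, trim 0.10/tail, detection breadth >= 0.75)
#>   23.3% of cells detected

d <- hellingerDistance(am)
permanova(d, meta, terms = "site", n_perm = 999, seed = 1)
#> PERMANOVA (by = terms, 999 permutations)
#>          Df SumOfSqs     R2     F Pr..F.
#> site      3    7.990 0.8558 15.83  0.001
#> Residual  8    1.346 0.1442    NA     NA
#> Total    11    9.337 1.0000    NA     NA

mantelTest(as.matrix(d), geoDistanceMatrix(meta), n_perm = 999, seed = 1)
#> Mantel test: r = 0.4395, p = 0.005 (999 permutations, n = 12)
```

The 25 simulated contigs collapse into 15 vOTUs: each 2%-divergent
descendant rejoins its ancestor's cluster (identity ≈ 98% > 95%), while
each 10%-divergent descendant (identity ≈ 90%) founds its own — 5
ancestral clusters plus 10 singletons. Detection is sparse (23% of cells)
because presence probability decays with distance from each vOTU's home
site; that same planted decay is what the PERMANOVA site effect
(R² = 0.86, p = 0.001) and the positive Mantel correlation (r = 0.44,
p = 0.005) recover from the abundance matrix alone.

`simulateFixture()` writes a complete input directory (FASTA, quality
table, coverage BED, metadata CSV, hit tables with taxonomy sidecars,
protein-cluster profiles, AMG table, truth tables) and `runPipeline()`
executes all stages end to end, producing per-stage TSVs and a plain-text
report. A thin command-line front-end lives at
`inst/scripts/endovirome-cli.R` (`simulate`, `cluster`, `run`
subcommands).

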