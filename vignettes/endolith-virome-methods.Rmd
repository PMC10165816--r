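---
title: "Methods: from predicted viral contigs to a vOTU catalog and its spatial ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from predicted viral contigs to a vOTU catalog and its spatial ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endovirome)
```

# Overview

`endovirome` implements the analysis stages that turn predicted viral
contigs and read-mapping coverage into a quality-filtered catalog of viral
operational taxonomic units (vOTUs) and then into ecology: host
predictions, gene-sharing viral clusters (VCs), auxiliary-metabolic-gene
(AMG) summaries, and permutation-based spatial statistics. Everything
upstream of the contigs — assembly, viral prediction, quality estimation,
read mapping — is consumed as files, not recomputed. Everything downstream
is implemented here, and every stage can be validated against a
synthetic-data generator that plants known ground truth.

# vOTU clustering

Contigs are clustered greedily into species-rank vOTUs at the community
standard of 95% nucleotide identity. Sequences are sorted by length
descending (ties broken by id, so the partition never depends on input file
order) and each sequence joins the first representative it matches;
otherwise it founds a new cluster. A match requires two things of the best
local alignment:

* identity $\ge 0.95$, defined as matches divided by alignment columns
  (gap columns count);
* the alignment covering $\ge 0.85$ of the shorter sequence. Because
  candidates arrive longest-first, the candidate is always the shorter
  sequence, reproducing the usual short-sequence-coverage semantics of
  greedy dereplication tools under length sorting.

Local (not global) identity is assumed; representatives are therefore the
longest member of each cluster, and members can be partial matches of their
representative. Alignments are exact Smith–Waterman (via Biostrings) with
blastn-like scoring (match 2, mismatch −3, gap open 5, extend 2). A
deterministic 16-mer prescreen skips candidate/representative pairs that
cannot plausibly reach the thresholds: a pair at ≥95% identity over ≥85%
of the candidate retains intact probes with overwhelming probability, while
unrelated pairs essentially never do. The test suite verifies the engine
against a pure-R dynamic-programming oracle (within 0.5 percentage points
of identity) and the whole greedy procedure against a brute-force
all-pairs implementation.

Catalog filtering happens *after* clustering, matching the order of
operations in mapping-based virome studies: a vOTU survives if its
representative is at least 10 kbp, its quality tier is not
`not_determined`, and it is detected in at least one sample. Sequences
with more than 50% `N` are excluded before clustering.

# Detection and abundance

Detection follows the standard breadth criterion: a vOTU counts as present
in a sample when at least 75% of its length is covered by ≥1 mapped read
(the threshold is inclusive — exactly 75% passes, since the filtering rule
removes *less than* 75%). Abundance is the trimmed mean of per-base depth
("tpmean"): depths are sorted, `floor(trim_fraction * n)` positions are
removed from each tail, and the remainder averaged. The trim fraction is
not standardized across tools, so it is an explicit parameter
(default 0.10 per tail, recorded in the matrix metadata); conclusions
sensitive to it should be checked at other values. The upstream
read-mapping identity (90%) is a property of the mapping, not of this
package; it is carried as provenance metadata only. Cells failing
detection hold exactly zero, and vOTUs detected nowhere are dropped.

# Host prediction

The procedure is a faithful implementation of BLAST-consensus host calling
against two databases (a RefSeq-style genome database and an
environment-matched MAG database):

1. **Thresholds** — keep hits with alignment ≥ 2000 bp, identity ≥ 70%,
   bitscore ≥ 50 and e-value ≤ 0.001. The e-value rule is read as a
   maximum (the field convention), despite the inverted phrasing such
   thresholds are sometimes given with. MAG hits must additionally cover
   < 50% of the subject contig, so entirely viral MAG contigs are not
   mistaken for hosts; each hit is judged alone (no HSP merging).
2. **Top-5 consensus** — hits are ranked by bitscore (ties: e-value, then
   subject id, making the procedure fully deterministic) and at most five
   are considered. Walking domain → species, a rank is assigned only if
   every considered hit agrees on a non-empty name; an unknown name counts
   as a disagreement (asserting agreement with missing data would be
   anti-conservative), and the first disagreement blocks that rank and all
   ranks below.
3. **Merge** — where the two databases disagree at a rank, the MAG-based
   name wins (MAGs come from the same environment). After merging, rank
   consistency is enforced by truncation below the first unassigned rank,
   so no prediction ever has a species without a genus.

# Gene-sharing viral clusters

VCs approximate genus-rank groupings. The package does not reproduce the
full vContact2 pipeline; it consumes per-genome protein-cluster profiles
and reconstructs the genome-graph stage that the VC counts and taxonomy
logic depend on:

* **Edges** — for genomes sharing $a$ protein clusters out of profiles of
  sizes $n$ and $m$ in a universe of $N$ clusters, the weight is
  $-\log_{10} P(X \ge a)$ with $X$ hypergeometric. Computed in log space;
  the suite checks it against an exact binomial-coefficient tail sum to
  $10^{-9}$ relative error (absolute agreement where the tail probability
  sits at double-precision rounding of 1 and the weight is numerically
  zero). Edges below a significance threshold (default 1.0, i.e.
  $P \le 0.1$) are kept in the table but excluded from clustering.
* **Clustering** — Markov flow clustering (expansion 2, inflation 2 by
  default) on the significant edges, with sorted node order, a fixed
  convergence tolerance of $10^{-8}$ and self-loops at each node's maximum
  incident weight, so results are deterministic across runs and platforms.
  Single-genome flow components are not VCs.
* **Status** — the usual vocabulary: `clustered` (in a VC), `singleton`
  (no gene-sharing edges at all), `overlap` (significant edges into two or
  more VCs without membership), `outlier` (edges, but no confident
  placement).
* **Taxonomy** — per VC and per rank from class downward, evaluated
  independently (a class can be assigned while families disagree, matching
  how class-level assignments are reported in practice): unanimous
  non-empty reference names are adopted; references disagreeing at every
  rank give `Mixed`; VCs without references are `Unique VC`, the package's
  operational definition of a putatively novel genus.

# Ecology

All ecology statistics are implemented from first principles (the
independent cross-checks in the test suite use vegan, `cmdscale` and
geosphere, which never stand in for the implementation):

* **Hellinger distance** — Euclidean distance of rows after the
  square-root relative-abundance transform; bounded by $\sqrt 2$. All-zero
  samples are left as zeros with a warning.
* **PCoA** — Gower double-centering of $-\tfrac12 D^2$ and
  eigendecomposition; negative eigenvalues are reported, their axes
  dropped from coordinates.
* **PERMANOVA** — McArdle–Anderson partitioning with hat matrices from
  dummy-coded factors (treatment contrasts, alphabetical reference level;
  sums of squares are contrast-invariant). `by = "terms"` gives sequential
  Type-I sums of squares in formula order; `by = "margin"` adjusts each
  term for all others; both use the full-model residual mean square.
  Aliased columns are dropped with a warning; a fully aliased term is an
  error naming the term.
* **Dispersion test** — samples are embedded by PCoA keeping
  negative-eigenvalue axes as imaginary coordinates; each sample's
  distance to its group's spatial median subtracts the imaginary-axis
  contribution from the squared real-axis distance (floored at zero); the
  one-way F on those distances is tested by permuting them across samples.
* **Mantel** — Spearman correlation (average ranks) of lower-triangle
  distances, permuting rows and columns of the community matrix jointly.
  With zero-distance exclusion, the mask is defined by the *unpermuted*
  geographic matrix and applied after each permutation of the community
  matrix — the geographic structure is fixed; community labels are what
  permute.
* **Geographic distance** — haversine great-circle distance with Earth
  radius 6,378,137 m, the default of the common geographic libraries, so
  one degree of longitude at the equator is 111.3195 km.

All permutation tests share one convention: free permutation of sample
labels (no strata), one-sided "greater" alternative, and
$p = (\#\{stat^* \ge stat\} + 1)/(P + 1)$, so $p = 0$ is impossible. When
$n! \le P$ the permutation distribution is enumerated exhaustively instead
(with $p = \#\{stat^* \ge stat\}/n!$, the identity permutation included);
the suite verifies exact agreement with independent enumeration oracles on
small fixtures. Both PERMANOVA modes and both Mantel variants (with and
without zero-distance pairs) are computed by the pipeline, since reported
analyses of this kind rarely state which variant produced a headline
number.

# The synthetic-data generator

The generator exists so that every stage has a fixture with known truth;
its defaults describe a plausible multi-region rock survey.

* **Populations** — random ancestral genomes with descendants created by
  i.i.d. per-site substitution. Substitutions only: the realized identity
  of a descendant is then *exactly* $1 - \text{substitutions}/L$, which
  the threshold tests rely on. No indel model is provided — none of the
  downstream consumers would exercise it, and it would break the exactness
  of the identity bookkeeping. Ancestors are mutually unrelated (~25%
  background identity).
* **Communities** — each vOTU is anchored at a home site and present in a
  sample with probability $0.9\,e^{-\lambda d}$, where $d$ is the
  great-circle distance from home and $\lambda$ the decay rate (default
  0.01/km, an e-folding distance of 100 km — strong regional structuring
  of the kind reported for endolithic communities). Present vOTUs are
  covered over one contiguous segment equal to the breadth target
  (covered positions are drawn $1 + \text{Poisson}$, so realized breadth
  equals the target exactly), with per-vOTU log-normal abundance scaling
  and piecewise-constant depth in 100-bp windows emulating read-pileup
  smoothness.
* **Metadata** — sites interpolate a latitudinal transect between the
  survey region's endpoints; regions are assigned by latitude band; rock
  types are drawn sandstone-dominated (141:43:5:2).
* **Hosts** — planted hits at configurable identity/length in both
  databases, plus decoys that each violate exactly one filter rule and
  carry a wrong-phylum lineage, so any decoy leaking through is visible as
  a precision loss. Conflicting RefSeq/MAG lineages are planted on
  distinct MAG subjects (a subject's taxonomy is single-valued, as in a
  real database).
* **Profiles** — VC members share a configurable fraction of a VC core
  (default 0.6) plus private clusters; singletons are all-private;
  references carry class/family labels.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and chimeric assembly,
incomplete and fragmented genomes (lengths are exact), multi-mapping
ambiguity in coverage (tables are taken at face value), horizontal gene
flow between unrelated phages, database incompleteness biases in host
prediction, and the environmental covariates (altitude, sun exposure)
beyond their presence in metadata.

# Numerical choices and problem sizes

Determinism: every stochastic routine accepts a seed and restores the
caller's RNG state; generators derive per-stage substreams from the config
seed. Ties are broken lexicographically throughout (cluster
representatives, hit ordering, node order in graph clustering).

The test suite sizes its simulations for a desk machine: clustering
fixtures use 0.25–3 kbp genomes (the alignment engine is exact DP, so
identity semantics do not depend on length); the calibration studies use
500 null simulations with 999 permutations at 12–16 samples; the
distance-decay study uses 4 sites ~100 km apart with 5 samples per site
and 100 replicates; the end-to-end pipeline demonstration uses 2–3 kbp
genomes with a correspondingly lowered length filter. The acceptance
script runs the full pipeline at 9–16 kbp with the standard 10 kbp filter.

# Known limitations

* The greedy partition depends on the documented ordering rule; other
  dereplication tools with different orderings or word filters can split
  borderline pairs (identity within a fraction of a point of 0.95)
  differently.
* The VC stage is a reconstruction of the genome-graph step, not of the
  full protein-clustering pipeline; VC counts on real data are not
  expected to match any particular external tool run.
* PERMANOVA uses free permutation; designs needing restricted permutation
  (repeated measures, nested sites) are out of scope.
* Coverage input is trusted: the package does not model mapping identity
  or multi-mapped reads.
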