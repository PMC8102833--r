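---
title: "Building and evaluating population major-allele reference genomes"
author: "majref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating population major-allele reference genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(majref)
```

## The problem

A standard human reference genome carries, at every position, the allele of
the handful of individuals it was assembled from — not the allele most
common in any particular population. When a cohort from an understudied,
admixed population is sequenced against such a reference, every site where
the cohort's majority allele differs from the reference base produces a
variant call in most samples. These majority-allele calls inflate per-sample
callsets by hundreds of thousands of records, and they are exactly the calls
least likely to be disease relevant.

A *major-allele reference* fixes this at the source: compute cohort
alternate allele frequencies (AF) from a joint-called VCF, find every site
where the alternate AF strictly exceeds 50%, and substitute that allele into
the reference FASTA. `majref` implements this construction end to end, with
exact coordinate bookkeeping, plus the population-genetic toolkit used
around it: diversity-maximizing sample selection, the AF spectrum,
heterozygosity and inbreeding statistics, population-specific variant
filters, and biallelic catalog overlap.

## The model, stage by stage

### Allele frequencies and the majority rule

Sites are first decomposed to biallelic records and left-aligned to the
unique minimal representation (the standard vt/bcftools normalization:
trim identical trailing bases, extending left with the preceding reference
base when an allele would empty; then trim identical leading bases while
both alleles remain non-empty). In the record for alternate allele *a* of a
multiallelic site, genotype indices pointing at *other* alternates are
recoded as non-carrier, so AC counts only allele *a* while AN counts all
called alleles. This makes per-site alternate AFs sum to at most one — the
property that guarantees at most one alternate allele per site can ever be
the majority.

AF is AC/AN over *called* alleles: missing alleles never enter AN, and
hemizygous calls contribute a single allele. The majority test is the exact
rational comparison `2*AC > AN` rather than a floating-point `AF > 0.5`,
so 50% ties are reproducibly excluded (a site where exactly half the
alleles are alternate has no majority).

### The spectrum

The AF spectrum uses 20 bins of width 0.05 and four categories: rare
alternate (AF < 5%), common alternate (5–50%), common reference (50–95%),
and rare-or-unobserved reference (≥ 95%), with AF = 1 tracked as a separate
fixed-alternate sub-count. The prose conventions "up to 5%" and "between
5 and 50%" leave the boundaries ambiguous; we place 0.05 and 0.5 in the
common-alternate bin so that the bin edge at 0.5 agrees with the strict
majority rule — a site at exactly 50% is *not* substituted and therefore
should not sit in a majority category.

### Reference construction and liftover

Substitutions are verified against the genome (a ref mismatch, including an
N in the genome, is a hard error naming chrom:pos — it means the VCF and
FASTA are different builds) and applied per chromosome. Overlapping
candidate edits are resolved left-most-first: candidates are processed in
position order and any edit whose reference span intersects an already
accepted span is skipped, with a full skip log. Any overlap policy is
necessarily a convention; this one is deterministic, and overlaps are rare
because at most one allele per site can be a majority.

Indel substitutions shift all downstream coordinates, so the builder emits
an exact liftover chain alongside the new FASTA. Internally the shared
ref/alt prefix (the VCF anchor base) is trimmed from each edit, so the
recorded span covers only the bases that change; same-length substitutions
(SNPs) therefore sit *inside* aligned blocks and a SNP-only build yields a
single full-length block per contig. Only length-changing edits interrupt
blocks. The chain is written in UCSC chain format with the new genome as
target and the old genome as query, so standard liftover tooling fed this
file projects coordinates from the new build back onto the old one;
`liftPositions()` handles both directions natively. Construction is
byte-identical for any worker count.

### Evaluating call reduction by reprojection

The original study re-ran its whole alignment and calling pipeline against
both references for four held-out genomes. At desk scale we instead compute
the *exact set-theoretic consequence* of the reference swap on a callset.
At a substituted biallelic site with old ref R / old alt A, the new
reference has A, so for any sample:

| old genotype | old callset | new callset |
|---|---|---|
| hom-alt (1/1) | one call | — (matches new reference) |
| het (0/1) | one call | one call, ref/alt swapped |
| hom-ref (absent) | — | one hom-alt call appears |

Absence means homozygous reference, mirroring the GVCF joint-calling
convention in which non-variant positions carry reference-confidence
information. Non-substituted variants are retained with positions lifted
through the chain. A sample variant that overlaps an applied edit without
matching it (a third allele at a substituted site, or a call straddling an
applied indel) cannot be resolved without realignment; such variants are
moved to a side list with a count and the affected substitution sites do
not receive the hom-ref default. Reprojection is an involution: applying
the inverse edit set (`invertBuild()`) restores the original callset.

Under Hardy–Weinberg genotypes with alternate frequency *p*, the expected
net per-sample reduction at a substituted site is
`P(hom-alt) − P(hom-ref) = p² − (1−p)² = 2p − 1`, summed over substituted
sites. This closed form is the oracle the end-to-end suite checks against;
the package exposes it as `expectedCallReduction()`.

The comparison table reports per-chromosome counts, differences and
`100·(a−b)/a`, with percents kept unrounded internally and displayed at two
decimals. The totals row reports *both* the percent of summed counts and
the mean of per-chromosome percents: published tables of this kind often
print the latter, and the two differ whenever chromosomes differ in size.

### Representative sample selection

To pick a construction cohort that spans a population's diversity, samples
are ordered along a phylogenetic tree and taken at a fixed stride:

1. **IBS distance.** For a pair of samples over jointly-called markers,
   each marker contributes `2 − |g_i − g_j|` shared alleles (dosages in
   0/1/2; het–het counts as 2 shared, the standard unphased-dosage
   convention), and the distance is one minus the shared fraction. IBS
   distance need not satisfy the triangle inequality, and no such property
   is assumed.
2. **Neighbor joining.** Classical NJ on the Q-criterion with the standard
   branch-length and distance-update formulas. Exact Q-ties are broken by
   the lexicographically smallest pair of representative labels (the
   smallest sample id in each subtree), which makes the tree a pure
   function of the distance matrix, independent of input row order.
   Negative branch lengths are retained, as in the classical algorithm;
   clamping would silently perturb the leaf ordering.
3. **Leaf ordering.** Depth-first traversal from the final join, visiting
   children by ascending subtree leaf count with the smallest contained tip
   label as tie-break. Tree libraries do not promise any particular leaf
   order, so a deterministic rule is part of the method's contract here.
4. **Stride.** Every k-th leaf starting at the first (k = 8 by default), so
   1,000 ordered samples yield 125 representatives. Starting at index 0 is
   a choice; it is the one that reproduces the 1,000 → 125 design. An
   exclude list (e.g. samples failing an external relatedness screen) can
   be applied before striding; relatedness inference itself is out of
   scope.

### Heterozygosity, inbreeding and filters

Per-sample statistics count het, hom-alt and hom-ref genotypes; the
het/hom ratio uses the homozygous *non-reference* count as denominator
(the standard QC convention) and is undefined when that count is zero.
The inbreeding coefficient is the method-of-moments estimator
`F = 1 − O_het/E_het`, with `E_het = Σ 2p(1−p)` over the sample's called
sites at cohort AFs and no small-sample AN/(AN−1) correction — the
simplest standard per-individual estimator; studies sometimes label such
per-individual values "F_ST", but a per-sample coefficient is what values
like 0.4–0.6 describe. Correlations with admixture components go through
`pearsonCorrelation()`, a validating wrapper over the standard estimator.

The population-specific filter keeps records with cohort AF strictly
above 0.05 that are rare (strictly below 0.01) *or missing* in every
external population column — a missing external record is evidence of
rarity, not of absence of evidence, in catalogs of this size. Thresholds
are strict as printed; published rows with cohort AF 0.05229 are kept,
which is only consistent with a strict > 0.05. The cohort AF column is
used directly (values above 0.5 occur in such tables, so the literal
minor-allele reading would contradict the published rows). The
loss-of-function filter composes with it: severity label plus
cohort AF > 1%.

## The synthetic cohort generator

Real joint-called cohorts of this kind are access-controlled, so the
package ships a generator whose outputs are pure functions of a
`simConfig()`:

* **Spectrum.** Category proportions default to 66% rare alternate, 25%
  common alternate, 8% common reference, 1% rare-or-unobserved reference —
  about 9% of sites carry a majority alternate, echoing the share reported
  for a large admixed human cohort. Within categories, AFs are uniform.
* **Genotypes.** Hardy–Weinberg with per-sample inbreeding F deflating
  heterozygosity (`2p(1−p)(1−F)`), and per-genotype missingness
  (default 1%).
* **Admixture.** Optionally, K ancestral AF profiles drawn around the base
  AF by a Balding–Nichols model at a configurable divergence, mixed per
  sample with Dirichlet proportions. This reproduces the qualitative
  relationships between admixture, heterozygosity and F; it does not model
  linkage, ancestry tracts, or population-specific site discovery.
* **Indels.** Planted at 20% of substitution-eligible sites by default
  (lengths 1–10 bp, anchor-base convention), so chain logic is exercised
  in every end-to-end run. Site positions are sampled on a grid with a
  guard gap wider than the longest indel, so planted spans never overlap;
  asking for more sites than the grid holds is an error.
* **Cluster matrices.** For the selection module, clusters own
  Balding–Nichols-diverged profiles with i.i.d. binomial samples inside.

What passing tests on this generator do **not** show: realistic linkage
disequilibrium, sequencing or calling error, batch effects between
genome and exome samples, or reference bias at the read level. The
generator validates the *arithmetic* of the pipeline, not the upstream
calling.

## Numerical and testing choices

* Exact rational majority test (`2*AC > AN`); AF stored as the exact
  ratio of integers.
* Degenerate inputs are errors, not silent defaults: AN = 0 sites are
  dropped with a warning, AF outside [0,1] is an error, ref/genome
  mismatches and unknown contigs are hard errors naming the site.
* The held-out evaluation design: in the end-to-end reduction check, the
  substitution set is derived from a construction cohort and the reduction
  is measured on freshly drawn samples, mirroring the study design of
  testing on genomes not used for construction. (Reprojecting the
  construction cohort itself makes the measured mean reduction *exactly*
  `Σ(2p̂−1)` at the empirical frequencies — an identity the unit suite
  checks separately — so held-out samples are what make the comparison
  against the truth-frequency oracle informative.)
* Suite problem sizes: the consensus-vs-oracle sweep uses 1,000 random
  genomes of 10–100 kb; the reduction check uses 200 samples × 5,000
  sites × 5 seeds with 200 held-out samples each; NJ checks use additive
  4- and 8-taxon matrices plus 20-permutation determinism sweeps. These
  sizes give the property checks real coverage while keeping a full run
  in minutes on one CPU.

## Limitations

* Reprojection is exact at the callset level but deliberately does not
  model what a re-run aligner would do: mapping-quality gains near
  substituted indels, recovered reads, or genotype-likelihood changes.
  Variants overlapping applied edits are reported, not resolved.
* Sex chromosomes carry no ploidy model: genotypes are taken as emitted,
  and a hemizygous call contributes one allele to AN. How the original
  analyses counted hemizygous male X/Y alleles is not documented; this is
  a stated convention, not a reconstruction.
* The NJ leaf ordering is *a* deterministic rule satisfying the published
  selection design, not a reverse-engineering of any specific tree
  library's internal order.
* Multiallelic decomposition recodes other-alternate alleles as
  non-carrier for the target record; allele-specific depths and
  likelihoods (not consumed by this package) would need a richer
  convention.
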