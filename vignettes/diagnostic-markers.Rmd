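---
title: "Diagnostic SNP discovery and hybrid classification in the Mytilus species complex"
author: "MytilusPanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic SNP discovery and hybrid classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MytilusPanel)
```

## The problem

The blue mussels *Mytilus edulis* (Me), *M. galloprovincialis* (Mg) and
*M. trossulus* (Mt) form a hybridising species complex. Morphology is
unreliable for telling them apart, and the single-locus Me15/16 PCR marker —
which assigns species by amplicon length (180 bp Me, 168 bp Mt, 126 bp Mg) —
sees only one point in the genome: an individual that looks "pure" at
Me15/16 can carry substantial introgressed ancestry elsewhere. A panel of
*diagnostic* SNPs — loci where one allele is fixed (private) in a single
species and the alternative allele is shared by the other two — turns a
handful of cheap allele-specific (KASP-style) assays into a multilocus
classifier that separates pure individuals, F1 hybrids and introgressed
composites.

`MytilusPanel` implements that whole chain: a synthetic cohort generator
with truth labels, the Me15/16 size classifier, the two-tier
informative/diagnostic locus filter, an assay-feasibility screen,
PCA/discriminant marker ranking, and the composite-genotype classifier with
per-site summaries and ancestry fractions.

## The marker filters

Starting from RAD-seq genotypes of reference individuals sampled in putative
pure populations, loci are filtered in two tiers.

**Informative loci** (`filterInformative()`) must show

* at most `maxSnps` SNPs per locus (default 3),
* between `minAlleles` and `maxAlleles` distinct alleles per SNP (defaults
  1–3; one allele admits loci monomorphic in the cohort),
* a genotype in at least `minSampleFraction` of all samples (default 50%,
  boundary inclusive — "at least half"),
* a genotype in at least one sample of every species.

A sample "has" a locus when at least one of the locus' SNP calls is
non-missing; this is the only sample-level presence notion available in a
genotype matrix. The allele-count bound is applied per SNP; counting
haplotype alleles per locus instead is possible in principle but the per-SNP
reading keeps both the SNP-count and allele-count constraints independently
testable, and is what the downstream assay design consumes.

**Diagnostic SNPs** (`selectDiagnostic()`) are informative SNPs with a fixed
allele within species but different alleles between at least two species.
Fixation is assessed at the sample level: every genotyped member of the
species must be homozygous for the same allele — a single heterozygote
breaks fixation. A species is only assessed when the SNP is genotyped in at
least `minSpeciesSampleFraction` of that species' samples (default 50%);
species below the floor are reported `N` (not assessed). By default a fixed
difference between the two assessable species suffices (`requireAllSpecies =
FALSE`, matching the `N` convention of published marker tables); requiring
all three is a switch.

A marker is **panel-grade** when all three species were assessed and exactly
one carries a private allele while the other two share the alternative —
the one-diagnostic-vs-one-shared structure a biallelic fluorescent assay
needs. Markers with three distinct fixed alleles are kept as diagnostic
(`diag_species = "three-way"`) but are not panel-grade unless
`threeWayPanel = TRUE`.

**Assay feasibility** (`assayFeasible()`): the SNP must lie at least
`minFlank = 20` bp from *both* ends of the locus consensus. Reading the rule
against both ends is the conservative choice that guarantees primer room on
either side of the SNP; coordinates are 0-based internally and converted to
1-based only on VCF emission.

## Marker ranking

`dapcLoadings()` realises discriminant analysis of principal components as
PCA followed by linear discriminant analysis on the retained PC scores
(default retention: smallest number of PCs reaching 90% cumulative
variance), with the discriminant axes back-projected into marker space. The
loading of a marker is the sum of its squared back-projected coefficients
over the discriminant axes — non-negative, zero for constant markers, and
larger for markers that separate the species more cleanly. Missing dosages
are imputed by the marker mean before PCA, which preserves the marker count
and is the standard neutral choice.

The default ranking key in `rankMarkers()` multiplies the loading by the
marker's coverage (fraction of samples genotyped). Markers observed in more
individuals are less likely to be assembly or genotyping artifacts, so
high-coverage loci are preferred among similarly discriminant ones; the raw
loading is available as `key = "loading"` since the best definition of the
ranking key is genuinely open.

Two numerical guards matter here. PCs with near-zero pooled within-group
variance (below `1e-8`) are dropped before the discriminant fit: perfectly
separated noise-free cohorts otherwise make the within-group scatter
singular. If *no* PC has within-group variance — every group is a single
point in PC space — markers are ranked by their squared projection onto the
retained PCs alone, which preserves the intended ordering in this degenerate
case. An all-constant dosage matrix returns all-zero loadings rather than
failing.

## The composite-genotype classifier

Across a panel of one-vs-two markers, each call at a marker of species *s*
is summarised by its diagnostic-allele dosage (0, 1, 2). The rules, applied
in order:

1. **Unknown** — more than `maxMissingLoci` missing calls (default 2 of 12;
   published validation data were complete, so the cap is a package choice:
   small enough that every class pattern remains identifiable).
2. **Pure(s)** — every *s*-locus homozygous diagnostic, every other locus
   homozygous shared (predicates are evaluated over non-missing calls, and
   a Pure claim needs at least one observed own-species locus).
3. **F1(s1, s2)** — every s1- and s2-locus heterozygous, the third species'
   loci homozygous shared.
4. **Introgressed(S)** otherwise, with S the set of species whose diagnostic
   allele is observed at least once at their own loci — the composite
   classes Me, Mg, Mt combinations: `MeMg`, `MeMt`, `MtMg`, `MeMgMt`
   (that ordering, including `MtMg`, is kept for output stability).

One situation is genuinely ambiguous: an individual carrying diagnostic
alleles of only one species, plus at least one shared allele at an
own-species locus. The shared allele is carried by *both* other species, so
the introgression source cannot be resolved from the panel. The default
policy (`ambiguousSharedRule = "three_way"`) widens the call to
`Introgressed(MeMgMt)` with an `"ambiguous"` flag — a composite class is
forced, and the ambiguity is not silently hidden. The alternative
(`"own_flagged"`) keeps the single-species set and flags `"own_shared"`.
The genotype with *no* diagnostic allele anywhere (all loci homozygous
shared) is handled by the same logic — every locus shows an allele of two
possible donors — and maps to `Introgressed(MeMgMt)` with the ambiguity
flag under both policies, keeping the classifier total and single-valued.

### Ancestry fractions

`ancestryFractions()` estimates the genome fraction of species *s* as the
frequency of *s*-diagnostic alleles among the non-missing calls at the
*s*-loci, renormalised across the three species. This estimator was chosen
over attributing each shared allele ½ to each of its two sharing species:
the ½-attribution credits a pure *M. edulis* individual with Mg and Mt
ancestry through the shared alleles it necessarily carries at G- and
T-loci (0.625/0.188/0.188 on the 12-marker panel instead of 1/0/0), and it
biases the expected minor fraction of a first backcross to 0.30. The
per-species dosage-frequency estimator returns exactly 1 for pure
individuals, ½/½ for F1s, and is unbiased per locus for backcrosses (the
normalisation across species introduces a ratio bias below 0.005 for the
12-marker panel — an order of magnitude under the sampling noise at these
panel sizes).

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the discovery and
classification steps assume; it is the package's test bed, not a sequencing
simulator.

* **Planted diagnostic loci** — `nDiagnosticPerSpecies` loci per species
  carry a single SNP whose diagnostic allele is at frequency 1 in that
  species and 0 elsewhere, with the alternative allele shared by the other
  two; SNP positions are placed with ≥ 20 bp flanks so the planted panel is
  assayable by construction. `pairDiagnostics` optionally plants loci fixed
  differently in exactly two species (polymorphic in the third) to exercise
  the broader diagnostic rule.
* **Shared polymorphism** — every other locus carries 1–3 biallelic SNPs
  whose minor allele segregates at `sharedMaf` in *all three* species. The
  species' true allele frequencies at non-diagnostic loci are not published
  anywhere, so `sharedMaf` is a free parameter; the default 0.2 is a
  typical intermediate minor-allele frequency that makes shared loci
  clearly polymorphic without ever mimicking a fixed difference in cohorts
  of the sizes used here.
* **Pedigrees** — pure individuals draw both gametes from their species'
  frequencies; F1s take one gamete from each parent; BC1/BC2 individuals
  recombine an F1 (or BC1) gamete with recurrent-parent gametes; a
  three-way cross pairs an F1 gamete with a third-species gamete. Loci
  assort independently (no linkage), matching the analysis' treatment of
  markers as independent loci.
* **Missingness** — applied per genotype call, uniformly at random: the
  simplest mechanism consistent with presence-fraction thresholds.
* **Determinism** — one root seed drives every draw; the session RNG is
  saved and restored, and identical seeds give byte-identical cohorts.
* **Defaults** — the default population layout (21 Me / 15 Mg / 4 Mt across
  five sites) mirrors a realistic discovery design in which one species is
  badly undersampled; 500 loci with 4 planted markers per species is the
  scale used for the recovery checks.

What the generator deliberately does **not** model: read-level error,
allele dropout correlated with depth, linkage, selection, or population
structure within species. Passing tests therefore demonstrate the
correctness of the filters and classifier under their own assumptions —
they do not certify performance on real RAD data, where missingness is
non-uniform and "fixed" differences can be sampling artifacts of small
reference panels (the 4-individual trossulus reference here is the cautionary
example: with 8 chromosomes, a 0.2-frequency allele is absent by chance in
17% of loci).

## Me15/16 single-locus screen

`classifyMe15()` matches observed fragment sizes to the expected
180/168/126 bp within `toleranceBp = 3` bp. Sizes are read off 2% agarose
gels, so exact integer matching would be unrealistic; 3 bp keeps the three
windows separated by more than twice the tolerance (the `sizeTable()`
validity rule). One matched size is a homozygote, two sizes matching two
species a heterozygote composite; an empty profile flags
`no_amplification`, three or more distinct sizes flag `contamination`
(band-intensity dosage is not modelled — only presence/absence of sizes).

## Problem sizes and scope choices

The package's checks run at desk scale by design: recovery of 12 planted
markers among 500 loci across 20 seeds, classifier–oracle agreement over
all 3^12 = 531,441 complete 12-locus states, and ancestry recovery over 200
simulated backcrosses. Genome-scale discovery counts (millions of RAD tags,
thousands of informative loci) depend on raw-read assembly with external
tools and are out of scope, as are maximum-likelihood tree inference and
Bayesian admixture modelling — the package exports PHYLIP distance matrices
and genotype tables for those tools instead. The user-facing surface is R
functions plus `runPipeline()`; a shell wrapper would add nothing a
`Rscript -e` call does not already provide.

## Known limitations

* Diagnostic status is only as good as the reference panel: fixation in a
  handful of individuals is weak evidence, and the per-species ≥50%
  coverage floor cannot rescue a species represented by very few samples.
* The classifier is rule-based, not probabilistic: it reports what the
  diagnostic alleles say, with flags where the panel cannot resolve the
  source of an allele, and leaves admixture-proportion inference to
  dedicated tools.
* `ancestryFractions()` is a panel summary (a few dozen loci), not a
  genome-wide admixture estimate; its variance at 12 loci is substantial
  for any single individual.
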