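# MytilusPanel

Diagnostic SNP marker discovery and multilocus hybrid classification for
the blue mussel species complex (*Mytilus edulis* [Me],
*M. galloprovincialis* [Mg], *M. trossulus* [Mt]).

The three species hybridise wherever they meet, and introgressed
individuals are invisible to morphology and to the standard single-locus
Me15/16 PCR assay (one amplicon size per species: 180 bp Me, 168 bp Mt,
126 bp Mg). `MytilusPanel` builds and applies panels of **diagnostic
SNPs** — loci where one allele is fixed in a single species and the
alternative allele is shared by the other two — so that a dozen cheap
allele-specific assays classify any individual as a pure species, an F1
hybrid, or an introgressed composite (`MeMg`, `MeMt`, `MtMg`, `MeMgMt`).

## What the package does

* **Marker discovery** — `filterInformative()` keeps RAD loci with ≤ 3
  SNPs, 1–3 alleles per SNP, genotypes in ≥ 50% of samples and in all
  three species; `selectDiagnostic()` keeps SNPs with a fixed allele
  within species and different alleles between ≥ 2 species, grades strict
  one-vs-two markers as panel-ready, and `assayFeasible()` screens for
  ≥ 20 bp of primer room on both sides of the SNP.
* **Marker ranking** — `genoPCA()` and `dapcLoadings()` (PCA + linear
  discriminant analysis, loadings back-projected to marker space);
  `rankMarkers()` orders candidates by coverage-weighted loading.
* **Classification** — `classifyIndividual()` / `classifyCohort()` apply
  the composite-genotype rules (all diagnostic alleles from one species ⇒
  pure; heterozygous at all loci of two species ⇒ F1; anything else ⇒
  introgressed, labelled by the species whose diagnostic alleles it
  carries), with `summarizeSites()` and `ancestryFractions()` for
  per-site tables and admixture-style summaries.
* **Single-locus screen** — `classifyMe15()` / `summarizeMe15()` reproduce
  the amplicon-size pre-screen.
* **Synthetic cohorts** — `simulateCohort()` generates seeded cohorts with
  planted diagnostic loci, shared polymorphism, F1/backcross/three-way
  pedigrees, per-call missingness and full truth labels.
* **Pipeline & IO** — `runPipeline()` chains everything and writes VCF,
  FASTA, CSV and PHYLIP artifacts with provenance headers.

## Worked example

Simulate a study-shaped cohort — three pure reference populations plus a
field site of first-generation backcrosses (Me×Mt F1 × Me) — then discover,
rank and apply the marker panel:

```r
library(MytilusPanel)

cfg <- simConfig(
  nLoci = 300, nDiagnosticPerSpecies = 4,
  populations = c(purePopulations(15),
                  list(FLD = list(spec = hybridSpec("Me", "Mt", "BC1",
                                                    bcTo = "Me"), n = 10))),
  missingRate = 0.05, seed = 101)
res <- runPipeline(pipelineConfig(sim = cfg, outDir = tempfile()))
#> [MytilusPanel] input: 300 loci, 55 samples
#> [MytilusPanel] informative: 300 of 300 loci retained
#> [MytilusPanel] diagnostic: 12 SNPs (12 panel-grade)
#> [MytilusPanel] panel: 12 markers after ranking
#> [MytilusPanel] classified 55 individuals at 4 sites
```

The discovery funnel found exactly the 12 planted one-vs-two markers (4
per species). The top of the ranked panel:

```r
res$panel[1:3, c("marker_id", "diag_species", "diag_allele",
                 "shared_allele", "loading", "coverage")]
#>            marker_id diag_species diag_allele shared_allele   loading  coverage
#> L0005_22    L0005_22           Mg           T             G   6.52601  1.000000
#> L0007_25    L0007_25           Mg           G             C   6.52601  1.000000
#> L0008_47    L0008_47           Mg           C             G   6.16867  0.933333
```

`loading` is the discriminant loading (larger = more species-separating);
`coverage` the fraction of reference samples genotyped. Per-site
classification and ancestry:

```r
res$siteSummary
#>   site Me Mg Mt MeMg MeMt MtMg MeMgMt F1_MeMg F1_MeMt F1_MtMg Unknown
#> 1  FLD  0  0  0    0    9    0      0       0       0       0       1
#> 2  SME 15  0  0    0    0    0      0       0       0       0       0
#> 3  SMG  0 15  0    0    0    0      0       0       0       0       0
#> 4  SMT  0  0 15    0    0    0      0       0       0       0       0

head(subset(res$ancestry, site == "FLD"), 3)
#>    sample_id site        Me Mg        Mt flag
#> 46    FLD_01  FLD 0.7142857  0 0.2857143
#> 47    FLD_02  FLD 0.6923077  0 0.3076923
#> 48    FLD_03  FLD 0.7142857  0 0.2857143
```

Every pure reference individual classifies as its species; the backcrosses
classify as `MeMt` composites (none as F1 — a BC1 is heterozygous at only
about half its trossulus loci), one with too many missing calls is
`Unknown`, and their estimated trossulus ancestry sits around the pedigree
expectation of 0.25.

Classification of real KASP exports works the same way via
`readKaspCsv()` + `classifyCohort()`; see the vignette
(`vignettes/diagnostic-markers.Rmd`) for the model, the filter rules and
every tunable threshold.

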