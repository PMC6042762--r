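## Synthetic cohort generator: pure populations with planted species-private
## fixed alleles, F1/backcross/three-way hybrids, shared polymorphism and
## per-call missingness, with full truth labels.

#' Specification of a hybrid individual's pedigree
#'
#' @param parentA,parentB The two parental species of the founding cross
#'   (must differ).
#' @param generation `"F1"`, `"BC1"` or `"BC2"` (first/second backcross) or
#'   `"three-way"` (an F1 of `parentA` x `parentB` crossed to `third`).
#' @param bcTo For backcrosses, the recurrent parent (one of the two
#'   parents; default `parentA`).
#' @param third For `"three-way"`, the third species.
#' @return A `HybridSpec` object.
#' @export
#' @examples
#' hybridSpec("Me", "Mt", "BC1", bcTo = "Me")
hybridSpec <- function(parentA, parentB,
                       generation = c("F1", "BC1", "BC2", "three-way"),
                       bcTo = parentA, third = NULL) {
  generation <- match.arg(generation)
  new("HybridSpec", parentA = parentA, parentB = parentB,
      generation = generation, bcTo = bcTo,
      third = if (is.null(third)) NA_character_ else third)
}

#' @rdname hybridSpec
#' @export
setClass("HybridSpec",
  slots = c(parentA = "character", parentB = "character",
            generation = "character", bcTo = "character", third = "character"))

setValidity("HybridSpec", function(object) {
  sp <- mytilusSpecies()
  if (!object@parentA %in% sp) return("invalid 'parentA': not a species")
  if (!object@parentB %in% sp) return("invalid 'parentB': not a species")
  if (object@parentA == object@parentB)
    return("invalid 'parentB': parents of the founding cross must differ")
  if (object@generation %in% c("BC1", "BC2") &&
      !object@bcTo %in% c(object@parentA, object@parentB))
    return("invalid 'bcTo': backcross parent must be one of the two parents")
  if (object@generation == "three-way" &&
      (is.na(object@third) || !object@third %in% sp))
    return("invalid 'third': three-way cross needs a third species")
  TRUE
})

#' Configuration of a synthetic RAD cohort
#'
#' The generator plants, for each species, `nDiagnosticPerSpecies` loci
#' carrying a strict one-vs-two diagnostic SNP (the diagnostic allele at
#' frequency 1 in that species and 0 in the other two, the alternative
#' allele shared by the other two). All remaining loci carry 1 to
#' `maxSnpsPerLocus` biallelic SNPs whose minor allele segregates at
#' frequency `sharedMaf` in every species (shared polymorphism). Loci are
#' unlinked; gametes assort independently across loci.
#'
#' @param nLoci Total number of RAD loci.
#' @param nDiagnosticPerSpecies Planted one-vs-two diagnostic loci per
#'   species.
#' @param populations Named list, one element per site label, each a
#'   `list(spec=, n=)` where `spec` is a species (`"Me"`, `"Mg"`, `"Mt"`) or
#'   a [hybridSpec()] and `n` the number of individuals. The default
#'   emulates a marker-discovery reference design: 21 *M. edulis*, 15
#'   *M. galloprovincialis* and 4 *M. trossulus* across five sites.
#' @param missingRate Per-genotype-call missingness probability.
#' @param sharedMaf Minor-allele frequency at non-diagnostic SNPs.
#' @param maxSnpsPerLocus Maximum SNPs per non-diagnostic locus.
#' @param locusLength Consensus sequence length in bp (default 90, a typical
#'   RAD-tag length after barcode and cut-site trimming of 100 bp reads).
#' @param pairDiagnostics Optionally plant this many additional loci fixed
#'   differently in exactly two species and polymorphic in the third
#'   (exercises the broader diagnostic rule; default 0).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `SimConfig` object.
#' @export
#' @examples
#' cfg <- simConfig(nLoci = 60, nDiagnosticPerSpecies = 2,
#'                  populations = purePopulations(4), seed = 7)
simConfig <- function(nLoci = 500L, nDiagnosticPerSpecies = 4L,
                      populations = list(
                        LR = list(spec = "Me", n = 10L),
                        RB = list(spec = "Me", n = 10L),
                        MON = list(spec = "Me", n = 1L),
                        BP = list(spec = "Mg", n = 15L),
                        PC = list(spec = "Mt", n = 4L)),
                      missingRate = 0.1, sharedMaf = 0.2,
                      maxSnpsPerLocus = 3L, locusLength = 90L,
                      pairDiagnostics = 0L, seed = 1L) {
  new("SimConfig", nLoci = as.integer(nLoci),
      nDiagnosticPerSpecies = as.integer(nDiagnosticPerSpecies),
      populations = populations, missingRate = as.numeric(missingRate),
      sharedMaf = as.numeric(sharedMaf),
      maxSnpsPerLocus = as.integer(maxSnpsPerLocus),
      locusLength = as.integer(locusLength),
      pairDiagnostics = as.integer(pairDiagnostics), seed = as.integer(seed))
}

#' @rdname simConfig
#' @export
setClass("SimConfig",
  slots = c(nLoci = "integer", nDiagnosticPerSpecies = "integer",
            populations = "list", missingRate = "numeric",
            sharedMaf = "numeric", maxSnpsPerLocus = "integer",
            locusLength = "integer", pairDiagnostics = "integer",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  scalarOk <- function(x) length(x) == 1L && !is.na(x)
  if (!scalarOk(object@nLoci) || object@nLoci < 1L)
    return("invalid 'nLoci': must be a positive integer")
  if (!scalarOk(object@nDiagnosticPerSpecies) || object@nDiagnosticPerSpecies < 0L)
    return("invalid 'nDiagnosticPerSpecies': must be a non-negative integer")
  if (!scalarOk(object@pairDiagnostics) || object@pairDiagnostics < 0L)
    return("invalid 'pairDiagnostics': must be a non-negative integer")
  if (3L * object@nDiagnosticPerSpecies + object@pairDiagnostics > object@nLoci)
    return("invalid 'nDiagnosticPerSpecies': planted loci exceed nLoci")
  if (!scalarOk(object@missingRate) ||
      object@missingRate < 0 || object@missingRate > 1)
    return("invalid 'missingRate': must be a probability in [0, 1]")
  if (!scalarOk(object@sharedMaf) ||
      object@sharedMaf < 0 || object@sharedMaf > 0.5)
    return("invalid 'sharedMaf': must be in [0, 0.5]")
  if (!scalarOk(object@maxSnpsPerLocus) || object@maxSnpsPerLocus < 1L)
    return("invalid 'maxSnpsPerLocus': must be a positive integer")
  if (!scalarOk(object@locusLength) || object@locusLength < 45L)
    return("invalid 'locusLength': must be at least 45 bp")
  if (!scalarOk(object@seed)) return("invalid 'seed': must be an integer")
  if (length(object@populations) == 0L)
    return("invalid 'populations': at least one population required")
  if (is.null(names(object@populations)) ||
      anyDuplicated(names(object@populations)))
    return("invalid 'populations': must be uniquely named by site label")
  for (p in object@populations) {
    if (!is.list(p) || !all(c("spec", "n") %in% names(p)))
      return("invalid 'populations': each element needs 'spec' and 'n'")
    if (is.character(p$spec)) {
      if (!p$spec %in% mytilusSpecies())
        return(sprintf("invalid 'populations': unknown species '%s'", p$spec))
    } else if (!is(p$spec, "HybridSpec")) {
      return("invalid 'populations': spec must be a species or a hybridSpec()")
    }
    if (length(p$n) != 1L || is.na(p$n) || p$n < 1L)
      return("invalid 'populations': n must be a positive integer")
  }
  TRUE
})

#' Convenience population layout: one pure population per species
#'
#' @param n Individuals per species.
#' @param sites Site labels for the three populations.
#' @return A `populations` list for [simConfig()].
#' @export
purePopulations <- function(n = 20L, sites = c("SME", "SMG", "SMT")) {
  setNames(
    lapply(mytilusSpecies(), function(s) list(spec = s, n = as.integer(n))),
    sites)
}

## Expected genome fractions by pedigree; returns named numeric over species.
.expectedAncestry <- function(spec) {
  frac <- setNames(numeric(3), mytilusSpecies())
  if (is.character(spec)) {
    frac[spec] <- 1
    return(frac)
  }
  a <- spec@parentA; b <- spec@parentB
  switch(spec@generation,
    "F1" = { frac[a] <- 0.5; frac[b] <- 0.5 },
    "BC1" = {
      other <- setdiff(c(a, b), spec@bcTo)
      frac[spec@bcTo] <- 0.75; frac[other] <- 0.25
    },
    "BC2" = {
      other <- setdiff(c(a, b), spec@bcTo)
      frac[spec@bcTo] <- 0.875; frac[other] <- 0.125
    },
    "three-way" = { frac[spec@third] <- 0.5; frac[a] <- 0.25; frac[b] <- 0.25 })
  frac
}

## Pedigree-implied genotype class label for the truth table.
.trueClassLabel <- function(spec) {
  if (is.character(spec)) return(spec)
  switch(spec@generation,
    "F1" = paste0("F1_", compositeLabel(c(spec@parentA, spec@parentB))),
    "three-way" = compositeLabel(c(spec@parentA, spec@parentB, spec@third)),
    compositeLabel(c(spec@parentA, spec@parentB)))
}

#' Simulate a RAD genotype cohort with truth labels
#'
#' Generates locus consensus sequences, plants species-diagnostic SNPs,
#' draws per-individual diploid genotypes by independent assortment across
#' loci according to each population's pedigree, and applies uniform
#' per-call missingness. The truth labels (pedigree class and expected
#' ancestry fractions) are stored in `colData()` and retrievable with
#' [truthLabels()]. The same seed always produces an identical cohort.
#'
#' @param config A [simConfig()] object.
#' @return A [RadCohort-class]. `metadata()$plantedMarkers` records the
#'   planted diagnostic loci as a `DataFrame` (locus, pos, species,
#'   diagnostic and shared allele).
#' @export
#' @examples
#' rc <- simulateCohort(simConfig(nLoci = 50, nDiagnosticPerSpecies = 2,
#'                                populations = purePopulations(5),
#'                                missingRate = 0, seed = 42))
#' rc
#' S4Vectors::metadata(rc)$plantedMarkers
simulateCohort <- function(config) {
  validObject(config)
  .withSeed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  species <- mytilusSpecies()
  nLoci <- config@nLoci
  len <- config@locusLength
  locusIds <- sprintf("L%04d", seq_len(nLoci))

  ## consensus sequences
  consensusChar <- vapply(seq_len(nLoci), function(i)
    paste(sample(.NUCLEOTIDES, len, replace = TRUE), collapse = ""),
    character(1))
  consensus <- DNAStringSet(setNames(consensusChar, locusIds))

  ## SNP layout. Planted diagnostic loci carry one SNP placed with >= 20 bp
  ## flanks (assayable by construction); other loci carry 1..maxSnps SNPs
  ## anywhere.
  nDiag <- config@nDiagnosticPerSpecies
  nPair <- config@pairDiagnostics
  diagLocusIdx <- seq_len(3L * nDiag)
  pairLocusIdx <- if (nPair > 0L) 3L * nDiag + seq_len(nPair) else integer(0)
  plantedIdx <- c(diagLocusIdx, pairLocusIdx)
  diagSpecies <- rep(species, each = nDiag)

  locusOfSnp <- integer(0); posOfSnp <- integer(0)
  for (i in seq_len(nLoci)) {
    if (i %in% plantedIdx) {
      p <- sample(20:(len - 21L), 1L)
      locusOfSnp <- c(locusOfSnp, i); posOfSnp <- c(posOfSnp, p)
    } else {
      k <- sample.int(config@maxSnpsPerLocus, 1L)
      p <- sort(sample.int(len, k) - 1L)
      locusOfSnp <- c(locusOfSnp, rep(i, k)); posOfSnp <- c(posOfSnp, p)
    }
  }
  nSnp <- length(posOfSnp)

  ## allele model per SNP: the consensus base is the major/shared allele,
  ## one random alternative base is the minor/diagnostic allele
  refAllele <- substring(consensusChar[locusOfSnp], posOfSnp + 1L, posOfSnp + 1L)
  altAllele <- vapply(refAllele, function(r)
    sample(setdiff(.NUCLEOTIDES, r), 1L), character(1), USE.NAMES = FALSE)

  ## per-species frequency of the alt allele at each SNP
  altFreq <- matrix(config@sharedMaf, nrow = nSnp, ncol = 3,
                    dimnames = list(NULL, species))
  snpKind <- rep("shared", nSnp)
  for (j in seq_along(diagLocusIdx)) {
    row <- which(locusOfSnp == diagLocusIdx[j])
    altFreq[row, ] <- 0
    altFreq[row, diagSpecies[j]] <- 1
    snpKind[row] <- "diagnostic"
  }
  ## pair-difference loci: fixed alt in one species, fixed ref in a second;
  ## in the third species the SNP is mostly ungenotyped (below the
  ## per-species assessment floor, the "N" convention) — masked below
  pairSpecies <- matrix(character(0), ncol = 2)
  if (nPair > 0L) {
    pairSpecies <- t(vapply(seq_len(nPair), function(j)
      as.character(sort(factor(sample(species, 2L), levels = species))),
      character(2)))
    for (j in seq_len(nPair)) {
      row <- which(locusOfSnp == pairLocusIdx[j])
      altFreq[row, ] <- config@sharedMaf
      altFreq[row, pairSpecies[j, 1L]] <- 1
      altFreq[row, pairSpecies[j, 2L]] <- 0
      snpKind[row] <- "pair"
    }
  }

  ## gamete machinery: a gamete is a logical vector over SNPs (TRUE = alt)
  gamete <- function(spec) stats::runif(nSnp) < altFreq[, spec]
  genotype <- function(spec) {
    if (is.character(spec))
      return(cbind(gamete(spec), gamete(spec)))
    a <- spec@parentA; b <- spec@parentB
    f1Gamete <- function() {
      pick <- stats::runif(nSnp) < 0.5
      ifelse(pick, gamete(a), gamete(b))
    }
    bc1Gamete <- function(to) {
      h1 <- gamete(to); h2 <- f1Gamete()
      pick <- stats::runif(nSnp) < 0.5
      ifelse(pick, h1, h2)
    }
    switch(spec@generation,
      "F1" = cbind(gamete(a), gamete(b)),
      "BC1" = cbind(gamete(spec@bcTo), f1Gamete()),
      "BC2" = cbind(gamete(spec@bcTo), bc1Gamete(spec@bcTo)),
      "three-way" = cbind(gamete(spec@third), f1Gamete()))
  }

  ## draw individuals population by population
  nTotal <- sum(vapply(config@populations, function(p) as.integer(p$n),
                       integer(1)))
  h1 <- matrix(FALSE, nSnp, nTotal); h2 <- matrix(FALSE, nSnp, nTotal)
  sampleIds <- character(nTotal); siteOf <- character(nTotal)
  speciesOf <- character(nTotal); classOf <- character(nTotal)
  ancestry <- matrix(0, nTotal, 3, dimnames = list(NULL, species))
  k <- 0L
  for (site in names(config@populations)) {
    p <- config@populations[[site]]
    for (i in seq_len(p$n)) {
      k <- k + 1L
      g <- genotype(p$spec)
      h1[, k] <- g[, 1L]; h2[, k] <- g[, 2L]
      sampleIds[k] <- sprintf("%s_%02d", site, i)
      siteOf[k] <- site
      speciesOf[k] <- if (is.character(p$spec)) p$spec else NA_character_
      classOf[k] <- .trueClassLabel(p$spec)
      ancestry[k, ] <- .expectedAncestry(p$spec)
    }
  }

  a1 <- matrix(ifelse(h1, altAllele, refAllele), nSnp, nTotal,
               dimnames = list(NULL, sampleIds))
  a2 <- matrix(ifelse(h2, altAllele, refAllele), nSnp, nTotal,
               dimnames = list(NULL, sampleIds))
  if (config@missingRate > 0) {
    miss <- matrix(stats::runif(nSnp * nTotal) < config@missingRate,
                   nSnp, nTotal)
    a1[miss] <- NA_character_; a2[miss] <- NA_character_
  }

  ## mask pair-difference loci in the uninvolved species: keep ~40% of that
  ## species' calls (at least one) so the locus stays observed in all three
  ## species while the SNP falls below the 50% per-species assessment floor
  if (nPair > 0L) {
    for (j in seq_len(nPair)) {
      row <- which(locusOfSnp == pairLocusIdx[j])
      third <- setdiff(species, pairSpecies[j, ])
      cols <- which(speciesOf == third)
      if (length(cols) > 1L) {
        drop <- cols[-seq_len(max(1L, floor(0.4 * length(cols))))]
        a1[row, drop] <- NA_character_; a2[row, drop] <- NA_character_
      }
    }
  }

  cohort <- RadCohort(
    a1 = a1, a2 = a2, locus = locusIds[locusOfSnp], pos = posOfSnp,
    site = siteOf, species = speciesOf, consensus = consensus,
    colData = DataFrame(true_class = classOf,
                        ancestry_Me = ancestry[, "Me"],
                        ancestry_Mg = ancestry[, "Mg"],
                        ancestry_Mt = ancestry[, "Mt"],
                        row.names = sampleIds))
  rowData(cohort)$kind <- snpKind

  planted <- DataFrame(
    locus = locusIds[plantedIdx],
    pos = posOfSnp[match(plantedIdx, locusOfSnp)],
    species = c(diagSpecies,
                if (nPair > 0L) apply(pairSpecies, 1L, paste, collapse = "|")
                else character(0)),
    diag_allele = altAllele[match(plantedIdx, locusOfSnp)],
    shared_allele = refAllele[match(plantedIdx, locusOfSnp)])
  metadata(cohort)$plantedMarkers <- planted
  metadata(cohort)$simConfig <- config
  cohort
}

#' Canonical representative genotype of a class
#'
#' Builds, for a given genotype class and marker panel, the canonical
#' diploid genotype an individual of that class would carry:
#' \itemize{
#'   \item `Pure(s)`: homozygous diagnostic at every s-locus, homozygous
#'     shared at every other locus;
#'   \item `F1(s1, s2)`: heterozygous diagnostic/shared at every s1- and
#'     s2-locus, homozygous shared at the third species' loci;
#'   \item `Introgressed(S)` (|S| >= 2): homozygous diagnostic at every
#'     locus of the species in S, homozygous shared elsewhere — carries
#'     diagnostic alleles of every species in S and matches neither the
#'     pure nor the F1 pattern.
#' }
#' The construction inverts [classifyIndividual()]: classifying the result
#' returns the input class.
#'
#' @param cls A [genotypeClass()] (`Unknown` is rejected), or a class label
#'   such as `"Me"`, `"F1_MeMt"`, `"MtMg"`.
#' @param panel A [MarkerPanel-class]; only panel-grade markers are used.
#' @param sampleId,site Identifiers for the returned individual.
#' @return A one-individual [PanelGenotypes-class].
#' @export
#' @examples
#' rep <- makeClassRepresentative("MeMt", mytilusPanel12())
#' classLabel(classifyIndividual(rep, mytilusPanel12()))
makeClassRepresentative <- function(cls, panel, sampleId = NULL,
                                    site = "REP") {
  if (is.character(cls)) {
    if (startsWith(cls, "F1_"))
      cls <- genotypeClass("F1", .speciesFromLabel(sub("^F1_", "", cls)))
    else {
      sp <- .speciesFromLabel(cls)
      cls <- if (length(sp) == 1L) genotypeClass("Pure", sp)
             else genotypeClass("Introgressed", sp)
    }
  }
  validObject(cls)
  if (cls@kind == "Unknown")
    stop("cannot build a representative of the Unknown class")
  if (cls@kind == "Introgressed" && length(cls@species) < 2L)
    stop("a single-species Introgressed class has no canonical representative")
  panel <- panel[panel$panel_grade & panel$diag_species %in% mytilusSpecies(), ]
  if (nrow(panel) == 0L) stop("panel has no panel-grade markers")
  own <- panel$diag_species %in% cls@species
  a1 <- ifelse(own, panel$diag_allele, panel$shared_allele)
  a2 <- if (cls@kind == "F1") panel$shared_allele else a1
  if (is.null(sampleId)) sampleId <- classLabel(cls)
  PanelGenotypes(
    a1 = matrix(a1, ncol = 1, dimnames = list(NULL, sampleId)),
    a2 = matrix(a2, ncol = 1, dimnames = list(NULL, sampleId)),
    panel = MarkerPanel(panel), site = site)
}

#' The canonical 12-assay Mytilus demo panel
#'
#' A synthetic stand-in for the validated 12-assay KASP panel: three
#' *M. edulis* assays (E1--E3), four *M. galloprovincialis* assays (G1--G4)
#' and five *M. trossulus* assays (T1--T5), each a strict one-vs-two marker.
#' The allele assignments are synthetic (fixed, deterministic choices); the
#' panel structure — assay names, per-species counts, one diagnostic vs one
#' shared allele — mirrors the validated panel and is intended for examples,
#' representatives and tests.
#'
#' @return A [MarkerPanel-class] of 12 panel-grade markers.
#' @export
#' @examples
#' mytilusPanel12()
mytilusPanel12 <- function() {
  ids <- c("E1", "E2", "E3", "G1", "G2", "G3", "G4",
           "T1", "T2", "T3", "T4", "T5")
  sp <- c(rep("Me", 3), rep("Mg", 4), rep("Mt", 5))
  diag <- c("A", "G", "T", "C", "A", "G", "T", "A", "C", "G", "T", "A")
  shared <- c("G", "A", "C", "T", "G", "A", "C", "G", "T", "A", "C", "G")
  alle <- function(s) ifelse(sp == s, diag, shared)
  MarkerPanel(data.frame(
    marker_id = ids, locus = paste0("LOC_", ids), pos = 45L,
    diag_species = sp, diag_allele = diag, shared_allele = shared,
    allele_Me = alle("Me"), allele_Mg = alle("Mg"), allele_Mt = alle("Mt"),
    panel_grade = TRUE, feasible = TRUE,
    loading = NA_real_, coverage = NA_real_))
}
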