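## Two-tier marker filter: informative RAD loci, then species-diagnostic
## SNPs, plus the KASP-style assay feasibility screen.

## Per-sample locus presence: a sample "has" a locus when at least one of
## the locus' SNP calls is non-missing.
.locusPresence <- function(cohort) {
  a1 <- assay(cohort, "a1")
  locus <- rowData(cohort)$locus
  pres <- rowsum((!is.na(a1)) + 0L, locus) > 0L
  pres[unique(locus), , drop = FALSE]
}

#' Filter RAD loci to informative markers
#'
#' Retains a locus when (i) it carries at most `maxSnps` SNPs, (ii) every
#' one of its SNPs shows between `minAlleles` and `maxAlleles` distinct
#' alleles across the cohort, (iii) it is genotyped (at least one
#' non-missing SNP call) in at least `minSampleFraction` of all samples
#' (boundary inclusive), and (iv) it is genotyped in at least one sample of
#' each of the three species.
#'
#' @param cohort A [RadCohort-class] whose samples all carry species labels,
#'   with all three species represented.
#' @param thresholds A [filterThresholds()].
#' @return The [RadCohort-class] restricted to the retained loci.
#' @export
filterInformative <- function(cohort, thresholds = filterThresholds()) {
  validObject(thresholds)
  sp <- sampleSpecies(cohort)
  if (anyNA(sp))
    stop("all samples must carry a species label for marker discovery")
  absent <- setdiff(mytilusSpecies(), unique(sp))
  if (length(absent))
    stop("cohort lacks species: ", paste(absent, collapse = ", "))

  locus <- rowData(cohort)$locus
  a1 <- assay(cohort, "a1"); a2 <- assay(cohort, "a2")

  ## (i) SNP count per locus
  nSnps <- table(locus)
  okSnps <- names(nSnps)[nSnps <= thresholds@maxSnps]

  ## (ii) distinct alleles per SNP, all SNPs of a locus must comply
  nAllele <- vapply(seq_len(nrow(cohort)), function(i) {
    length(unique(stats::na.omit(c(a1[i, ], a2[i, ]))))
  }, integer(1))
  snpOk <- nAllele >= thresholds@minAlleles & nAllele <= thresholds@maxAlleles
  badLoci <- unique(locus[!snpOk])
  okAlleles <- setdiff(unique(locus), badLoci)

  ## (iii) presence in >= minSampleFraction of all samples
  pres <- .locusPresence(cohort)
  frac <- rowMeans(pres)
  okPresence <- rownames(pres)[frac >= thresholds@minSampleFraction]

  ## (iv) observed in every species
  perSpecies <- vapply(mytilusSpecies(), function(s)
    rowSums(pres[, sp == s, drop = FALSE]) > 0L,
    logical(nrow(pres)))
  okSpecies <- rownames(pres)[rowSums(perSpecies) == 3L]

  keep <- Reduce(intersect, list(okSnps, okAlleles, okPresence, okSpecies))
  cohort[locus %in% keep, ]
}

#' Select species-diagnostic SNPs
#'
#' A SNP is diagnostic when, within every species where it can be assessed,
#' the observed allele is fixed (every genotyped member homozygous for the
#' same allele) and the fixed alleles of at least two species differ. A
#' species is assessed only when the SNP is genotyped in at least
#' `minSpeciesSampleFraction` of that species' samples; unassessed species
#' are reported as `"N"`. A marker is `panel_grade` when all three species
#' were assessed and exactly one carries a private allele while the other
#' two share the alternative (the one-vs-two structure required by
#' allele-specific assays).
#'
#' @param cohort A [RadCohort-class], normally the output of
#'   [filterInformative()].
#' @param thresholds A [filterThresholds()].
#' @param requireAllSpecies When `TRUE`, only SNPs assessable in all three
#'   species are considered (default `FALSE`: a fixed difference between two
#'   assessed species suffices, the third reported `"N"`).
#' @param threeWayPanel When `TRUE`, markers with three distinct fixed
#'   alleles (one per species) are also graded `panel_grade` (default
#'   `FALSE`: strict one-vs-two only).
#' @param minFlank Flank length (bp) used for the feasibility screen (see
#'   [assayFeasible()]); applied only when consensus sequences are present.
#' @return A [MarkerPanel-class] (possibly empty).
#' @export
selectDiagnostic <- function(cohort, thresholds = filterThresholds(),
                             requireAllSpecies = FALSE,
                             threeWayPanel = FALSE, minFlank = 20L) {
  validObject(thresholds)
  sp <- sampleSpecies(cohort)
  if (anyNA(sp)) stop("all samples must carry a species label")
  species <- mytilusSpecies()
  a1 <- assay(cohort, "a1"); a2 <- assay(cohort, "a2")
  rd <- rowData(cohort)
  cons <- consensusSeqs(cohort)

  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    fixed <- setNames(rep("N", 3L), species)
    for (s in species) {
      j <- which(sp == s)
      x1 <- a1[i, j]; x2 <- a2[i, j]
      called <- !is.na(x1)
      if (sum(called) < thresholds@minSpeciesSampleFraction * length(j) ||
          sum(called) == 0L)
        next  # insufficient data: species not assessed ("N")
      alleles <- unique(c(x1[called], x2[called]))
      if (length(alleles) == 1L) fixed[s] <- alleles
      else fixed[s] <- "-"  # assessed but polymorphic / heterozygous
    }
    assessed <- fixed %in% .NUCLEOTIDES
    if (any(fixed == "-")) return(NULL)           # not fixed within a species
    if (requireAllSpecies && !all(assessed)) return(NULL)
    if (sum(assessed) < 2L) return(NULL)
    vals <- fixed[assessed]
    if (length(unique(vals)) < 2L) return(NULL)   # no between-species difference

    ## structure of the fixed alleles
    diagSpecies <- NA_character_; diagAllele <- NA_character_
    sharedAllele <- NA_character_; panelGrade <- FALSE
    if (all(assessed)) {
      tab <- table(fixed)
      if (length(tab) == 2L && any(tab == 1L)) {
        diagAllele <- names(tab)[tab == 1L]
        sharedAllele <- names(tab)[tab == 2L]
        diagSpecies <- species[fixed == diagAllele]
        panelGrade <- TRUE
      } else if (length(tab) == 3L) {
        ## three distinct fixed alleles: no single shared allele exists
        diagSpecies <- "three-way"
        panelGrade <- isTRUE(threeWayPanel)
      }
    } else {
      diagSpecies <- paste(species[assessed], collapse = "|")
    }

    feas <- NA
    if (length(cons) > 0L) {
      seqI <- cons[[rd$locus[i]]]
      feas <- assayFeasible(seqI, rd$pos[i], minFlank = minFlank)
    }
    DataFrame(marker_id = rownames(cohort)[i], locus = rd$locus[i],
              pos = rd$pos[i], diag_species = diagSpecies,
              diag_allele = diagAllele, shared_allele = sharedAllele,
              allele_Me = unname(fixed["Me"]), allele_Mg = unname(fixed["Mg"]),
              allele_Mt = unname(fixed["Mt"]),
              panel_grade = panelGrade, feasible = feas,
              loading = NA_real_, coverage = NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    empty <- DataFrame(marker_id = character(0), locus = character(0),
                       pos = integer(0), diag_species = character(0),
                       diag_allele = character(0), shared_allele = character(0),
                       allele_Me = character(0), allele_Mg = character(0),
                       allele_Mt = character(0), panel_grade = logical(0),
                       feasible = logical(0), loading = numeric(0),
                       coverage = numeric(0))
    return(MarkerPanel(empty))
  }
  MarkerPanel(do.call(rbind, rows))
}

#' Assay feasibility of a SNP position
#'
#' A SNP supports allele-specific primer design when it lies at least
#' `minFlank` bp from **both** ends of its locus consensus sequence (the
#' conservative reading that guarantees primer room on either side).
#' Positions are 0-based.
#'
#' @param sequence The locus consensus: a `DNAString`, a character string,
#'   or a single-sequence `DNAStringSet`.
#' @param snpPosition 0-based SNP offset; must lie within the sequence.
#' @param minFlank Minimum flank length in bp (default 20).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' assayFeasible(paste(rep("A", 100), collapse = ""), 50)  # TRUE
#' assayFeasible(paste(rep("A", 100), collapse = ""), 10)  # FALSE
assayFeasible <- function(sequence, snpPosition, minFlank = 20L) {
  len <- if (is.character(sequence)) nchar(sequence)
         else if (is(sequence, "XStringSet")) {
           stopifnot(length(sequence) == 1L)
           width(sequence)[1L]
         } else length(sequence)
  snpPosition <- as.integer(snpPosition)
  if (snpPosition < 0L || snpPosition >= len)
    stop(sprintf("snpPosition %d out of bounds for a %d bp sequence",
                 snpPosition, len))
  left <- snpPosition
  right <- len - 1L - snpPosition
  min(left, right) >= minFlank
}
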