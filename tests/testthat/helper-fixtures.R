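## Shared fixture builders. Everything is generated in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

## Build a RadCohort from an explicit per-SNP genotype specification.
## `snps` is a list; each element describes one SNP:
##   list(locus=, pos=, calls=) where calls is a character vector of
##   "A/G"-style diploid calls (NA or "" = missing), one per sample.
## Consensus sequences are synthesised long enough for every SNP, with the
## first listed allele of each SNP as the consensus base.
makeCohort <- function(snps, species, site = NULL, consensusLen = 90L) {
  n <- length(species)
  if (is.null(site)) site <- paste0("S_", species)
  a1 <- matrix(NA_character_, length(snps), n,
               dimnames = list(NULL, sprintf("ind%02d", seq_len(n))))
  a2 <- a1
  locus <- character(length(snps)); pos <- integer(length(snps))
  for (i in seq_along(snps)) {
    s <- snps[[i]]
    locus[i] <- s$locus; pos[i] <- s$pos
    calls <- s$calls
    ok <- !is.na(calls) & nzchar(calls)
    a1[i, ok] <- sub("/.*", "", calls[ok])
    a2[i, ok] <- sub(".*/", "", calls[ok])
  }
  cons <- vapply(unique(locus), function(l) {
    base <- rep("A", consensusLen)
    for (i in which(locus == l)) {
      first <- stats::na.omit(a1[i, ])[1]
      base[pos[i] + 1L] <- if (length(first)) first else "A"
    }
    paste(base, collapse = "")
  }, character(1))
  RadCohort(a1 = a1, a2 = a2, locus = locus, pos = pos,
            site = site, species = species,
            consensus = Biostrings::DNAStringSet(cons))
}

## A species vector for a balanced reference cohort.
balancedSpecies <- function(nPer = 4L) rep(mytilusSpecies(), each = nPer)

## Homozygous call string helper: hom("A") -> "A/A".
hom <- function(a) paste0(a, "/", a)

## Independently coded brute-force classification oracle: a direct per-
## individual transcription of the composite-genotype rules, structured
## nothing like the vectorised engine. `d` is a dosage vector over the
## panel loci, `speciesOf` the diagnostic species per locus.
oracleClassify <- function(d, speciesOf, maxMissing = 2L,
                           rule = "three_way") {
  species <- c("Me", "Mg", "Mt")
  if (sum(is.na(d)) > maxMissing) return("Unknown")
  for (s in species) {
    own <- d[speciesOf == s]; oth <- d[speciesOf != s]
    own <- own[!is.na(own)]; oth <- oth[!is.na(oth)]
    if (length(own) > 0 && all(own == 2) && all(oth == 0)) return(s)
  }
  for (p in list(c("Me", "Mg"), c("Me", "Mt"), c("Mg", "Mt"))) {
    inP <- d[speciesOf %in% p]; outP <- d[!speciesOf %in% p]
    ok <- TRUE
    for (s in p) {
      v <- d[speciesOf == s]; v <- v[!is.na(v)]
      if (length(v) == 0 || any(v != 1)) ok <- FALSE
    }
    if (ok && all(outP[!is.na(outP)] == 0))
      return(paste0("F1_", compositeLabel(p)))
  }
  set <- character(0)
  for (s in species) {
    v <- d[speciesOf == s]
    if (any(v >= 1, na.rm = TRUE)) set <- c(set, s)
  }
  if (length(set) >= 2) return(compositeLabel(set))
  if (rule == "three_way" || length(set) == 0) return("MeMgMt")
  compositeLabel(set)  # own_flagged keeps the single-species label
}

## Wrap dosage states (individuals x loci) into a PanelGenotypes on the
## 12-marker demo panel (or a subset of it).
panelFromDosage <- function(states, panel = mytilusPanel12()) {
  states <- as.matrix(states)
  stopifnot(ncol(states) == nrow(panel))
  d <- t(states)  # markers x individuals
  a1 <- ifelse(is.na(d), NA_character_,
               ifelse(d >= 1, panel$diag_allele, panel$shared_allele))
  a2 <- ifelse(is.na(d), NA_character_,
               ifelse(d == 2, panel$diag_allele, panel$shared_allele))
  ids <- sprintf("st%06d", seq_len(ncol(d)))
  colnames(a1) <- colnames(a2) <- ids
  PanelGenotypes(a1 = a1, a2 = a2, panel = panel, site = rep("SIM", ncol(d)))
}
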