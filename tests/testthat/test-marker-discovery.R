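## A random cohort generator for filter property tests: loci with varying
## SNP counts, allele counts and missingness, independent of simulateCohort.
randomFilterCohort <- function(seed, nLoci = 30, nPer = 4) {
  set.seed(seed)
  species <- balancedSpecies(nPer)
  n <- length(species)
  snps <- list()
  for (l in seq_len(nLoci)) {
    k <- sample(1:5, 1)
    poss <- sort(sample(0:79, k))
    for (p in poss) {
      alleles <- sample(c("A", "C", "G", "T"), sample(1:4, 1))
      calls <- paste0(sample(alleles, n, TRUE), "/", sample(alleles, n, TRUE))
      calls[runif(n) < 0.3] <- NA
      snps[[length(snps) + 1]] <-
        list(locus = sprintf("R%03d", l), pos = p, calls = calls)
    }
  }
  makeCohort(snps, species)
}

## Independent re-implementation of the informative-locus predicates,
## written as plain per-locus loops.
bruteInformative <- function(cohort, thr = filterThresholds()) {
  sp <- sampleSpecies(cohort)
  a1 <- assay(cohort, "a1"); a2 <- assay(cohort, "a2")
  loci <- unique(rowData(cohort)$locus)
  keep <- character(0)
  for (l in loci) {
    rows <- which(rowData(cohort)$locus == l)
    ok <- length(rows) <= thr@maxSnps
    for (r in rows) {
      nAll <- length(unique(na.omit(c(a1[r, ], a2[r, ]))))
      if (nAll < thr@minAlleles || nAll > thr@maxAlleles) ok <- FALSE
    }
    present <- apply(!is.na(a1[rows, , drop = FALSE]), 2, any)
    if (mean(present) < thr@minSampleFraction) ok <- FALSE
    for (s in mytilusSpecies())
      if (!any(present[sp == s])) ok <- FALSE
    if (ok) keep <- c(keep, l)
  }
  keep
}

test_that("informative filter enforces SNP count, allele count, presence and species coverage", {
  species <- balancedSpecies(4)  # 12 samples
  homA <- rep(hom("A"), 12)
  snps <- c(
    # locus with 4 SNPs: removed even though each SNP is clean
    lapply(0:3, function(i) list(locus = "L4snp", pos = 25 + i, calls = homA)),
    # monomorphic locus present everywhere: retained (1 allele allowed)
    list(list(locus = "Lmono", pos = 30, calls = homA)),
    # presence boundary at the 12-sample scale (present calls spread over
    # all species): 5/12 (<50%) removed, 6/12 (=50%, inclusive) retained
    list(list(locus = "L49", pos = 30,
              calls = hom("A")[c(1, 1, NA, NA, 1, 1, NA, NA, 1, NA, NA, NA)])),
    list(list(locus = "L50", pos = 30,
              calls = hom("A")[c(1, 1, NA, NA, 1, 1, NA, NA, 1, 1, NA, NA)])),
    # a SNP with 4 alleles: removed
    list(list(locus = "L4all", pos = 30,
              calls = c(rep(hom("A"), 3), rep(hom("C"), 3),
                        rep(hom("G"), 3), rep(hom("T"), 3)))))
  rc <- makeCohort(snps, species)
  kept <- unique(rowData(filterInformative(rc))$locus)
  expect_setequal(kept, c("Lmono", "L50"))
})

test_that("a cohort missing one species is rejected by name", {
  rc <- makeCohort(list(list(locus = "L1", pos = 30,
                             calls = rep(hom("A"), 8))),
                   species = rep(c("Me", "Mg"), each = 4))
  expect_error(filterInformative(rc), "Mt")
})

test_that("informative filter agrees with a brute-force re-check on random cohorts", {
  for (seed in c(2, 7, 19)) {
    rc <- randomFilterCohort(seed)
    kept <- unique(rowData(filterInformative(rc))$locus)
    expect_setequal(kept, bruteInformative(rc))
  }
})

test_that("informative filter is idempotent and monotone in the presence threshold", {
  rc <- randomFilterCohort(11)
  f1 <- filterInformative(rc)
  f2 <- filterInformative(f1)
  expect_identical(rownames(f1), rownames(f2))
  prev <- NULL
  for (frac in c(0.2, 0.4, 0.6, 0.8)) {
    kept <- unique(rowData(filterInformative(
      rc, filterThresholds(minSampleFraction = frac)))$locus)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("fixed-allele assignments are graded against an enumerated truth table", {
  species <- balancedSpecies(2)  # 2 samples per species, complete data
  combos <- expand.grid(Me = c("A", "C", "G"), Mg = c("A", "C", "G"),
                        Mt = c("A", "C", "G"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    al <- unlist(combos[i, ])
    calls <- hom(al[c(1, 1, 2, 2, 3, 3)])
    rc <- makeCohort(list(list(locus = "L1", pos = 30, calls = calls)), species)
    mk <- selectDiagnostic(rc)
    nDistinct <- length(unique(al))
    # diagnostic iff at least two species' fixed alleles differ
    expect_equal(nrow(mk), as.integer(nDistinct >= 2), info = paste(al, collapse = ""))
    if (nDistinct == 2) {
      # one-vs-two: the lone species is the diagnostic one
      lone <- names(al)[!duplicated(al) & !duplicated(al, fromLast = TRUE)]
      expect_true(mk$panel_grade[1])
      expect_equal(mk$diag_species[1], lone)
      expect_equal(mk$diag_allele[1], unname(al[lone]))
      expect_equal(mk$shared_allele[1], unname(al[setdiff(names(al), lone)[1]]))
    }
    if (nDistinct == 3) {
      expect_false(mk$panel_grade[1])
      expect_equal(mk$diag_species[1], "three-way")
      mk3 <- selectDiagnostic(rc, threeWayPanel = TRUE)
      expect_true(mk3$panel_grade[1])
    }
  }
})

test_that("a single heterozygote breaks within-species fixation", {
  species <- balancedSpecies(2)
  calls <- c(hom("A"), "A/G", rep(hom("G"), 4))
  rc <- makeCohort(list(list(locus = "L1", pos = 30, calls = calls)), species)
  expect_equal(nrow(selectDiagnostic(rc)), 0L)
})

test_that("species below the per-species coverage floor are reported N, not assessed", {
  species <- rep(mytilusSpecies(), each = 4)
  # Mt genotyped in 1/4 samples (25% < 50%): unassessed
  calls <- c(rep(hom("A"), 4), rep(hom("G"), 4), hom("G"), NA, NA, NA)
  rc <- makeCohort(list(list(locus = "L1", pos = 30, calls = calls)), species)
  mk <- selectDiagnostic(rc)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$allele_Mt[1], "N")
  expect_equal(mk$diag_species[1], "Me|Mg")
  expect_false(mk$panel_grade[1])
  # requiring all three species drops the marker
  expect_equal(nrow(selectDiagnostic(rc, requireAllSpecies = TRUE)), 0L)
  # at exactly 50% coverage the species is assessed (boundary inclusive)
  calls2 <- c(rep(hom("A"), 4), rep(hom("G"), 4), hom("G"), hom("G"), NA, NA)
  rc2 <- makeCohort(list(list(locus = "L1", pos = 30, calls = calls2)), species)
  mk2 <- selectDiagnostic(rc2)
  expect_equal(mk2$allele_Mt[1], "G")
  expect_true(mk2$panel_grade[1])
})

test_that("diagnostic selection is stable and a subset of its input", {
  rc <- simulateCohort(simConfig(nLoci = 50, nDiagnosticPerSpecies = 3,
                                 populations = purePopulations(8),
                                 missingRate = 0.1, seed = 8L))
  inf <- filterInformative(rc)
  mk <- selectDiagnostic(inf)
  expect_true(all(mk$marker_id %in% rownames(inf)))
  # panel-grade is a subset of diagnostic
  expect_true(all(mk$marker_id[mk$panel_grade] %in% mk$marker_id))
  # re-selection from the loci carrying the markers returns the same SNPs
  mk2 <- selectDiagnostic(inf[rowData(inf)$locus %in% mk$locus, ])
  expect_setequal(mk2$marker_id, mk$marker_id)
})

test_that("assay feasibility requires both flanks to reach the minimum", {
  seq100 <- paste(rep("A", 100), collapse = "")
  expect_true(assayFeasible(seq100, 50))
  expect_false(assayFeasible(seq100, 10))
  expect_false(assayFeasible(seq100, 85))  # right flank 14 < 20
  seq41 <- paste(rep("A", 41), collapse = "")
  expect_true(assayFeasible(seq41, 20))    # both flanks exactly 20
  expect_false(assayFeasible(seq41, 19))
  expect_error(assayFeasible(seq41, 41), "out of bounds")
  expect_error(assayFeasible(seq41, -1), "out of bounds")
  expect_true(assayFeasible(Biostrings::DNAString(seq100), 30))
})
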