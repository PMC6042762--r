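test_that("identical seeds give identical cohorts and the session RNG is untouched", {
  cfg <- simConfig(nLoci = 40, nDiagnosticPerSpecies = 2,
                   populations = purePopulations(4), missingRate = 0.1,
                   seed = 9L)
  set.seed(123); before <- runif(3)
  set.seed(123)
  rc1 <- simulateCohort(cfg)
  after <- runif(3)
  rc2 <- simulateCohort(cfg)
  expect_identical(assay(rc1, "a1"), assay(rc2, "a1"))
  expect_identical(assay(rc1, "a2"), assay(rc2, "a2"))
  expect_identical(as.data.frame(rowData(rc1)), as.data.frame(rowData(rc2)))
  expect_identical(as.data.frame(colData(rc1)), as.data.frame(colData(rc2)))
  expect_identical(as.character(consensusSeqs(rc1)),
                   as.character(consensusSeqs(rc2)))
  expect_identical(before, after)  # generator must not disturb the session stream
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simConfig(missingRate = 1.5), "missingRate")
  expect_error(simConfig(nLoci = 0), "nLoci")
  expect_error(simConfig(sharedMaf = 0.9), "sharedMaf")
  expect_error(simConfig(nLoci = 10, nDiagnosticPerSpecies = 5),
               "nDiagnosticPerSpecies")
  expect_error(simConfig(populations = list(X = list(spec = "Xx", n = 5))),
               "populations")
  expect_error(simConfig(populations = list(X = list(spec = "Me", n = 0))),
               "populations")
  expect_error(hybridSpec("Me", "Me"), "parent")
  expect_error(hybridSpec("Me", "Mt", "BC1", bcTo = "Mg"), "bcTo")
})

test_that("planted diagnostic loci are fixed: private in their species, absent elsewhere", {
  rc <- simulateCohort(simConfig(nLoci = 60, nDiagnosticPerSpecies = 3,
                                 populations = purePopulations(8),
                                 missingRate = 0, seed = 21L))
  planted <- S4Vectors::metadata(rc)$plantedMarkers
  sp <- sampleSpecies(rc)
  a1 <- assay(rc, "a1"); a2 <- assay(rc, "a2")
  key <- paste0(rowData(rc)$locus, "_", rowData(rc)$pos)
  for (i in seq_len(nrow(planted))) {
    row <- match(paste0(planted$locus[i], "_", planted$pos[i]), key)
    own <- sp == planted$species[i]
    # every own-species sample homozygous for the diagnostic allele
    expect_true(all(a1[row, own] == planted$diag_allele[i]))
    expect_true(all(a2[row, own] == planted$diag_allele[i]))
    # diagnostic allele absent outside the species
    expect_false(any(c(a1[row, !own], a2[row, !own]) == planted$diag_allele[i]))
  }
})

test_that("truth labels carry pedigree classes and expected ancestry fractions", {
  pops <- list(P1 = list(spec = "Me", n = 3),
               F1 = list(spec = hybridSpec("Me", "Mt"), n = 3),
               B1 = list(spec = hybridSpec("Me", "Mt", "BC1", bcTo = "Me"), n = 3),
               B2 = list(spec = hybridSpec("Me", "Mt", "BC2", bcTo = "Mt"), n = 3),
               TW = list(spec = hybridSpec("Me", "Mt", "three-way", third = "Mg"),
                         n = 3))
  rc <- simulateCohort(simConfig(nLoci = 30, nDiagnosticPerSpecies = 2,
                                 populations = pops, missingRate = 0, seed = 5L))
  tr <- truthLabels(rc)
  expect_equal(nrow(tr), 15L)
  byClass <- split(as.data.frame(tr), tr$site)
  expect_equal(unique(byClass$P1$true_class), "Me")
  expect_equal(unique(byClass$F1$true_class), "F1_MeMt")
  expect_equal(unique(byClass$B1$true_class), "MeMt")
  expect_equal(unique(byClass$TW$true_class), "MeMgMt")
  expect_equal(unique(byClass$B1$ancestry_Me), 0.75)
  expect_equal(unique(byClass$B1$ancestry_Mt), 0.25)
  expect_equal(unique(byClass$B2$ancestry_Mt), 0.875)
  expect_equal(unique(byClass$TW$ancestry_Mg), 0.5)
  # fractions always sum to 1
  expect_equal(tr$ancestry_Me + tr$ancestry_Mg + tr$ancestry_Mt, rep(1, 15))
})

test_that("discovery on a clean simulated cohort recovers exactly the planted loci", {
  rc <- simulateCohort(simConfig(nLoci = 100, nDiagnosticPerSpecies = 4,
                                 populations = purePopulations(20),
                                 missingRate = 0, seed = 31L))
  mk <- selectDiagnostic(filterInformative(rc))
  planted <- S4Vectors::metadata(rc)$plantedMarkers
  expect_setequal(mk$locus, planted$locus)
  expect_equal(nrow(mk), 12L)
  expect_true(all(mk$panel_grade))
  # alleles and species agree with what was planted
  m <- match(mk$locus, planted$locus)
  expect_equal(mk$diag_species, planted$species[m])
  expect_equal(mk$diag_allele, planted$diag_allele[m])
  expect_equal(mk$shared_allele, planted$shared_allele[m])
})

test_that("pair-difference planting yields diagnostic but not panel-grade markers", {
  rc <- simulateCohort(simConfig(nLoci = 40, nDiagnosticPerSpecies = 1,
                                 pairDiagnostics = 3,
                                 populations = purePopulations(10),
                                 missingRate = 0, seed = 13L))
  mk <- selectDiagnostic(filterInformative(rc))
  planted <- S4Vectors::metadata(rc)$plantedMarkers
  expect_setequal(mk$locus, planted$locus)
  pairRows <- mk[!mk$diag_species %in% mytilusSpecies(), ]
  expect_equal(nrow(pairRows), 3L)
  expect_false(any(pairRows$panel_grade))
})

test_that("class representatives follow the canonical patterns and round-trip", {
  p <- mytilusPanel12()
  rep <- makeClassRepresentative("Me", p)
  a1 <- assay(rep, "a1")[, 1]; a2 <- assay(rep, "a2")[, 1]
  isE <- p$diag_species == "Me"
  expect_true(all(a1[isE] == p$diag_allele[isE] & a2[isE] == p$diag_allele[isE]))
  expect_true(all(a1[!isE] == p$shared_allele[!isE] &
                  a2[!isE] == p$shared_allele[!isE]))

  f1 <- makeClassRepresentative("F1_MeMt", p)
  b1 <- assay(f1, "a1")[, 1]; b2 <- assay(f1, "a2")[, 1]
  own <- p$diag_species %in% c("Me", "Mt")
  expect_true(all(b1[own] == p$diag_allele[own] & b2[own] == p$shared_allele[own]))
  expect_true(all(b1[!own] == p$shared_allele[!own]))

  expect_error(makeClassRepresentative(genotypeClass("Unknown"), p), "Unknown")
  expect_equal(classLabel(classifyIndividual(
    makeClassRepresentative("MeMgMt", p))), "MeMgMt")
})
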