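test_that("the composite-genotype rules classify the canonical patterns", {
  p <- mytilusPanel12()
  # all diagnostic alleles from one species: pure
  pure <- classifyIndividual(makeClassRepresentative("Me", p))
  expect_equal(pure@kind, "Pure")
  expect_equal(classLabel(pure), "Me")
  # heterozygous at all loci of two species: F1
  f1 <- classifyIndividual(makeClassRepresentative("F1_MeMg", p))
  expect_equal(f1@kind, "F1")
  expect_setequal(f1@species, c("Me", "Mg"))
  # diagnostic alleles of all three species: MeMgMt composite
  tri <- classifyIndividual(makeClassRepresentative("MeMgMt", p))
  expect_equal(tri@kind, "Introgressed")
  expect_equal(classLabel(tri), "MeMgMt")
})

test_that("a shared allele at an own-species locus follows the ambiguity policy", {
  p <- mytilusPanel12()
  # only Me-diagnostic alleles, but one E-locus heterozygous: the foreign
  # allele could come from Mg or Mt
  states <- c(1, 2, 2, rep(0, 9))
  pg <- panelFromDosage(matrix(states, nrow = 1), p)
  threeWay <- classifyIndividual(pg, policy = classifyPolicy())
  expect_equal(classLabel(threeWay), "MeMgMt")
  expect_true("ambiguous" %in% threeWay@flags)
  own <- classifyIndividual(pg,
    policy = classifyPolicy(ambiguousSharedRule = "own_flagged"))
  expect_equal(own@kind, "Introgressed")
  expect_equal(own@species, "Me")
  expect_true("own_shared" %in% own@flags)
  # with a second diagnostic species present the source is explained
  states2 <- c(1, 2, 2, rep(0, 5), 1, 0, 0, 0)
  two <- classifyIndividual(panelFromDosage(matrix(states2, nrow = 1), p))
  expect_equal(classLabel(two), "MeMt")
  expect_length(two@flags, 0)
})

test_that("missingness beyond the policy cap yields Unknown", {
  p <- mytilusPanel12()
  states <- c(2, 2, 2, rep(0, 6), NA, NA, NA)
  g3 <- classifyIndividual(panelFromDosage(matrix(states, nrow = 1), p))
  expect_equal(g3@kind, "Unknown")
  expect_true("too_many_missing" %in% g3@flags)
  # within the cap the pure pattern still resolves
  states2 <- c(2, 2, 2, rep(0, 7), NA, NA)
  g2 <- classifyIndividual(panelFromDosage(matrix(states2, nrow = 1), p))
  expect_equal(classLabel(g2), "Me")
  # the cap must stay below the panel size
  expect_error(classifyCohort(panelFromDosage(matrix(0, 1, 12), p),
                              policy = classifyPolicy(maxMissingLoci = 12)),
               "panel size")
})

test_that("alleles outside the panel's allele set are rejected with the marker named", {
  p <- mytilusPanel12()
  rep <- makeClassRepresentative("Me", p)
  a1 <- assay(rep, "a1"); a2 <- assay(rep, "a2")
  a1["G2", 1] <- "T"  # G2's alleles are A (diag) / G (shared)
  bad <- PanelGenotypes(a1 = a1, a2 = a2, panel = p,
                        site = colData(rep)$site)
  expect_error(classifyCohort(bad), "G2")
})

test_that("site summaries have the published seven-class shape and conserve counts", {
  p <- mytilusPanel12()
  # a site of 50 pure galloprovincialis
  reps <- do.call(cbind, lapply(1:50, function(i)
    makeClassRepresentative("Mg", p, sampleId = paste0("bp", i), site = "BP")))
  cl <- classifyCohort(reps)
  s <- summarizeSites(cl)
  expect_equal(s$Mg[s$site == "BP"], 50L)
  expect_equal(sum(s[s$site == "BP", -1]), 50L)

  # a mixed site rebuilt from published per-class counts
  counts <- c(Mt = 5, MeMt = 6, MtMg = 4, MeMgMt = 5)
  reps2 <- do.call(cbind, unlist(lapply(names(counts), function(lab)
    lapply(seq_len(counts[lab]), function(i)
      makeClassRepresentative(lab, p, sampleId = paste0(lab, i),
                              site = "LET"))), recursive = FALSE))
  s2 <- summarizeSites(classifyCohort(reps2))
  expect_equal(s2$Mt[1], 5L)
  expect_equal(s2$MeMt[1], 6L)
  expect_equal(s2$MtMg[1], 4L)
  expect_equal(s2$MeMgMt[1], 5L)
  expect_equal(sum(s2[1, -1]), 20L)

  expect_equal(nrow(summarizeSites(data.frame(site = character(0),
                                              label = character(0)))), 0L)
})

test_that("ancestry fractions recover pure, F1 and backcross expectations", {
  p <- mytilusPanel12()
  af <- ancestryFractions(makeClassRepresentative("Me", p))
  expect_equal(unlist(af[1, c("Me", "Mg", "Mt")]),
               c(Me = 1, Mg = 0, Mt = 0))
  afF1 <- ancestryFractions(makeClassRepresentative("F1_MeMt", p))
  expect_equal(afF1$Me[1], afF1$Mt[1])
  expect_equal(afF1$Me[1] + afF1$Mg[1] + afF1$Mt[1], 1)

  # all-missing and no-diagnostic-allele cases are flagged
  pgMiss <- panelFromDosage(matrix(NA_integer_, 1, 12), p)
  afM <- ancestryFractions(pgMiss)
  expect_equal(afM$flag[1], "all_missing")
  expect_true(is.na(afM$Me[1]))
  pgNone <- panelFromDosage(matrix(0L, 1, 12), p)
  expect_equal(ancestryFractions(pgNone)$flag[1], "no_diagnostic_alleles")
})

test_that("simulated pure populations never classify as F1 or introgressed", {
  rc <- simulateCohort(simConfig(nLoci = 80, nDiagnosticPerSpecies = 4,
                                 populations = purePopulations(15),
                                 missingRate = 0, seed = 41L))
  panel <- MarkerPanel(selectDiagnostic(filterInformative(rc)))
  cl <- classifyCohort(panelGenotypesFromCohort(rc, panel))
  expect_true(all(cl$kind == "Pure"))
  expect_equal(unname(cl$label), unname(sampleSpecies(rc)[cl$sample_id]))
})

test_that("a simulated F1 agrees across the single-locus and panel classifiers", {
  rc <- simulateCohort(simConfig(
    nLoci = 60, nDiagnosticPerSpecies = 4,
    populations = c(purePopulations(8),
                    list(HYB = list(spec = hybridSpec("Me", "Mt"), n = 6))),
    missingRate = 0, seed = 19L))
  panel <- MarkerPanel(selectDiagnostic(
    filterInformative(rc[, !is.na(sampleSpecies(rc))])))
  cl <- classifyCohort(panelGenotypesFromCohort(rc, panel))
  hyb <- cl[cl$site == "HYB", ]
  expect_true(all(hyb$label == "F1_MeMt"))
  # the same individual's Me15/16 profile (one band per parent species)
  me15 <- classifyMe15(c(180, 168))
  expect_equal(as.character(me15), "Me/Mt")
  expect_setequal(strsplit(as.character(me15), "/")[[1]],
                  strsplit(hyb$species[1], ",")[[1]])
})

test_that("classification is total and single-valued on random complete genotypes", {
  p <- mytilusPanel12()
  set.seed(12)
  states <- matrix(sample(0:2, 200 * 12, TRUE), 200, 12)
  cl <- classifyCohort(panelFromDosage(states, p))
  expect_equal(nrow(cl), 200L)
  expect_false(anyNA(cl$label))
  valid <- c("Me", "Mg", "Mt", "MeMg", "MeMt", "MtMg", "MeMgMt",
             "F1_MeMg", "F1_MeMt", "F1_MtMg", "Unknown")
  expect_true(all(cl$label %in% valid))
  # per-site summary cells add back to the number of individuals
  s <- summarizeSites(cl)
  expect_equal(sum(s[, -1]), 200L)
})
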