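## Accessors and show() methods.

#' Locus consensus sequences of a cohort
#'
#' @param x A [RadCohort-class].
#' @return A named [Biostrings::DNAStringSet] (possibly empty).
#' @export
setMethod("consensusSeqs", "RadCohort", function(x) x@consensus)

#' Species labels of the samples
#'
#' @param x A [RadCohort-class].
#' @return Named character vector (`NA` for unlabeled samples).
#' @export
setMethod("sampleSpecies", "RadCohort", function(x)
  setNames(colData(x)$species, colnames(x)))

#' Site labels of the samples
#'
#' @param x A [RadCohort-class] or [PanelGenotypes-class].
#' @return Named character vector of site labels.
#' @export
setMethod("sampleSites", "SummarizedExperiment", function(x)
  setNames(colData(x)$site, colnames(x)))

#' Truth labels of a simulated cohort
#'
#' @param x A [RadCohort-class] produced by [simulateCohort()].
#' @return A `DataFrame` with `sample_id`, `site`, `true_class` and
#'   `ancestry_Me`/`ancestry_Mg`/`ancestry_Mt` columns.
#' @export
setMethod("truthLabels", "RadCohort", function(x) {
  cd <- colData(x)
  need <- c("true_class", "ancestry_Me", "ancestry_Mg", "ancestry_Mt")
  if (!all(need %in% colnames(cd)))
    stop("cohort carries no truth labels (not produced by simulateCohort?)")
  DataFrame(sample_id = colnames(x), site = cd$site,
            cd[, need, drop = FALSE], row.names = colnames(x))
})

#' The marker panel behind a PanelGenotypes object
#'
#' @param x A [PanelGenotypes-class].
#' @return The [MarkerPanel-class] stored in `rowData(x)`.
#' @export
setMethod("markerPanel", "PanelGenotypes", function(x)
  MarkerPanel(rowData(x)))

#' Allele call matrices
#'
#' @param x A [RadCohort-class] or [PanelGenotypes-class].
#' @param which `"a1"` or `"a2"`.
#' @return Character matrix of allele calls (rows = SNPs/markers).
#' @export
setMethod("alleleCalls", "SummarizedExperiment", function(x, which = c("a1", "a2")) {
  which <- match.arg(which)
  assay(x, which)
})

#' Diagnostic-allele dosage matrix
#'
#' Counts, per marker and individual, the copies (0/1/2) of the marker's
#' diagnostic allele; `NA` for missing calls. Alleles outside a panel-grade
#' marker's \{diagnostic, shared\} pair are an error naming the marker.
#'
#' @param x A [PanelGenotypes-class].
#' @param ... Unused.
#' @return Integer matrix, samples x markers (rows = samples so that the
#'   result feeds PCA/DAPC directly).
#' @export
setMethod("dosageMatrix", "PanelGenotypes", function(x, ...) {
  panel <- rowData(x)
  a1 <- assay(x, "a1"); a2 <- assay(x, "a2")
  diag <- panel$diag_allele; shr <- panel$shared_allele
  for (i in seq_len(nrow(panel))) {
    if (is.na(diag[i]) || is.na(shr[i])) next  # non-panel marker: dosage is NA
    obs <- unique(c(a1[i, ], a2[i, ]))
    obs <- obs[!is.na(obs)]
    bad <- setdiff(obs, c(diag[i], shr[i]))
    if (length(bad))
      stop(sprintf("allele %s at marker %s is not in the panel's allele set {%s, %s}",
                   paste(bad, collapse = ","), panel$marker_id[i],
                   diag[i], shr[i]))
  }
  d <- (a1 == diag) + (a2 == diag)
  t(d)
})

#' Label of a genotype class
#'
#' `"Me"`, `"MeMt"`, `"MeMgMt"`, ... for Pure/Introgressed calls,
#' `"F1_MeMt"`-style labels for F1 hybrids, `"Unknown"` otherwise.
#'
#' @param x A [GenotypeClass-class].
#' @return A single character label.
#' @export
setMethod("classLabel", "GenotypeClass", function(x) {
  switch(x@kind,
    Pure = compositeLabel(x@species),
    Introgressed = compositeLabel(x@species),
    F1 = paste0("F1_", compositeLabel(x@species)),
    Unknown = "Unknown")
})

setMethod("show", "RadCohort", function(object) {
  rd <- rowData(object)
  sp <- table(factor(colData(object)$species, levels = mytilusSpecies()),
              useNA = "ifany")
  cat(sprintf("RadCohort: %d SNPs in %d loci x %d samples\n",
              nrow(object), length(unique(rd$locus)), ncol(object)))
  cat("  species: ", paste(sprintf("%s=%d", names(sp), sp), collapse = " "),
      "\n", sep = "")
  cat(sprintf("  consensus sequences: %d\n", length(object@consensus)))
  miss <- mean(is.na(assay(object, "a1")))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d markers (%d panel-grade)\n",
              nrow(object), sum(object$panel_grade, na.rm = TRUE)))
  tab <- table(object$diag_species)
  cat("  by diagnostic species: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n", sep = "")
  callNextMethod()
})

setMethod("show", "PanelGenotypes", function(object) {
  cat(sprintf("PanelGenotypes: %d markers x %d individuals\n",
              nrow(object), ncol(object)))
  st <- table(colData(object)$site)
  cat("  sites: ", paste(sprintf("%s=%d", names(st), st), collapse = " "),
      "\n", sep = "")
})

setMethod("show", "GenotypeClass", function(object) {
  lab <- classLabel(object)
  fl <- if (length(object@flags))
    paste0(" [", paste(object@flags, collapse = ","), "]") else ""
  cat(sprintf("GenotypeClass: %s (%s)%s\n", lab, object@kind, fl))
})
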