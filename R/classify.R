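## Panel-based classification of individuals into pure / F1 / introgressed
## composite classes, per-site summaries and diagnostic-allele ancestry
## fractions.

## Vectorised rule engine. `d` is an integer matrix of diagnostic-allele
## dosages (markers x samples, values 0/1/2 or NA), `speciesOf` the
## diagnostic species of each marker. Returns a data.frame with one row per
## sample: kind, label, species (comma-joined), flags, n_missing.
.classifyDosage <- function(d, speciesOf, policy) {
  species <- mytilusSpecies()
  n <- ncol(d)
  nMissing <- colSums(is.na(d))

  ## per-species summaries over that species' loci
  stat <- lapply(species, function(s) {
    ds <- d[speciesOf == s, , drop = FALSE]
    nm <- colSums(!is.na(ds))
    list(nm = nm,
         allDiag = colSums(ds == 2L, na.rm = TRUE) == nm & nm >= 1L,
         allHet = colSums(ds == 1L, na.rm = TRUE) == nm & nm >= 1L,
         allShared = colSums(ds == 0L, na.rm = TRUE) == nm,  # vacuous if nm==0
         anyDiag = colSums(ds >= 1L, na.rm = TRUE) >= 1L)
  })
  names(stat) <- species

  pureMat <- vapply(species, function(s) {
    others <- setdiff(species, s)
    stat[[s]]$allDiag & stat[[others[1]]]$allShared & stat[[others[2]]]$allShared
  }, logical(n))
  pureMat <- matrix(pureMat, nrow = n, dimnames = list(NULL, species))

  pairs <- list(c("Me", "Mg"), c("Me", "Mt"), c("Mg", "Mt"))
  f1Mat <- vapply(pairs, function(p) {
    third <- setdiff(species, p)
    stat[[p[1]]]$allHet & stat[[p[2]]]$allHet & stat[[third]]$allShared
  }, logical(n))
  f1Mat <- matrix(f1Mat, nrow = n)

  diagMat <- vapply(species, function(s) stat[[s]]$anyDiag, logical(n))
  diagMat <- matrix(diagMat, nrow = n, dimnames = list(NULL, species))

  ## species-set keys: bit 1 = Me, 2 = Mg, 4 = Mt
  setLab <- c("Me", "Mg", "MeMg", "Mt", "MeMt", "MtMg", "MeMgMt")
  setStr <- c("Me", "Mg", "Me,Mg", "Mt", "Me,Mt", "Mg,Mt", "Me,Mg,Mt")
  key <- as.integer(diagMat %*% c(1L, 2L, 4L))
  nSet <- rowSums(diagMat)

  ## default: Introgressed with the observed diagnostic-species set
  kind <- rep("Introgressed", n)
  labs <- setLab[pmax(key, 1L)]
  specStr <- setStr[pmax(key, 1L)]
  flags <- rep("", n)

  ## a single (or empty) diagnostic-species set means foreign alleles at the
  ## own-species loci have no second diagnostic species to explain them: the
  ## introgression source is ambiguous
  amb <- nSet <= 1L
  if (policy@ambiguousSharedRule == "three_way") {
    labs[amb] <- "MeMgMt"; specStr[amb] <- "Me,Mg,Mt"
    flags[amb] <- "ambiguous"
  } else {
    flags[amb & nSet == 1L] <- "own_shared"
    none <- amb & nSet == 0L
    labs[none] <- "MeMgMt"; specStr[none] <- "Me,Mg,Mt"
    flags[none] <- "ambiguous"
  }

  isF1 <- rowSums(f1Mat) > 0L
  if (any(isF1)) {
    wf <- max.col(f1Mat, "first")[isF1]
    pairLab <- vapply(pairs, compositeLabel, character(1))
    pairStr <- vapply(pairs, paste, character(1), collapse = ",")
    kind[isF1] <- "F1"; labs[isF1] <- paste0("F1_", pairLab[wf])
    specStr[isF1] <- pairStr[wf]; flags[isF1] <- ""
  }

  isPure <- rowSums(pureMat) > 0L
  if (any(isPure)) {
    wp <- species[max.col(pureMat, "first")[isPure]]
    kind[isPure] <- "Pure"; labs[isPure] <- wp
    specStr[isPure] <- wp; flags[isPure] <- ""
  }

  unknown <- nMissing > policy@maxMissingLoci
  kind[unknown] <- "Unknown"; labs[unknown] <- "Unknown"
  specStr[unknown] <- ""; flags[unknown] <- "too_many_missing"

  data.frame(kind = kind, label = labs, species = specStr, flags = flags,
             n_missing = nMissing, stringsAsFactors = FALSE)
}

#' Classify one individual from its panel genotype
#'
#' Applies the composite-genotype rules: an individual whose diagnostic
#' alleles all belong to one species (homozygous diagnostic at that
#' species' loci, homozygous shared elsewhere) is **pure**; an individual
#' heterozygous diagnostic/shared at *all* loci of exactly two species (and
#' homozygous shared at the third's) is an **F1 hybrid**; every other
#' individual is **introgressed**, labelled with the set of species whose
#' diagnostic alleles it carries. A shared allele observed at a locus of
#' the individual's only diagnostic species leaves the introgression source
#' ambiguous and is resolved per `policy` (see [classifyPolicy()]).
#' Individuals missing more than `maxMissingLoci` calls are `Unknown`.
#'
#' @param g A single-individual [PanelGenotypes-class] (or a
#'   multi-individual one together with `which`).
#' @param panel Optional [MarkerPanel-class]; defaults to the panel stored
#'   in `g`. Only panel-grade single-species markers are used.
#' @param policy A [classifyPolicy()].
#' @param which Column index/name when `g` holds several individuals.
#' @return A [GenotypeClass-class].
#' @export
#' @examples
#' p <- mytilusPanel12()
#' classifyIndividual(makeClassRepresentative("F1_MeMg", p))
classifyIndividual <- function(g, panel = NULL, policy = classifyPolicy(),
                               which = 1L) {
  res <- classifyCohort(g[, which, drop = FALSE], panel = panel,
                        policy = policy)
  sp <- if (nzchar(res$species[1L]))
    strsplit(res$species[1L], ",", fixed = TRUE)[[1L]] else character(0)
  fl <- if (nzchar(res$flags[1L]))
    strsplit(res$flags[1L], ",", fixed = TRUE)[[1L]] else character(0)
  genotypeClass(res$kind[1L], sp, fl)
}

#' Classify every individual in a PanelGenotypes object
#'
#' Vectorised version of [classifyIndividual()].
#'
#' @inheritParams classifyIndividual
#' @param g A [PanelGenotypes-class].
#' @return A data.frame with one row per individual: `sample_id`, `site`,
#'   `kind`, `label`, `species`, `flags`, `n_missing`.
#' @export
classifyCohort <- function(g, panel = NULL, policy = classifyPolicy()) {
  validObject(policy)
  if (is.null(panel)) panel <- markerPanel(g)
  keep <- panel$panel_grade & panel$diag_species %in% mytilusSpecies()
  panel <- panel[keep, ]
  if (nrow(panel) == 0L) stop("panel has no panel-grade markers")
  if (policy@maxMissingLoci >= nrow(panel))
    stop("maxMissingLoci must be smaller than the panel size")
  g <- g[match(panel$marker_id, rowData(g)$marker_id), ]
  d <- t(dosageMatrix(g))  # markers x samples
  res <- .classifyDosage(d, panel$diag_species, policy)
  data.frame(sample_id = colnames(g), site = colData(g)$site, res,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-site genotype-class summary
#'
#' Tabulates classified individuals per site over the seven composite
#' classes (Me, Mg, Mt, MeMg, MeMt, MtMg, MeMgMt), the three possible F1
#' classes and Unknown. Row sums equal the per-site sample counts.
#'
#' @param classes A data.frame with `site` and `label` columns, e.g. from
#'   [classifyCohort()].
#' @return A data.frame, one row per site.
#' @export
summarizeSites <- function(classes) {
  levelsAll <- c(.COMPOSITE_LABELS,
                 paste0("F1_", c("MeMg", "MeMt", "MtMg")), "Unknown")
  if (nrow(classes) == 0L) {
    out <- as.data.frame(setNames(rep(list(integer(0)), length(levelsAll)),
                                  levelsAll), check.names = FALSE)
    return(cbind(data.frame(site = character(0)), out))
  }
  tab <- table(site = classes$site,
               class = factor(classes$label, levels = levelsAll))
  out <- as.data.frame.matrix(tab)
  cbind(data.frame(site = rownames(out)), out, row.names = NULL)
}

#' Diagnostic-allele ancestry fractions
#'
#' For each individual and species *s*, estimates the genome fraction
#' contributed by *s* as the frequency of *s*-diagnostic alleles among the
#' individual's non-missing calls at the *s*-diagnostic loci, renormalised
#' across the three species so the fractions sum to 1. A pure individual
#' scores 1 for its species; an F1 scores 1/2 for each parent; a first
#' backcross scores 3/4 / 1/4 in expectation.
#'
#' @param g A [PanelGenotypes-class].
#' @param panel Optional [MarkerPanel-class] (defaults to the panel in `g`).
#' @return A data.frame with `sample_id`, `site`, `Me`, `Mg`, `Mt` and
#'   `flag` columns. Individuals with no non-missing call are flagged
#'   `"all_missing"` (fractions `NA`); individuals carrying no diagnostic
#'   allele at all are flagged `"no_diagnostic_alleles"`.
#' @export
#' @examples
#' p <- mytilusPanel12()
#' ancestryFractions(makeClassRepresentative("F1_MeMt", p))
ancestryFractions <- function(g, panel = NULL) {
  if (is.null(panel)) panel <- markerPanel(g)
  keep <- panel$panel_grade & panel$diag_species %in% mytilusSpecies()
  panel <- panel[keep, ]
  g <- g[match(panel$marker_id, rowData(g)$marker_id), ]
  d <- t(dosageMatrix(g))  # markers x samples
  species <- mytilusSpecies()
  raw <- vapply(species, function(s) {
    ds <- d[panel$diag_species == s, , drop = FALSE]
    nm <- colSums(!is.na(ds))
    ifelse(nm > 0L, colSums(ds, na.rm = TRUE) / (2 * nm), 0)
  }, numeric(ncol(d)))
  raw <- matrix(raw, ncol = 3, dimnames = list(colnames(g), species))
  tot <- rowSums(raw)
  frac <- raw / tot  # rows with tot==0 become NaN
  allMissing <- colSums(!is.na(d)) == 0L
  flag <- ifelse(allMissing, "all_missing",
                 ifelse(tot == 0, "no_diagnostic_alleles", ""))
  frac[allMissing, ] <- NA_real_
  data.frame(sample_id = colnames(g), site = colData(g)$site,
             Me = frac[, "Me"], Mg = frac[, "Mg"], Mt = frac[, "Mt"],
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Stacked-bar ancestry plot
#'
#' Ancestry-composition bar plot (one bar per individual, stacked by
#' species fraction, faceted by site) in the style of admixture plots.
#'
#' @param af Output of [ancestryFractions()].
#' @return A ggplot object.
#' @export
plotAncestry <- function(af) {
  long <- do.call(rbind, lapply(mytilusSpecies(), function(s)
    data.frame(sample_id = af$sample_id, site = af$site, species = s,
               fraction = af[[s]])))
  long$sample_id <- factor(long$sample_id, levels = unique(af$sample_id))
  ggplot2::ggplot(long,
      ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                   fill = .data$species)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(. ~ site, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "ancestry fraction", fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @importFrom ggplot2 .data
NULL
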