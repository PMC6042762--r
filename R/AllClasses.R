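#' @import methods
#' @importFrom BiocGenerics cbind rbind
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

## ---------------------------------------------------------------------------
## RadCohort: per-sample diploid allele calls at RAD SNPs + locus consensus
## ---------------------------------------------------------------------------

#' RadCohort: RAD-seq genotypes for a cohort of Mytilus samples
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container. Rows are
#' SNPs (grouped into RAD loci via `rowData()$locus`; `rowData()$pos` is the
#' 0-based offset of the SNP in the locus consensus), columns are samples.
#' Two character assays, `a1` and `a2`, hold the diploid allele calls
#' (`"A"`/`"C"`/`"G"`/`"T"`, `NA` for a missing call; the two assays are
#' `NA` together). `colData()` carries at least `site` and `species`
#' (`NA` species marks an unlabeled/field sample). Locus consensus sequences
#' live in the `consensus` slot (a named [Biostrings::DNAStringSet]; may be
#' empty when sequences are unknown, in which case assay-feasibility
#' screening is unavailable).
#'
#' @slot consensus Named `DNAStringSet` of locus consensus sequences.
#' @export
setClass("RadCohort",
  contains = "SummarizedExperiment",
  slots = c(consensus = "DNAStringSet"))

setValidity("RadCohort", function(object) {
  msg <- character(0)
  if (!all(c("a1", "a2") %in% names(assays(object))))
    msg <- c(msg, "assays 'a1' and 'a2' are required")
  else {
    a1 <- assay(object, "a1"); a2 <- assay(object, "a2")
    ok <- function(a) all(a %in% c(.NUCLEOTIDES, NA_character_))
    if (!ok(a1) || !ok(a2))
      msg <- c(msg, "allele calls must be A/C/G/T or NA")
    if (!identical(is.na(a1), is.na(a2)))
      msg <- c(msg, "a1 and a2 must be missing together")
  }
  rd <- rowData(object)
  if (!all(c("locus", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must have 'locus' and 'pos' columns")
  cd <- colData(object)
  if (!all(c("site", "species") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'site' and 'species' columns")
  else {
    sp <- cd$species
    if (!all(sp %in% c(mytilusSpecies(), NA_character_)))
      msg <- c(msg, "species labels must be Me/Mg/Mt or NA")
  }
  if (length(object@consensus) > 0L && all(c("locus", "pos") %in% colnames(rd))) {
    hit <- match(rd$locus, names(object@consensus))
    if (anyNA(hit))
      msg <- c(msg, "every locus must have a consensus sequence (or none)")
    else if (any(rd$pos < 0L | rd$pos >= width(object@consensus)[hit]))
      msg <- c(msg, "SNP positions must fall within their consensus sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RadCohort
#'
#' @param a1,a2 Character matrices (SNPs x samples) of first/second allele
#'   calls; `NA` (in both) marks a missing genotype.
#' @param locus Character vector of locus identifiers, one per SNP row.
#' @param pos Integer vector of 0-based SNP offsets into the locus consensus.
#' @param site,species Per-sample site and species labels (`species` may be
#'   `NA` for field samples of unknown ancestry).
#' @param consensus Optional named `DNAStringSet` of locus consensus
#'   sequences.
#' @param colData Optional extra per-sample columns (a `DataFrame` or
#'   data.frame) merged alongside `site`/`species`.
#' @return A [RadCohort-class] object. Row names are `"<locus>_<pos>"` SNP
#'   ids; column names are sample ids (taken from `colnames(a1)`).
#' @export
#' @examples
#' a1 <- matrix(c("A", "A", "G", "G"), 1, 4,
#'              dimnames = list(NULL, paste0("s", 1:4)))
#' rc <- RadCohort(a1, a1, locus = "L1", pos = 10L,
#'                 site = rep(c("LR", "BP"), each = 2),
#'                 species = rep(c("Me", "Mg"), each = 2),
#'                 consensus = Biostrings::DNAStringSet(c(
#'                   L1 = paste(rep("A", 50), collapse = ""))))
#' rc
RadCohort <- function(a1, a2, locus, pos, site, species,
                      consensus = DNAStringSet(), colData = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)))
  pos <- as.integer(pos)
  snpId <- paste0(locus, "_", pos)
  rownames(a1) <- rownames(a2) <- snpId
  cd <- DataFrame(site = as.character(site), species = as.character(species),
                  row.names = colnames(a1))
  if (!is.null(colData)) {
    extra <- as(colData, "DFrame")
    cd <- cbind(cd, extra[, setdiff(colnames(extra), colnames(cd)), drop = FALSE])
  }
  se <- SummarizedExperiment(
    assays = SimpleList(a1 = a1, a2 = a2),
    rowData = DataFrame(locus = as.character(locus), pos = pos,
                        row.names = snpId),
    colData = cd)
  new("RadCohort", se, consensus = consensus)
}

## ---------------------------------------------------------------------------
## MarkerPanel: table of diagnostic SNP markers
## ---------------------------------------------------------------------------

#' MarkerPanel: a table of species-diagnostic SNP markers
#'
#' A [S4Vectors::DataFrame]-derived class with one row per diagnostic SNP.
#' Required columns:
#' \describe{
#'   \item{marker_id}{unique marker name (assay name or `"<locus>_<pos>"`).}
#'   \item{locus, pos}{RAD locus id and 0-based SNP offset.}
#'   \item{diag_species}{the species the marker diagnoses (`Me`/`Mg`/`Mt`)
#'     for one-vs-two markers, or a tag such as `"Me|Mg"` (pairwise fixed
#'     difference, third species unassessed) or `"three-way"`.}
#'   \item{diag_allele, shared_allele}{the species-private allele and the
#'     allele shared by the other two species (NA unless `panel_grade`).}
#'   \item{allele_Me, allele_Mg, allele_Mt}{the fixed allele observed in each
#'     species, `"N"` when the species could not be assessed.}
#'   \item{panel_grade}{`TRUE` for strict one-vs-two markers usable in the
#'     KASP-style panel.}
#'   \item{feasible}{`TRUE` when the SNP is far enough from both consensus
#'     ends for primer design (`NA` when no consensus was available).}
#'   \item{loading, coverage}{discriminant loading and genotyped fraction,
#'     filled by [rankMarkers()].}
#' }
#' @export
setClass("MarkerPanel", contains = "DFrame")

.MARKER_COLS <- c("marker_id", "locus", "pos", "diag_species", "diag_allele",
                  "shared_allele", "allele_Me", "allele_Mg", "allele_Mt",
                  "panel_grade", "feasible", "loading", "coverage")

setValidity("MarkerPanel", function(object) {
  msg <- character(0)
  missing <- setdiff(.MARKER_COLS, colnames(object))
  if (length(missing))
    msg <- c(msg, paste0("missing column(s): ", paste(missing, collapse = ", ")))
  else if (nrow(object) > 0L) {
    if (anyDuplicated(object$marker_id))
      msg <- c(msg, "marker_id must be unique")
    ## one-vs-two panel markers need a single diagnostic species and two
    ## distinct alleles; three-way markers may be panel-graded by choice
    pg <- which(object$panel_grade & object$diag_species != "three-way")
    if (length(pg)) {
      if (!all(object$diag_species[pg] %in% mytilusSpecies()))
        msg <- c(msg, "panel_grade markers need a single diagnostic species")
      if (anyNA(object$diag_allele[pg]) || anyNA(object$shared_allele[pg]) ||
          any(object$diag_allele[pg] == object$shared_allele[pg]))
        msg <- c(msg, "panel_grade markers need distinct diag/shared alleles")
    }
  }
  if (length(msg)) msg else TRUE
})

## Subsetting that drops required columns degrades to a plain DataFrame
## instead of returning an invalid MarkerPanel.
setMethod("[", "MarkerPanel", function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  if (is(out, "DFrame") && !all(.MARKER_COLS %in% colnames(out)))
    out <- S4Vectors::DataFrame(out, check.names = FALSE)
  out
})

## Column replacement on a DFrame subclass tries to wrap the value in a
## length-one object of the subclass; route it through a plain DFrame.
setReplaceMethod("$", "MarkerPanel", function(x, name, value) {
  df <- S4Vectors::DataFrame(x, check.names = FALSE)
  df[[name]] <- value
  new("MarkerPanel", df)
})

setReplaceMethod("[[", "MarkerPanel", function(x, i, j, ..., value) {
  df <- S4Vectors::DataFrame(x, check.names = FALSE)
  df[[i]] <- value
  new("MarkerPanel", df)
})

#' Construct a MarkerPanel from a marker table
#'
#' @param df A data.frame or `DataFrame` with the columns documented in
#'   [MarkerPanel-class]; `loading` and `coverage` default to `NA`.
#' @return A `MarkerPanel`.
#' @export
MarkerPanel <- function(df) {
  df <- as(df, "DFrame")
  for (col in c("loading", "coverage")) {
    if (!col %in% colnames(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])  # all-NA CSV columns read as logical
  }
  if (!"feasible" %in% colnames(df)) df$feasible <- NA
  df$feasible <- as.logical(df$feasible)
  df$panel_grade <- as.logical(df$panel_grade)
  df$pos <- as.integer(df$pos)
  df <- df[, .MARKER_COLS, drop = FALSE]
  rownames(df) <- df$marker_id
  new("MarkerPanel", df)
}

## ---------------------------------------------------------------------------
## PanelGenotypes: individuals genotyped at a marker panel
## ---------------------------------------------------------------------------

#' PanelGenotypes: diploid calls of individuals at a diagnostic marker panel
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container: rows are
#' panel markers (with the full [MarkerPanel-class] columns as `rowData()`),
#' columns are individuals. Assays `a1`/`a2` hold allele calls as in
#' [RadCohort-class]; at panel-grade markers every non-missing allele must be
#' either the marker's diagnostic or shared allele. `colData()$site` carries
#' the sampling site.
#' @export
setClass("PanelGenotypes", contains = "SummarizedExperiment")

setValidity("PanelGenotypes", function(object) {
  msg <- character(0)
  if (!all(c("a1", "a2") %in% names(assays(object))))
    msg <- c(msg, "assays 'a1' and 'a2' are required")
  if (!all(.MARKER_COLS %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must carry the MarkerPanel columns")
  if (!"site" %in% colnames(colData(object)))
    msg <- c(msg, "colData must have a 'site' column")
  if (length(msg)) msg else TRUE
})

#' Construct PanelGenotypes from call matrices
#'
#' @param a1,a2 Character matrices (markers x samples) of allele calls.
#' @param panel A [MarkerPanel-class] whose rows match the rows of `a1`.
#' @param site Per-sample site labels.
#' @param colData Optional extra per-sample columns.
#' @return A [PanelGenotypes-class] object.
#' @export
PanelGenotypes <- function(a1, a2, panel, site, colData = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)), nrow(a1) == nrow(panel))
  rownames(a1) <- rownames(a2) <- panel$marker_id
  cd <- DataFrame(site = as.character(site), row.names = colnames(a1))
  if (!is.null(colData)) {
    extra <- as(colData, "DFrame")
    cd <- cbind(cd, extra[, setdiff(colnames(extra), colnames(cd)), drop = FALSE])
  }
  se <- SummarizedExperiment(
    assays = SimpleList(a1 = a1, a2 = a2),
    rowData = as(panel, "DFrame"), colData = cd)
  new("PanelGenotypes", se)
}

## ---------------------------------------------------------------------------
## GenotypeClass: the classification result for one individual
## ---------------------------------------------------------------------------

#' GenotypeClass: a pure / F1 / introgressed / unknown call
#'
#' @slot kind One of `"Pure"`, `"F1"`, `"Introgressed"`, `"Unknown"`.
#' @slot species The species set supporting the call (length 1 for Pure,
#'   2 for F1, 1--3 for Introgressed, 0 for Unknown).
#' @slot flags Zero or more of `"ambiguous"` (shared allele at an own-species
#'   locus with no second diagnostic species to explain it),
#'   `"own_shared"` (same situation under the `own_flagged` policy),
#'   `"too_many_missing"`.
#' @export
setClass("GenotypeClass",
  slots = c(kind = "character", species = "character", flags = "character"))

setValidity("GenotypeClass", function(object) {
  k <- object@kind; n <- length(object@species)
  if (length(k) != 1L || !k %in% c("Pure", "F1", "Introgressed", "Unknown"))
    return("kind must be one of Pure/F1/Introgressed/Unknown")
  if (!all(object@species %in% mytilusSpecies()))
    return("species must be drawn from Me/Mg/Mt")
  ok <- switch(k,
    Pure = n == 1L,
    F1 = n == 2L,
    Introgressed = (n >= 2L && n <= 3L) ||
      (n == 1L && length(object@flags) > 0L),
    Unknown = n == 0L)
  if (!ok) return(sprintf("species set of size %d invalid for kind %s", n, k))
  TRUE
})

#' Construct a GenotypeClass
#'
#' @param kind `"Pure"`, `"F1"`, `"Introgressed"` or `"Unknown"`.
#' @param species Species set (see [GenotypeClass-class]).
#' @param flags Optional character flags.
#' @return A `GenotypeClass`.
#' @export
#' @examples
#' genotypeClass("F1", c("Me", "Mt"))
genotypeClass <- function(kind, species = character(0), flags = character(0)) {
  new("GenotypeClass", kind = kind,
      species = unique(as.character(species)), flags = as.character(flags))
}

## ---------------------------------------------------------------------------
## Small configuration value classes
## ---------------------------------------------------------------------------

#' Thresholds for the informative / diagnostic marker filters
#'
#' @param maxSnps Maximum SNPs per retained locus (default 3).
#' @param minAlleles,maxAlleles Allowed range of distinct alleles per SNP
#'   (defaults 1 and 3; 1 admits loci monomorphic in the cohort).
#' @param minSampleFraction Minimum fraction of all samples in which a locus
#'   must be genotyped (default 0.5, boundary inclusive).
#' @param minSpeciesSampleFraction Minimum fraction of a species' samples in
#'   which a SNP must be genotyped for that species' fixation to be assessed
#'   (default 0.5, boundary inclusive).
#' @return A `FilterThresholds` object.
#' @export
filterThresholds <- function(maxSnps = 3L, minAlleles = 1L, maxAlleles = 3L,
                             minSampleFraction = 0.5,
                             minSpeciesSampleFraction = 0.5) {
  new("FilterThresholds", maxSnps = as.integer(maxSnps),
      minAlleles = as.integer(minAlleles), maxAlleles = as.integer(maxAlleles),
      minSampleFraction = as.numeric(minSampleFraction),
      minSpeciesSampleFraction = as.numeric(minSpeciesSampleFraction))
}

#' @rdname filterThresholds
#' @export
setClass("FilterThresholds",
  slots = c(maxSnps = "integer", minAlleles = "integer", maxAlleles = "integer",
            minSampleFraction = "numeric", minSpeciesSampleFraction = "numeric"))

setValidity("FilterThresholds", function(object) {
  f <- function(x) length(x) == 1L && !is.na(x)
  if (!f(object@maxSnps) || object@maxSnps < 1L)
    return("invalid 'maxSnps': must be a positive integer")
  if (!f(object@minAlleles) || object@minAlleles < 1L)
    return("invalid 'minAlleles': must be a positive integer")
  if (!f(object@maxAlleles) || object@maxAlleles < object@minAlleles)
    return("invalid 'maxAlleles': must be >= minAlleles")
  for (fld in c("minSampleFraction", "minSpeciesSampleFraction")) {
    v <- slot(object, fld)
    if (!f(v) || v <= 0 || v > 1)
      return(sprintf("invalid '%s': must be in (0, 1]", fld))
  }
  TRUE
})

#' Policy for panel-based classification
#'
#' @param maxMissingLoci Maximum missing panel calls tolerated before an
#'   individual is returned as `Unknown` (default 2).
#' @param ambiguousSharedRule How to treat a shared allele observed at an
#'   own-species locus when no second diagnostic species explains it:
#'   `"three_way"` (default) widens the call to `Introgressed(MeMgMt)` with
#'   an `"ambiguous"` flag; `"own_flagged"` keeps the single-species set and
#'   flags `"own_shared"`.
#' @return A `ClassifyPolicy` object.
#' @export
classifyPolicy <- function(maxMissingLoci = 2L,
                           ambiguousSharedRule = c("three_way", "own_flagged")) {
  new("ClassifyPolicy", maxMissingLoci = as.integer(maxMissingLoci),
      ambiguousSharedRule = match.arg(ambiguousSharedRule))
}

#' @rdname classifyPolicy
#' @export
setClass("ClassifyPolicy",
  slots = c(maxMissingLoci = "integer", ambiguousSharedRule = "character"))

setValidity("ClassifyPolicy", function(object) {
  if (length(object@maxMissingLoci) != 1L || is.na(object@maxMissingLoci) ||
      object@maxMissingLoci < 0L)
    return("invalid 'maxMissingLoci': must be a non-negative integer")
  if (!object@ambiguousSharedRule %in% c("three_way", "own_flagged"))
    return("invalid 'ambiguousSharedRule'")
  TRUE
})

#' Expected Me15/16 amplicon sizes
#'
#' Fragment sizes of the Me15/16 PCR marker: 180 bp for *M. edulis*, 168 bp
#' for *M. trossulus* and 126 bp for *M. galloprovincialis*. Sizes are read
#' off agarose gels, so matches are accepted within `toleranceBp`.
#'
#' @param sizes Named numeric vector of expected sizes (bp) per species.
#' @param toleranceBp Matching tolerance in bp (default 3).
#' @return A `SizeTable` object.
#' @export
#' @examples
#' sizeTable()
sizeTable <- function(sizes = c(Me = 180, Mt = 168, Mg = 126), toleranceBp = 3L) {
  new("SizeTable", sizes = sizes, toleranceBp = as.integer(toleranceBp))
}

#' @rdname sizeTable
#' @export
setClass("SizeTable",
  slots = c(sizes = "numeric", toleranceBp = "integer"))

setValidity("SizeTable", function(object) {
  s <- object@sizes
  if (is.null(names(s)) || !all(names(s) %in% mytilusSpecies()))
    return("invalid 'sizes': must be named by species Me/Mg/Mt")
  if (any(s <= 0)) return("invalid 'sizes': must be positive")
  if (length(s) >= 2L) {
    gaps <- abs(diff(sort(s)))
    if (any(gaps <= 2 * object@toleranceBp))
      return("invalid 'sizes': expected sizes must differ by more than 2x tolerance")
  }
  if (object@toleranceBp < 0L) return("invalid 'toleranceBp': must be >= 0")
  TRUE
})
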