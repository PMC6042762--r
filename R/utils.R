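## Internal constants and small helpers shared across the package.

#' The three species of the Mytilus complex
#'
#' Canonical two-letter abbreviations used throughout the package:
#' `Me` = *M. edulis*, `Mg` = *M. galloprovincialis*, `Mt` = *M. trossulus*.
#'
#' @return Character vector `c("Me", "Mg", "Mt")`.
#' @export
#' @examples
#' mytilusSpecies()
mytilusSpecies <- function() c("Me", "Mg", "Mt")

## Composite class labels in stable output order. "MtMg" (not "MgMt") is the
## conventional label for the galloprovincialis/trossulus composite.
.COMPOSITE_LABELS <- c("Me", "Mg", "Mt", "MeMg", "MeMt", "MtMg", "MeMgMt")

.NUCLEOTIDES <- c("A", "C", "G", "T")

#' Canonical label for a set of species
#'
#' Maps a subset of [mytilusSpecies()] to its composite genotype-class label
#' (`"Me"`, `"MeMg"`, `"MeMt"`, `"MtMg"`, `"MeMgMt"`, ...).
#'
#' @param species Character vector, a subset of `c("Me","Mg","Mt")`.
#' @return A single character label.
#' @export
#' @examples
#' compositeLabel(c("Mt", "Mg"))  # "MtMg"
compositeLabel <- function(species) {
  species <- unique(species)
  bad <- setdiff(species, mytilusSpecies())
  if (length(bad) > 0L)
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  if (length(species) == 0L) return("Unknown")
  key <- paste(sort(match(species, mytilusSpecies())), collapse = "")
  switch(key,
    "1" = "Me", "2" = "Mg", "3" = "Mt",
    "12" = "MeMg", "13" = "MeMt", "23" = "MtMg",
    "123" = "MeMgMt")
}

## Inverse of compositeLabel().
.speciesFromLabel <- function(label) {
  switch(label,
    Me = "Me", Mg = "Mg", Mt = "Mt",
    MeMg = c("Me", "Mg"), MeMt = c("Me", "Mt"), MtMg = c("Mg", "Mt"),
    MeMgMt = c("Me", "Mg", "Mt"),
    Unknown = character(0),
    stop("unknown class label: ", label))
}

## Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
## state afterwards so simulation never perturbs the session stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## MD5 of a serialized R object; used for provenance headers. Serialization
## version is pinned so hashes are stable across sessions.
.configHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(tmp))
}

.pkgVersion <- function() {
  as.character(utils::packageVersion("MytilusPanel"))
}

## Provenance header lines for text artifacts (no timestamp: re-running with
## unchanged inputs must be byte-identical).
.provenanceHeader <- function(configHash = NA_character_, seed = NA_integer_,
                              comment = "#") {
  paste0(comment, " MytilusPanel v", .pkgVersion(),
         "; config=", configHash, "; seed=", seed)
}

## Stopifnot-with-field-name validation helper: msg names the failing field.
.checkField <- function(ok, field, what) {
  if (!isTRUE(ok)) stop("invalid '", field, "': ", what, call. = FALSE)
}
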