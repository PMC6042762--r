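## Single-locus Me15/16 genotyping: species assignment from PCR amplicon
## fragment sizes (180 bp M. edulis, 168 bp M. trossulus, 126 bp
## M. galloprovincialis; hybrids show two sizes).

.ME15_CLASSES <- c("Me", "Mg", "Mt", "Me/Mg", "Me/Mt", "Mg/Mt", "Unknown")

#' Classify one sample from Me15/16 fragment sizes
#'
#' Matches each observed fragment size to the expected per-species sizes
#' within the table's tolerance. One matched size gives a species
#' homozygote; two sizes matching two species give a heterozygote (hybrid)
#' composite; anything else is `Unknown`.
#'
#' @param sizes Numeric vector of distinct fragment sizes (bp) observed for
#'   one diploid sample; empty means no amplification.
#' @param table A [sizeTable()].
#' @return A character label (`"Me"`, `"Mg"`, `"Mt"`, `"Me/Mg"`, `"Me/Mt"`,
#'   `"Mg/Mt"` or `"Unknown"`) with a `"flag"` attribute:
#'   `"no_amplification"` (empty input), `"contamination"` (three or more
#'   distinct sizes), `"unmatched_size"` (a size matching no species), or
#'   `NA` when clean.
#' @export
#' @examples
#' classifyMe15(c(180, 168))   # Me/Mt heterozygote
#' classifyMe15(126)           # Mg homozygote
classifyMe15 <- function(sizes, table = sizeTable()) {
  validObject(table)
  sizes <- unique(sizes[!is.na(sizes)])
  flag <- NA_character_
  if (length(sizes) == 0L)
    return(structure("Unknown", flag = "no_amplification"))
  if (any(sizes <= 0)) stop("fragment sizes must be positive")
  if (length(sizes) > 2L)
    return(structure("Unknown", flag = "contamination"))
  hit <- vapply(sizes, function(s) {
    d <- abs(table@sizes - s)
    if (min(d) <= table@toleranceBp) names(table@sizes)[which.min(d)]
    else NA_character_
  }, character(1))
  if (anyNA(hit))
    return(structure("Unknown", flag = "unmatched_size"))
  hit <- unique(hit)
  lab <- if (length(hit) == 1L) hit
         else paste(sort(factor(hit, levels = mytilusSpecies())), collapse = "/")
  structure(lab, flag = flag)
}

#' Summarize Me15/16 genotypes per site
#'
#' Classifies every sample with [classifyMe15()] and tabulates genotype
#' classes per site. Each sample lands in exactly one cell; row sums equal
#' the per-site sample counts.
#'
#' @param profiles A data.frame with columns `sample_id`, `site` and either
#'   `size1`/`size2` columns (`NA` allowed) or a list-column `sizes`.
#' @param table A [sizeTable()].
#' @return A data.frame with one row per site and columns `site`, `Me`,
#'   `Mg`, `Mt`, `Me/Mg`, `Me/Mt`, `Mg/Mt`, `Unknown`.
#' @export
#' @examples
#' prof <- data.frame(sample_id = c("s1", "s2"), site = "LET",
#'                    size1 = c(168, 168), size2 = c(NA, 180))
#' summarizeMe15(prof)
summarizeMe15 <- function(profiles, table = sizeTable()) {
  if (nrow(profiles) == 0L) {
    out <- as.data.frame(setNames(
      rep(list(integer(0)), length(.ME15_CLASSES)), .ME15_CLASSES),
      check.names = FALSE)
    return(cbind(data.frame(site = character(0)), out))
  }
  if (!all(c("sample_id", "site") %in% names(profiles)))
    stop("profiles need 'sample_id' and 'site' columns")
  sizesOf <- if ("sizes" %in% names(profiles)) profiles$sizes
             else Map(c, profiles$size1,
                     if ("size2" %in% names(profiles)) profiles$size2 else NA)
  labels <- vapply(sizesOf, function(s) as.character(classifyMe15(s, table)),
                   character(1))
  tab <- table(site = profiles$site,
               class = factor(labels, levels = .ME15_CLASSES))
  out <- as.data.frame.matrix(tab)
  cbind(data.frame(site = rownames(out)), out, row.names = NULL)
}

#' Read an Me15/16 fragment-size CSV
#'
#' Expected columns: `sample_id`, `site`, `size1` and optionally `size2`
#' (blank/NA when only one band was observed).
#'
#' @param path CSV file path.
#' @return A data.frame of amplicon profiles for [summarizeMe15()].
#' @export
readMe15Csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "site", "size1")
  if (!all(need %in% names(df)))
    stop("Me15 CSV needs columns: ", paste(need, collapse = ", "))
  df
}
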