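## Bundled validation inputs: per-site genotype-class counts from the
## published Me15/16 screen and the 12-assay SNP panel validation of seven
## Mytilus sampling sites. These are summary counts, used as inputs for
## reconstructing site summaries from canonical representative genotypes.

#' Reference Me15/16 site counts
#'
#' Per-site genotype counts from a single-locus Me15/16 amplicon screen of
#' seven Mytilus populations: Loch Ryan (LR), Rascarrel Bay (RB), Montrose
#' (MON), Bay of Piran (BP), Penn Cove (PC), Bras d'Or Lake (BDL) and Loch
#' Etive (LET). Columns are the three homozygote classes and the three
#' two-species heterozygote classes.
#'
#' @return A data.frame with one row per site and columns
#'   `Me`, `Mg`, `Mt`, `Me/Mg`, `Me/Mt`, `Mg/Mt`.
#' @export
#' @examples
#' me15ReferenceCounts()
me15ReferenceCounts <- function() {
  df <- data.frame(
    site = c("LR", "RB", "MON", "BP", "PC", "BDL", "LET"),
    Me   = c(49, 50, 48,  0,  1,  0,  0),
    Mg   = c( 0,  0,  0, 50,  0,  0,  0),
    Mt   = c( 0,  0,  0,  0,  7, 40, 20),
    MeMg = c( 1,  0,  2,  0,  0,  0,  0),
    MeMt = c( 0,  0,  0,  0,  0, 10,  0),
    MgMt = c( 0,  0,  0,  0,  0,  0,  0),
    check.names = FALSE)
  names(df) <- c("site", "Me", "Mg", "Mt", "Me/Mg", "Me/Mt", "Mg/Mt")
  df
}

#' Reference SNP-panel site counts
#'
#' Per-site genotype-class counts from the 12-assay diagnostic SNP panel
#' validation of the same seven Mytilus populations (see
#' [me15ReferenceCounts()] for site abbreviations). Columns are the three
#' pure classes and the four introgressed composite classes; no F1 hybrids
#' were observed.
#'
#' @return A data.frame with one row per site and columns
#'   `Me`, `Mg`, `Mt`, `MeMg`, `MeMt`, `MtMg`, `MeMgMt`.
#' @export
#' @examples
#' panelReferenceCounts()
panelReferenceCounts <- function() {
  data.frame(
    site   = c("LR", "RB", "MON", "BP", "PC", "BDL", "LET"),
    Me     = c(48, 49, 44,  0,  1,  0,  0),
    Mg     = c( 0,  0,  0, 50,  0,  0,  0),
    Mt     = c( 0,  0,  0,  0,  7, 12,  5),
    MeMg   = c( 2,  0,  3,  0,  0,  0,  0),
    MeMt   = c( 0,  1,  2,  0,  0,  5,  6),
    MtMg   = c( 0,  0,  0,  0,  0, 10,  4),
    MeMgMt = c( 0,  0,  1,  0,  0, 23,  5))
}
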