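## Readers and writers: VCF v4.2, FASTA, sample sheets, genotype-matrix and
## KASP-style CSVs, truth labels. CSV dialect: UTF-8, comma-separated,
## alleles within a call joined by "/" (e.g. "A/G"), missing as empty
## string; provenance lines start with "#".

#' Write a cohort to VCF v4.2 (+ sample sheet and FASTA)
#'
#' One record per SNP; the locus id travels in the `LOCUS` INFO key and the
#' 0-based SNP offset is emitted as the 1-based `POS` with `CHROM` set to
#' the locus id. Genotypes are unphased diploid `GT` fields (`./.` for
#' missing). The REF allele is the consensus base at the SNP when consensus
#' sequences are present, otherwise the majority allele.
#'
#' @param cohort A [RadCohort-class].
#' @param path Output VCF path (plain text).
#' @param sampleSheet Optional path for a companion sample-sheet CSV
#'   (`sample_id`, `site`, `species`).
#' @param fasta Optional path for the locus consensus FASTA.
#' @param configHash,seed Optional provenance fields for the header.
#' @return Invisibly, `path`.
#' @export
writeCohortVcf <- function(cohort, path, sampleSheet = NULL, fasta = NULL,
                           configHash = NA_character_, seed = NA_integer_) {
  a1 <- assay(cohort, "a1"); a2 <- assay(cohort, "a2")
  rd <- rowData(cohort)
  cons <- consensusSeqs(cohort)
  nSnp <- nrow(cohort)

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=MytilusPanel_v", .pkgVersion()),
    paste0("##mytilusPanel_config=", configHash),
    paste0("##mytilusPanel_seed=", seed),
    "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"RAD locus identifier\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort)), collapse = "\t"))

  records <- vapply(seq_len(nSnp), function(i) {
    x1 <- a1[i, ]; x2 <- a2[i, ]
    obs <- unique(stats::na.omit(c(x1, x2)))
    ref <- if (length(cons) > 0L) {
      as.character(Biostrings::subseq(cons[[rd$locus[i]]],
                                      rd$pos[i] + 1L, rd$pos[i] + 1L))
    } else {
      tab <- sort(table(c(x1, x2)), decreasing = TRUE)
      names(tab)[1L]
    }
    alt <- setdiff(obs, ref)
    alleles <- c(ref, alt)
    gt <- ifelse(is.na(x1), "./.",
                 paste0(match(x1, alleles) - 1L, "/", match(x2, alleles) - 1L))
    paste(c(rd$locus[i], rd$pos[i] + 1L, rownames(cohort)[i], ref,
            if (length(alt)) paste(alt, collapse = ",") else ".",
            ".", "PASS", paste0("LOCUS=", rd$locus[i]), "GT", gt),
          collapse = "\t")
  }, character(1))

  writeLines(c(header, records), path)
  if (!is.null(sampleSheet))
    writeSampleSheet(cohort, sampleSheet, configHash = configHash, seed = seed)
  if (!is.null(fasta) && length(cons) > 0L)
    writeXStringSet(cons, fasta)
  invisible(path)
}

#' Write the per-sample sheet CSV
#'
#' @param cohort A [RadCohort-class].
#' @param path Output CSV path.
#' @param configHash,seed Optional provenance fields.
#' @return Invisibly, `path`.
#' @export
writeSampleSheet <- function(cohort, path, configHash = NA_character_,
                             seed = NA_integer_) {
  df <- data.frame(sample_id = colnames(cohort),
                   site = colData(cohort)$site,
                   species = colData(cohort)$species)
  .writeCsvWithHeader(df, path, configHash, seed)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with columns `sample_id`, `site`, `species`.
#' @return A data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  need <- c("sample_id", "site", "species")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  df
}

#' Read a VCF into a RadCohort
#'
#' Parses a VCF v4.2 with diploid `GT` fields (via `vcfR`), groups records
#' into loci by the `LOCUS` INFO key (falling back to `CHROM`), converts
#' 1-based positions to 0-based offsets, and preserves `./.` as missing.
#'
#' @param path VCF file.
#' @param sampleSheet Path of, or data.frame from, [readSampleSheet()];
#'   must cover every VCF sample.
#' @param fasta Optional consensus FASTA (names = locus ids); required for
#'   downstream assay feasibility screening.
#' @return A [RadCohort-class].
#' @export
readCohortVcf <- function(path, sampleSheet, fasta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(v@gt) == 0L) stop("VCF contains no genotype records")
  gt <- v@gt[, -1L, drop = FALSE]  # drop FORMAT column
  vcfSamples <- colnames(gt)

  sheet <- if (is.character(sampleSheet)) readSampleSheet(sampleSheet)
           else sampleSheet
  missing <- setdiff(vcfSamples, sheet$sample_id)
  if (length(missing))
    stop("sample(s) in VCF absent from sample sheet: ",
         paste(missing, collapse = ", "))
  sheet <- sheet[match(vcfSamples, sheet$sample_id), ]

  ## locus id: LOCUS INFO key, else CHROM
  info <- fix[, "INFO"]
  locus <- sub("^.*LOCUS=([^;]+).*$", "\\1", info)
  noKey <- !grepl("LOCUS=", info)
  locus[noKey] <- fix[noKey, "CHROM"]
  pos <- as.integer(fix[, "POS"]) - 1L

  ## header line count for error messages pointing at file lines
  nHeader <- length(v@meta) + 1L

  alleleList <- lapply(seq_len(nrow(fix)), function(i) {
    alt <- fix[i, "ALT"]
    alts <- if (is.na(alt) || alt == ".") character(0)
            else strsplit(alt, ",", fixed = TRUE)[[1L]]
    c(fix[i, "REF"], alts)
  })

  n <- nrow(gt); m <- ncol(gt)
  a1 <- matrix(NA_character_, n, m, dimnames = list(NULL, vcfSamples))
  a2 <- a1
  for (i in seq_len(n)) {
    tok <- sub(":.*$", "", gt[i, ])
    missingGt <- is.na(tok) | tok %in% c("./.", ".", ".|.")
    parts <- strsplit(tok[!missingGt], "[/|]")
    bad <- vapply(parts, function(p)
      length(p) != 2L || anyNA(suppressWarnings(as.integer(p))), logical(1))
    if (any(bad))
      stop(sprintf("malformed GT token '%s' at VCF line %d",
                   tok[!missingGt][bad][1L], nHeader + i))
    idx <- vapply(parts, function(p) as.integer(p), integer(2))
    alleles <- alleleList[[i]]
    if (length(parts) && max(idx) + 1L > length(alleles))
      stop(sprintf("GT allele index out of range at VCF line %d", nHeader + i))
    a1[i, !missingGt] <- alleles[idx[1L, ] + 1L]
    a2[i, !missingGt] <- alleles[idx[2L, ] + 1L]
  }

  cons <- if (!is.null(fasta)) readDNAStringSet(fasta) else DNAStringSet()
  if (length(cons) > 0L)
    names(cons) <- sub("\\s.*$", "", names(cons))
  RadCohort(a1 = a1, a2 = a2, locus = locus, pos = pos,
            site = sheet$site, species = sheet$species, consensus = cons)
}

#' Write a genotype-matrix CSV
#'
#' Rows are samples, columns are markers (`<locus>_<pos>` or assay names),
#' cells are `"A/G"`-style diploid calls, missing as empty string.
#'
#' @param x A [RadCohort-class] or [PanelGenotypes-class].
#' @param path Output CSV path.
#' @param configHash,seed Optional provenance fields.
#' @return Invisibly, `path`.
#' @export
writeGenotypeCsv <- function(x, path, configHash = NA_character_,
                             seed = NA_integer_) {
  a1 <- assay(x, "a1"); a2 <- assay(x, "a2")
  calls <- matrix(ifelse(is.na(a1), "", paste0(a1, "/", a2)),
                  nrow = nrow(a1), dimnames = dimnames(a1))
  df <- data.frame(sample_id = colnames(x), site = colData(x)$site,
                   t(calls), check.names = FALSE)
  .writeCsvWithHeader(df, path, configHash, seed)
}

#' Read a KASP-style genotype CSV into PanelGenotypes
#'
#' Expected layout: `sample_id`, `site`, then one column per assay holding
#' `"A/G"`-style calls (empty/NA = missing). Assay columns must match the
#' panel's `marker_id`s.
#'
#' @param path CSV file.
#' @param panel A [MarkerPanel-class].
#' @return A [PanelGenotypes-class].
#' @export
readKaspCsv <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "site")
  if (!all(need %in% names(df)))
    stop("KASP CSV needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(panel$marker_id, names(df))
  if (length(missing))
    stop("KASP CSV lacks assay column(s): ", paste(missing, collapse = ", "))
  calls <- t(as.matrix(df[, panel$marker_id, drop = FALSE]))
  split1 <- sub("/.*$", "", calls); split2 <- sub("^.*/", "", calls)
  badTok <- !is.na(calls) & !grepl("^[ACGT]/[ACGT]$", calls)
  if (any(badTok))
    stop("malformed call(s): ", paste(unique(calls[badTok]), collapse = ", "))
  a1 <- matrix(ifelse(is.na(calls), NA_character_, split1), nrow = nrow(calls),
               dimnames = list(panel$marker_id, df$sample_id))
  a2 <- matrix(ifelse(is.na(calls), NA_character_, split2), nrow = nrow(calls),
               dimnames = list(panel$marker_id, df$sample_id))
  PanelGenotypes(a1 = a1, a2 = a2, panel = panel, site = df$site)
}

#' Write a marker table CSV
#'
#' Columns mirror the per-species allele layout of published diagnostic
#' marker tables: locus, position, alleles per species (`N` when
#' unassessed), diagnostic species, panel grade, feasibility, loading.
#'
#' @param panel A [MarkerPanel-class].
#' @param path Output CSV path.
#' @param configHash,seed Optional provenance fields.
#' @return Invisibly, `path`.
#' @export
writeMarkerCsv <- function(panel, path, configHash = NA_character_,
                           seed = NA_integer_) {
  .writeCsvWithHeader(as.data.frame(panel), path, configHash, seed)
}

#' Read a marker table CSV
#'
#' @param path CSV written by [writeMarkerCsv()].
#' @return A [MarkerPanel-class].
#' @export
readMarkerCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  MarkerPanel(df)
}

#' Write truth labels of a simulated cohort
#'
#' @param cohort A simulated [RadCohort-class].
#' @param path Output CSV path.
#' @param configHash,seed Optional provenance fields.
#' @return Invisibly, `path`.
#' @export
writeTruthCsv <- function(cohort, path, configHash = NA_character_,
                          seed = NA_integer_) {
  .writeCsvWithHeader(as.data.frame(truthLabels(cohort)), path,
                      configHash, seed)
}

## provenance-headed CSV writer (header line starts with '#', so readers
## use comment.char = "#")
.writeCsvWithHeader <- function(df, path, configHash = NA_character_,
                                seed = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(configHash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
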