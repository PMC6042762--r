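## Umbrella pipeline: simulation (or VCF input) -> informative filter ->
## diagnostic selection -> ranking -> panel classification, with provenance
## headers and a logged marker funnel.

#' Pipeline configuration
#'
#' @param thresholds A [filterThresholds()].
#' @param policy A [classifyPolicy()].
#' @param sim Optional [simConfig()]; when present the cohort is simulated,
#'   otherwise `vcf`/`sampleSheet` are read.
#' @param vcf,sampleSheet,fasta Input paths (used when `sim` is `NULL`).
#' @param outDir Output directory (created if absent).
#' @param panelSize Number of top-ranked feasible panel-grade markers kept
#'   for classification (`NULL` = keep all).
#' @param requireAllSpecies,threeWayPanel,minFlank Passed to
#'   [selectDiagnostic()].
#' @param logLevel `"info"` (stage messages to stderr) or `"quiet"`.
#' @return A `PipelineConfig` list (classed).
#' @export
pipelineConfig <- function(thresholds = filterThresholds(),
                           policy = classifyPolicy(), sim = NULL,
                           vcf = NULL, sampleSheet = NULL, fasta = NULL,
                           outDir = tempfile("mytilus_run_"),
                           panelSize = NULL, requireAllSpecies = FALSE,
                           threeWayPanel = FALSE, minFlank = 20L,
                           logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  if (is.null(sim) && (is.null(vcf) || is.null(sampleSheet)))
    stop("invalid 'sim': either a simConfig or vcf+sampleSheet paths required")
  if (!is.null(sim)) validObject(sim)
  validObject(thresholds); validObject(policy)
  structure(list(thresholds = thresholds, policy = policy, sim = sim,
                 vcf = vcf, sampleSheet = sampleSheet, fasta = fasta,
                 outDir = outDir, panelSize = panelSize,
                 requireAllSpecies = requireAllSpecies,
                 threeWayPanel = threeWayPanel, minFlank = as.integer(minFlank),
                 logLevel = logLevel),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `thresholds` (fields of [filterThresholds()]),
#' `policy` (fields of [classifyPolicy()]), `sim` (fields of [simConfig()];
#' populations as `site: {spec: Me, n: 10}`), `vcf`, `sample_sheet`,
#' `fasta`, `out_dir`, `panel_size`, `require_all_species`,
#' `three_way_panel`, `min_flank`, `log_level`.
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(filterThresholds, as.list(y$thresholds))
  pol <- do.call(classifyPolicy, as.list(y$policy))
  sim <- NULL
  if (!is.null(y$sim)) {
    simArgs <- y$sim
    if (!is.null(simArgs$populations)) {
      simArgs$populations <- lapply(simArgs$populations, function(p) {
        ## YAML 1.1 reads a bare key "n" as boolean FALSE; undo that
        names(p)[names(p) %in% c("FALSE", "no")] <- "n"
        spec <- if (is.list(p$spec)) do.call(hybridSpec, p$spec) else p$spec
        list(spec = spec, n = as.integer(p$n))
      })
    }
    sim <- do.call(simConfig, simArgs)
  }
  pipelineConfig(
    thresholds = thr, policy = pol, sim = sim,
    vcf = y$vcf, sampleSheet = y$sample_sheet, fasta = y$fasta,
    outDir = if (is.null(y$out_dir)) tempfile("mytilus_run_") else y$out_dir,
    panelSize = y$panel_size,
    requireAllSpecies = isTRUE(y$require_all_species),
    threeWayPanel = isTRUE(y$three_way_panel),
    minFlank = if (is.null(y$min_flank)) 20L else y$min_flank,
    logLevel = if (is.null(y$log_level)) "info" else y$log_level)
}

#' Run the discovery-to-classification pipeline
#'
#' Stages: (1) obtain the cohort (simulate or read VCF); (2) filter to
#' informative loci; (3) select diagnostic SNPs and grade/screen them;
#' (4) rank markers by discriminant loading on the species-labeled
#' reference samples; (5) genotype all individuals at the panel and
#' classify them; (6) write artifacts (cohort VCF + sample sheet + FASTA,
#' marker table, ranked panel, per-sample classes, site summary, ancestry
#' fractions, distance matrix) with provenance headers. The marker funnel
#' (input loci, informative, diagnostic, panel-grade) is logged. A failing
#' stage aborts with the stage name; artifacts written so far remain, plus
#' an `INCOMPLETE` flag file naming the failed stage.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the cohort, informative subset, markers,
#'   panel, classes, site summary, ancestry table and the output paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$sim)) config$sim@seed else NA_integer_
  ## hash the analysis-relevant configuration only (not paths/log level), so
  ## identical analyses give identical provenance headers
  hash <- .configHash(config[c("thresholds", "policy", "sim", "panelSize",
                               "requireAllSpecies", "threeWayPanel",
                               "minFlank")])
  logi <- function(...) {
    if (config$logLevel == "info") message("[MytilusPanel] ", sprintf(...))
  }
  out <- function(f) file.path(config$outDir, f)
  stage <- "input"
  onFail <- function(e) {
    writeLines(paste0("INCOMPLETE at stage: ", stage, " — ",
                      conditionMessage(e)), out("INCOMPLETE"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    cohort <- if (!is.null(config$sim)) simulateCohort(config$sim)
              else readCohortVcf(config$vcf, config$sampleSheet, config$fasta)
    nLociIn <- length(unique(rowData(cohort)$locus))
    logi("input: %d loci, %d samples", nLociIn, ncol(cohort))
    writeCohortVcf(cohort, out("cohort.vcf"), sampleSheet = out("samples.csv"),
                   fasta = out("loci.fa"), configHash = hash, seed = seed)
    if (!is.null(config$sim)) writeTruthCsv(cohort, out("truth.csv"), hash, seed)

    stage <- "filter_informative"
    ref <- cohort[, !is.na(sampleSpecies(cohort))]
    informative <- filterInformative(ref, config$thresholds)
    nInf <- length(unique(rowData(informative)$locus))
    logi("informative: %d of %d loci retained", nInf, nLociIn)

    stage <- "select_diagnostic"
    markers <- selectDiagnostic(informative, config$thresholds,
                                requireAllSpecies = config$requireAllSpecies,
                                threeWayPanel = config$threeWayPanel,
                                minFlank = config$minFlank)
    nPanelGrade <- sum(markers$panel_grade, na.rm = TRUE)
    logi("diagnostic: %d SNPs (%d panel-grade)", nrow(markers), nPanelGrade)
    writeMarkerCsv(markers, out("markers.csv"), hash, seed)

    stage <- "rank_markers"
    candidates <- markers[markers$panel_grade &
                          markers$diag_species %in% mytilusSpecies() &
                          (is.na(markers$feasible) | markers$feasible), ]
    if (nrow(candidates) == 0L) stop("no feasible panel-grade markers found")
    pgRef <- panelGenotypesFromCohort(informative, MarkerPanel(candidates))
    ranked <- rankMarkers(MarkerPanel(candidates), pgRef,
                          groups = sampleSpecies(informative))
    if (!is.null(config$panelSize))
      ranked <- MarkerPanel(ranked[seq_len(min(config$panelSize, nrow(ranked))), ])
    logi("panel: %d markers after ranking%s", nrow(ranked),
         if (!is.null(config$panelSize)) sprintf(" (top %d kept)",
                                                 config$panelSize) else "")
    writeMarkerCsv(ranked, out("panel.csv"), hash, seed)

    stage <- "classify"
    pgAll <- panelGenotypesFromCohort(cohort, ranked)
    classes <- classifyCohort(pgAll, policy = config$policy)
    summary <- summarizeSites(classes)
    ancestry <- ancestryFractions(pgAll)
    .writeCsvWithHeader(classes, out("classes.csv"), hash, seed)
    .writeCsvWithHeader(summary, out("site_summary.csv"), hash, seed)
    .writeCsvWithHeader(ancestry, out("ancestry.csv"), hash, seed)
    writePhylipDist(distanceMatrix(pgAll), out("distances.phy"))
    logi("classified %d individuals at %d sites", nrow(classes),
         nrow(summary))

    invisible(list(cohort = cohort, informative = informative,
                   markers = markers, panel = ranked, genotypes = pgAll,
                   classes = classes, siteSummary = summary,
                   ancestry = ancestry, outDir = config$outDir))
  }, error = onFail)
}

#' Extract panel genotypes from a RAD cohort
#'
#' Subsets a cohort's SNP calls to the loci/positions of a marker panel and
#' repackages them as [PanelGenotypes-class].
#'
#' @param cohort A [RadCohort-class].
#' @param panel A [MarkerPanel-class]; every marker must exist in the
#'   cohort.
#' @return A [PanelGenotypes-class].
#' @export
panelGenotypesFromCohort <- function(cohort, panel) {
  key <- paste0(rowData(cohort)$locus, "_", rowData(cohort)$pos)
  idx <- match(paste0(panel$locus, "_", panel$pos), key)
  if (anyNA(idx))
    stop("marker(s) absent from cohort: ",
         paste(panel$marker_id[is.na(idx)], collapse = ", "))
  PanelGenotypes(
    a1 = assay(cohort, "a1")[idx, , drop = FALSE],
    a2 = assay(cohort, "a2")[idx, , drop = FALSE],
    panel = panel, site = colData(cohort)$site,
    colData = colData(cohort)[, setdiff(colnames(colData(cohort)), "site"),
                              drop = FALSE])
}
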