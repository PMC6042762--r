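#' @rdname consensusSeqs
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))

#' @rdname sampleSpecies
#' @export
setGeneric("sampleSpecies", function(x) standardGeneric("sampleSpecies"))

#' @rdname sampleSites
#' @export
setGeneric("sampleSites", function(x) standardGeneric("sampleSites"))

#' @rdname truthLabels
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname markerPanel
#' @export
setGeneric("markerPanel", function(x) standardGeneric("markerPanel"))

#' @rdname alleleCalls
#' @export
setGeneric("alleleCalls", function(x, which = c("a1", "a2"))
  standardGeneric("alleleCalls"))

#' @rdname dosageMatrix
#' @export
setGeneric("dosageMatrix", function(x, ...) standardGeneric("dosageMatrix"))

#' @rdname classLabel
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
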