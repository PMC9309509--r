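#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("nsaf", function(x) standardGeneric("nsaf"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("producingGroup", function(x) standardGeneric("producingGroup"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("orfIndex", function(x) standardGeneric("orfIndex"))

#' @rdname ProteomineExperiment-accessors
#' @export
setGeneric("contigId", function(x) standardGeneric("contigId"))

#' @rdname computeNSAF
#' @export
setGeneric("computeNSAF", function(x, ...) standardGeneric("computeNSAF"))

#' @rdname imputeAbundance
#' @export
setGeneric("imputeAbundance", function(x, ...) standardGeneric("imputeAbundance"))

#' @rdname scoreNodes
#' @export
setGeneric("scoreNodes", function(x, ...) standardGeneric("scoreNodes"))

#' @rdname nodeTable
#' @export
setGeneric("nodeTable", function(x, ...) standardGeneric("nodeTable"))

#' @rdname findPBCs
#' @export
setGeneric("findPBCs", function(x, ...) standardGeneric("findPBCs"))

#' @rdname PBCSet-accessors
#' @export
setGeneric("pbcTable", function(x, ...) standardGeneric("pbcTable"))

#' @rdname PBCSet-accessors
#' @export
setGeneric("annotatedPBCs", function(x, ...) standardGeneric("annotatedPBCs"))

#' @rdname PBCSet-accessors
#' @export
setGeneric("candidatePBCs", function(x, ...) standardGeneric("candidatePBCs"))

#' @rdname PBCSet-accessors
#' @export
setGeneric("pbcSummary", function(x) standardGeneric("pbcSummary"))

#' @rdname pbcRanges
#' @export
setGeneric("pbcRanges", function(x, ...) standardGeneric("pbcRanges"))
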