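#' @include AllClasses.R
NULL

#' @rdname MilkExperiment-class
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname MilkExperiment-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname MilkExperiment-class
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname MilkExperiment-class
#' @export
setGeneric("otuSequences", function(x) standardGeneric("otuSequences"))

#' @rdname MilkExperiment-class
#' @export
setGeneric("otuLineage", function(x) standardGeneric("otuLineage"))

#' @rdname MilkExperiment-class
#' @export
setGeneric("isDecontaminated", function(x) standardGeneric("isDecontaminated"))

#' @rdname MockProfile-class
#' @export
setGeneric("mockTaxa", function(x) standardGeneric("mockTaxa"))

#' @rdname MockProfile-class
#' @export
setGeneric("mockAbundance", function(x) standardGeneric("mockAbundance"))

#' @rdname MockProfile-class
#' @export
setGeneric("gramFlags", function(x) standardGeneric("gramFlags"))

#' @rdname ContaminantProfile-class
#' @export
setGeneric("profileScope", function(x) standardGeneric("profileScope"))

#' @rdname ContaminantProfile-class
#' @export
setGeneric("profileMeans", function(x, kit) standardGeneric("profileMeans"))

#' @rdname ContaminantProfile-class
#' @export
setGeneric("profileNtcIds", function(x) standardGeneric("profileNtcIds"))
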