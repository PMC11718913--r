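#' @export
setGeneric("heritability", function(object, ...) standardGeneric("heritability"))

#' @export
setGeneric("repeatability", function(object, ...) standardGeneric("repeatability"))

#' @export
setGeneric("inbreeding", function(object, ...) standardGeneric("inbreeding"))

#' @export
setGeneric("animalIds", function(object, ...) standardGeneric("animalIds"))

#' @export
setGeneric("genotypeCalls", function(object, ...) standardGeneric("genotypeCalls"))

#' @export
setGeneric("alleleFreqs", function(object, ...) standardGeneric("alleleFreqs"))

#' @export
setGeneric("markerMap", function(object, ...) standardGeneric("markerMap"))

#' @export
setGeneric("breedingValues", function(object, ...) standardGeneric("breedingValues"))

#' @export
setGeneric("varianceComponents", function(object, ...) standardGeneric("varianceComponents"))
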