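#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers, so user code never
#' touches slots directly.
#'
#' @param object an RDCrank S4 object.
#' @param x an RDCrank S4 object.
#' @param ... passed to methods.
#' @return the accessed component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("couplingRecords", function(object) standardGeneric("couplingRecords"))

#' @rdname accessors
#' @export
setGeneric("datasetName", function(object) standardGeneric("datasetName"))

#' @rdname accessors
#' @export
setGeneric("nUsable", function(object) standardGeneric("nUsable"))

#' @rdname accessors
#' @export
setGeneric("atomLabels", function(object) standardGeneric("atomLabels"))

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(object) standardGeneric("atomCoords"))

#' @rdname accessors
#' @export
setGeneric("conformerEnergy", function(object) standardGeneric("conformerEnergy"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("saupeMatrix", function(object) standardGeneric("saupeMatrix"))

#' @rdname accessors
#' @export
setGeneric("tensorComponents", function(object) standardGeneric("tensorComponents"))

#' @rdname accessors
#' @export
setGeneric("tensorEigenvalues", function(object) standardGeneric("tensorEigenvalues"))

#' @rdname accessors
#' @export
setGeneric("axialComponent", function(object) standardGeneric("axialComponent"))

#' @rdname accessors
#' @export
setGeneric("rhombicity", function(object) standardGeneric("rhombicity"))

#' @rdname accessors
#' @export
setGeneric("generalizedOrder", function(object) standardGeneric("generalizedOrder"))

#' @rdname accessors
#' @export
setGeneric("fittedTensor", function(object) standardGeneric("fittedTensor"))

#' @rdname accessors
#' @export
setGeneric("dCalc", function(object) standardGeneric("dCalc"))

#' @rdname accessors
#' @export
setGeneric("conditionNumber", function(object) standardGeneric("conditionNumber"))

#' @rdname accessors
#' @export
setGeneric("populationWeights", function(object) standardGeneric("populationWeights"))

#' @rdname accessors
#' @export
setGeneric("conformers", function(object) standardGeneric("conformers"))

#' @rdname accessors
#' @export
setGeneric("qFactor", function(object) standardGeneric("qFactor"))

#' @rdname accessors
#' @export
setGeneric("chi2Values", function(object) standardGeneric("chi2Values"))

#' @rdname accessors
#' @export
setGeneric("nOverChi2", function(object) standardGeneric("nOverChi2"))

#' @rdname accessors
#' @export
setGeneric("outlierIds", function(object) standardGeneric("outlierIds"))

#' @rdname accessors
#' @export
setGeneric("outlierCount", function(object) standardGeneric("outlierCount"))

#' @rdname accessors
#' @export
setGeneric("isFalsified", function(object) standardGeneric("isFalsified"))

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setGeneric("stateFractions", function(object) standardGeneric("stateFractions"))
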