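#' @rdname GeneObservation-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("predictedPhase", function(x) standardGeneric("predictedPhase"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("switchRates", function(x) standardGeneric("switchRates"))

#' @rdname GeneObservation-accessors
#' @export
setGeneric("switchRates<-", function(x, value) standardGeneric("switchRates<-"))

#' @rdname ThetaPosterior-accessors
#' @export
setGeneric("thetaMedian", function(x) standardGeneric("thetaMedian"))

#' @rdname ThetaPosterior-accessors
#' @export
setGeneric("log2Theta", function(x) standardGeneric("log2Theta"))

#' @rdname ThetaPosterior-accessors
#' @export
setGeneric("meanLog2Theta", function(x) standardGeneric("meanLog2Theta"))

#' @rdname ThetaPosterior-accessors
#' @export
setGeneric("credInt", function(x) standardGeneric("credInt"))

#' @rdname ThetaPosterior-accessors
#' @export
setGeneric("aseMagnitude", function(x) standardGeneric("aseMagnitude"))
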