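#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats cor prcomp sd coef lm predict quantile rnorm runif
#'   var plogis setNames lm.fit
#' @importFrom utils read.csv write.csv head
NULL

#' @export
setGeneric("wavelengths", function(x, ...) standardGeneric("wavelengths"))

#' @export
setGeneric("spectraMatrix", function(x, ...) standardGeneric("spectraMatrix"))

#' @export
setGeneric("chlorophyll", function(x, ...) standardGeneric("chlorophyll"))

#' @export
setGeneric("leafInfo", function(x, ...) standardGeneric("leafInfo"))

#' @export
setGeneric("transformTag", function(x) standardGeneric("transformTag"))

#' @export
setGeneric("transformTag<-", function(x, value) standardGeneric("transformTag<-"))

#' @export
setGeneric("bandValue", function(x, nm, ...) standardGeneric("bandValue"))

#' @export
setGeneric("bandIndex", function(x, nm, ...) standardGeneric("bandIndex"))

#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @export
setGeneric("bandProvenance", function(x) standardGeneric("bandProvenance"))
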