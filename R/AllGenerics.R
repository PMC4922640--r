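#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @export
setGeneric("sexChroms", function(x) standardGeneric("sexChroms"))

#' @export
setGeneric("autosomes", function(x) standardGeneric("autosomes"))

#' @export
setGeneric("cgiTrack", function(x) standardGeneric("cgiTrack"))

#' @export
setGeneric("repeatTrack", function(x) standardGeneric("repeatTrack"))

#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @export
setGeneric("exonModels", function(x) standardGeneric("exonModels"))

#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @export
setGeneric("spikedWindows", function(x) standardGeneric("spikedWindows"))

#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))

#' @export
setGeneric("couplingMap", function(x) standardGeneric("couplingMap"))

#' @export
setGeneric("meanFdr", function(x) standardGeneric("meanFdr"))

#' @export
setGeneric("perSetFractions", function(x) standardGeneric("perSetFractions"))
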