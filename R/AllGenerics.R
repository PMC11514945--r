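#' @rdname stageLabels
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname cellStates
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' @rdname fractions
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname expressionUnit
#' @export
setGeneric("expressionUnit", function(x) standardGeneric("expressionUnit"))

#' @rdname writeTable
#' @export
setGeneric("writeTable", function(x, path, ...) standardGeneric("writeTable"))

#' @rdname mapOrthologs
#' @export
setGeneric("mapOrthologs", function(x, map) standardGeneric("mapOrthologs"))
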